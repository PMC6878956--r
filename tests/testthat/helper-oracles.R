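# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: counting by literal substring enumeration,
# split detection by the four-point condition on path distances.

# Naive k-mer counting: enumerate every window, drop windows with
# non-ACGT characters, optionally fold with the reverse complement.
naiveCountKmers <- function(reads, k, canonical = FALSE) {
  words <- unlist(lapply(toupper(reads), function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  words <- words[grepl("^[ACGT]+$", words)]
  if (canonical && length(words)) {
    rc <- reverseComplement(words)
    words <- ifelse(words <= rc, words, rc)
  }
  if (!length(words)) return(numeric(0))
  tab <- table(words)
  counts <- as.numeric(tab)
  names(counts) <- names(tab)
  counts[order(names(counts), method = "radix")]
}

# Random nucleotide string, optionally salted with ambiguity characters.
randSeq <- function(n, nProb = 0) {
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, n, replace = TRUE)
  if (nProb > 0) {
    hit <- runif(n) < nProb
    s[hit] <- sample(c("N", "R", "Y"), sum(hit), replace = TRUE)
  }
  paste(s, collapse = "")
}

# Random probability vector (possibly sparse), normalized exponentials.
randProb <- function(len, zeroFrac = 0) {
  x <- rexp(len)
  if (zeroFrac > 0) x[runif(len) < zeroFrac] <- 0
  if (sum(x) == 0) x[1] <- 1
  x / sum(x)
}

# Random unrooted binary tree with branch lengths in (lo, hi).
randTree <- function(nLeaves, lo = 0.1, hi = 2.0) {
  t <- ape::rtree(nLeaves, rooted = FALSE,
                  tip.label = sprintf("t%02d", seq_len(nLeaves)))
  t$edge.length <- runif(nrow(t$edge), lo, hi)
  t
}

# Canonical split key used by the package: sorted labels of the side not
# containing the lexicographically smallest leaf.
canonicalKey <- function(side, labs) {
  if (sort(labs, method = "radix")[1] %in% side)
    side <- setdiff(labs, side)
  paste(sort(side, method = "radix"), collapse = ",")
}

# Brute-force non-trivial split enumeration through the four-point
# condition: S is a split iff every quartet (a, b in S; c, d outside)
# is separated, judged on unit-branch-length path distances. Exponential
# in the leaf count; for oracle use on small trees only.
bruteSplits <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  u <- tree
  u$edge.length <- rep(1, nrow(u$edge))
  D <- ape::cophenetic.phylo(u)[labs, labs]
  keys <- character(0)
  for (sz in 2:(n - 2)) {
    for (idx in utils::combn(n, sz, simplify = FALSE)) {
      S <- labs[idx]
      Sc <- setdiff(labs, S)
      ok <- TRUE
      for (ab in utils::combn(S, 2, simplify = FALSE)) {
        for (cd in utils::combn(Sc, 2, simplify = FALSE)) {
          a <- ab[1]; b <- ab[2]; cc <- cd[1]; d <- cd[2]
          if (!(D[a, b] + D[cc, d] <
                min(D[a, cc] + D[b, d], D[a, d] + D[b, cc]))) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (ok) keys <- c(keys, canonicalKey(S, labs))
    }
  }
  sort(unique(keys), method = "radix")
}

hammingDistance <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Root-to-tip path lengths from a named leaf.
tipDepthsFrom <- function(tree, from) {
  ape::cophenetic.phylo(tree)[from, ]
}
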