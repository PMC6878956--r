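#' Bipartitions (splits) of an unrooted tree
#'
#' Every edge of an unrooted leaf-labeled tree induces a bipartition of
#' the leaf set. Splits are returned in canonical form: each is identified
#' by the side *not* containing the lexicographically smallest leaf label,
#' serialized as the sorted, comma-joined labels of that side. Pendant
#' edges induce trivial splits (one leaf against the rest); these are
#' excluded unless `trivial = TRUE`. Rooted binary input is unrooted
#' first, merging the two root edges (their lengths sum), so the split set
#' is independent of an arbitrary rooting. Multifurcating trees are
#' handled as-is: they simply have fewer internal edges.
#'
#' @param tree A `phylo` tree.
#' @param trivial Also return the pendant (single-leaf) splits.
#' @return A data frame with columns `split` (canonical key), `length`
#'   (branch length, 0 if the tree carries none), and `trivial`.
#' @seealso [symmetricDistance()], [branchScoreDistance()]
#' @export
bipartitions <- function(tree, trivial = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  if (nt < 2L) stop("tree must have at least 2 leaves")
  if (ape::is.rooted(tree) && nt > 2L) tree <- ape::unroot(tree)
  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  el <- tree$edge.length %||% rep(0, nrow(edge))
  labs <- tree$tip.label
  smallest <- radixMin(labs)
  desc <- vector("list", nt + tree$Nnode)
  desc[seq_len(nt)] <- as.list(seq_len(nt))
  keys <- character(nrow(edge))
  isTrivial <- logical(nrow(edge))
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]
    ch <- edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
    side <- labs[desc[[ch]]]
    if (smallest %in% side) side <- setdiff(labs, side)
    keys[e] <- paste(radixSort(side), collapse = ",")
    isTrivial[e] <- length(side) %in% c(1L, nt - 1L)
  }
  df <- data.frame(split = keys, length = el, trivial = isTrivial,
                   stringsAsFactors = FALSE)
  # distinct edges of a tree always induce distinct splits, but aggregate
  # defensively so degenerate inputs cannot double-count
  if (anyDuplicated(df$split)) {
    agg <- tapply(df$length, df$split, sum)
    df <- data.frame(split = names(agg), length = as.numeric(agg),
                     trivial = isTrivial[match(names(agg), df$split)],
                     stringsAsFactors = FALSE)
  }
  if (!trivial) df <- df[!df$trivial, , drop = FALSE]
  rownames(df) <- NULL
  df[order(df$split, method = "radix"), , drop = FALSE]
}

.checkSameLeaves <- function(t1, t2) {
  l1 <- t1$tip.label
  l2 <- t2$tip.label
  if (!setequal(l1, l2)) {
    only1 <- setdiff(l1, l2)
    only2 <- setdiff(l2, l1)
    stop(sprintf(
      "leaf-set mismatch: only in tree 1: {%s}; only in tree 2: {%s}",
      paste(only1, collapse = ", "), paste(only2, collapse = ", ")))
  }
}

#' Robinson-Foulds symmetric distance between trees
#'
#' Counts the non-trivial bipartitions present in exactly one of the two
#' trees: `|S1 \\ S2| + |S2 \\ S1|`. Zero iff the unrooted topologies are
#' identical; bounded by `2 (n - 3)` for binary trees on `n` leaves.
#' Topology-only -- branch lengths are ignored.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Non-negative integer (even when both trees are binary).
#' @seealso [branchScoreDistance()], [bipartitions()]
#' @export
symmetricDistance <- function(t1, t2) {
  .checkSameLeaves(t1, t2)
  s1 <- bipartitions(t1, trivial = FALSE)$split
  s2 <- bipartitions(t2, trivial = FALSE)$split
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Branch-score distance between trees
#'
#' Kuhner-Felsenstein branch score: over the union of all bipartitions of
#' the two trees (including the trivial pendant splits, which carry length
#' signal), sum the squared branch-length differences, taking length 0 for
#' a split absent from a tree. By default the square root of the sum is
#' returned, the form that is a metric; `takeSqrt = FALSE` returns the raw
#' sum of squares, as some implementations report. With all branch lengths
#' equal to 1 and `takeSqrt = FALSE` the value equals the number of
#' unshared splits.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @param takeSqrt Return the square root of the sum of squares.
#' @return Non-negative real.
#' @export
branchScoreDistance <- function(t1, t2, takeSqrt = TRUE) {
  .checkSameLeaves(t1, t2)
  b1 <- bipartitions(t1, trivial = TRUE)
  b2 <- bipartitions(t2, trivial = TRUE)
  keys <- union(b1$split, b2$split)
  l1 <- b1$length[match(keys, b1$split)]
  l2 <- b2$length[match(keys, b2$split)]
  l1[is.na(l1)] <- 0
  l2[is.na(l2)] <- 0
  ss <- sum((l1 - l2)^2)
  if (takeSqrt) sqrt(ss) else ss
}

#' All-pairs tree distances
#'
#' Convenience batch comparison: symmetric and branch-score distances for
#' every pair of trees, the table behind tree-stability heatmaps.
#'
#' @param trees Named list of `phylo` trees over the same leaf set.
#' @param takeSqrt Passed to [branchScoreDistance()].
#' @return Data frame with columns `tree1`, `tree2`, `sd`, `bsd`.
#' @export
treeDistanceTable <- function(trees, takeSqrt = TRUE) {
  stopifnot(is.list(trees), length(trees) >= 2L)
  nm <- names(trees) %||% paste0("tree", seq_along(trees))
  pairs <- utils::combn(seq_along(trees), 2L)
  data.frame(
    tree1 = nm[pairs[1L, ]],
    tree2 = nm[pairs[2L, ]],
    sd = apply(pairs, 2L, function(ij)
      symmetricDistance(trees[[ij[1L]]], trees[[ij[2L]]])),
    bsd = apply(pairs, 2L, function(ij)
      branchScoreDistance(trees[[ij[1L]]], trees[[ij[2L]]],
                          takeSqrt = takeSqrt)),
    stringsAsFactors = FALSE
  )
}
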