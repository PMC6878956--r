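# Internal: coerce DistanceMatrix / dist / labeled matrix to a plain
# labeled square matrix.
.asSquareMatrix <- function(d) {
  if (is(d, "DistanceMatrix")) {
    list(m = d@values, labels = d@labels)
  } else if (inherits(d, "dist")) {
    m <- as.matrix(d)
    list(m = unname(m), labels = rownames(m) %||% paste0("S", seq_len(nrow(m))))
  } else if (is.matrix(d)) {
    list(m = unname(d), labels = rownames(d) %||% paste0("S", seq_len(nrow(d))))
  } else {
    stop("expected a DistanceMatrix, dist, or square matrix")
  }
}

# Quote a leaf label for newick output if it contains reserved characters.
.quoteLabel <- function(x) {
  needs <- grepl("[][ (),:;']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration using the Studier-Keppler criterion
#' `Q_ij = (r - 2) d_ij - R_i - R_j`. For an additive (tree-metric) input
#' the unique generating topology and its exact branch lengths are
#' recovered. The algorithm is fully deterministic: ties in `Q` are broken
#' by the smallest `(i, j)` index pair, replacing the input-order
#' randomization some implementations use.
#'
#' Negative branch lengths (possible on non-additive inputs) are kept by
#' default, as classical implementations do. With `clampNegative = TRUE` a
#' negative estimate is set to 0 and the deficit transferred to the
#' adjacent branch created at the same join (for the final trifurcation,
#' split equally between the other two branches), preserving path lengths
#' approximately while keeping the tree interpretable.
#'
#' @param d A [DistanceMatrix-class], `dist`, or labeled square matrix with
#'   at least 3 taxa, symmetric with zero diagonal.
#' @param clampNegative Clamp negative branch lengths to zero.
#' @return Unrooted `phylo` tree (trifurcating root node).
#' @examples
#' m <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighborJoining(m)  # branches A:0.5, B:1.5, C:2.5
#' @seealso [writeNewick()], [symmetricDistance()]
#' @export
neighborJoining <- function(d, clampNegative = FALSE) {
  sq <- .asSquareMatrix(d)
  m <- sq$m
  labs <- sq$labels
  n <- nrow(m)
  if (n < 3L) stop("neighbor joining requires at least 3 taxa")
  if (any(!is.finite(m))) stop("invalid distances: NaN or infinite entries")
  if (any(m < 0)) stop("invalid distances: negative entries")
  if (any(abs(m - t(m)) > 0)) stop("distance matrix must be symmetric")
  nodes <- .quoteLabel(labs)
  while (n > 3L) {
    R <- rowSums(m)
    Q <- (n - 2) * m - outer(R, R, "+")
    diag(Q) <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pick <- order(cand[, 1L], cand[, 2L])[1L]
    i <- cand[pick, 1L]
    j <- cand[pick, 2L]
    li <- m[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    lj <- m[i, j] - li
    if (clampNegative) {
      if (li < 0) { lj <- lj + li; li <- 0 }
      if (lj < 0) { li <- li + lj; lj <- 0 }
    }
    newNode <- sprintf("(%s:%s,%s:%s)", nodes[i], fmtFull(li),
                       nodes[j], fmtFull(lj))
    dk <- (m[i, ] + m[j, ] - m[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    m <- rbind(cbind(m[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    nodes <- c(nodes[keep], newNode)
    n <- n - 1L
  }
  a <- (m[1L, 2L] + m[1L, 3L] - m[2L, 3L]) / 2
  b <- m[1L, 2L] - a
  cc <- m[1L, 3L] - a
  if (clampNegative) {
    v <- c(a, b, cc)
    for (idx in 1:3) {
      if (v[idx] < 0) {
        oth <- setdiff(1:3, idx)
        v[oth] <- v[oth] + v[idx] / 2
        v[idx] <- 0
      }
    }
    a <- v[1L]; b <- v[2L]; cc <- v[3L]
  }
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1L], fmtFull(a),
                 nodes[2L], fmtFull(b), nodes[3L], fmtFull(cc))
  ape::read.tree(text = nwk)
}

#' Serialize a tree to newick with canonical child ordering
#'
#' Writes standard newick with branch lengths, terminated by `;`. Children
#' of every node are ordered by their lexicographically smallest descendant
#' leaf label, so topologically identical trees serialize to byte-identical
#' strings regardless of construction order. Labels containing
#' newick-reserved characters are single-quoted (an embedded quote is
#' doubled, per the newick standard; note the bundled parser cannot
#' re-read labels with embedded quotes, an upstream limitation).
#'
#' @param tree A `phylo` tree.
#' @param path Optional file to write to.
#' @return The newick string (invisibly when `path` is given).
#' @seealso [parseNewick()]
#' @export
writeNewick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  edge <- tree$edge
  el <- tree$edge.length
  kids <- split(seq_len(nrow(edge)), edge[, 1L])
  root <- unique(edge[!(edge[, 1L] %in% edge[, 2L]), 1L])
  ser <- function(node, edgeIdx) {
    if (node <= nt) {
      lab <- tree$tip.label[node]
      s <- .quoteLabel(lab)
      mn <- lab
    } else {
      parts <- lapply(kids[[as.character(node)]], function(e) {
        ser(edge[e, 2L], e)
      })
      mins <- vapply(parts, `[[`, character(1L), "mn")
      ord <- order(mins, method = "radix")
      s <- paste0("(", paste(vapply(parts[ord], `[[`, character(1L), "s"),
                             collapse = ","), ")")
      mn <- mins[ord[1L]]
    }
    if (!is.null(edgeIdx) && !is.null(el) && !is.na(el[edgeIdx]))
      s <- paste0(s, ":", fmtLen(el[edgeIdx]))
    list(s = s, mn = mn)
  }
  out <- paste0(ser(root, NULL)$s, ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Parse a newick string
#'
#' Validates parenthesis balance and termination (reporting the failing
#' character position) before handing the string to the `ape` parser.
#' Missing branch lengths default to 0.
#'
#' @param s A single newick string.
#' @return A `phylo` tree.
#' @export
parseNewick <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- 0L
  inQuote <- FALSE
  semi <- NA_integer_
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    if (ch == "'") inQuote <- !inQuote
    if (inQuote) next
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error: unbalanced ')' at position %d", pos))
    } else if (ch == ";") { semi <- pos; break }
  }
  if (depth > 0L)
    stop(sprintf("newick parse error: %d unclosed '(' at end of input", depth))
  if (is.na(semi))
    stop("newick parse error: missing ';' terminator")
  rest <- paste(chars[-seq_len(semi)], collapse = "")
  if (nzchar(trimws(rest)))
    stop(sprintf("newick parse error: trailing characters at position %d",
                 semi + 1L))
  tree <- tryCatch(
    ape::read.tree(text = substr(s, 1L, semi)),
    error = function(e) stop(sprintf("newick parse error: %s",
                                     conditionMessage(e)), call. = FALSE)
  )
  if (is.null(tree)) stop("newick parse error: not a valid tree")
  # the ape parser keeps surrounding quotes on quoted labels; strip them
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", substr(x[q], 2L, nchar(x[q]) - 1L), fixed = TRUE)
    x
  }
  tree$tip.label <- unquote(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- unquote(tree$node.label)
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else {
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and returns the top `dims`
#' eigenvector coordinates scaled by the square roots of the eigenvalues.
#' Negative eigenvalues (which arise when the divergences are not exactly
#' Euclidean) are clamped to zero, the standard Torgerson treatment; all
#' eigenvalues are retained for diagnostics. Each coordinate axis' sign is
#' fixed by making its largest-magnitude entry positive, so embeddings are
#' reproducible.
#'
#' @param d A [DistanceMatrix-class], `dist`, or labeled square matrix.
#' @param dims Number of embedding dimensions (default 2; must be < n).
#' @return An [MdsEmbedding-class].
#' @seealso [writeMdsTable()]
#' @export
classicalMds <- function(d, dims = 2L) {
  sq <- .asSquareMatrix(d)
  n <- nrow(sq$m)
  dims <- as.integer(dims)
  if (dims < 1L || dims >= n)
    stop("dims must satisfy 1 <= dims < number of samples")
  fit <- stats::cmdscale(sq$m, k = dims, eig = TRUE)
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < dims) {
    # cmdscale drops axes with non-positive eigenvalues; pad with zeros
    # (the clamped-eigenvalue coordinates are exactly zero).
    pad <- matrix(0, n, dims - ncol(pts))
    pts <- cbind(pts, pad)
  }
  for (jj in seq_len(ncol(pts))) {
    col <- pts[, jj]
    if (any(col != 0) && col[which.max(abs(col))] < 0)
      pts[, jj] <- -col
  }
  rownames(pts) <- NULL
  new("MdsEmbedding", sampleIds = sq$labels, points = pts,
      eigenvalues = fit$eig)
}

#' Write MDS coordinates as a tab-separated table
#'
#' First line is a `#`-prefixed comment carrying the eigenvalue list; then
#' a header and one `label / axis1 / axis2 / ...` row per sample.
#'
#' @param mds An [MdsEmbedding-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeMdsTable <- function(mds, path) {
  stopifnot(is(mds, "MdsEmbedding"))
  pts <- mds@points
  hdr <- paste(c("sample", paste0("axis", seq_len(ncol(pts)))),
               collapse = "\t")
  rows <- paste0(mds@sampleIds, "\t",
                 apply(pts, 1L, function(r) paste(fmtLen(r),
                                                  collapse = "\t")))
  writeLines(c(paste0("# eigenvalues: ",
                      paste(fmtLen(mds@eigenvalues), collapse = " ")),
               hdr, rows), path)
  invisible(path)
}
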