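#' Kullback-Leibler divergence in bits
#'
#' Computes `sum(p_i * log2(p_i / m_i))` with the standard convention
#' `0 * log2(0 / m) = 0`. When `m` is a Jensen-Shannon mixture it is
#' positive wherever `p` is, so the divergence is always finite there.
#'
#' @param p,m Aligned probability vectors; `p` must sum to 1 and `m` must
#'   be positive wherever `p` is.
#' @return Non-negative divergence in bits.
#' @export
klDivergence <- function(p, m) {
  if (length(p) != length(m))
    stop("alignment error: p and m must have the same length")
  pos <- p > 0
  if (any(m[pos] <= 0))
    stop("infinite divergence: p has mass where m is zero")
  sum(p[pos] * log2(p[pos] / m[pos]))
}

#' Jensen-Shannon divergence between probability vectors
#'
#' `JS(P, Q) = 1/2 KL(P, M) + 1/2 KL(Q, M)` with the mixture
#' `M = (P + Q) / 2` and logarithms in base 2, so the divergence is
#' symmetric, zero iff `P = Q`, and bounded by 1 (attained on disjoint
#' supports). Its square root is a metric.
#'
#' @param p,q Probability vectors aligned to the same k-mer axis.
#' @return Divergence in `[0, 1]`.
#' @examples
#' jsDivergence(c(1, 0), c(0, 1))            # 1: disjoint supports
#' jsDivergence(c(0.5, 0.5), c(0.25, 0.75))  # ~0.0488
#' @seealso [hellingerDistance()], [pairwiseDistances()]
#' @export
jsDivergence <- function(p, q) {
  if (length(p) != length(q))
    stop("alignment error: p and q must have the same length")
  m <- (p + q) / 2
  0.5 * klDivergence(p, m) + 0.5 * klDivergence(q, m)
}

#' Hellinger distance between probability vectors
#'
#' The standard square-root form
#' `H(P, Q) = sqrt(1/2 * sum((sqrt(p_i) - sqrt(q_i))^2))`, a metric in
#' `[0, 1]` that is 0 iff `P = Q` and 1 iff the supports are disjoint.
#' `form = "literal"` instead computes the scaled Euclidean distance
#' `sqrt(1/2 * sum((p_i - q_i)^2))` on the raw frequencies (no inner
#' radicals), exposed for comparison with implementations that read the
#' definition without the element-wise square roots.
#'
#' @param p,q Probability vectors aligned to the same k-mer axis.
#' @param form `"sqrt"` (standard Hellinger, default) or `"literal"`.
#' @return Distance in `[0, 1]`.
#' @examples
#' hellingerDistance(c(1, 0), c(0, 1))            # 1
#' hellingerDistance(c(0.5, 0.5), c(0.25, 0.75))  # ~0.1846
#' @export
hellingerDistance <- function(p, q, form = c("sqrt", "literal")) {
  if (length(p) != length(q))
    stop("alignment error: p and q must have the same length")
  form <- match.arg(form)
  if (form == "sqrt") {
    sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2))
  } else {
    sqrt(0.5 * sum((p - q)^2))
  }
}

#' Construct a labeled distance matrix
#'
#' @param values Square numeric matrix (symmetric, zero diagonal).
#' @param labels Sample labels; defaults to the matrix rownames.
#' @param metric Metric name.
#' @return A [DistanceMatrix-class].
#' @export
DistanceMatrix <- function(values, labels = rownames(values),
                           metric = "custom") {
  if (is.null(labels)) labels <- paste0("S", seq_len(nrow(values)))
  values <- unname(as.matrix(values))
  new("DistanceMatrix", labels = as.character(labels), values = values,
      metric = metric)
}

#' Pairwise sample distances from a frequency matrix
#'
#' Computes the chosen divergence between every pair of sample rows. Each
#' pair is computed once and mirrored, so the result is exactly symmetric
#' with an exactly zero diagonal; the fixed k-mer order of the input makes
#' the result bit-reproducible across runs.
#'
#' @param fm A [FrequencyMatrix-class] with at least 2 rows.
#' @param metric `"jsd"` (Jensen-Shannon divergence, default) or
#'   `"hellinger"`.
#' @param hellingerForm Passed to [hellingerDistance()] as `form`.
#' @return A [DistanceMatrix-class].
#' @export
pairwiseDistances <- function(fm, metric = c("jsd", "hellinger"),
                              hellingerForm = "sqrt") {
  stopifnot(is(fm, "FrequencyMatrix"))
  metric <- match.arg(metric)
  v <- fm@values
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 samples")
  bad <- which(abs(rowSums(v) - 1) > 1e-6)
  if (length(bad))
    stop(sprintf("degenerate row(s) not summing to 1: %s",
                 paste(fm@sampleIds[bad], collapse = ", ")))
  f <- if (metric == "jsd") jsDivergence else
    function(p, q) hellingerDistance(p, q, form = hellingerForm)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dij <- f(v[i, ], v[j, ])
      # guard against representation error just past the analytic bounds
      dij <- min(max(dij, 0), 1)
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  new("DistanceMatrix", labels = fm@sampleIds, values = d, metric = metric)
}

#' Write a distance matrix to disk
#'
#' `format = "phylip"` writes the PHYLIP square format: the first line is
#' the number of taxa, each following row a name plus the distances. In
#' relaxed mode (default) names are written in full, tab-separated; in
#' strict mode names are padded/truncated to 10 characters and distances
#' are space-separated with 6 decimals, for strict PHYLIP consumers.
#' `format = "tsv"` writes a labeled square table at full precision
#' (header row and row names), suitable for plotting and byte-exact
#' comparison across runs.
#'
#' @param dm A [DistanceMatrix-class].
#' @param path Output file.
#' @param format `"tsv"` or `"phylip"`.
#' @param strict Use strict 10-character PHYLIP names.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(dm, path, format = c("tsv", "phylip"),
                                strict = FALSE) {
  stopifnot(is(dm, "DistanceMatrix"))
  format <- match.arg(format)
  v <- dm@values
  labs <- dm@labels
  lines <- if (format == "phylip") {
    rows <- if (strict) {
      nm <- sprintf("%-10s", substr(labs, 1L, 10L))
      paste0(nm, apply(v, 1L, function(r) paste(sprintf("%.6f", r),
                                                collapse = " ")))
    } else {
      paste0(labs, "\t",
             apply(v, 1L, function(r) paste(sprintf("%.10g", r),
                                            collapse = "\t")))
    }
    c(sprintf("%5d", length(labs)), rows)
  } else {
    c(paste(c("sample", labs), collapse = "\t"),
      paste0(labs, "\t",
             apply(v, 1L, function(r) paste(fmtFull(r), collapse = "\t"))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a tab-separated labeled distance matrix
#'
#' Inverse of `writeDistanceMatrix(format = "tsv")`.
#'
#' @param path File written by [writeDistanceMatrix()].
#' @param metric Metric name to attach.
#' @return A [DistanceMatrix-class].
#' @export
readDistanceMatrix <- function(path, metric = "custom") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
  DistanceMatrix(as.matrix(tab), labels = rownames(tab), metric = metric)
}
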