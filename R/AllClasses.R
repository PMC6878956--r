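#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib KmerPhylo, .registration = TRUE
NULL

setOldClass("phylo")

#' KmerProfile: per-sample k-mer occurrence counts
#'
#' Sparse map from k-mer to occurrence count for one sample. K-mers are
#' stored sorted lexicographically (byte order); with `canonical = TRUE`
#' every stored k-mer is the lexicographically smaller of the word and its
#' reverse complement, which makes counting strand-neutral.
#'
#' @slot k Integer word length (1-31).
#' @slot counts Named numeric vector of positive integral counts; names are
#'   the k-mers, sorted.
#' @slot total Sum of all counts.
#' @slot sampleId Sample label.
#' @slot canonical Whether k-mers were folded with their reverse complement.
#'
#' @seealso [countKmers()], [normalizeProfile()], [mergeProfiles()]
#' @export
setClass("KmerProfile",
  representation(
    k = "integer",
    counts = "numeric",
    total = "numeric",
    sampleId = "character",
    canonical = "logical"
  )
)

setValidity("KmerProfile", function(object) {
  msg <- character(0)
  k <- object@k
  if (length(k) != 1L || is.na(k) || k < 1L || k > 31L)
    msg <- c(msg, "k must be a single integer in [1, 31]")
  cnt <- object@counts
  nm <- names(cnt)
  if (length(cnt) > 0L) {
    if (is.null(nm) || anyNA(nm))
      msg <- c(msg, "counts must be a named vector")
    else {
      if (any(nchar(nm) != k))
        msg <- c(msg, "every stored k-mer must have length exactly k")
      if (any(!grepl("^[ACGT]+$", nm)))
        msg <- c(msg, "k-mers must be over the alphabet {A,C,G,T}")
      if (anyDuplicated(nm))
        msg <- c(msg, "duplicated k-mers in counts")
      if (isTRUE(object@canonical) && length(msg) == 0L) {
        # bounded spot-check: full reverse-complementation of very large
        # profiles is too costly to run on every construction
        chk <- nm[seq_len(min(length(nm), 10000L))]
        if (any(chk > reverseComplement(chk)))
          msg <- c(msg, "canonical profile contains non-canonical k-mers")
      }
    }
    if (any(!is.finite(cnt)) || any(cnt < 1) || any(cnt != floor(cnt)))
      msg <- c(msg, "counts must be positive integers")
  }
  if (!isTRUE(all.equal(object@total, sum(cnt), tolerance = 0)))
    msg <- c(msg, "total must equal the sum of counts")
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(msg)) msg else TRUE
})

setMethod("show", "KmerProfile", function(object) {
  cat(sprintf(
    "KmerProfile '%s': %d distinct %d-mers, total %s (%s)\n",
    object@sampleId, length(object@counts), object@k,
    format(object@total, big.mark = ","),
    if (object@canonical) "canonical" else "stranded"
  ))
})

#' FrequencyMatrix: samples-by-k-mer relative frequencies
#'
#' Dense matrix of per-sample k-mer frequencies over the sorted union of
#' k-mers observed in the merged profiles. Each row is a probability vector
#' (sums to 1); a k-mer absent from a sample has entry exactly 0.
#'
#' @slot sampleIds Ordered sample labels (row order).
#' @slot kmers Ordered union of k-mers (strictly increasing, byte order).
#' @slot values Numeric matrix, samples in rows, k-mers in columns.
#'
#' @seealso [mergeProfiles()], [pairwiseDistances()]
#' @export
setClass("FrequencyMatrix",
  representation(
    sampleIds = "character",
    kmers = "character",
    values = "matrix"
  )
)

setValidity("FrequencyMatrix", function(object) {
  msg <- character(0)
  v <- object@values
  if (nrow(v) != length(object@sampleIds))
    msg <- c(msg, "row count must match sampleIds")
  if (ncol(v) != length(object@kmers))
    msg <- c(msg, "column count must match kmers")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "duplicated sample ids")
  km <- object@kmers
  if (length(km) > 1L && (anyDuplicated(km) ||
      !identical(km, sort(km, method = "radix"))))
    msg <- c(msg, "k-mers must be strictly increasing lexicographically")
  if (length(v) > 0L) {
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      msg <- c(msg, "all entries must lie in [0, 1]")
    if (any(abs(rowSums(v) - 1) > 1e-9))
      msg <- c(msg, "each row must sum to 1 within 1e-9")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "FrequencyMatrix", function(object) {
  cat(sprintf(
    "FrequencyMatrix: %d samples x %d k-mers (k = %d)\n",
    length(object@sampleIds), length(object@kmers),
    if (length(object@kmers)) nchar(object@kmers[1L]) else NA_integer_
  ))
  cat("samples:", paste(utils::head(object@sampleIds, 8L), collapse = ", "),
      if (length(object@sampleIds) > 8L) "..." else "", "\n")
})

#' DistanceMatrix: labeled symmetric pairwise distances
#'
#' Square, symmetric, zero-diagonal matrix of pairwise sample distances.
#' For the divergence metrics (`jsd`, `hellinger`) all entries lie in
#' \[0, 1\]; other metric names (for example path distances on a tree) are
#' only required to be non-negative.
#'
#' @slot labels Ordered sample names.
#' @slot values Square numeric matrix of distances.
#' @slot metric Metric name, e.g. `"jsd"` or `"hellinger"`.
#'
#' @seealso [pairwiseDistances()], [neighborJoining()], [classicalMds()]
#' @export
setClass("DistanceMatrix",
  representation(
    labels = "character",
    values = "matrix",
    metric = "character"
  )
)

setValidity("DistanceMatrix", function(object) {
  msg <- character(0)
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (nrow(v) != length(object@labels))
    msg <- c(msg, "labels must match matrix dimension")
  if (anyDuplicated(object@labels)) msg <- c(msg, "duplicated labels")
  if (length(v) > 0L) {
    if (any(!is.finite(v))) msg <- c(msg, "distances must be finite")
    else {
      if (!identical(v, t(v))) msg <- c(msg, "matrix must be exactly symmetric")
      if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be exactly zero")
      if (any(v < 0)) msg <- c(msg, "distances must be non-negative")
      if (length(object@metric) == 1L &&
          object@metric %in% c("jsd", "hellinger") && any(v > 1))
        msg <- c(msg, "divergence distances must lie in [0, 1]")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix (%s): %d samples\n",
              object@metric, length(object@labels)))
  if (length(object@labels) <= 8L) {
    m <- object@values
    dimnames(m) <- list(object@labels, object@labels)
    print(round(m, 4L))
  } else {
    cat("samples:", paste(utils::head(object@labels, 8L), collapse = ", "),
        "...\n")
  }
})

#' MdsEmbedding: classical multidimensional scaling coordinates
#'
#' Torgerson (classical) MDS embedding of a distance matrix: coordinates
#' are centered and each axis' sign is fixed so that its largest-magnitude
#' entry is positive. Eigenvalues of the doubly centered Gram matrix are
#' retained for diagnostics (negative eigenvalues indicate the input
#' distances are not exactly Euclidean).
#'
#' @slot sampleIds Sample labels.
#' @slot points Numeric matrix, one row per sample, `dims` columns.
#' @slot eigenvalues Eigenvalues of the centered Gram matrix (all of them,
#'   not just the retained axes).
#'
#' @seealso [classicalMds()]
#' @export
setClass("MdsEmbedding",
  representation(
    sampleIds = "character",
    points = "matrix",
    eigenvalues = "numeric"
  )
)

setValidity("MdsEmbedding", function(object) {
  msg <- character(0)
  if (nrow(object@points) != length(object@sampleIds))
    msg <- c(msg, "points must have one row per sample")
  if (length(object@points) > 0L &&
      any(abs(colMeans(object@points)) > 1e-9))
    msg <- c(msg, "coordinates must be centered (column means 0 within 1e-9)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MdsEmbedding", function(object) {
  cat(sprintf("MdsEmbedding: %d samples in %d dimensions\n",
              length(object@sampleIds), ncol(object@points)))
  cat("eigenvalues:",
      paste(signif(utils::head(object@eigenvalues, 5L), 4L), collapse = ", "),
      if (length(object@eigenvalues) > 5L) "..." else "", "\n")
})

#' LineageSpec: plan for a simulated clonal-evolution cohort
#'
#' Parameters of the built-in clonal lineage simulator. The lineage plan is
#' fixed: a normal genome N is mutated once into a cancerous genome C, C is
#' mutated three separate times into subclone founders C1a, C2a, C3a, and
#' each founder is mutated two successive times (the "b" and "c" samples).
#' Every step applies the same per-step mutation budget.
#'
#' @slot referenceLength Reference genome length in bases (>= 1000).
#' @slot nSnv Single-nucleotide variants per step.
#' @slot nIndel Short insertions/deletions per step (geometric lengths).
#' @slot nSv Structural variants per step (deletion, tandem duplication,
#'   inversion; drawn uniformly).
#' @slot indelMeanLength Mean of the geometric indel length distribution.
#' @slot svSizeRange Structural-variant size range in bases
#'   (minimum >= 50, maximum < 10% of the reference length).
#' @slot gc GC fraction of the generated reference.
#' @slot seed RNG seed controlling the whole lineage.
#'
#' @seealso [simulateLineage()], [simulateCohort()]
#' @export
setClass("LineageSpec",
  representation(
    referenceLength = "numeric",
    nSnv = "integer",
    nIndel = "integer",
    nSv = "integer",
    indelMeanLength = "numeric",
    svSizeRange = "numeric",
    gc = "numeric",
    seed = "numeric"
  )
)

setValidity("LineageSpec", function(object) {
  msg <- character(0)
  if (object@referenceLength < 1000)
    msg <- c(msg, "referenceLength must be at least 1000 bases")
  if (any(c(object@nSnv, object@nIndel, object@nSv) < 0L))
    msg <- c(msg, "mutation budgets must be non-negative")
  if (object@indelMeanLength < 1)
    msg <- c(msg, "indelMeanLength must be >= 1")
  if (length(object@svSizeRange) != 2L ||
      object@svSizeRange[1L] > object@svSizeRange[2L])
    msg <- c(msg, "svSizeRange must be c(min, max) with min <= max")
  else if (object@nSv > 0L && (object@svSizeRange[1L] < 50 ||
           object@svSizeRange[2L] >= 0.1 * object@referenceLength))
    msg <- c(msg, "SV sizes must be >= 50 bases and < 10% of the reference")
  if (object@gc < 0 || object@gc > 1)
    msg <- c(msg, "gc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ReadSimSpec: parameters of the shotgun read simulator
#'
#' @slot readLength Read length in bases.
#' @slot coverage Mean fold coverage (> 0).
#' @slot errorRate Per-base substitution error rate, in \[0, 0.1\].
#' @slot paired Whether to emit paired-end mates from each fragment.
#' @slot insertMean Mean fragment (insert) length for paired-end mode.
#' @slot insertSd Standard deviation of the fragment length.
#' @slot seed RNG seed.
#'
#' @seealso [simulateReads()]
#' @export
setClass("ReadSimSpec",
  representation(
    readLength = "integer",
    coverage = "numeric",
    errorRate = "numeric",
    paired = "logical",
    insertMean = "numeric",
    insertSd = "numeric",
    seed = "numeric"
  )
)

setValidity("ReadSimSpec", function(object) {
  msg <- character(0)
  if (object@readLength < 1L) msg <- c(msg, "readLength must be positive")
  if (object@coverage <= 0) msg <- c(msg, "coverage must be > 0")
  if (object@errorRate < 0 || object@errorRate > 0.1)
    msg <- c(msg, "errorRate must lie in [0, 0.1]")
  if (isTRUE(object@paired) && object@insertMean < 2 * object@readLength)
    msg <- c(msg, "insertMean must be at least twice the read length")
  if (length(msg)) msg else TRUE
})

#' LineageTruth: generating tree and mutation ledger of a simulation
#'
#' Ground truth attached to a simulated cohort: the generating tree (leaves
#' are the sequenced samples; branch lengths are mutation-event counts per
#' step), the full per-step mutation ledger, and all RNG seeds used, so a
#' cohort can be replayed exactly.
#'
#' @slot tree `phylo` truth tree.
#' @slot ledger Data frame of mutation events (sample, type, pos, length,
#'   ref, alt), in application order.
#' @slot seeds Named numeric vector of all seeds used.
#'
#' @seealso [simulateLineage()], [replayLedger()]
#' @export
setClass("LineageTruth",
  representation(
    tree = "phylo",
    ledger = "data.frame",
    seeds = "numeric"
  )
)

setMethod("show", "LineageTruth", function(object) {
  cat(sprintf("LineageTruth: %d samples, %d ledger events\n",
              length(object@tree$tip.label), nrow(object@ledger)))
})
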