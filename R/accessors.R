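#' Accessors for KmerPhylo classes
#'
#' Small accessor generics so that code never reaches into slots directly:
#' `sampleIds()` returns the ordered sample labels of a container,
#' `kmers()` the ordered k-mer axis, `kmerLength()` the word length,
#' `kmerCounts()` / `profileTotal()` the raw counts of a profile,
#' `distanceMetric()` the metric name of a distance matrix,
#' `mdsEigenvalues()` the Gram-matrix eigenvalues of an embedding, and
#' `truthTree()` / `mutationLedger()` the components of a simulation truth.
#'
#' @param x An object of the documented class.
#' @return See the individual generic descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("kmers", function(x) standardGeneric("kmers"))

#' @rdname accessors
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))

#' @rdname accessors
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))

#' @rdname accessors
#' @export
setGeneric("profileTotal", function(x) standardGeneric("profileTotal"))

#' @rdname accessors
#' @export
setGeneric("isCanonical", function(x) standardGeneric("isCanonical"))

#' @rdname accessors
#' @export
setGeneric("distanceMetric", function(x) standardGeneric("distanceMetric"))

#' @rdname accessors
#' @export
setGeneric("mdsEigenvalues", function(x) standardGeneric("mdsEigenvalues"))

#' @rdname accessors
#' @export
setGeneric("truthTree", function(x) standardGeneric("truthTree"))

#' @rdname accessors
#' @export
setGeneric("mutationLedger", function(x) standardGeneric("mutationLedger"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "KmerProfile", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("sampleIds", "FrequencyMatrix", function(x) x@sampleIds)

#' @rdname accessors
#' @export
setMethod("sampleIds", "DistanceMatrix", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("sampleIds", "MdsEmbedding", function(x) x@sampleIds)

#' @rdname accessors
#' @export
setMethod("kmers", "KmerProfile", function(x) names(x@counts))

#' @rdname accessors
#' @export
setMethod("kmers", "FrequencyMatrix", function(x) x@kmers)

#' @rdname accessors
#' @export
setMethod("kmerLength", "KmerProfile", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("kmerLength", "FrequencyMatrix", function(x) {
  if (length(x@kmers)) nchar(x@kmers[1L]) else NA_integer_
})

#' @rdname accessors
#' @export
setMethod("kmerCounts", "KmerProfile", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("profileTotal", "KmerProfile", function(x) x@total)

#' @rdname accessors
#' @export
setMethod("isCanonical", "KmerProfile", function(x) x@canonical)

#' @rdname accessors
#' @export
setMethod("distanceMetric", "DistanceMatrix", function(x) x@metric)

#' @rdname accessors
#' @export
setMethod("mdsEigenvalues", "MdsEmbedding", function(x) x@eigenvalues)

#' @rdname accessors
#' @export
setMethod("truthTree", "LineageTruth", function(x) x@tree)

#' @rdname accessors
#' @export
setMethod("mutationLedger", "LineageTruth", function(x) x@ledger)

#' Coerce containers to base matrices
#'
#' `as.matrix()` on a [FrequencyMatrix-class] returns the samples-by-k-mer
#' frequency matrix with dimnames; on a [DistanceMatrix-class] the labeled
#' square distance matrix; on an [MdsEmbedding-class] the coordinate matrix
#' with samples as rownames.
#'
#' @param x Object to coerce.
#' @param ... Ignored.
#' @return A base matrix with dimnames.
#' @name as.matrix-methods
NULL

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "FrequencyMatrix", function(x, ...) {
  m <- x@values
  dimnames(m) <- list(x@sampleIds, x@kmers)
  m
})

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) {
  m <- x@values
  dimnames(m) <- list(x@labels, x@labels)
  m
})

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "MdsEmbedding", function(x, ...) {
  m <- x@points
  rownames(m) <- x@sampleIds
  colnames(m) <- paste0("axis", seq_len(ncol(m)))
  m
})
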