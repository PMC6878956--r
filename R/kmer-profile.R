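#' Count k-mers in a set of reads
#'
#' Slides a window of length `k` over every read and counts each word over
#' the alphabet \{A,C,G,T\}. Windows containing any other character (N or
#' IUPAC ambiguity codes) are skipped entirely, so counts stay integral and
#' unambiguous. With `canonical = TRUE` (the default) each window
#' contributes to the lexicographically smaller of the word and its reverse
#' complement, making the profile invariant to the sequencing strand --
#' the appropriate choice for shotgun reads, which sample both strands.
#'
#' @param reads Character vector of nucleotide strings (any case).
#' @param k Word length, between 1 and 31 (a word must pack into a 64-bit
#'   integer via 2-bit encoding).
#' @param canonical Fold each k-mer with its reverse complement.
#' @param minCount Drop k-mers observed fewer than `minCount` times
#'   (default 1, i.e. no filtering).
#' @param sampleId Label to attach to the profile.
#' @return A [KmerProfile-class]. Reads shorter than `k` contribute
#'   nothing; an empty read set gives a valid profile with total 0.
#' @examples
#' countKmers("ACGT", k = 2, canonical = FALSE)
#' countKmers("ACGT", k = 2, canonical = TRUE)  # GT folds onto AC
#' @seealso [normalizeProfile()], [mergeProfiles()], [readFastq()]
#' @export
countKmers <- function(reads, k, canonical = TRUE, minCount = 1L,
                       sampleId = "sample") {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 31L)
    stop("k must be a single integer between 1 and 31")
  if (!is.character(reads)) reads <- as.character(reads)
  res <- .countKmersCpp(toupper(reads), k, isTRUE(canonical))
  counts <- res$count
  names(counts) <- res$kmer
  if (minCount > 1L) counts <- counts[counts >= minCount]
  new("KmerProfile",
      k = k, counts = counts, total = sum(counts),
      sampleId = sampleId, canonical = isTRUE(canonical))
}

#' Read sequences from a FASTQ file
#'
#' Reads a plain or gzip-compressed FASTQ file of 4-line records and
#' returns the sequences, uppercased, in file order. Paired-end mates are
#' handled by reading each mate file and pooling the results. Qualities
#' are ignored (reads are expected to be quality-trimmed beforehand).
#'
#' @param path Path to a `.fastq` or `.fastq.gz` file.
#' @param minLen Drop records whose sequence is shorter than this.
#' @return Character vector of sequences.
#' @details Malformed records abort with an error naming the (1-based)
#'   record index: a separator line not starting with `+`, a length
#'   mismatch between sequence and quality, a header not starting with
#'   `@`, or a truncated trailing record.
#' @seealso [countKmers()]
#' @export
readFastq <- function(path, minLen = 0L) {
  if (!file.exists(path)) stop(sprintf("FASTQ file not found: '%s'", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) return(character(0))
  if (length(lines) %% 4L != 0L)
    stop(sprintf("malformed FASTQ '%s': truncated record %d",
                 path, length(lines) %/% 4L + 1L))
  hd <- lines[seq(1L, length(lines), by = 4L)]
  sq <- lines[seq(2L, length(lines), by = 4L)]
  sep <- lines[seq(3L, length(lines), by = 4L)]
  ql <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad))
    stop(sprintf("malformed FASTQ '%s': header does not start with '@' at record %d",
                 path, bad[1L]))
  bad <- which(!startsWith(sep, "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ '%s': separator line does not start with '+' at record %d",
                 path, bad[1L]))
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad))
    stop(sprintf("malformed FASTQ '%s': sequence/quality length mismatch at record %d",
                 path, bad[1L]))
  sq <- toupper(sq)
  if (minLen > 0L) sq <- sq[nchar(sq) >= minLen]
  sq
}

#' Normalize a k-mer profile to relative frequencies
#'
#' Divides each count by the profile total, giving the sample's feature
#' frequency profile: a probability vector over its own k-mers, the form
#' required by the Jensen-Shannon and Hellinger comparisons.
#'
#' @param profile A [KmerProfile-class] with total > 0.
#' @return Named numeric vector of frequencies summing to 1 (within 1e-12).
#' @examples
#' p <- countKmers("ACGT", k = 2, canonical = TRUE)
#' normalizeProfile(p)
#' @export
normalizeProfile <- function(profile) {
  stopifnot(is(profile, "KmerProfile"))
  if (profile@total <= 0)
    stop(sprintf("degenerate sample '%s': profile total is 0, cannot normalize",
                 profile@sampleId))
  profile@counts / profile@total
}

#' Merge per-sample profiles into a frequency matrix
#'
#' Aligns the profiles on the sorted union of their k-mers and fills each
#' sample's normalized frequencies into its row, with exact zeros where a
#' k-mer was not observed. Row order preserves the input order; the fixed
#' lexicographic column order makes downstream distance computations
#' reproducible byte-for-byte.
#'
#' @param profiles List of [KmerProfile-class] objects (>= 2), all with the
#'   same `k` and canonical flag, all with total > 0.
#' @return A [FrequencyMatrix-class].
#' @export
mergeProfiles <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2L)
    stop("need at least 2 profiles to merge")
  if (!all(vapply(profiles, is, logical(1L), "KmerProfile")))
    stop("profiles must all be KmerProfile objects")
  ks <- vapply(profiles, function(p) p@k, integer(1L))
  if (length(unique(ks)) != 1L)
    stop(sprintf("incompatible profiles: mixed k (%s)",
                 paste(unique(ks), collapse = ", ")))
  can <- vapply(profiles, function(p) p@canonical, logical(1L))
  if (length(unique(can)) != 1L)
    stop("incompatible profiles: mixed canonical flags")
  tot <- vapply(profiles, function(p) p@total, numeric(1L))
  if (any(tot <= 0)) {
    ids <- vapply(profiles, function(p) p@sampleId, character(1L))
    stop(sprintf("degenerate sample(s) with zero total: %s",
                 paste(ids[tot <= 0], collapse = ", ")))
  }
  km <- radixSort(unique(unlist(lapply(profiles, function(p) names(p@counts)),
                                use.names = FALSE)))
  ids <- vapply(profiles, function(p) p@sampleId, character(1L))
  if (anyDuplicated(ids))
    ids <- make.unique(ids)
  v <- matrix(0, nrow = length(profiles), ncol = length(km))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    v[i, match(names(p@counts), km)] <- p@counts / p@total
  }
  rownames(v) <- ids
  new("FrequencyMatrix", sampleIds = ids, kmers = km, values = v)
}

#' Write / read a k-mer profile as two-column text
#'
#' Plain-text dump (k-mer TAB count, sorted) for interoperability with
#' external k-mer counters.
#'
#' @param profile A [KmerProfile-class].
#' @param path Output path (`.gz` supported).
#' @return `writeProfile` returns `path` invisibly; `readProfile` returns
#'   a [KmerProfile-class].
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "KmerProfile"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d", names(profile@counts),
                     as.integer(profile@counts)), con)
  invisible(path)
}

#' @rdname writeProfile
#' @param canonical,sampleId Metadata to attach to the re-read profile
#'   (the dump format does not carry them).
#' @export
readProfile <- function(path, canonical = TRUE, sampleId = "sample") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  km <- vapply(parts, `[`, character(1L), 1L)
  cnt <- as.numeric(vapply(parts, `[`, character(1L), 2L))
  ord <- order(km, method = "radix")
  counts <- cnt[ord]
  names(counts) <- km[ord]
  new("KmerProfile", k = nchar(km[1L]), counts = counts, total = sum(counts),
      sampleId = sampleId, canonical = isTRUE(canonical))
}
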