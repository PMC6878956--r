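# Normalize the sample manifest to a named list of path vectors and
# validate it before any counting happens.
.normalizeSamples <- function(samples) {
  if (is.character(samples)) samples <- as.list(samples)
  if (!is.list(samples) || is.null(names(samples)) ||
      any(!nzchar(names(samples))))
    stop("samples must be a named list (or named character vector) of FASTQ paths")
  samples <- lapply(samples, as.character)
  paths <- unlist(samples, use.names = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("manifest validation failed, missing file(s): %s",
                 paste(missing, collapse = ", ")))
  samples
}

.profileCacheKey <- function(paths, k, canonical, minCount, minReadLength) {
  sums <- unname(tools::md5sum(paths))
  paste(c(sums, sprintf("k%d", k), sprintf("c%d", as.integer(canonical)),
          sprintf("m%d", minCount), sprintf("l%d", minReadLength)),
        collapse = "-")
}

# Count one sample's pooled FASTQ files, optionally through the on-disk
# profile cache (keyed by file checksums + counting parameters, so k-mer
# sweeps over the same inputs never recount an unchanged sample twice).
.countSample <- function(name, paths, k, canonical, minCount,
                         minReadLength, cacheDir) {
  cacheFile <- NULL
  if (!is.null(cacheDir)) {
    dir.create(cacheDir, recursive = TRUE, showWarnings = FALSE)
    key <- .profileCacheKey(paths, k, canonical, minCount, minReadLength)
    cacheFile <- file.path(cacheDir, paste0(key, ".rds"))
    if (file.exists(cacheFile)) {
      prof <- readRDS(cacheFile)
      prof@sampleId <- name
      return(prof)
    }
  }
  reads <- unlist(lapply(paths, readFastq, minLen = minReadLength),
                  use.names = FALSE)
  prof <- countKmers(reads, k = k, canonical = canonical,
                     minCount = minCount, sampleId = name)
  if (prof@total <= 0)
    stop(sprintf("degenerate sample '%s': no usable k-mers at k = %d",
                 name, k))
  if (!is.null(cacheFile)) saveRDS(prof, cacheFile)
  prof
}

#' Run the alignment-free pipeline end to end
#'
#' Executes the five pipeline steps in order -- count k-mers per sample,
#' normalize and sort, merge into a frequency matrix, compute pairwise
#' divergences, infer the neighbor-joining tree -- plus a classical MDS
#' embedding of the distance matrix. All artifacts are written under
#' `outDir` together with a machine-readable manifest (parameters, input
#' checksums, output names). The run is fully deterministic: rerunning on
#' identical inputs yields byte-identical distance matrices, newick trees,
#' and MDS tables.
#'
#' @param samples Named list (or named character vector) mapping sample
#'   ids to one or more FASTQ paths (mates/lanes are pooled). At least 3
#'   samples (the neighbor-joining minimum). Counting is single-threaded
#'   and the merge order fixed, so results never depend on worker count
#'   or scheduling.
#' @param outDir Output directory, created if needed.
#' @param k K-mer length (hard limit 31; values below 13 warn, as short
#'   words saturate and lose phylogenetic signal on genome-scale data).
#' @param metric `"jsd"` or `"hellinger"`.
#' @param canonical Fold k-mers with their reverse complements.
#' @param minReadLength Drop reads shorter than this.
#' @param minCount Drop k-mers below this count per sample.
#' @param phylipStrict Write the PHYLIP matrix with strict 10-character
#'   names.
#' @param cacheDir Optional profile cache directory (see Details in
#'   [sweepK()]).
#' @param mdsDims MDS embedding dimensions.
#' @param hellingerForm Passed to [hellingerDistance()].
#' @return List with `distance` ([DistanceMatrix-class]), `tree`
#'   (`phylo`), `mds` ([MdsEmbedding-class]), `profiles`, and `files`
#'   (named vector of artifact paths).
#' @seealso [sweepK()], [simulateCohort()]
#' @export
runPipeline <- function(samples, outDir, k = 21L,
                        metric = c("jsd", "hellinger"), canonical = TRUE,
                        minReadLength = 0L, minCount = 1L,
                        phylipStrict = FALSE, cacheDir = NULL,
                        mdsDims = 2L, hellingerForm = "sqrt") {
  metric <- match.arg(metric)
  k <- as.integer(k)
  if (k < 1L || k > 31L) stop("k must be between 1 and 31")
  if (k < 13L)
    warning(sprintf("k = %d is below the recommended band (13-31); profiles saturate quickly at short word lengths", k))
  samples <- .normalizeSamples(samples)
  if (length(samples) < 3L)
    stop("pipeline requires at least 3 samples (neighbor-joining minimum)")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  note <- function(fmt, ...) {
    log[[length(log) + 1L]] <<- sprintf(fmt, ...)
  }
  note("pipeline: k=%d metric=%s canonical=%s samples=%d", k, metric,
       canonical, length(samples))
  profiles <- vector("list", length(samples))
  names(profiles) <- names(samples)
  for (nm in names(samples)) {
    profiles[[nm]] <- .countSample(nm, samples[[nm]], k, canonical,
                                   minCount, minReadLength, cacheDir)
    note("counted %s: %d distinct k-mers, total %d", nm,
         length(profiles[[nm]]@counts), as.integer(profiles[[nm]]@total))
  }
  fm <- mergeProfiles(profiles)
  note("merged: %d x %d frequency matrix", nrow(fm@values), ncol(fm@values))
  dm <- pairwiseDistances(fm, metric = metric,
                          hellingerForm = hellingerForm)
  tree <- neighborJoining(dm)
  mds <- classicalMds(dm, dims = min(mdsDims, length(samples) - 1L))
  files <- c(
    distances_tsv = file.path(outDir, sprintf("distances_%s.tsv", metric)),
    distances_phylip = file.path(outDir,
                                 sprintf("distances_%s.phylip", metric)),
    tree = file.path(outDir, sprintf("tree_%s.nwk", metric)),
    mds = file.path(outDir, sprintf("mds_%s.tsv", metric)),
    manifest = file.path(outDir, "run_manifest.json"),
    log = file.path(outDir, "run.log")
  )
  writeDistanceMatrix(dm, files[["distances_tsv"]], format = "tsv")
  writeDistanceMatrix(dm, files[["distances_phylip"]], format = "phylip",
                      strict = phylipStrict)
  writeNewick(tree, files[["tree"]])
  writeMdsTable(mds, files[["mds"]])
  inputs <- lapply(samples, function(p)
    list(paths = p, md5 = unname(tools::md5sum(p))))
  jsonlite::write_json(list(
    package = "KmerPhylo",
    version = as.character(utils::packageVersion("KmerPhylo")),
    parameters = list(k = k, metric = metric, canonical = canonical,
                      minReadLength = minReadLength, minCount = minCount,
                      phylipStrict = phylipStrict,
                      hellingerForm = hellingerForm),
    inputs = inputs,
    outputs = as.list(files[setdiff(names(files), "manifest")])
  ), files[["manifest"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("wrote %d artifacts to %s", length(files), outDir)
  writeLines(log, files[["log"]])
  list(distance = dm, tree = tree, mds = mds, profiles = profiles,
       files = files)
}

#' Sweep the k-mer length and compare the resulting trees
#'
#' Runs the pipeline once per k-mer length and compares every pair of
#' inferred trees by symmetric and branch-score distance -- the table
#' behind k-stability heatmaps -- plus the branch-score series between
#' consecutive k values. A shared per-sample profile cache (keyed by file
#' checksum, k, and counting flags) makes repeated sweeps over the same
#' inputs cheap.
#'
#' @param samples As in [runPipeline()].
#' @param kValues Integer vector of at least 2 k-mer lengths.
#' @param outDir Output directory; per-k artifacts go to `outDir/k<k>/`.
#' @param metric,canonical,minReadLength,minCount,hellingerForm Passed to
#'   [runPipeline()].
#' @return List with `trees` (named by k), `pairs` (data frame k1, k2,
#'   sd, bsd), `sequential` (consecutive-k branch scores), and `runs`.
#' @export
sweepK <- function(samples, kValues, outDir,
                   metric = c("jsd", "hellinger"), canonical = TRUE,
                   minReadLength = 0L, minCount = 1L,
                   hellingerForm = "sqrt") {
  metric <- match.arg(metric)
  kValues <- as.integer(kValues)
  if (length(kValues) < 2L) stop("sweep requires at least 2 k values")
  cacheDir <- file.path(outDir, "profile_cache")
  runs <- lapply(kValues, function(k) {
    runPipeline(samples, outDir = file.path(outDir, sprintf("k%d", k)),
                k = k, metric = metric, canonical = canonical,
                minReadLength = minReadLength, minCount = minCount,
                cacheDir = cacheDir, hellingerForm = hellingerForm)
  })
  names(runs) <- sprintf("k%d", kValues)
  trees <- lapply(runs, `[[`, "tree")
  pairs <- utils::combn(seq_along(kValues), 2L)
  pairTab <- data.frame(
    k1 = kValues[pairs[1L, ]],
    k2 = kValues[pairs[2L, ]],
    sd = apply(pairs, 2L, function(ij)
      symmetricDistance(trees[[ij[1L]]], trees[[ij[2L]]])),
    bsd = apply(pairs, 2L, function(ij)
      branchScoreDistance(trees[[ij[1L]]], trees[[ij[2L]]]))
  )
  ord <- order(kValues)
  seqTab <- if (length(kValues) >= 2L) {
    i1 <- ord[-length(ord)]
    i2 <- ord[-1L]
    data.frame(
      k1 = kValues[i1],
      k2 = kValues[i2],
      bsd = mapply(function(a, b) branchScoreDistance(trees[[a]],
                                                      trees[[b]]),
                   i1, i2)
    )
  } else NULL
  utils::write.table(pairTab, file.path(outDir, "sweep_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(seqTab, file.path(outDir, "sweep_sequential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(trees = trees, pairs = pairTab, sequential = seqTab, runs = runs)
}
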