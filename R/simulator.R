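.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct a lineage simulation plan
#'
#' Defaults describe the reference cohort used throughout the package's
#' validation: a 100 kb reference, 50 SNVs and 5 short indels per
#' mutational step, and no structural variants (set `nSv > 0` for the
#' whole-genome-style cohort with deletions, tandem duplications, and
#' inversions).
#'
#' @param referenceLength Reference length in bases.
#' @param nSnv,nIndel,nSv Mutation budget per lineage step.
#' @param indelMeanLength Mean geometric indel length.
#' @param svSizeRange SV size range, `c(min, max)`.
#' @param gc GC fraction of the reference.
#' @param seed RNG seed.
#' @return A [LineageSpec-class].
#' @export
LineageSpec <- function(referenceLength = 1e5, nSnv = 50L, nIndel = 5L,
                        nSv = 0L, indelMeanLength = 3, svSizeRange = c(50, 500),
                        gc = 0.5, seed = 1L) {
  new("LineageSpec", referenceLength = referenceLength,
      nSnv = as.integer(nSnv), nIndel = as.integer(nIndel),
      nSv = as.integer(nSv), indelMeanLength = indelMeanLength,
      svSizeRange = as.numeric(svSizeRange), gc = gc, seed = as.numeric(seed))
}

#' Construct a read simulation plan
#'
#' Defaults emulate a typical short-read run: 100 bp reads at 30-fold
#' coverage with a 0.1% uniform substitution error rate, single-end.
#'
#' @param readLength Read length in bases.
#' @param coverage Mean fold coverage.
#' @param errorRate Per-base substitution error rate.
#' @param paired Emit paired-end mates.
#' @param insertMean,insertSd Fragment length distribution (paired mode).
#' @param seed RNG seed.
#' @return A [ReadSimSpec-class].
#' @export
ReadSimSpec <- function(readLength = 100L, coverage = 30, errorRate = 0.001,
                        paired = FALSE, insertMean = 300, insertSd = 30,
                        seed = 1L) {
  new("ReadSimSpec", readLength = as.integer(readLength), coverage = coverage,
      errorRate = errorRate, paired = isTRUE(paired),
      insertMean = insertMean, insertSd = insertSd, seed = as.numeric(seed))
}

#' Generate a random reference genome
#'
#' I.i.d. bases with `P(G or C) = gc`, deterministic given the seed.
#'
#' @param length Genome length in bases (>= 1000).
#' @param seed RNG seed.
#' @param gc GC fraction.
#' @return A single nucleotide string.
#' @export
generateReference <- function(length, seed, gc = 0.5) {
  if (length < 1000) stop("reference length must be at least 1000 bases")
  withSeed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(.BASES, length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Apply a mutational step to a genome
#'
#' Applies, in ledger order: `nSnv` single-nucleotide substitutions at
#' distinct positions (each forced to a different base), `nIndel` short
#' insertions/deletions with geometric lengths (mean `indelMeanLength`),
#' then `nSv` structural variants (deletion, tandem duplication, or
#' reverse-complement inversion, sizes uniform in `svSizeRange`). All
#' positions refer to the genome state at the moment the event is applied,
#' so the ledger replays deterministically with [replayLedger()].
#'
#' @param genome Nucleotide string.
#' @param nSnv,nIndel,nSv Event counts.
#' @param indelMeanLength Mean geometric indel length.
#' @param svSizeRange SV size range `c(min, max)`.
#' @param seed RNG seed (`NULL` to use the current RNG stream).
#' @return List with elements `genome` (mutated string) and `ledger`
#'   (data frame: type, pos, length, ref, alt).
#' @seealso [replayLedger()], [simulateLineage()]
#' @export
applyMutations <- function(genome, nSnv = 0L, nIndel = 0L, nSv = 0L,
                           indelMeanLength = 3, svSizeRange = c(50, 500),
                           seed = NULL) {
  n0 <- nchar(genome)
  if (nSnv > n0)
    stop(sprintf("infeasible budget: %d SNVs requested for %d positions",
                 nSnv, n0))
  if (nSv > 0L && svSizeRange[2L] >= n0)
    stop("infeasible budget: SVs larger than the genome")
  withSeed(seed, {
    g <- strsplit(genome, "", fixed = TRUE)[[1L]]
    rows <- vector("list", nSnv + nIndel + nSv)
    ri <- 0L
    if (nSnv > 0L) {
      pos <- sample.int(length(g), nSnv)
      ref <- g[pos]
      alt <- vapply(ref, function(r) sample(.BASES[.BASES != r], 1L),
                    character(1L), USE.NAMES = FALSE)
      g[pos] <- alt
      for (t in seq_len(nSnv)) {
        ri <- ri + 1L
        rows[[ri]] <- list("snv", pos[t], 1L, ref[t], alt[t])
      }
    }
    for (t in seq_len(nIndel)) {
      len <- stats::rgeom(1L, 1 / indelMeanLength) + 1L
      del <- stats::runif(1L) < 0.5 && length(g) > len + 1L
      ri <- ri + 1L
      if (del) {
        p <- sample.int(length(g) - len + 1L, 1L)
        rows[[ri]] <- list("del", p, len,
                           paste(g[p:(p + len - 1L)], collapse = ""), "")
        g <- g[-(p:(p + len - 1L))]
      } else {
        p <- sample.int(length(g) + 1L, 1L)
        ins <- sample(.BASES, len, replace = TRUE)
        rows[[ri]] <- list("ins", p, len, "", paste(ins, collapse = ""))
        g <- append(g, ins, after = p - 1L)
      }
    }
    for (t in seq_len(nSv)) {
      size <- sample(seq.int(svSizeRange[1L], svSizeRange[2L]), 1L)
      if (size >= length(g)) size <- length(g) - 1L
      type <- sample(c("sv_del", "sv_dup", "sv_inv"), 1L)
      p <- sample.int(length(g) - size + 1L, 1L)
      seg <- g[p:(p + size - 1L)]
      ri <- ri + 1L
      rows[[ri]] <- list(type, p, size, "", "")
      g <- switch(type,
        sv_del = g[-(p:(p + size - 1L))],
        sv_dup = append(g, seg, after = p + size - 1L),
        sv_inv = { g[p:(p + size - 1L)] <- rev(unname(.COMP[seg])); g }
      )
    }
    ledger <- if (ri > 0L) {
      data.frame(
        type = vapply(rows, `[[`, character(1L), 1L),
        pos = vapply(rows, function(r) as.integer(r[[2L]]), integer(1L)),
        length = vapply(rows, function(r) as.integer(r[[3L]]), integer(1L)),
        ref = vapply(rows, `[[`, character(1L), 4L),
        alt = vapply(rows, `[[`, character(1L), 5L),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(type = character(0), pos = integer(0), length = integer(0),
                 ref = character(0), alt = character(0),
                 stringsAsFactors = FALSE)
    }
    list(genome = paste(g, collapse = ""), ledger = ledger)
  })
}

#' Replay a mutation ledger
#'
#' Deterministically re-applies a ledger produced by [applyMutations()]
#' (or a root-to-leaf concatenation of step ledgers) to a genome,
#' reproducing the mutated genome byte-for-byte.
#'
#' @param genome Starting nucleotide string.
#' @param ledger Ledger data frame (columns type, pos, length, ref, alt).
#' @return The mutated nucleotide string.
#' @export
replayLedger <- function(genome, ledger) {
  g <- strsplit(genome, "", fixed = TRUE)[[1L]]
  for (t in seq_len(nrow(ledger))) {
    p <- ledger$pos[t]
    len <- ledger$length[t]
    g <- switch(ledger$type[t],
      snv = { g[p] <- ledger$alt[t]; g },
      ins = append(g, strsplit(ledger$alt[t], "", fixed = TRUE)[[1L]],
                   after = p - 1L),
      del = g[-(p:(p + len - 1L))],
      sv_del = g[-(p:(p + len - 1L))],
      sv_dup = append(g, g[p:(p + len - 1L)], after = p + len - 1L),
      sv_inv = {
        g[p:(p + len - 1L)] <- rev(unname(.COMP[g[p:(p + len - 1L)]]))
        g
      },
      stop(sprintf("unknown ledger event type '%s'", ledger$type[t]))
    )
  }
  paste(g, collapse = "")
}

# Fixed lineage plan: every sample and its parent, in generation order.
.LINEAGE_ORDER <- c("C", "C1a", "C1b", "C1c", "C2a", "C2b", "C2c",
                    "C3a", "C3b", "C3c")
.LINEAGE_PARENT <- c(C = "N", C1a = "C", C1b = "C1a", C1c = "C1b",
                     C2a = "C", C2b = "C2a", C2c = "C2b",
                     C3a = "C", C3b = "C3a", C3c = "C3b")

#' Simulate a clonal lineage of genomes
#'
#' Generates the fixed clonal-evolution plan: a normal genome N, a
#' cancerous genome C derived from it, three subclone founders C1a, C2a,
#' C3a derived from C, and two successive mutants (b, c) within each
#' subclone. Every step applies the spec's per-step mutation budget with
#' its own derived seed.
#'
#' The sequenced cohort consists of the 10 samples N, C1a..C3c; the
#' intermediate genome C sits at the internal branching point of the truth
#' tree and is returned alongside the others for ledger replay. Truth-tree
#' branch lengths count the mutation events applied on each step; samples
#' that are ancestors of later samples are attached as zero-length leaves
#' at their lineage position.
#'
#' @param spec A [LineageSpec-class].
#' @return List with `genomes` (named list of 11 nucleotide strings,
#'   including C) and `truth` (a [LineageTruth-class]).
#' @seealso [simulateCohort()]
#' @export
simulateLineage <- function(spec) {
  stopifnot(is(spec, "LineageSpec"))
  seeds <- withSeed(spec@seed,
                    sample.int(2147483646L, length(.LINEAGE_ORDER) + 1L))
  refSeed <- seeds[1L]
  stepSeeds <- seeds[-1L]
  names(stepSeeds) <- .LINEAGE_ORDER
  genomes <- list(N = generateReference(spec@referenceLength, refSeed,
                                        spec@gc))
  ledgers <- list()
  events <- integer(0)
  for (s in .LINEAGE_ORDER) {
    res <- applyMutations(genomes[[.LINEAGE_PARENT[[s]]]],
                          nSnv = spec@nSnv, nIndel = spec@nIndel,
                          nSv = spec@nSv,
                          indelMeanLength = spec@indelMeanLength,
                          svSizeRange = spec@svSizeRange,
                          seed = stepSeeds[[s]])
    genomes[[s]] <- res$genome
    if (nrow(res$ledger) > 0L) {
      res$ledger <- cbind(sample = s, parent = .LINEAGE_PARENT[[s]],
                          res$ledger, stringsAsFactors = FALSE)
    } else {
      res$ledger <- cbind(sample = character(0), parent = character(0),
                          res$ledger)
    }
    ledgers[[s]] <- res$ledger
    events[s] <- nrow(res$ledger)
  }
  chain <- function(b) {
    sprintf("(%sa:0,(%sb:0,%sc:%d):%d):%d",
            b, b, b, events[[paste0(b, "c")]], events[[paste0(b, "b")]],
            events[[paste0(b, "a")]])
  }
  nwk <- sprintf("(N:%d,%s,%s,%s);", events[["C"]],
                 chain("C1"), chain("C2"), chain("C3"))
  truth <- new("LineageTruth",
               tree = parseNewick(nwk),
               ledger = do.call(rbind, unname(ledgers)),
               seeds = c(plan = spec@seed, reference = refSeed,
                         as.numeric(stepSeeds) |>
                           stats::setNames(paste0("step_", names(stepSeeds)))))
  list(genomes = genomes, truth = truth)
}

#' Simulate shotgun reads from a genome
#'
#' Uniform fragment start positions, random strand, uniform per-base
#' substitution errors, constant placeholder qualities (`I`). The expected
#' read count is `coverage * genomeLength / readLength`; deterministic
#' given the spec seed. In paired mode each fragment (normal fragment
#' length distribution) yields a forward mate from its start and a
#' reverse-complemented mate from its end.
#'
#' @param genome Nucleotide string at least one read long.
#' @param spec A [ReadSimSpec-class].
#' @return Data frame with columns `id`, `seq`, `qual`.
#' @seealso [writeFastq()]
#' @export
simulateReads <- function(genome, spec) {
  stopifnot(is(spec, "ReadSimSpec"))
  n <- nchar(genome)
  L <- spec@readLength
  if (n < L) stop("genome shorter than the read length")
  withSeed(spec@seed, {
    if (spec@paired) {
      nFrag <- max(1L, round(spec@coverage * n / (2 * L)))
      f <- pmin(pmax(round(stats::rnorm(nFrag, spec@insertMean,
                                        spec@insertSd)), L), n)
      start <- floor(stats::runif(nFrag) * (n - f + 1)) + 1L
      m1 <- substring(genome, start, start + L - 1L)
      m2 <- reverseComplement(substring(genome, start + f - L,
                                        start + f - 1L))
      seqs <- as.vector(rbind(m1, m2))
      ids <- as.vector(rbind(sprintf("frag_%06d/1", seq_len(nFrag)),
                             sprintf("frag_%06d/2", seq_len(nFrag))))
    } else {
      nReads <- max(1L, round(spec@coverage * n / L))
      start <- sample.int(n - L + 1L, nReads, replace = TRUE)
      seqs <- substring(genome, start, start + L - 1L)
      ids <- sprintf("read_%06d", seq_len(nReads))
    }
    flip <- stats::runif(length(seqs)) < 0.5
    if (any(flip)) seqs[flip] <- reverseComplement(seqs[flip])
    nerr <- stats::rbinom(length(seqs), L, spec@errorRate)
    for (i in which(nerr > 0L)) {
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      at <- sample.int(L, nerr[i])
      chars[at] <- vapply(chars[at],
                          function(b) sample(.BASES[.BASES != b], 1L),
                          character(1L), USE.NAMES = FALSE)
      seqs[i] <- paste(chars, collapse = "")
    }
    data.frame(id = ids, seq = seqs, qual = strrep("I", nchar(seqs)),
               stringsAsFactors = FALSE)
  })
}

#' Write simulated reads as FASTQ
#'
#' @param reads Data frame from [simulateReads()].
#' @param path Output path; gzip-compressed when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+",
                           reads$qual))
  writeLines(lines, con)
  invisible(path)
}

#' Simulate a full cohort and write it to disk
#'
#' Runs [simulateLineage()], renders one FASTQ file per truth-tree sample
#' with [simulateReads()] (each sample gets its own derived read seed),
#' and writes the truth tree (newick), the mutation ledger (TSV), and a
#' JSON manifest carrying every parameter and seed needed for exact
#' replay.
#'
#' @param lineageSpec A [LineageSpec-class].
#' @param readSpec A [ReadSimSpec-class].
#' @param dir Output directory (created if needed).
#' @param gzip Write `.fastq.gz` instead of plain `.fastq`.
#' @return List with `fastq` (named vector of paths), `truth`
#'   (a [LineageTruth-class]), `genomes`, and the paths of the truth tree,
#'   ledger, and manifest.
#' @export
simulateCohort <- function(lineageSpec = LineageSpec(),
                           readSpec = ReadSimSpec(),
                           dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateLineage(lineageSpec)
  leaves <- sim$truth@tree$tip.label
  readSeeds <- withSeed(readSpec@seed, sample.int(2147483646L,
                                                  length(leaves)))
  names(readSeeds) <- leaves
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  fastq <- character(0)
  for (s in leaves) {
    rs <- readSpec
    rs@seed <- as.numeric(readSeeds[[s]])
    reads <- simulateReads(sim$genomes[[s]], rs)
    fastq[s] <- file.path(dir, paste0(s, ext))
    writeFastq(reads, fastq[s])
  }
  truthPath <- file.path(dir, "truth.nwk")
  writeNewick(sim$truth@tree, truthPath)
  ledgerPath <- file.path(dir, "ledger.tsv")
  utils::write.table(sim$truth@ledger, ledgerPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifestPath <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    lineage = list(referenceLength = lineageSpec@referenceLength,
                   nSnv = lineageSpec@nSnv, nIndel = lineageSpec@nIndel,
                   nSv = lineageSpec@nSv,
                   indelMeanLength = lineageSpec@indelMeanLength,
                   svSizeRange = lineageSpec@svSizeRange,
                   gc = lineageSpec@gc, seed = lineageSpec@seed),
    reads = list(readLength = readSpec@readLength,
                 coverage = readSpec@coverage,
                 errorRate = readSpec@errorRate, paired = readSpec@paired,
                 insertMean = readSpec@insertMean,
                 insertSd = readSpec@insertSd, seed = readSpec@seed,
                 perSampleSeeds = as.list(readSeeds)),
    lineageSeeds = as.list(sim$truth@seeds),
    samples = as.list(fastq)
  ), manifestPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(fastq = fastq, truth = sim$truth, genomes = sim$genomes,
       truthPath = truthPath, ledgerPath = ledgerPath,
       manifestPath = manifestPath, dir = dir)
}
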