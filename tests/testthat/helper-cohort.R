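# Shared simulated cohorts, built lazily and reused across test files so
# the expensive end-to-end fixtures are rendered at most once per run.
.cohortCache <- new.env(parent = emptyenv())

cohortFixture <- function(seed, referenceLength = 1e5, coverage = 30,
                          errorRate = 0.001) {
  key <- sprintf("s%d_L%g_c%g_e%g", seed, referenceLength, coverage,
                 errorRate)
  if (!is.null(.cohortCache[[key]])) return(.cohortCache[[key]])
  dir <- file.path(tempdir(), "kmerphylo_cohorts", key)
  co <- simulateCohort(
    LineageSpec(referenceLength = referenceLength, seed = seed),
    ReadSimSpec(coverage = coverage, errorRate = errorRate, seed = seed),
    dir = dir
  )
  .cohortCache[[key]] <- co
  co
}

# Small, fast cohort for pipeline plumbing tests.
smallCohort <- function(seed = 11) {
  cohortFixture(seed, referenceLength = 10000, coverage = 8)
}
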