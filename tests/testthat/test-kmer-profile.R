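test_that("window counting matches hand-enumerated examples", {
  expect_equal(kmerCounts(countKmers("ACGT", 2, canonical = FALSE)),
               c(AC = 1, CG = 1, GT = 1))
  # rc(GT) = AC, so GT folds onto AC under canonical counting
  expect_equal(kmerCounts(countKmers("ACGT", 2, canonical = TRUE)),
               c(AC = 2, CG = 1))
  # windows containing N are skipped entirely
  expect_equal(kmerCounts(countKmers("ACNGT", 2, canonical = FALSE)),
               c(AC = 1, GT = 1))
  # reads shorter than k contribute nothing
  p <- countKmers("AC", 3)
  expect_equal(profileTotal(p), 0)
  expect_length(kmerCounts(p), 0)
  # empty read set is a valid degenerate profile
  expect_equal(profileTotal(countKmers(character(0), 5)), 0)
  expect_error(countKmers("ACGT", 0), "k must be")
  expect_error(countKmers("ACGT", 32), "k must be")
})

test_that("counting agrees with naive substring enumeration", {
  set.seed(4021)
  for (rep in 1:12) {
    reads <- vapply(sample(20:600, 5), randSeq, character(1), nProb = 0.02)
    for (k in c(3, 5, 11, 21)) {
      for (canonical in c(FALSE, TRUE)) {
        got <- kmerCounts(countKmers(reads, k, canonical = canonical))
        want <- naiveCountKmers(reads, k, canonical = canonical)
        expect_equal(got, want,
                     info = sprintf("k=%d canonical=%s rep=%d",
                                    k, canonical, rep))
      }
    }
  }
})

test_that("canonical counting is strand-neutral and totals are conserved", {
  set.seed(7311)
  reads <- vapply(rep(300, 8), randSeq, character(1), nProb = 0.01)
  p1 <- countKmers(reads, 7, canonical = TRUE)
  p2 <- countKmers(reverseComplement(reads), 7, canonical = TRUE)
  expect_identical(kmerCounts(p1), kmerCounts(p2))
  # total equals the number of valid windows
  naive <- naiveCountKmers(reads, 7, canonical = FALSE)
  expect_equal(profileTotal(p1), sum(naive))
  # stranded counting differs between strands in general, but totals match
  expect_equal(profileTotal(countKmers(reads, 7, canonical = FALSE)),
               sum(naive))
})

test_that("stored k-mers are sorted, canonical, and filterable", {
  set.seed(88)
  p <- countKmers(randSeq(2000), 5, canonical = TRUE)
  km <- kmers(p)
  expect_identical(km, sort(km, method = "radix"))
  expect_true(all(km <= reverseComplement(km)))
  p2 <- countKmers(randSeq(2000), 5, minCount = 3)
  expect_true(all(kmerCounts(p2) >= 3))
})

test_that("FASTQ reading handles plain, gzipped, filtered, and malformed input", {
  recs <- c("@r1", "ACGTACGT", "+", "IIIIIIII",
            "@r2", "ggttaa", "+r2", "IIIIII")
  fq <- tempfile(fileext = ".fastq")
  writeLines(recs, fq)
  expect_equal(readFastq(fq), c("ACGTACGT", "GGTTAA"))
  expect_equal(readFastq(fq, minLen = 7), "ACGTACGT")

  gz <- tempfile(fileext = ".fastq.gz")
  con <- gzfile(gz, "wt"); writeLines(recs, con); close(con)
  expect_identical(readFastq(gz), readFastq(fq))

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "x", "IIII"), bad)
  expect_error(readFastq(bad), "separator.*record 1")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "III"), bad)
  expect_error(readFastq(bad), "length mismatch at record 2")
  writeLines(c("@r1", "ACGT", "+"), bad)
  expect_error(readFastq(bad), "truncated record 1")
  expect_error(readFastq(tempfile()), "not found")
})

test_that("normalization yields probability vectors and rejects empty profiles", {
  p <- countKmers(c("ACG", "AC", "GT"), 2, canonical = FALSE)
  f <- normalizeProfile(p)  # counts AC:2, CG:1, GT:1
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_equal(unname(f[c("AC", "CG", "GT")]), c(0.5, 0.25, 0.25))
  expect_equal(unname(normalizeProfile(countKmers(strrep("A", 9), 3))), 1)
  expect_error(normalizeProfile(countKmers("AC", 3)), "degenerate")
})

test_that("merging aligns profiles on the sorted union with exact zeros", {
  p1 <- countKmers("ACG", 2, canonical = FALSE, sampleId = "s1")  # AC, CG
  p2 <- countKmers("CGCG", 2, canonical = FALSE, sampleId = "s2") # CG x2, GC
  fm <- mergeProfiles(list(p1, p2))
  m <- as.matrix(fm)
  expect_identical(kmers(fm), c("AC", "CG", "GC"))
  expect_equal(m["s1", ], c(AC = 0.5, CG = 0.5, GC = 0))
  expect_equal(m["s2", ], c(AC = 0, CG = 2 / 3, GC = 1 / 3))
  expect_equal(rowSums(m), c(s1 = 1, s2 = 1), tolerance = 1e-12)

  # three disjoint-support profiles give the identity matrix
  ps <- list(countKmers("AAAA", 3, canonical = FALSE, sampleId = "a"),
             countKmers("CCCC", 3, canonical = FALSE, sampleId = "b"),
             countKmers("GGGG", 3, canonical = FALSE, sampleId = "c"))
  expect_equal(unname(as.matrix(mergeProfiles(ps))), diag(3))

  expect_error(mergeProfiles(list(p1)), "at least 2")
  expect_error(mergeProfiles(list(p1, countKmers("ACGT", 3))), "mixed k")
  expect_error(
    mergeProfiles(list(p1, countKmers("ACGT", 2, canonical = TRUE))),
    "canonical")
  expect_error(mergeProfiles(list(p1, countKmers("NN", 2, canonical = FALSE))),
               "degenerate")
})

test_that("merge preserves count/total for every sample and k-mer", {
  set.seed(515)
  ps <- lapply(1:4, function(i)
    countKmers(vapply(rep(200, 4), randSeq, character(1)), 6,
               sampleId = paste0("s", i)))
  fm <- mergeProfiles(ps)
  m <- as.matrix(fm)
  for (p in ps) {
    expect_equal(unname(m[sampleIds(p), kmers(p)]),
                 unname(kmerCounts(p) / profileTotal(p)))
  }
})

test_that("profile text dump round-trips", {
  p <- countKmers(randSeq(500), 4, sampleId = "dump")
  path <- tempfile(fileext = ".tsv")
  writeProfile(p, path)
  q <- readProfile(path, canonical = TRUE, sampleId = "dump")
  expect_identical(kmerCounts(q), kmerCounts(p))
  expect_equal(kmerLength(q), 4L)
})
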