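test_that("Kullback-Leibler divergence matches direct evaluation", {
  expect_equal(klDivergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(klDivergence(c(1, 0), c(0.5, 0.5)), 1)  # 1 * log2(2)
  # term-by-term: 0.5 log2(0.5/0.375) + 0.5 log2(0.5/0.625)
  expect_equal(klDivergence(c(0.5, 0.5), c(0.375, 0.625)), 0.0465546,
               tolerance = 1e-3)
  expect_error(klDivergence(c(0.5, 0.5), c(1, 0)), "infinite")
  expect_error(klDivergence(c(1, 0), c(0.5, 0.3, 0.2)), "alignment")
})

test_that("Jensen-Shannon and Hellinger match their closed forms", {
  p <- c(0.5, 0.5); q <- c(0.25, 0.75)
  expect_equal(jsDivergence(p, p), 0)
  expect_equal(jsDivergence(c(1, 0), c(0, 1)), 1)
  expect_equal(jsDivergence(p, q), 0.0487949, tolerance = 1e-3)
  expect_equal(hellingerDistance(p, p), 0)
  expect_equal(hellingerDistance(c(1, 0), c(0, 1)), 1)
  expect_equal(hellingerDistance(p, q), 0.1845919, tolerance = 1e-3)
  # literal (no inner radicals) reading: sqrt(0.5 * (0.25^2 + 0.25^2))
  expect_equal(hellingerDistance(p, q, form = "literal"), 0.25)
  expect_equal(hellingerDistance(c(1, 0), c(0, 1), form = "literal"), 1)
  expect_error(jsDivergence(p, c(0.5, 0.3, 0.2)), "alignment")
})

test_that("divergences match independent term-by-term evaluation on random pairs", {
  # oracle written directly from the definitions, summed per index
  jsdOracle <- function(p, q) {
    m <- (p + q) / 2
    tot <- 0
    for (i in seq_along(p)) {
      if (p[i] > 0) tot <- tot + 0.5 * p[i] * log2(p[i] / m[i])
      if (q[i] > 0) tot <- tot + 0.5 * q[i] * log2(q[i] / m[i])
    }
    tot
  }
  hdOracle <- function(p, q) {
    tot <- 0
    for (i in seq_along(p)) tot <- tot + (sqrt(p[i]) - sqrt(q[i]))^2
    sqrt(tot / 2)
  }
  set.seed(2718)
  for (rep in 1:200) {
    len <- sample(2:40, 1)
    p <- randProb(len, zeroFrac = 0.3)
    q <- randProb(len, zeroFrac = 0.3)
    expect_equal(jsDivergence(p, q), jsdOracle(p, q), tolerance = 1e-12)
    expect_equal(hellingerDistance(p, q), hdOracle(p, q), tolerance = 1e-12)
  }
})

test_that("divergences are bounded, symmetric, and permutation-invariant", {
  set.seed(31415)
  for (rep in 1:100) {
    len <- sample(2:50, 1)
    p <- randProb(len, zeroFrac = 0.4)
    q <- randProb(len, zeroFrac = 0.4)
    j <- jsDivergence(p, q)
    h <- hellingerDistance(p, q)
    expect_gte(j, 0); expect_lte(j, 1)
    expect_gte(h, 0); expect_lte(h, 1)
    expect_identical(j, jsDivergence(q, p))
    expect_identical(h, hellingerDistance(q, p))
    perm <- sample(len)
    expect_equal(jsDivergence(p[perm], q[perm]), j, tolerance = 1e-14)
    expect_equal(hellingerDistance(p[perm], q[perm]), h, tolerance = 1e-14)
  }
})

test_that("sqrt(JSD) and Hellinger satisfy the triangle inequality", {
  set.seed(1618)
  for (rep in 1:200) {
    len <- sample(2:30, 1)
    a <- randProb(len, 0.3); b <- randProb(len, 0.3); c <- randProb(len, 0.3)
    expect_lte(sqrt(jsDivergence(a, c)),
               sqrt(jsDivergence(a, b)) + sqrt(jsDivergence(b, c)) + 1e-12)
    expect_lte(hellingerDistance(a, c),
               hellingerDistance(a, b) + hellingerDistance(b, c) + 1e-12)
  }
})

test_that("divergences vanish at the expected rates for small perturbations", {
  set.seed(99)
  q <- randProb(20)
  v <- rnorm(20); v <- v - mean(v)
  d <- function(eps) {
    p <- q + eps * v
    stopifnot(all(p > 0))
    c(jsDivergence(p / sum(p), q), hellingerDistance(p / sum(p), q))
  }
  big <- d(1e-3); small <- d(1e-4)
  # JSD is quadratic in the perturbation: 10x smaller eps, ~100x smaller
  expect_lt(small[1], big[1] / 50)
  expect_gt(small[1], big[1] / 200)
  # Hellinger is locally linear (its square is quadratic)
  expect_lt(small[2], big[2] / 5)
  expect_gt(small[2], big[2] / 20)
  expect_lt(small[2]^2, big[2]^2 / 50)
  expect_lt(big[1], 1e-3)
  expect_lt(big[2], 1e-1)
})

test_that("pairwise distance matrices are exact-symmetric with zero diagonal", {
  p1 <- countKmers("AAAA", 3, canonical = FALSE, sampleId = "a")
  p2 <- countKmers("CCCC", 3, canonical = FALSE, sampleId = "b")
  p3 <- countKmers("GGGG", 3, canonical = FALSE, sampleId = "c")
  fm <- mergeProfiles(list(p1, p2, p3))
  dm <- pairwiseDistances(fm, "jsd")
  m <- as.matrix(dm)
  expect_equal(unname(m), matrix(1, 3, 3) - diag(3))  # disjoint supports
  expect_identical(distanceMetric(dm), "jsd")

  # identical rows are at distance zero
  fm2 <- mergeProfiles(list(p1, countKmers("AAAA", 3, canonical = FALSE,
                                           sampleId = "a2")))
  expect_equal(unname(as.matrix(pairwiseDistances(fm2, "jsd"))),
               matrix(0, 2, 2))

  set.seed(55)
  ps <- lapply(1:5, function(i)
    countKmers(vapply(rep(150, 3), randSeq, character(1)), 4,
               sampleId = paste0("s", i)))
  dmr <- pairwiseDistances(mergeProfiles(ps), "hellinger")
  v <- as.matrix(dmr)
  expect_identical(v, t(v))
  expect_equal(unname(diag(v)), rep(0, 5))
  expect_true(all(v >= 0 & v <= 1))
})

test_that("single-pair distances propagate into the matrix", {
  p1 <- countKmers(c("ACA", "AGA"), 2, canonical = FALSE, sampleId = "x")
  p2 <- countKmers(c("ACA", "AGAGA"), 2, canonical = FALSE, sampleId = "y")
  fm <- mergeProfiles(list(p1, p2))
  expect_equal(as.matrix(fm)["x", ], c(AC = 0.25, AG = 0.25, CA = 0.25,
                                       GA = 0.25))
  dmh <- pairwiseDistances(fm, "hellinger")
  dmj <- pairwiseDistances(fm, "jsd")
  fr <- as.matrix(fm)
  expect_equal(as.matrix(dmh)["x", "y"],
               hellingerDistance(fr["x", ], fr["y", ]))
  expect_equal(as.matrix(dmj)["x", "y"], jsDivergence(fr["x", ], fr["y", ]))
})

test_that("distance matrices serialize to PHYLIP and TSV", {
  m <- matrix(c(0, 0.2, 0.3, 0.2, 0, 0.4, 0.3, 0.4, 0), 3,
              dimnames = rep(list(c("alpha", "beta_long_name", "g")), 2))
  dm <- DistanceMatrix(m, metric = "jsd")
  phy <- tempfile(); tsv <- tempfile()
  writeDistanceMatrix(dm, phy, format = "phylip", strict = TRUE)
  lines <- readLines(phy)
  expect_equal(length(lines), 4L)
  expect_equal(as.integer(trimws(lines[1])), 3L)
  expect_match(lines[3], "^beta_long_")  # strict mode truncates to 10 chars
  writeDistanceMatrix(dm, phy, format = "phylip", strict = FALSE)
  expect_match(readLines(phy)[3], "^beta_long_name\t")
  writeDistanceMatrix(dm, tsv, format = "tsv")
  back <- readDistanceMatrix(tsv, metric = "jsd")
  expect_equal(as.matrix(back), as.matrix(dm))
})
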