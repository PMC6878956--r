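njLabels <- c("A", "B", "C", "D")

mat3 <- function() {
  m <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3)
  dimnames(m) <- list(njLabels[1:3], njLabels[1:3])
  m
}

test_that("three-taxon trees use the exact closed-form branch lengths", {
  t3 <- neighborJoining(mat3())
  expect_equal(writeNewick(t3), "(A:0.5,B:1.5,C:2.5);")
})

test_that("four-taxon additive distances recover the generating tree exactly", {
  # path lengths on ((A:1,B:2):1,(C:3,D:4))
  m <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, dimnames = list(njLabels, njLabels))
  tr <- neighborJoining(m)
  truth <- parseNewick("((A:1,B:2):1,C:3,D:4);")
  expect_equal(symmetricDistance(tr, truth), 0)
  expect_lt(branchScoreDistance(tr, truth), 1e-12)
})

test_that("identical taxa become sibling leaves with zero pendant branches", {
  m <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3,
              dimnames = list(njLabels[1:3], njLabels[1:3]))
  expect_equal(writeNewick(neighborJoining(m)), "(A:0,B:0,C:1);")
})

test_that("NJ is consistent on additive matrices from random trees", {
  set.seed(1234)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    truth <- randTree(n)
    D <- ape::cophenetic.phylo(truth)
    inferred <- neighborJoining(D)
    expect_equal(symmetricDistance(inferred, truth), 0)
    # every split's branch length reproduced within 1e-9
    bi <- bipartitions(inferred, trivial = TRUE)
    bt <- bipartitions(truth, trivial = TRUE)
    expect_setequal(bi$split, bt$split)
    expect_lt(max(abs(bi$length[match(bt$split, bi$split)] - bt$length)),
              1e-9)
    # independent implementation agrees on the topology
    expect_equal(symmetricDistance(inferred, ape::nj(D)), 0)
  }
})

test_that("NJ is deterministic and equivariant under leaf permutation", {
  set.seed(77)
  truth <- randTree(8)
  D <- ape::cophenetic.phylo(truth)
  s1 <- writeNewick(neighborJoining(D))
  s2 <- writeNewick(neighborJoining(D))
  expect_identical(s1, s2)
  perm <- sample(nrow(D))
  expect_identical(writeNewick(neighborJoining(D[perm, perm])), s1)
})

test_that("NJ rejects degenerate input and clamps negatives on request", {
  expect_error(neighborJoining(mat3()[1:2, 1:2]), "at least 3")
  bad <- mat3(); bad[1, 2] <- bad[2, 1] <- NaN
  expect_error(neighborJoining(bad), "NaN")
  bad2 <- mat3(); bad2[1, 2] <- bad2[2, 1] <- -1
  expect_error(neighborJoining(bad2), "negative")
  # random non-additive matrix known to produce a negative branch estimate
  set.seed(1)
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- runif(6, 0.1, 2)
  m <- m + t(m)
  dimnames(m) <- list(njLabels, njLabels)
  expect_true(any(neighborJoining(m)$edge.length < 0))
  clamped <- neighborJoining(m, clampNegative = TRUE)
  expect_true(all(clamped$edge.length >= 0))
})

test_that("newick output is canonical, quoted, and round-trips", {
  t1 <- parseNewick("((B:2,A:1):1,(D:4,C:3):2);")
  t2 <- parseNewick("((C:3,D:4):2,(A:1,B:2):1);")
  expect_identical(writeNewick(t1), writeNewick(t2))
  expect_match(writeNewick(t1), "\\(\\(A:1,B:2\\):1")

  rt <- parseNewick(writeNewick(t1))
  expect_equal(symmetricDistance(rt, t1), 0)
  expect_lt(branchScoreDistance(rt, t1), 1e-9)

  ws <- ape::rtree(3, tip.label = c("my sample", "b", "c"))
  expect_match(writeNewick(ws), "'my sample'", fixed = TRUE)
  expect_true("my sample" %in% parseNewick(writeNewick(ws))$tip.label)
})

test_that("newick parsing reports malformed input with a position", {
  tr <- parseNewick("(A:1,B:2,(C:3,D:4):1);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  internal <- bipartitions(tr)
  expect_equal(internal$split, "C,D")
  expect_equal(internal$length, 1)
  expect_equal(parseNewick("(A,B);")$edge.length, c(0, 0))
  expect_error(parseNewick("(A:1,B:2"), "unclosed")
  expect_error(parseNewick("(A:1,B:2));"), "position 10")
  expect_error(parseNewick("(A:1,B:2);extra"), "trailing")
})

test_that("classical MDS reproduces Euclidean configurations", {
  # two points at distance d sit at +/- d/2 on axis 1
  m2 <- matrix(c(0, 3, 3, 0), 2, dimnames = rep(list(c("p", "q")), 2))
  e2 <- classicalMds(m2, dims = 1)
  expect_equal(sort(as.vector(as.matrix(e2))), c(-1.5, 1.5))

  # equilateral triangle: embedding distances all 1
  m3 <- matrix(1, 3, 3) - diag(3)
  dimnames(m3) <- rep(list(c("a", "b", "c")), 2)
  e3 <- classicalMds(m3, dims = 2)
  expect_equal(unname(as.matrix(stats::dist(as.matrix(e3)))),
               unname(m3), tolerance = 1e-9)

  # distances from random planar points are reproduced exactly
  set.seed(42)
  pts <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(stats::dist(pts))
  dimnames(D) <- rep(list(paste0("s", 1:5)), 2)
  emb <- classicalMds(D, dims = 2)
  expect_equal(unname(as.matrix(stats::dist(as.matrix(emb)))), unname(D),
               tolerance = 1e-9)
  expect_equal(unname(colMeans(as.matrix(emb))), c(0, 0), tolerance = 1e-9)
  # sign convention: the largest-magnitude coordinate of each axis is +
  for (j in 1:2) {
    col <- as.matrix(emb)[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
  expect_length(mdsEigenvalues(emb), 5L)
  expect_error(classicalMds(D, dims = 5), "dims")

  # an all-zero matrix embeds everything at the origin
  z <- matrix(0, 3, 3, dimnames = rep(list(c("x", "y", "z")), 2))
  expect_equal(unname(as.matrix(suppressWarnings(classicalMds(z, 2)))),
               matrix(0, 3, 2))
})

test_that("MDS tables carry eigenvalues and coordinates", {
  m3 <- matrix(1, 3, 3) - diag(3)
  dimnames(m3) <- rep(list(c("a", "b", "c")), 2)
  path <- tempfile()
  writeMdsTable(classicalMds(m3, 2), path)
  lines <- readLines(path)
  expect_match(lines[1], "^# eigenvalues: ")
  expect_equal(lines[2], "sample\taxis1\taxis2")
  expect_equal(length(lines), 5L)
})
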