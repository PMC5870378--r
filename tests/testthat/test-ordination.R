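# Bray-Curtis, monotone regression, NMDS, ANOSIM and UPGMA.

test_that("Bray-Curtis matches the formula and vegan", {
  x <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.vector(brayCurtis(x)), 1)
  x2 <- rbind(a = c(0.3, 0.7), b = c(0.3, 0.7))
  expect_equal(as.vector(brayCurtis(x2)), 0)
  x3 <- rbind(a = c(0.6, 0.4), b = c(0.4, 0.6))
  expect_equal(as.vector(brayCurtis(x3)), 0.2)

  skip_if_not_installed("vegan")
  set.seed(31)
  m <- matrix(runif(40), 5, 8)
  m <- sweep(m, 1, rowSums(m), "/")
  rownames(m) <- paste0("s", 1:5)
  expect_equal(as.vector(brayCurtis(m)),
               as.vector(vegan::vegdist(m, method = "bray")),
               tolerance = 1e-12)

  bad <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0))
  expect_error(brayCurtis(bad), "all-zero")
})

test_that("percent similarity is the complementary percent scale", {
  expect_equal(percentSimilarity(0.25), 75)
})

test_that("monotone regression pools adjacent violators", {
  expect_equal(monotoneRegression(c(1, 3, 2)), c(1, 2.5, 2.5))
  expect_equal(monotoneRegression(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(monotoneRegression(c(2, 2, 2)), c(2, 2, 2))
  expect_equal(monotoneRegression(c(5, 1)), c(3, 3))
  # weighted pooling
  expect_equal(monotoneRegression(c(3, 1), w = c(3, 1)), c(2.5, 2.5))

  # agrees with stats::isoreg on random unweighted cases
  set.seed(41)
  for (i in 1:20) {
    y <- rnorm(sample(5:40, 1))
    expect_equal(monotoneRegression(y), as.vector(isoreg(y)$yf),
                 tolerance = 1e-12)
  }
})

test_that("NMDS recovers perfectly embeddable configurations", {
  # 3-4-5 right triangle scaled into [0, 1]
  d <- as.dist(matrix(c(0, 0.3, 0.4, 0.3, 0, 0.5, 0.4, 0.5, 0), 3))
  res <- nmdsEmbed(d, nStarts = 10, seed = 2)
  expect_lt(nmdsStress(res), 1e-3)

  # a known 6-point planar configuration re-embeds with matching ranks
  set.seed(5)
  X <- matrix(runif(12), 6, 2)
  d6 <- dist(X)
  res6 <- nmdsEmbed(d6, nStarts = 20, seed = 3)
  expect_lt(nmdsStress(res6), 0.01)
  dFit <- dist(nmdsCoordinates(res6))
  expect_gt(cor(rank(as.vector(d6)), rank(as.vector(dFit))), 0.99)
})

test_that("more starts from the same seed stream never increase the best
           stress", {
  set.seed(19)
  X <- matrix(runif(16), 8, 2)
  d <- dist(X) + as.dist(matrix(0.05 * abs(rnorm(64)), 8))  # not exact
  s1 <- nmdsStress(nmdsEmbed(d, nStarts = 1, seed = 7))
  s3 <- nmdsStress(nmdsEmbed(d, nStarts = 3, seed = 7))
  s5 <- nmdsStress(nmdsEmbed(d, nStarts = 5, seed = 7))
  expect_lte(s3, s1 + 1e-12)
  expect_lte(s5, s3 + 1e-12)
})

test_that("stress is invariant under rigid motion and uniform scaling", {
  set.seed(13)
  X <- matrix(runif(14), 7, 2)
  d <- dist(X) + as.dist(matrix(0.03 * abs(rnorm(49)), 7))
  res <- nmdsEmbed(d, nStarts = 5, seed = 11)
  Y <- nmdsCoordinates(res)
  s0 <- kruskalStress(d, Y)
  expect_equal(s0, nmdsStress(res), tolerance = 1e-10)
  theta <- 0.7
  Rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  expect_equal(kruskalStress(d, Y %*% Rot), s0, tolerance = 1e-9)
  shift <- matrix(rep(c(3, -2), each = 7), 7)
  expect_equal(kruskalStress(d, Y + shift), s0, tolerance = 1e-9)
  expect_equal(kruskalStress(d, 2.5 * Y), s0, tolerance = 1e-9)
})

test_that("NMDS result slots are self-consistent and reproducible", {
  set.seed(3)
  X <- matrix(runif(10), 5, 2)
  d <- dist(X)
  r1 <- nmdsEmbed(d, nStarts = 4, seed = 9)
  r2 <- nmdsEmbed(d, nStarts = 4, seed = 9)
  expect_identical(nmdsCoordinates(r1), nmdsCoordinates(r2))
  expect_equal(nmdsStress(r1), min(r1@startStress), tolerance = 1e-9)
  expect_error(nmdsEmbed(d, k = 5), "smaller")
})

test_that("ANOSIM gives R = 1 with exact p = 1/3 for perfectly separated
           2+2 groups", {
  # all between-distances exceed all within-distances
  m <- matrix(c(0, 0.1, 0.9, 0.8,
                0.1, 0, 0.85, 0.95,
                0.9, 0.85, 0, 0.12,
                0.8, 0.95, 0.12, 0), 4,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  d <- as.dist(m)
  res <- anosimTest(d, c("A", "A", "B", "B"))
  expect_equal(anosimR(res), 1)
  expect_equal(res@method, "exact")
  expect_equal(anosimP(res), 1 / 3)

  # inverted structure: R = -1
  inv <- as.dist(1 - m + diag(4) * 0)
  res2 <- anosimTest(as.dist(as.matrix(inv)), c("A", "A", "B", "B"))
  expect_equal(anosimR(res2), -1)
})

test_that("ANOSIM R is invariant under monotone transforms of the
           dissimilarities", {
  set.seed(29)
  m <- matrix(runif(36), 6); m <- (m + t(m)) / 2; diag(m) <- 0
  d <- as.dist(m)
  g <- c("A", "A", "A", "B", "B", "B")
  r1 <- anosimR(anosimTest(d, g))
  r2 <- anosimR(anosimTest(d^2, g))
  r3 <- anosimR(anosimTest(as.dist(log1p(as.matrix(d))), g))
  expect_equal(r1, r2)
  expect_equal(r1, r3)
})

test_that("ANOSIM matches vegan and sampled p agrees with exact p", {
  skip_if_not_installed("vegan")
  set.seed(37)
  m <- matrix(runif(64, 0.2, 1), 8); m <- (m + t(m)) / 2; diag(m) <- 0
  d <- as.dist(m)
  g <- rep(c("A", "B"), each = 4)
  mine <- anosimTest(d, g)
  veg <- vegan::anosim(d, factor(g), permutations = 999)
  expect_equal(anosimR(mine), unname(veg$statistic), tolerance = 1e-12)

  exact <- anosimTest(d, g, method = "exact")
  sampled <- anosimTest(d, g, nPermutations = 9999, method = "sampled",
                        seed = 5)
  se <- sqrt(exact@pValue * (1 - exact@pValue) / 9999)
  expect_lt(abs(sampled@pValue - exact@pValue), 3 * se + 2e-4)
})

test_that("ANOSIM R is near zero for random labels on i.i.d. points", {
  set.seed(43)
  Rs <- replicate(100, {
    X <- matrix(rnorm(16), 8, 2)
    d <- dist(X)
    g <- sample(rep(c("A", "B"), each = 4))
    anosimR(anosimTest(d, g, nPermutations = 199, method = "sampled"))
  })
  expect_lt(abs(mean(Rs)), 0.05)
})

test_that("pairwise ANOSIM tests every group pair", {
  set.seed(47)
  X <- rbind(matrix(rnorm(8, 0), 4, 2), matrix(rnorm(8, 3), 4, 2),
             matrix(rnorm(8, 6), 4, 2))
  rownames(X) <- paste0("s", 1:12)
  d <- dist(X)
  g <- setNames(rep(c("A", "B", "C"), each = 4), rownames(X))
  res <- anosimTest(d, g, nPermutations = 99)
  expect_equal(nrow(anosimPairwise(res)), 3L)
  expect_setequal(anosimPairwise(res)$groupA, c("A", "A", "B"))
  expect_error(anosimTest(d, setNames(c("A", rep(c("B", "C"), c(6, 5))),
                                      rownames(X))), "at least two samples")
})

test_that("UPGMA merges at group-average heights and is ultrametric", {
  m <- matrix(c(0, 0.2, 0.6, 0.2, 0, 0.8, 0.6, 0.8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- upgmaCluster(as.dist(m))
  expect_equal(hc$height, c(0.2, 0.7))
  expect_equal(similarityLevels(hc), c(80, 30))

  # two samples: a single merge at their distance
  hc2 <- upgmaCluster(as.dist(matrix(c(0, 0.4, 0.4, 0), 2,
                                     dimnames = list(c("x", "y"),
                                                     c("x", "y")))))
  expect_equal(hc2$height, 0.4)

  # ultrametric three-point condition on cophenetic distances
  set.seed(53)
  m2 <- matrix(runif(49, 0.1, 1), 7); m2 <- (m2 + t(m2)) / 2; diag(m2) <- 0
  hcr <- upgmaCluster(as.dist(m2))
  expect_true(all(diff(hcr$height) >= -1e-12))
  cp <- as.matrix(cophenetic(hcr))
  for (i in 1:7) for (j in 1:7) for (k in 1:7)
    expect_lte(cp[i, j], max(cp[i, k], cp[j, k]) + 1e-12)
})

test_that("dendrograms export to Newick with ultrametric branch lengths", {
  m <- matrix(c(0, 0.2, 0.6, 0.2, 0, 0.8, 0.6, 0.8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- upgmaCluster(as.dist(m))
  tf <- withr::local_tempfile(fileext = ".nwk")
  exportNewick(hc, tf)
  tree <- ape::read.tree(tf)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
  cp <- ape::cophenetic.phylo(tree)
  expect_equal(cp["A", "B"], 0.2)
  expect_equal(cp["A", "C"], 0.7)
})
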