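test_that("rdaR2 matches a pseudo-inverse projection oracle", {
  set.seed(14)
  Y <- matrix(rnorm(150), 30, 5)
  X <- matrix(rnorm(90), 30, 3)
  got <- rdaR2(Y, X)
  # oracle: explicit SVD pseudo-inverse projection of column-centred Y
  Yc <- scale(Y, scale = FALSE)
  Xi <- cbind(1, X)
  P <- Xi %*% MASS::ginv(Xi)
  expect_lt(abs(got - sum((P %*% Yc)^2) / sum(Yc^2)), 1e-10)
  # group-structured Y explained perfectly by group indicators
  g <- factor(rep(1:3, each = 10))
  Yg <- matrix(rnorm(9)[3 * (as.integer(g) - 1) + rep(1:3, each = 30)], 30, 3)
  expect_equal(rdaR2(Yg, g), 1, tolerance = 1e-10)
  # orthogonal design explains nothing
  Yo <- matrix(rep(c(-1, 1), 15), 30, 2)
  Xo <- matrix(rep(c(-1, -1, 1, 1), length.out = 30), 30, 1)
  expect_lt(rdaR2(Yo, Xo), 1e-10)
})

test_that("rdaR2 is bounded and monotone under added predictors", {
  set.seed(15)
  Y <- matrix(rnorm(120), 24, 5)
  X1 <- factor(rep(1:3, each = 8))
  X2 <- factor(rep(1:4, times = 6))
  r1 <- rdaR2(Y, X1); r2 <- rdaR2(Y, X2)
  D12 <- cbind(metabomark:::.designMatrix(X1), metabomark:::.designMatrix(X2))
  r12 <- rdaR2(Y, D12)
  expect_true(all(c(r1, r2, r12) >= 0 & c(r1, r2, r12) <= 1 + 1e-12))
  expect_gte(r12, max(r1, r2) - 1e-12)
})

test_that("adjusted R2 follows the Ezekiel formula", {
  expect_equal(adjustedR2(0.5, 11, 1), 1 - 0.5 * 10 / 9)
  expect_equal(adjustedR2(1, 20, 3), 1)
  expect_equal(adjustedR2(0.37, 50, 0), 0.37)
  expect_error(adjustedR2(0.5, 4, 3), "n > p")
})

test_that("variation partitioning identities and degenerate designs", {
  d <- generateCrossedResponse(seed = 6)
  vp <- variationPartition(d$Y, d$factor1, d$factor2, nPerm = 0)
  f <- fractions(vp)
  expect_lt(abs(sum(f) - 1), 1e-10)
  expect_equal(unname(f["a"] + f["b"]), unname(vp@r2["adj_x1"]),
               tolerance = 1e-10)
  expect_equal(unname(f["b"] + f["c"]), unname(vp@r2["adj_x2"]),
               tolerance = 1e-10)
  # duplicate factor: no unique fractions
  vpd <- variationPartition(d$Y, d$factor1, d$factor1, nPerm = 0)
  expect_lt(abs(fractions(vpd)["a"]), 1e-10)
  expect_lt(abs(fractions(vpd)["c"]), 1e-10)
  expect_equal(unname(fractions(vpd)["b"]), unname(vpd@r2["adj_x1"]),
               tolerance = 1e-10)
  # symmetry: swapping factors swaps a and c
  vps <- variationPartition(d$Y, d$factor2, d$factor1, nPerm = 0)
  expect_equal(unname(fractions(vps)["a"]), unname(f["c"]), tolerance = 1e-12)
  expect_equal(unname(fractions(vps)["c"]), unname(f["a"]), tolerance = 1e-12)
  expect_equal(unname(fractions(vps)["b"]), unname(f["b"]), tolerance = 1e-12)
})

test_that("fractions agree with vegan::varpart", {
  skip_if_not_installed("vegan")
  d <- generateCrossedResponse(seed = 16)
  vp <- variationPartition(d$Y, d$factor1, d$factor2, nPerm = 0)
  x1 <- d$factor1; x2 <- d$factor2
  v <- vegan::varpart(d$Y, ~x1, ~x2)
  # vegan rows: [a] = X1|X2, [b] = X2|X1, [c] = shared, [d] = residuals
  ind <- v$part$indfract$Adj.R.squared
  expect_equal(unname(fractions(vp)["a"]), ind[1], tolerance = 1e-10)
  expect_equal(unname(fractions(vp)["c"]), ind[2], tolerance = 1e-10)
  expect_equal(unname(fractions(vp)["b"]), ind[3], tolerance = 1e-10)
  expect_equal(unname(fractions(vp)["d"]), ind[4], tolerance = 1e-10)
})

test_that("permutation ANOVA bounds, strong effects and conditioning", {
  d <- generateCrossedResponse(varFrac1 = 0.5, varFrac2 = 0.1, seed = 26)
  pa <- permutationAnova(d$Y, d$factor1, d$factor2, nPerm = 99, seed = 2)
  expect_equal(pa$p.value, 1 / 100)  # strong planted effect: minimal p
  expect_gte(pa$p.value, 1 / (99 + 1))
  expect_lte(pa$p.value, 1)
  expect_error(permutationAnova(d$Y, d$factor1, d$factor2, nPerm = 50), "99")
})

test_that("clustering recovers planted blocks and respects Pearson scaling", {
  set.seed(33)
  base <- matrix(rnorm(40), 4, 10)
  profiles <- base[rep(1:4, times = c(4, 4, 3, 3)), ] +
    matrix(rnorm(140, 0, 0.05), 14, 10)
  rownames(profiles) <- sprintf("G%02d", 1:14)
  cut <- hclusterCut(profiles, k = 4)
  truthCl <- rep(1:4, times = c(4, 4, 3, 3))
  expect_equal(adjRandIndex(classAssignments(cut), truthCl), 1)
  expect_equal(length(unique(classAssignments(cut))), 4L)
  # row scaling leaves the partition unchanged (correlation distance)
  scaled <- profiles * rep(c(1, 10), length.out = 14)
  cut2 <- hclusterCut(scaled, k = 4)
  expect_equal(adjRandIndex(classAssignments(cut), classAssignments(cut2)), 1)
  # k = n: singletons
  cutN <- hclusterCut(profiles, k = 14)
  expect_equal(length(unique(classAssignments(cutN))), 14L)
  flat <- profiles; flat[2, ] <- 7
  expect_error(hclusterCut(flat, 3), "G02")
})

test_that("genotype grouping labels samples by their genotype's class", {
  cfg <- smallConfig(seed = 37)
  sim <- generateDataset(cfg)
  pp <- preprocess(sim$table)
  gg <- groupGenotypes(pp, "genotype", k = 3)
  expect_equal(gg$cut@k, 3)
  expect_length(gg$classLabels, ncol(pp))
  geno <- colData(pp)$genotype
  cl <- classAssignments(gg$cut)
  expect_true(all(gg$classLabels == sprintf("MC%d", cl[as.character(geno)])))
})

test_that("PCA explains variance fractions with the documented sign rule", {
  cfg <- smallConfig(seed = 43)
  sim <- generateDataset(cfg)
  pp <- preprocess(sim$table)
  pca <- pcaFingerprint(pp)
  expect_equal(sum(pca$explainedVariance), 1, tolerance = 1e-10)
  for (j in seq_len(ncol(pca$loadings))) {
    l <- pca$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  expect_error(pcaFingerprint(pp, nComponents = 10000), "exceeds")
  # rank-1 data: first component carries everything
  u <- rnorm(12); v <- rnorm(8)
  r1 <- featureTable(outer(v, u))
  p1 <- pcaFingerprint(r1, nComponents = 3)
  expect_equal(p1$explainedVariance[1], 1, tolerance = 1e-8)
})
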