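test_that("stratified split rounds per class and is seeded", {
  labels <- rep(letters[1:5], each = 10)
  sp <- stratifiedSplit(labels, c(0.6, 0.2, 0.2), seed = 4)
  expect_length(sp$train, 30)
  expect_length(sp$validation, 10)
  expect_length(sp$test, 10)
  for (cl in letters[1:5])
    expect_equal(sum(labels[sp$train] == cl), 6)
  expect_setequal(c(sp$train, sp$validation, sp$test), seq_along(labels))
  sp4 <- stratifiedSplit(rep("a", 4), c(0.5, 0.25, 0.25), seed = 1)
  expect_equal(lengths(sp4), c(train = 2L, validation = 1L, test = 1L))
  expect_identical(stratifiedSplit(labels, seed = 7),
                   stratifiedSplit(labels, seed = 7))
  expect_error(stratifiedSplit(c("a", "a", "b"), seed = 1), "fewer than 3")
  expect_error(stratifiedSplit(labels, c(0.5, 0.5, 0.2), seed = 1), "sum to 1")
})

test_that("full shrinkage zeroes coefficients and predicts the majority class", {
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  y <- factor(rep(c("a", "b"), c(12, 8)))
  m <- suppressWarnings(fitMultinomialElasticNet(X, y, alpha = 1, lambda = 50))
  expect_true(all(m@coefficients == 0))
  expect_true(all(predict(m, X) == "a"))
})

test_that("unpenalised separable problem reaches training accuracy 1", {
  X <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- factor(rep(c("lo", "hi"), each = 3), levels = c("lo", "hi"))
  m <- suppressWarnings(fitMultinomialElasticNet(X, y, alpha = 0.5, lambda = 0))
  expect_equal(mean(predict(m, X) == y), 1)
})

test_that("fitted objective matches the proximal-gradient oracle", {
  set.seed(12)
  for (i in 1:4) {
    n <- 15; p <- 3; K <- 3
    X <- scale(matrix(rnorm(n * p), n))
    y <- factor(rep(letters[1:K], length.out = n))
    alpha <- runif(1); lambda <- runif(1, 0.03, 0.3)
    m <- suppressWarnings(fitMultinomialElasticNet(X, y, alpha, lambda))
    o <- istaMultinomial(X, y, alpha, lambda)
    objFit <- enetObjectiveOracle(X, o$yInd, m@coefficients, m@intercepts,
                                  alpha, lambda)
    expect_lt(abs(objFit - o$objective), 1e-6)
  }
  expect_error(fitMultinomialElasticNet(matrix(1:4, 2), c("a", "b"),
                                        alpha = 2, lambda = 1), "alpha")
  expect_error(fitMultinomialElasticNet(matrix(1:4, 2), c("a", "b"),
                                        alpha = 0.5, lambda = -1), "lambda")
})

test_that("tuning tie-break prefers larger lambda then smaller alpha", {
  grid <- data.frame(alpha = c(0.2, 0.2, 0.8, 0.8),
                     lambda = c(0.5, 0.1, 0.5, 0.1),
                     accuracy = c(0.8, 0.8, 0.8, 0.8))
  best <- metabomark:::.selectBest(grid)
  expect_equal(best$alpha, 0.2)
  expect_equal(best$lambda, 0.5)
  grid$accuracy[2] <- 0.9
  best <- metabomark:::.selectBest(grid)
  expect_equal(best$lambda, 0.1)
  expect_equal(best$alpha, 0.2)
  expect_error(tuneAndFit(matrix(1, 2, 2), c("a", "b"), matrix(1, 2, 2),
                          c("a", "b"), alphaGrid = numeric(0)), "empty")
})

test_that("single-point grid reduces tuning to a plain fit", {
  set.seed(3)
  X <- matrix(rnorm(80), 20, 4)
  y <- factor(rep(c("a", "b"), each = 10))
  tuned <- suppressWarnings(
    tuneAndFit(X[1:12, ], y[1:12], X[13:20, ], y[13:20],
               alphaGrid = 0.5, lambdaPath = 0.1))
  direct <- suppressWarnings(
    fitMultinomialElasticNet(X[1:12, ], y[1:12], 0.5, 0.1))
  expect_equal(tuned@coefficients, direct@coefficients, tolerance = 1e-10)
  expect_equal(tuned@alpha, 0.5)
  expect_equal(tuned@lambda, 0.1)
})

test_that("selected-feature count shrinks monotonically along the lambda path", {
  cfg <- smallConfig(seed = 13)
  sim <- generateDataset(cfg)
  pp <- preprocess(sim$table)
  X <- scale(t(intensities(pp)))
  y <- factor(colData(pp)$chemotype)
  fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 1,
                        nlambda = 20, standardize = FALSE)
  nsel <- vapply(seq_along(fit$lambda), function(i) {
    co <- lapply(glmnet::coef.glmnet(fit, s = fit$lambda[i]),
                 function(b) as.numeric(b)[-1])
    sum(Reduce(`+`, lapply(co, function(b) b != 0)) > 0)
  }, numeric(1))
  # lambda decreasing along the path => selection non-decreasing
  expect_true(all(diff(nsel) >= 0))
})

test_that("ensemble bookkeeping, determinism and marker tie-breaks", {
  cfg <- smallConfig(seed = 17)
  sim <- generateDataset(cfg)
  pp <- preprocess(sim$table)
  ens <- runEnsemble(pp, "chemotype", fastControl(nModels = 4, baseSeed = 5))
  expect_equal(unname(occurrence(ens)),
               unname(as.integer(colSums(ens@selectionMatrix))))
  ens2 <- runEnsemble(pp, "chemotype", fastControl(nModels = 4, baseSeed = 5))
  expect_identical(testScores(ens), testScores(ens2))
  expect_identical(occurrence(ens), occurrence(ens2))

  # manual EnsembleResult to pin down ranking rules
  sel <- matrix(c(1, 1, 1, 0,
                  1, 1, 0, 0), nrow = 2, byrow = TRUE,
                dimnames = list(NULL, c("fB", "fA", "fC", "fD")))
  mk <- new("EnsembleResult", testScores = c(0.8, 0.9),
            selectionMatrix = sel,
            occurrence = structure(as.integer(colSums(sel)),
                                   names = colnames(sel)),
            classOccurrence = matrix(0, 4, 2,
                                     dimnames = list(colnames(sel), c("a", "b"))),
            classCoefMean = matrix(0, 4, 2,
                                   dimnames = list(colnames(sel), c("a", "b"))),
            meanAbsCoef = c(fB = 0.5, fA = 0.5, fC = 0.9, fD = 0),
            alphas = c(0.5, 0.5), lambdas = c(0.1, 0.1),
            classes = c("a", "b"), baseSeed = 1)
  ms <- selectMarkers(mk, k = 3)
  # occurrence 2,2,1,0; fB/fA tie on occurrence and coefficient -> id order
  expect_equal(featureIds(ms), c("fA", "fB", "fC"))
  expect_equal(occurrence(ms), c(2L, 2L, 1L))
  expect_warning(all4 <- selectMarkers(mk, k = 9), "returning all")
  expect_length(featureIds(all4), 4)
  expect_equal(length(featureIds(selectMarkers(mk, fraction = 0.5))), 2L)
  expect_error(selectMarkers(mk, k = 2, fraction = 0.5), "exactly one")
})

test_that("permutation null preserves label multiset and is reproducible", {
  cfg <- smallConfig(seed = 23)
  sim <- generateDataset(cfg)
  pp <- preprocess(sim$table)
  ctrl <- fastControl(nModels = 2, baseSeed = 31)
  n1 <- permutationNull(pp, "chemotype", 3, ctrl)
  n2 <- permutationNull(pp, "chemotype", 3, ctrl)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0 & n1 <= 1))
  perm <- metabomark:::.withSeed(65L, sample(factor(colData(pp)$chemotype)))
  expect_equal(sort(as.character(perm)),
               sort(as.character(colData(pp)$chemotype)))
})

test_that("score comparison is symmetric with degenerate conventions", {
  a <- c(0.9, 0.95, 0.85, 0.92)
  b <- c(0.2, 0.25, 0.18, 0.22)
  cmp <- compareScores(a, b)
  swp <- compareScores(b, a)
  expect_equal(cmp$statistic, -swp$statistic)
  expect_equal(cmp$p.value, swp$p.value)
  expect_lt(cmp$p.value, 1e-4)
  same <- compareScores(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(same$p.value, 1)
  diffc <- compareScores(c(0.8, 0.8), c(0.2, 0.2))
  expect_equal(diffc$p.value, 0)
  expect_equal(compareScores(a, a)$p.value, 1)
  expect_error(compareScores(0.5, b), "length")
})

test_that("transfer restricts to shared markers and scores the new batch", {
  cfg <- smallConfig(seed = 41, nFeatures = 150, fracChemotypeMarkers = 0.2,
                     batchShiftSigma = 0.2)
  sim <- generateDataset(cfg)
  pp <- preprocess(sim$table)
  ens <- runEnsemble(pp, "chemotype", fastControl(nModels = 3, baseSeed = 2))
  ms <- selectMarkers(ens, k = 20)
  comp <- generateComplementarySet(cfg, sim$truth, nSamplesPerGenotype = 4,
                                   dropFraction = 0.1)
  tr <- transferPredict(pp, "chemotype", comp, featureIds(ms),
                        newLabels = "chemotype", control = fastControl(baseSeed = 2))
  expect_setequal(tr$usedFeatures,
                  intersect(featureIds(ms), rownames(comp)))
  expect_equal(length(tr$model@featureIds), length(tr$usedFeatures))
  expect_length(tr$predictions, ncol(comp))
  expect_true(tr$accuracy >= 0 && tr$accuracy <= 1)
  expect_error(transferPredict(pp, "chemotype", comp, c("nope1", "nope2")),
               "absent from reference")
})
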