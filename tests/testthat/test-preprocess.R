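mkTable <- function(m, ...) {
  featureTable(m, sampleData = data.frame(..., row.names = colnames(m)))
}

test_that("blank filter boundary is inclusive and zero-blank features pass", {
  m <- rbind(F1 = rep(100, 4), F2 = rep(99, 4), F3 = rep(100, 4))
  colnames(m) <- paste0("S", 1:4)
  tab <- featureTable(m)
  bl <- rbind(F1 = rep(2, 2), F2 = rep(2, 2), F3 = rep(0, 2))
  colnames(bl) <- c("B1", "B2")
  blanks <- featureTable(bl)
  out <- blankFilter(tab, blanks, 50)
  expect_setequal(rownames(out), c("F1", "F3"))  # 100/2 = 50 kept, 99/2 dropped
  # feature absent from the blank table: treated as blank mean 0, kept
  bl2 <- featureTable(bl[1:2, , drop = FALSE])
  expect_true("F3" %in% rownames(blankFilter(tab, bl2, 50)))
  expect_error(blankFilter(tab, featureTable(matrix(1, 1, 2,
    dimnames = list("Z9", c("B1", "B2")))), 50), "overlap")
})

test_that("presence filter keeps boundary features, drops all-zero rows", {
  m <- rbind(F1 = c(1, 2, 0, 0), F2 = c(0, 0, 0, 0), F3 = c(1, 0, 0, 0))
  colnames(m) <- paste0("S", 1:4)
  tab <- featureTable(m)
  expect_setequal(rownames(presenceFilter(tab, 2)), "F1")
  expect_setequal(rownames(presenceFilter(tab, 1)), c("F1", "F3"))
  expect_error(presenceFilter(tab, 5), "exceeds")
})

test_that("filters are idempotent", {
  cfg <- smallConfig(seed = 4, blankFractionWeak = 0.1)
  sim <- generateDataset(cfg)
  blanks <- generateBlanks(cfg, 3)
  once <- blankFilter(sim$table, blanks)
  expect_identical(intensities(blankFilter(once, blanks)), intensities(once))
  once <- presenceFilter(sim$table, 2)
  expect_identical(intensities(presenceFilter(once, 2)), intensities(once))
})

test_that("IS normalisation divides by the IS channel and errors on bad IS", {
  m <- rbind(F1 = c(10, 20), F2 = c(4, 8), IS = c(2, 4))
  colnames(m) <- c("S1", "S2")
  tab <- featureTable(m, featureData = data.frame(
    is_internal_standard = c(FALSE, FALSE, TRUE), row.names = rownames(m)))
  out <- isNormalize(tab)
  expect_equal(unname(intensities(out)["F1", ]), c(5, 5))
  expect_false("IS" %in% rownames(out))
  # IS constant across samples: between-sample ranks unchanged
  m2 <- m; m2["IS", ] <- c(2, 2)
  tab2 <- featureTable(m2, featureData = data.frame(
    is_internal_standard = c(FALSE, FALSE, TRUE), row.names = rownames(m2)))
  expect_equal(rank(intensities(isNormalize(tab2))["F1", ]),
               rank(m2["F1", ]))
  m3 <- m; m3["IS", 2] <- 0
  tab3 <- featureTable(m3, featureData = data.frame(
    is_internal_standard = c(FALSE, FALSE, TRUE), row.names = rownames(m3)))
  expect_error(isNormalize(tab3), "S2")
})

test_that("dry-weight normalisation divides rows by sample weight", {
  tab <- tinyTable()
  out <- dryWeightNormalize(tab)
  expect_equal(unname(intensities(out)["F1", 2]), 12 / 2)
  bad <- tab
  expect_error({colData(bad)$dry_weight_mg[1] <- 0; validObject(bad)},
               "dry_weight_mg")
})

test_that("median normalisation equalises sample medians, preserves scale", {
  m <- cbind(S1 = c(1, 2, 3), S2 = c(2, 4, 6))
  rownames(m) <- paste0("F", 1:3)
  out <- medianNormalize(featureTable(m))
  med <- apply(intensities(out), 2, median)
  expect_equal(unname(diff(med)), 0)
  expect_equal(unname(intensities(out)[, 1]), unname(intensities(out)[, 2]))
  # single sample: identity
  one <- featureTable(cbind(S1 = c(1, 2, 3)))
  expect_equal(unname(intensities(medianNormalize(one))[, 1]), c(1, 2, 3))
  zero <- featureTable(cbind(S1 = c(1, 2, 3), S2 = c(0, 0, 0)))
  expect_error(medianNormalize(zero), "S2")
})

test_that("cube root is exact on knowns and preserves ranking", {
  m <- cbind(S1 = c(8, 0, 0.001), S2 = c(27, 1, 64))
  rownames(m) <- paste0("F", 1:3)
  out <- cubeRoot(featureTable(m))
  expect_equal(unname(intensities(out)[, 1]), c(2, 0, 0.1))
  x <- runif(20) * 100
  tabr <- featureTable(cbind(S1 = x, S2 = x + 1))
  expect_equal(order(intensities(cubeRoot(tabr))[, 1]), order(x))
  neg <- featureTable(cbind(S1 = c(-1, 2)))
  expect_error(cubeRoot(neg), "non-negative")
})

test_that("Pareto scaling matches its definition and zeroes constants", {
  m <- cbind(S1 = c(1, 5), S2 = c(2, 5), S3 = c(3, 5))
  rownames(m) <- c("F1", "F2")
  out <- paretoScale(featureTable(m))
  expect_equal(unname(intensities(out)["F1", ]), c(-1, 0, 1))  # sd = 1
  expect_equal(unname(intensities(out)["F2", ]), c(0, 0, 0))
  expect_error(paretoScale(featureTable(cbind(S1 = 1:3))), "two samples")
})

test_that("Pareto identity: variance after scaling equals sd before", {
  set.seed(1)
  m <- matrix(rlnorm(300, 5, 1), nrow = 20)
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  out <- paretoScale(featureTable(m))
  sdBefore <- apply(m, 1, sd)
  varAfter <- apply(intensities(out), 1, var)
  expect_lt(max(abs(varAfter - sdBefore)), 1e-10)
})

test_that("full chain runs in order and logs per-step feature counts", {
  cfg <- smallConfig(seed = 9, blankFractionWeak = 0.1)
  sim <- generateDataset(cfg)
  pp <- preprocess(sim$table, blanks = generateBlanks(cfg, 3))
  log <- metadata(pp)$preprocessLog
  expect_equal(log$step,
               c("blank_filter", "presence_filter", "is_normalize",
                 "dry_weight_normalize", "median_normalize", "cube_root",
                 "pareto_scale"))
  expect_false(any(rowData(pp)$is_internal_standard))
  # equal dry weights: median normalisation absorbs them into one global
  # scalar (the grand-median rescale keeps the input's units)
  tab <- sim$table
  colData(tab)$dry_weight_mg <- rep(2, ncol(tab))
  a <- medianNormalize(dryWeightNormalize(tab))
  b <- medianNormalize(tab)
  pos <- intensities(a) > 0
  ratio <- intensities(b)[pos] / intensities(a)[pos]
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
})
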