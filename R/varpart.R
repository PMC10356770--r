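#' @include AllClasses.R accessors.R
NULL

# Reference-cell (treatment-coded) indicator design for a factor; matrices
# pass through unchanged.
.designMatrix <- function(x) {
  if (is.matrix(x)) return(x)
  f <- droplevels(factor(x))
  stats::model.matrix(~f)[, -1, drop = FALSE]
}

# Projection of centred Y onto the column space of (1, X); rank deficiency
# is handled by the pivoting in qr() (pseudo-inverse contract).
.projectFit <- function(Yc, X) {
  q <- qr(cbind(1, X))
  qr.fitted(q, Yc)
}

.designRank <- function(X) qr(cbind(1, X))$rank - 1L

#' Redundancy-analysis R-squared
#'
#' Fraction of the total (centred) variance of a response matrix explained
#' by projection onto the column space of a design matrix:
#' `R2 = ||P_X Yc||^2_F / ||Yc||^2_F`.
#'
#' @param Y sample x feature response matrix.
#' @param X design matrix or factor (reference-cell coded internally).
#' @return R-squared in `[0, 1]`.
#' @export
rdaR2 <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- .designMatrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must have matching rows")
  if (nrow(Y) <= ncol(X)) stop("need more samples than predictors")
  Yc <- sweep(Y, 2, colMeans(Y))
  tot <- sum(Yc^2)
  if (tot == 0) return(0)
  sum(.projectFit(Yc, X)^2) / tot
}

#' Ezekiel-adjusted R-squared
#'
#' `1 - (1 - R2) (n - 1) / (n - p - 1)`; may be negative. With `p = 0` the
#' input is returned unchanged.
#'
#' @param r2 raw R-squared.
#' @param n number of samples.
#' @param p number of predictors (design rank).
#' @return adjusted R-squared.
#' @export
adjustedR2 <- function(r2, n, p) {
  if (p == 0) return(r2)
  if (n <= p + 1) stop("adjusted R2 requires n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Permutation ANOVA for a partial (conditioned) effect
#'
#' Tests the effect of `Xtest` given `Xcond` by the pseudo-F of the partial
#' redundancy model, permuting the residuals of the conditioning model
#' (residual permutation, the standard scheme for partial RDA):
#' `p = (1 + #(F_perm >= F_obs)) / (1 + nPerm)`.
#'
#' @param Y sample x feature response matrix.
#' @param Xtest design (or factor) whose partial effect is tested.
#' @param Xcond conditioning design, or `NULL` for a marginal test.
#' @param nPerm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return list with `statistic` (pseudo-F), `p.value` and `nPerm`.
#' @export
permutationAnova <- function(Y, Xtest, Xcond = NULL, nPerm = 999, seed = 1L) {
  if (nPerm < 99) stop("nPerm must be >= 99")
  Y <- as.matrix(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  Xtest <- .designMatrix(Xtest)
  Xcond <- if (is.null(Xcond)) matrix(numeric(0), nrow(Y), 0)
           else .designMatrix(Xcond)
  n <- nrow(Y)
  Xfull <- cbind(Xcond, Xtest)
  rFull <- .designRank(Xfull)
  rCond <- .designRank(Xcond)
  if (rFull >= n) stop("design rank must be below the number of samples")
  dfTest <- rFull - rCond
  dfRes <- n - 1 - rFull
  if (dfTest == 0) {
    # X_test adds nothing beyond X_cond (fully nested/confounded designs):
    # there is no partial effect to test
    return(list(statistic = NA_real_, p.value = NA_real_, nPerm = nPerm))
  }
  tot <- sum(Yc^2)
  condFit <- if (ncol(Xcond) > 0) .projectFit(Yc, Xcond) else
    matrix(0, n, ncol(Yc))
  pseudoF <- function(Ymat) {
    Ymc <- sweep(Ymat, 2, colMeans(Ymat))
    ssFull <- sum(.projectFit(Ymc, Xfull)^2)
    ssCond <- if (ncol(Xcond) > 0) sum(.projectFit(Ymc, Xcond)^2) else 0
    ((ssFull - ssCond) / dfTest) / ((sum(Ymc^2) - ssFull) / dfRes)
  }
  fObs <- pseudoF(Yc)
  resid <- Yc - condFit
  fPerm <- .withSeed(seed, vapply(seq_len(nPerm), function(i) {
    pseudoF(condFit + resid[sample.int(n), , drop = FALSE])
  }, numeric(1)))
  list(statistic = fObs,
       p.value = (1 + sum(fPerm >= fObs)) / (1 + nPerm),
       nPerm = nPerm)
}

#' Two-factor variation partitioning by partial redundancy analysis
#'
#' Decomposes the adjusted explained variance of `Y` into the fraction
#' unique to `X1` (a), unique to `X2` (c), shared (b) and residual (d):
#' `a = adjR2(X1 u X2) - adjR2(X2)`, `c = adjR2(X1 u X2) - adjR2(X1)`,
#' `b = adjR2(X1) - a`, `d = 1 - adjR2(X1 u X2)`. Unique fractions are
#' tested by residual-permutation ANOVA of the partial models; the shared
#' fraction has no valid permutation test and is reported untested.
#'
#' @param Y sample x feature response matrix (e.g. the Pareto-scaled table,
#'   transposed to samples-in-rows).
#' @param X1,X2 explanatory factors (e.g. chemotype and maternal genotype)
#'   or ready-made design matrices.
#' @param nPerm permutations for the partial tests (0 to skip testing).
#' @param seed RNG seed for the permutation tests.
#' @return a [VarpartResult-class].
#' @export
variationPartition <- function(Y, X1, X2, nPerm = 999, seed = 1L) {
  Y <- as.matrix(Y)
  D1 <- .designMatrix(X1)
  D2 <- .designMatrix(X2)
  n <- nrow(Y)
  if (.designRank(cbind(D1, D2)) >= n)
    stop("combined design rank must be below the number of samples")
  r1 <- rdaR2(Y, D1)
  r2 <- rdaR2(Y, D2)
  r12 <- rdaR2(Y, cbind(D1, D2))
  a1 <- adjustedR2(r1, n, .designRank(D1))
  a2 <- adjustedR2(r2, n, .designRank(D2))
  a12 <- adjustedR2(r12, n, .designRank(cbind(D1, D2)))
  a <- a12 - a2
  c_ <- a12 - a1
  b <- a1 - a
  d <- 1 - a12
  pv <- c(a = NA_real_, c = NA_real_)
  if (nPerm > 0) {
    pv["a"] <- permutationAnova(Y, D1, D2, nPerm = nPerm,
                                seed = seed)$p.value
    pv["c"] <- permutationAnova(Y, D2, D1, nPerm = nPerm,
                                seed = seed + 1L)$p.value
  }
  new("VarpartResult",
      fractions = c(a = a, b = b, c = c_, d = d),
      r2 = c(r2_x1 = r1, r2_x2 = r2, r2_x12 = r12,
             adj_x1 = a1, adj_x2 = a2, adj_x12 = a12),
      pValues = pv, nPerm = as.numeric(nPerm))
}

#' Principal component analysis of a feature table
#'
#' Eigendecomposition of the feature covariance (no further scaling beyond
#' the upstream chain; the table is expected to be Pareto-scaled). The sign
#' convention makes the largest-magnitude loading of each component
#' positive.
#'
#' @param table a [FeatureTable-class].
#' @param nComponents components to keep (default all, `min(n - 1, p)`).
#' @return list with `scores` (samples x components), `loadings` (features x
#'   components) and `explainedVariance` (fractions).
#' @export
pcaFingerprint <- function(table, nComponents = NULL) {
  stopifnot(is(table, "FeatureTable"))
  if (ncol(table) < 2) stop("PCA requires at least two samples")
  X <- t(intensities(table))
  maxComp <- min(nrow(X) - 1, ncol(X))
  if (is.null(nComponents)) nComponents <- maxComp
  if (nComponents > maxComp)
    stop("nComponents exceeds min(n - 1, p) = ", maxComp)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  keep <- seq_len(nComponents)
  flip <- vapply(keep, function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  list(scores = sweep(pc$x[, keep, drop = FALSE], 2, flip, `*`),
       loadings = sweep(pc$rotation[, keep, drop = FALSE], 2, flip, `*`),
       explainedVariance = (pc$sdev^2 / sum(pc$sdev^2))[keep])
}

#' Hierarchical clustering on correlation distance, cut into k classes
#'
#' Agglomerative clustering of entity profiles with distance
#' `d = 1 - Pearson correlation` and Ward linkage (`ward.D2`), cut to
#' exactly `k` classes.
#'
#' @param profiles entity x feature numeric matrix (no constant rows).
#' @param k number of classes (`<=` number of entities).
#' @return a [DendrogramCut-class].
#' @export
hclusterCut <- function(profiles, k) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- sprintf("E%02d", seq_len(nrow(profiles)))
  if (k > nrow(profiles)) stop("k exceeds the number of entities")
  sdv <- apply(profiles, 1, stats::sd)
  if (any(sdv == 0))
    stop("constant profile row(s): ",
         paste(rownames(profiles)[sdv == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(t(profiles)))
  hc <- stats::hclust(d, method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  new("DendrogramCut", hclust = hc, k = k, classes = cl)
}

#' Group maternal genotypes into k classes by their mean profiles
#'
#' Computes the per-genotype mean feature profile from a (preprocessed)
#' table and clusters the genotypes with [hclusterCut()]. Used to turn many
#' maternal genotypes into a few classes with enough samples per class for
#' ensemble modelling.
#'
#' @param table a preprocessed [FeatureTable-class].
#' @param genotypes genotype label per sample (vector or `sampleData` column
#'   name, default `"genotype"`).
#' @param k number of classes (default 4).
#' @return list with `cut` (a [DendrogramCut-class]) and `classLabels`
#'   (per-sample class labels, `"MC1"...`).
#' @export
groupGenotypes <- function(table, genotypes = "genotype", k = 4) {
  stopifnot(is(table, "FeatureTable"))
  genotypes <- .resolveLabels(table, genotypes)
  m <- intensities(table)
  profiles <- t(vapply(levels(genotypes), function(g)
    rowMeans(m[, genotypes == g, drop = FALSE]), numeric(nrow(m))))
  cut <- hclusterCut(profiles, k)
  classLabels <- factor(sprintf("MC%d", cut@classes[as.character(genotypes)]))
  list(cut = cut, classLabels = classLabels)
}
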