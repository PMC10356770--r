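#' @include AllClasses.R accessors.R preprocess.R
#' @importFrom glmnet glmnet
NULL

#' Stratified train/validation/test split
#'
#' Partitions sample indices class by class with largest-remainder rounding
#' of the per-class counts, so each class is represented in every partition
#' in (as close as possible to) the requested proportions. The shuffle
#' within classes is seeded.
#'
#' @param labels class label per sample.
#' @param fractions positive `(train, validation, test)` fractions summing
#'   to 1 (default `c(0.6, 0.2, 0.2)`).
#' @param seed RNG seed for the within-class shuffle.
#' @return list of integer index vectors `train`, `validation`, `test`;
#'   disjoint and covering `seq_along(labels)`.
#' @export
stratifiedSplit <- function(labels, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  labels <- droplevels(factor(labels))
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be positive and sum to 1")
  small <- names(which(table(labels) < 3))
  if (length(small))
    stop("class(es) with fewer than 3 samples: ", paste(small, collapse = ", "))
  .withSeed(seed, {
    parts <- list(train = integer(0), validation = integer(0),
                  test = integer(0))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      counts <- floor(n * fractions)
      short <- n - sum(counts)
      if (short > 0) {
        # largest remainder; ties resolved in listed order (train first)
        extra <- order(n * fractions - counts, decreasing = TRUE)[seq_len(short)]
        counts[extra] <- counts[extra] + 1
      }
      splits <- split(idx, rep(seq_along(counts), counts))
      for (k in seq_along(parts))
        parts[[k]] <- c(parts[[k]], splits[[as.character(k)]])
    }
    lapply(parts, sort)
  })
}

# Column standardisation used before every fit: the penalty is then
# comparable across features. Returns the scaled matrix and the transform.
.standardize <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0))
    stop("constant feature column(s): ",
         paste(colnames(X)[sdv == 0], collapse = ", "))
  list(X = sweep(sweep(X, 2, mu), 2, sdv, `/`), mu = mu, sd = sdv)
}

.applyStandardize <- function(X, std) {
  sweep(sweep(X, 2, std$mu), 2, std$sd, `/`)
}

# glmnet nags whenever a class has < 8 observations; resampled 60% splits of
# field-sized classes trip this constantly, so the advisory is muffled.
.glmnetQuiet <- function(...) {
  withCallingHandlers(glmnet::glmnet(...),
    warning = function(w) {
      if (grepl("fewer than 8|one multinomial or binomial class",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# glmnet needs >= 2 predictor columns; a zero column is inert under both
# penalty and likelihood, so single-feature problems are padded with one.
.padIfNeeded <- function(X) {
  if (ncol(X) >= 2) return(list(X = X, padded = FALSE))
  list(X = cbind(X, ..pad.. = 0), padded = TRUE)
}

.coefFromGlmnet <- function(fit, lambda, classes, p) {
  co <- stats::coef(fit, s = lambda)
  beta <- t(vapply(classes, function(cl) as.numeric(co[[cl]])[-1],
                   numeric(p)))
  b0 <- vapply(classes, function(cl) as.numeric(co[[cl]])[1], numeric(1))
  list(beta = matrix(beta, nrow = length(classes)), b0 = b0)
}

#' Fit one multinomial elastic-net model
#'
#' Minimises the glmnet-family objective
#' `-(1/n) loglik + lambda * sum_j [(1-alpha)/2 ||beta_j||^2 + alpha ||beta_j||_1]`
#' (symmetric multinomial parameterisation, ungrouped per-coefficient L1,
#' unpenalised intercepts) via [glmnet::glmnet()], with features
#' standardised to unit variance internally and coefficients reported on the
#' input scale.
#'
#' @param X sample x feature numeric matrix (no constant columns).
#' @param y class label per row of `X`.
#' @param alpha elastic-net mixing parameter in `[0, 1]`.
#' @param lambda penalty strength `>= 0`.
#' @param thresh glmnet convergence threshold (tight by default so the
#'   attained objective is reproducible to ~1e-8).
#' @return an [ElasticNetModel-class].
#' @export
fitMultinomialElasticNet <- function(X, y, alpha, lambda, thresh = 1e-12) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X contains non-finite values")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    stop("lambda must be >= 0")
  y <- droplevels(factor(y))
  if (nrow(X) < nlevels(y)) stop("need at least one sample per class")
  if (is.null(colnames(X))) colnames(X) <- sprintf("X%d", seq_len(ncol(X)))
  std <- .standardize(X)
  pad <- .padIfNeeded(std$X)
  # short warm-start path down to the target keeps coordinate descent stable
  lamSeq <- if (lambda > 0) lambda * c(100, 10, 3, 1) else c(1, 0.1, 0.01, 0)
  fit <- .glmnetQuiet(pad$X, y, family = "multinomial", alpha = alpha,
                        lambda = lamSeq, standardize = FALSE,
                        thresh = thresh, maxit = 1e7)
  cf <- .coefFromGlmnet(fit, lambda, levels(y), ncol(pad$X))
  beta <- cf$beta
  if (pad$padded) beta <- beta[, 1, drop = FALSE]
  betaInput <- sweep(beta, 2, std$sd, `/`)
  b0Input <- cf$b0 - as.numeric(betaInput %*% std$mu)
  colnames(betaInput) <- colnames(X)
  new("ElasticNetModel", classes = levels(y), coefficients = betaInput,
      intercepts = b0Input, alpha = alpha, lambda = lambda,
      featureIds = colnames(X), valAccuracy = NA_real_)
}

#' Predict classes from an ElasticNetModel
#'
#' @param object an [ElasticNetModel-class].
#' @param newdata sample x feature matrix; columns are matched to the
#'   model's `featureIds` by name when named.
#' @param type `"class"` (default) for labels, `"link"` for the K linear
#'   predictors, `"prob"` for softmax probabilities.
#' @return predictions per row of `newdata`.
#' @export
setMethod("predict", "ElasticNetModel",
          function(object, newdata, type = c("class", "link", "prob")) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    miss <- setdiff(object@featureIds, colnames(newdata))
    if (length(miss))
      stop("newdata lacks feature(s): ", paste(miss, collapse = ", "))
    newdata <- newdata[, object@featureIds, drop = FALSE]
  } else if (ncol(newdata) != length(object@featureIds))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object@featureIds))
  eta <- sweep(newdata %*% t(object@coefficients), 2, object@intercepts, `+`)
  colnames(eta) <- object@classes
  if (type == "link") return(eta)
  pr <- exp(eta - apply(eta, 1, max))
  pr <- pr / rowSums(pr)
  if (type == "prob") return(pr)
  factor(object@classes[max.col(pr, ties.method = "first")],
         levels = object@classes)
})

# Deterministic argmax over a tuning grid: highest validation accuracy,
# ties to the larger lambda, then to the smaller alpha.
.selectBest <- function(grid) {
  ord <- order(-grid$accuracy, -grid$lambda, grid$alpha)
  grid[ord[1], , drop = FALSE]
}

#' Tune (alpha, lambda) on a validation set and refit
#'
#' For every mixing value in `alphaGrid`, fits the lambda path on the
#' training set and scores each (alpha, lambda) pair on the validation set;
#' the accuracy-maximising pair (ties: larger lambda, then smaller alpha) is
#' refit on the training set and returned.
#'
#' @param Xtrain,ytrain training samples and labels.
#' @param Xval,yval validation samples and labels (same feature space).
#' @param alphaGrid mixing values in `[0, 1]`.
#' @param lambdaPath explicit decreasing lambda sequence, or `NULL` to let
#'   glmnet compute a per-alpha geometric path of `nLambda` values.
#' @param nLambda path length when `lambdaPath` is `NULL`.
#' @return an [ElasticNetModel-class] with `valAccuracy` filled in.
#' @export
tuneAndFit <- function(Xtrain, ytrain, Xval, yval,
                       alphaGrid = seq(0, 1, length.out = 1000),
                       lambdaPath = NULL, nLambda = 30) {
  if (length(alphaGrid) == 0 || (!is.null(lambdaPath) && length(lambdaPath) == 0))
    stop("empty tuning grid")
  Xtrain <- as.matrix(Xtrain); Xval <- as.matrix(Xval)
  ytrain <- droplevels(factor(ytrain))
  yval <- factor(yval, levels = levels(ytrain))
  std <- .standardize(Xtrain)
  padTr <- .padIfNeeded(std$X)
  Xvs <- .applyStandardize(Xval, std)
  if (padTr$padded) Xvs <- cbind(Xvs, 0)
  rows <- list()
  for (a in alphaGrid) {
    fit <- if (is.null(lambdaPath))
      .glmnetQuiet(padTr$X, ytrain, family = "multinomial", alpha = a,
                     nlambda = nLambda, standardize = FALSE)
    else
      .glmnetQuiet(padTr$X, ytrain, family = "multinomial", alpha = a,
                     lambda = sort(lambdaPath, decreasing = TRUE),
                     standardize = FALSE)
    pred <- predict(fit, Xvs, type = "class")
    acc <- colMeans(pred == as.character(yval))
    rows[[length(rows) + 1]] <- data.frame(alpha = a, lambda = fit$lambda,
                                           accuracy = as.numeric(acc))
  }
  grid <- do.call(rbind, rows)
  best <- .selectBest(grid)
  model <- fitMultinomialElasticNet(Xtrain, ytrain, best$alpha, best$lambda)
  model@valAccuracy <- best$accuracy
  model
}

#' Ensemble control parameters
#'
#' Defaults reflect the full-scale analysis (500 models, a 1000-point alpha
#' grid); reduced grids are appropriate for exploratory or desk-scale runs.
#'
#' @param nModels number of resampled models.
#' @param fractions train/validation/test fractions.
#' @param alphaGrid mixing-parameter grid in `[0, 1]`.
#' @param nLambda lambda path length per alpha.
#' @param baseSeed base seed; model m uses `baseSeed + m`.
#' @return a named list of class `EnsembleControl`.
#' @export
ensembleControl <- function(nModels = 500, fractions = c(0.6, 0.2, 0.2),
                            alphaGrid = seq(0, 1, length.out = 1000),
                            nLambda = 30, baseSeed = 1L) {
  stopifnot(nModels >= 1, all(alphaGrid >= 0 & alphaGrid <= 1))
  structure(list(nModels = nModels, fractions = fractions,
                 alphaGrid = alphaGrid, nLambda = nLambda,
                 baseSeed = as.integer(baseSeed)),
            class = "EnsembleControl")
}

# One split -> tune -> fit -> score cycle; the workhorse shared by
# runEnsemble and permutationNull.
.oneModel <- function(X, labels, control, seed) {
  split <- stratifiedSplit(labels, control$fractions, seed = seed)
  model <- tuneAndFit(X[split$train, , drop = FALSE], labels[split$train],
                      X[split$validation, , drop = FALSE],
                      labels[split$validation],
                      alphaGrid = control$alphaGrid,
                      nLambda = control$nLambda)
  pred <- predict(model, X[split$test, , drop = FALSE])
  list(model = model,
       score = mean(as.character(pred) == as.character(labels[split$test])))
}

#' Run the resampled elastic-net ensemble
#'
#' Performs `nModels` independent split -> tune -> fit -> score cycles with
#' per-model seeds `baseSeed + m`, recording each model's held-out test
#' accuracy and which features it selected (any nonzero class coefficient at
#' the chosen pair). Feature occurrence across models is the basis of marker
#' selection.
#'
#' @param table a preprocessed [FeatureTable-class].
#' @param labels class per sample (vector or `sampleData` column name).
#' @param control an [ensembleControl()].
#' @return an [EnsembleResult-class].
#' @examples
#' \donttest{
#' cfg <- simulationConfig(nChemotypes = 3, nGenotypes = 6,
#'                         nSamplesPerGenotype = 5, nFeatures = 60)
#' sim <- generateDataset(cfg)
#' pp <- preprocess(sim$table)
#' res <- runEnsemble(pp, "chemotype",
#'                    ensembleControl(nModels = 5, alphaGrid = c(0.5),
#'                                    nLambda = 10))
#' res
#' }
#' @export
runEnsemble <- function(table, labels, control = ensembleControl()) {
  stopifnot(is(table, "FeatureTable"))
  labels <- .resolveLabels(table, labels)
  X <- t(intensities(table))
  p <- ncol(X)
  K <- nlevels(labels)
  scores <- numeric(control$nModels)
  alphas <- numeric(control$nModels)
  lambdas <- numeric(control$nModels)
  selection <- matrix(0L, control$nModels, p,
                      dimnames = list(NULL, colnames(X)))
  classOcc <- matrix(0L, p, K, dimnames = list(colnames(X), levels(labels)))
  coefSum <- matrix(0, p, K, dimnames = dimnames(classOcc))
  absSum <- numeric(p)
  for (m in seq_len(control$nModels)) {
    res <- .oneModel(X, labels, control, seed = control$baseSeed + m)
    scores[m] <- res$score
    alphas[m] <- res$model@alpha
    lambdas[m] <- res$model@lambda
    beta <- res$model@coefficients         # K x p
    nz <- colSums(beta != 0) > 0
    selection[m, ] <- as.integer(nz)
    classOcc <- classOcc + t(beta != 0)
    coefSum <- coefSum + t(beta)
    absSum <- absSum + ifelse(nz, colMeans(abs(beta)), 0)
  }
  occ <- as.integer(colSums(selection))
  names(occ) <- colnames(X)
  meanAbs <- ifelse(occ > 0, absSum / occ, 0)
  names(meanAbs) <- colnames(X)
  classMean <- sweep(coefSum, 1, pmax(occ, 1L), `/`)
  new("EnsembleResult", testScores = scores, selectionMatrix = selection,
      occurrence = occ, classOccurrence = classOcc, classCoefMean = classMean,
      meanAbsCoef = meanAbs, alphas = alphas, lambdas = lambdas,
      classes = levels(labels), baseSeed = as.numeric(control$baseSeed))
}

#' Select markers by occurrence across the ensemble
#'
#' Features are ranked by selection occurrence (descending), ties broken by
#' the mean |coefficient| over the selecting models (descending), then by
#' feature id (ascending) so the ranking is fully reproducible.
#'
#' @param result an [EnsembleResult-class].
#' @param k number of markers, or
#' @param fraction top fraction of candidate features
#'   (`floor(fraction * p)` markers); give exactly one of `k`/`fraction`.
#' @return a [MarkerSet-class].
#' @export
selectMarkers <- function(result, k = NULL, fraction = NULL) {
  stopifnot(is(result, "EnsembleResult"))
  if (is.null(k) == is.null(fraction))
    stop("give exactly one of k or fraction")
  p <- length(result@occurrence)
  rule <- if (!is.null(k)) list(type = "top_k", value = k)
          else list(type = "top_fraction", value = fraction)
  size <- if (!is.null(k)) k else floor(fraction * p)
  if (size > p) {
    warning("requested ", size, " markers from ", p,
            " candidate features; returning all")
    size <- p
  }
  if (size < 1) stop("marker set size must be >= 1")
  ids <- names(result@occurrence)
  ord <- order(-result@occurrence, -result@meanAbsCoef, ids)
  pick <- ord[seq_len(size)]
  new("MarkerSet", featureIds = ids[pick],
      occurrence = unname(result@occurrence[pick]),
      rule = rule,
      coefSummary = result@classCoefMean[pick, , drop = FALSE])
}

#' Permutation-null score distribution
#'
#' For each of `nPerm` permuted datasets the labels are shuffled once (label
#' multiset preserved), then one full split -> tune -> fit -> score cycle is
#' run. The returned test scores estimate the accuracy attainable by chance.
#'
#' @param table a preprocessed [FeatureTable-class].
#' @param labels class per sample.
#' @param nPerm number of permuted datasets (>= 1).
#' @param control an [ensembleControl()]; `baseSeed + i` seeds permutation i.
#' @return numeric vector of `nPerm` null test accuracies.
#' @export
permutationNull <- function(table, labels, nPerm,
                            control = ensembleControl()) {
  stopifnot(is(table, "FeatureTable"))
  if (nPerm < 1) stop("nPerm must be >= 1")
  labels <- .resolveLabels(table, labels)
  X <- t(intensities(table))
  vapply(seq_len(nPerm), function(i) {
    seed <- control$baseSeed + i
    perm <- .withSeed(seed * 2L + 1L, sample(labels))
    .oneModel(X, perm, control, seed = seed)$score
  }, numeric(1))
}

#' Compare real and null score distributions
#'
#' Welch two-sample t-test on the two score vectors. Degenerate inputs
#' (both zero-variance) return p = 1 when the means agree and p = 0
#' otherwise.
#'
#' @param realScores,nullScores numeric vectors, each of length >= 2.
#' @return list with `statistic` (t), `df` and `p.value`.
#' @export
compareScores <- function(realScores, nullScores) {
  if (length(realScores) < 2 || length(nullScores) < 2)
    stop("both score vectors need length >= 2")
  if (stats::sd(realScores) == 0 && stats::sd(nullScores) == 0) {
    d <- mean(realScores) - mean(nullScores)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                df = NA_real_, p.value = as.numeric(d == 0)))
  }
  tt <- stats::t.test(realScores, nullScores)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Transfer a marker model to a complementary batch
#'
#' Restricts the marker panel to features present in both batches (markers
#' may be lost when a later batch is processed independently), normalises
#' the new batch with its own median/cube-root/Pareto chain, tunes and
#' refits one model on the full reference set over the shared markers, and
#' predicts the new batch.
#'
#' @param reference the preprocessed reference [FeatureTable-class] (the
#'   batch the model equations are calculated on).
#' @param labels class per reference sample.
#' @param new the raw complementary [FeatureTable-class].
#' @param markerIds marker feature ids (must exist in `reference`).
#' @param newLabels optional class per new sample (vector or `sampleData`
#'   column name of `new`) to score accuracy against.
#' @param control an [ensembleControl()] used for the tuning split and grid.
#' @return list with `model`, `predictions`, `accuracy` (`NA` without
#'   `newLabels`) and `usedFeatures` (the shared markers).
#' @export
transferPredict <- function(reference, labels, new, markerIds,
                            newLabels = NULL, control = ensembleControl()) {
  stopifnot(is(reference, "FeatureTable"), is(new, "FeatureTable"))
  miss <- setdiff(markerIds, rownames(reference))
  if (length(miss))
    stop("marker(s) absent from reference: ", paste(miss, collapse = ", "))
  labels <- .resolveLabels(reference, labels)
  shared <- intersect(markerIds, rownames(new))
  if (length(shared) < 2)
    stop("fewer than 2 markers shared with the new batch")
  newProc <- paretoScale(cubeRoot(medianNormalize(new)))
  Xref <- t(intensities(reference)[shared, , drop = FALSE])
  Xnew <- t(intensities(newProc)[shared, , drop = FALSE])
  split <- stratifiedSplit(labels, control$fractions,
                           seed = control$baseSeed)
  tuned <- tuneAndFit(Xref[split$train, , drop = FALSE], labels[split$train],
                      Xref[split$validation, , drop = FALSE],
                      labels[split$validation],
                      alphaGrid = control$alphaGrid,
                      nLambda = control$nLambda)
  model <- fitMultinomialElasticNet(Xref, labels, tuned@alpha, tuned@lambda)
  pred <- predict(model, Xnew)
  acc <- NA_real_
  if (!is.null(newLabels)) {
    newLabels <- .resolveLabels(new, newLabels)
    acc <- mean(as.character(pred) == as.character(newLabels))
  }
  list(model = model, predictions = pred, accuracy = acc,
       usedFeatures = shared)
}
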