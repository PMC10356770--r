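#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' FeatureTable: a sample x feature intensity table with aligned metadata
#'
#' `FeatureTable` extends [SummarizedExperiment::SummarizedExperiment] and is
#' the container every pipeline stage consumes and produces. Features are
#' stored in rows and samples in columns (the Bioconductor convention); the
#' delimited-text readers and writers transpose to/from the samples-in-rows
#' layout used on disk.
#'
#' The single assay is named `"intensity"`. Per-sample metadata live in
#' `colData` (typically `chemotype`, `genotype`, `batch`, `dry_weight_mg`,
#' `plot_type`), per-feature metadata in `rowData` (typically `platform`,
#' `retention_time_min`, `mz`, `is_internal_standard`).
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [featureTable()] for the constructor, [intensities()],
#'   [sampleData()], [featureData()] for accessors.
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- NULL
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else if (!is.numeric(assay(object, "intensity")))
    msg <- c(msg, "assay 'intensity' must be numeric")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample ids")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated feature ids")
  if ("dry_weight_mg" %in% colnames(colData(object))) {
    dw <- colData(object)$dry_weight_mg
    if (any(!is.finite(dw)) || any(dw <= 0))
      msg <- c(msg, "dry_weight_mg must be positive and finite")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a FeatureTable
#'
#' @param intensities numeric matrix, features in rows, samples in columns.
#'   Dimnames are used as feature/sample ids; defaults (`F0001...`,
#'   `S0001...`) are generated when absent.
#' @param sampleData `data.frame` or `DataFrame` of per-sample metadata,
#'   one row per column of `intensities`.
#' @param featureData per-feature metadata, one row per row of `intensities`.
#' @return a [FeatureTable-class] object.
#' @examples
#' m <- matrix(rlnorm(20), nrow = 4)
#' ft <- featureTable(m, sampleData = data.frame(chemotype = rep(c("A", "B"), c(3, 2))))
#' ft
#' @export
featureTable <- function(intensities, sampleData = NULL, featureData = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("F%04d", seq_len(nrow(intensities)))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- sprintf("S%04d", seq_len(ncol(intensities)))
  if (is.null(sampleData))
    sampleData <- DataFrame(row.names = colnames(intensities))
  if (is.null(featureData))
    featureData <- DataFrame(row.names = rownames(intensities))
  se <- SummarizedExperiment(
    assays = list(intensity = intensities),
    colData = sampleData, rowData = featureData)
  new("FeatureTable", se)
}

#' GroundTruth: the synthetic generator's ledger of planted effects
#'
#' Records which features carry chemotype vs. genotype effects, the planted
#' log-scale effect matrices, class-exclusive (structural-zero) assignments,
#' per-feature blank behaviour and the complementary-batch log shift.
#'
#' @slot chemoMarkerIds,genoMarkerIds character, disjoint feature id sets.
#' @slot chemoEffects numeric matrix feature x chemotype of log-mean shifts.
#' @slot genoEffects numeric matrix feature x genotype of log-mean shifts.
#' @slot exclusiveClass named character; for class-exclusive markers the only
#'   chemotype in which the feature occurs, `NA` otherwise.
#' @slot weakBlankIds character; features planted to fail the blank-ratio rule.
#' @slot batchShift named numeric; per-feature log shift applied to the
#'   complementary batch.
#' @slot config the `SimulationConfig` used.
#' @export
setClass("GroundTruth", representation(
  chemoMarkerIds = "character",
  genoMarkerIds  = "character",
  chemoEffects   = "matrix",
  genoEffects    = "matrix",
  exclusiveClass = "character",
  weakBlankIds   = "character",
  batchShift     = "numeric",
  config         = "list"))

setValidity("GroundTruth", function(object) {
  msg <- NULL
  if (length(intersect(object@chemoMarkerIds, object@genoMarkerIds)) > 0)
    msg <- c(msg, "chemotype and genotype marker sets must be disjoint")
  nm <- rownames(object@chemoEffects)
  nonmark <- setdiff(nm, object@chemoMarkerIds)
  if (length(nonmark) && any(object@chemoEffects[nonmark, , drop = FALSE] != 0))
    msg <- c(msg, "non-marker rows of chemoEffects must be zero")
  nonmark <- setdiff(rownames(object@genoEffects), object@genoMarkerIds)
  if (length(nonmark) && any(object@genoEffects[nonmark, , drop = FALSE] != 0))
    msg <- c(msg, "non-marker rows of genoEffects must be zero")
  if (is.null(msg)) TRUE else msg
})

#' ElasticNetModel: one fitted multinomial elastic-net model
#'
#' Coefficients follow the glmnet-family symmetric multinomial
#' parameterisation: one coefficient vector per class, with the objective
#' `-(1/n) loglik + lambda * sum_j [ (1-alpha)/2 ||beta_j||^2 + alpha ||beta_j||_1 ]`
#' (intercepts unpenalised, per-coefficient L1, i.e. ungrouped).
#'
#' @slot classes ordered class labels (length K).
#' @slot coefficients K x p matrix, input (unstandardised) scale.
#' @slot intercepts length-K numeric.
#' @slot alpha elastic-net mixing parameter in `[0, 1]`.
#' @slot lambda penalty strength, `>= 0`.
#' @slot featureIds length-p character.
#' @slot valAccuracy validation accuracy at the chosen pair (NA when not tuned).
#' @export
setClass("ElasticNetModel", representation(
  classes      = "character",
  coefficients = "matrix",
  intercepts   = "numeric",
  alpha        = "numeric",
  lambda       = "numeric",
  featureIds   = "character",
  valAccuracy  = "numeric"))

setValidity("ElasticNetModel", function(object) {
  msg <- NULL
  if (nrow(object@coefficients) != length(object@classes))
    msg <- c(msg, "coefficient rows must match classes")
  if (ncol(object@coefficients) != length(object@featureIds))
    msg <- c(msg, "coefficient columns must match featureIds")
  if (length(object@intercepts) != length(object@classes))
    msg <- c(msg, "one intercept per class required")
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (object@lambda < 0)
    msg <- c(msg, "lambda must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' EnsembleResult: scores and selections across the resampled models
#'
#' One row of `selectionMatrix` per model; a feature is selected in a model
#' iff any class coefficient is nonzero at that model's chosen (alpha, lambda).
#'
#' @slot testScores per-model test-set accuracy in `[0, 1]`.
#' @slot selectionMatrix model x feature 0/1 matrix.
#' @slot occurrence named integer, column sums of `selectionMatrix`.
#' @slot classOccurrence feature x class counts of nonzero class coefficients.
#' @slot classCoefMean feature x class mean coefficient across the models
#'   that selected the feature.
#' @slot meanAbsCoef named numeric; mean |coefficient| over the models that
#'   selected the feature (0 for never-selected features). Used to break
#'   occurrence ties in [selectMarkers()].
#' @slot alphas,lambdas per-model chosen tuning parameters.
#' @slot classes class labels of the task.
#' @slot baseSeed integer base seed; model m uses seed `baseSeed + m`.
#' @export
setClass("EnsembleResult", representation(
  testScores      = "numeric",
  selectionMatrix = "matrix",
  occurrence      = "integer",
  classOccurrence = "matrix",
  classCoefMean   = "matrix",
  meanAbsCoef     = "numeric",
  alphas          = "numeric",
  lambdas         = "numeric",
  classes         = "character",
  baseSeed        = "numeric"))

setValidity("EnsembleResult", function(object) {
  msg <- NULL
  if (length(object@testScores) != nrow(object@selectionMatrix))
    msg <- c(msg, "one test score per model required")
  if (!identical(unname(object@occurrence),
                 as.integer(unname(colSums(object@selectionMatrix)))))
    msg <- c(msg, "occurrence must equal column sums of selectionMatrix")
  if (any(object@testScores < 0 | object@testScores > 1))
    msg <- c(msg, "test scores must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' MarkerSet: occurrence-ranked selected features
#'
#' @slot featureIds ranked feature ids (best first).
#' @slot occurrence selection counts aligned with `featureIds`.
#' @slot rule list with elements `type` (`"top_k"` or `"top_fraction"`) and
#'   `value`.
#' @slot coefSummary marker x class matrix of mean coefficients across the
#'   selecting models.
#' @export
setClass("MarkerSet", representation(
  featureIds  = "character",
  occurrence  = "integer",
  rule        = "list",
  coefSummary = "matrix"))

#' VarpartResult: adjusted-R2 fractions of a two-factor variation partition
#'
#' Fractions follow the standard a/b/c/d decomposition: `a` unique to the
#' first factor, `c` unique to the second, `b` shared, `d` residual;
#' `a + b + c + d = 1` by construction. Unique fractions carry permutation
#' p-values from the partial test; the shared fraction is not testable.
#'
#' @slot fractions named numeric `c(a=, b=, c=, d=)` of adjusted-R2 fractions.
#' @slot r2 named numeric: raw and adjusted R2 of X1, X2 and their union.
#' @slot pValues named numeric p-values for fractions `a` and `c`.
#' @slot nPerm permutations used for the tests.
#' @export
setClass("VarpartResult", representation(
  fractions = "numeric",
  r2        = "numeric",
  pValues   = "numeric",
  nPerm     = "numeric"))

setValidity("VarpartResult", function(object) {
  msg <- NULL
  if (!all(c("a", "b", "c", "d") %in% names(object@fractions)))
    msg <- c(msg, "fractions must be named a, b, c, d")
  else {
    if (abs(sum(object@fractions) - 1) > 1e-8)
      msg <- c(msg, "fractions must sum to 1")
    if (any(object@fractions[c("a", "c")] < -0.05))
      msg <- c(msg, "unique fractions below -0.05 indicate a mis-specified design")
  }
  if (is.null(msg)) TRUE else msg
})

#' DendrogramCut: a Ward/Pearson dendrogram cut into k classes
#'
#' @slot hclust the [stats::hclust] merge history (Ward linkage on
#'   1 - Pearson correlation distances).
#' @slot k requested number of classes.
#' @slot classes named integer class assignment per leaf.
#' @export
setClass("DendrogramCut", representation(
  hclust  = "ANY",
  k       = "numeric",
  classes = "integer"))

setValidity("DendrogramCut", function(object) {
  if (length(unique(object@classes)) != object@k)
    "cut must produce exactly k classes" else TRUE
})
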