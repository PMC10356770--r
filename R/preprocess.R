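#' @include AllClasses.R accessors.R
NULL

.isFlag <- function(table) {
  fd <- rowData(table)
  if ("is_internal_standard" %in% colnames(fd))
    as.logical(fd$is_internal_standard)
  else rep(FALSE, nrow(table))
}

.logStep <- function(table, step, before, after) {
  log <- metadata(table)$preprocessLog
  log <- rbind(log, data.frame(step = step, features_in = before,
                               features_out = after))
  metadata(table)$preprocessLog <- log
  table
}

#' Blank-ratio feature filter
#'
#' Retains features whose mean intensity across samples is at least
#' `ratioMin` times the mean intensity across blanks (boundary inclusive,
#' reading "at least 50 times higher" as `>=`). Features absent from the
#' blank table are treated as blank mean 0 and always retained. A feature
#' flagged as the internal standard is exempt: it is a spiked chemical
#' standard, present in blanks by design.
#'
#' @param table a [FeatureTable-class] of samples.
#' @param blanks a [FeatureTable-class] of blank injections, aligned by
#'   feature id.
#' @param ratioMin minimum sample/blank mean ratio (default 50).
#' @return the filtered [FeatureTable-class].
#' @export
blankFilter <- function(table, blanks, ratioMin = 50) {
  stopifnot(is(table, "FeatureTable"), is(blanks, "FeatureTable"))
  if (!is.numeric(ratioMin) || ratioMin <= 0)
    stop("ratioMin must be > 0")
  shared <- intersect(rownames(table), rownames(blanks))
  if (length(shared) == 0)
    stop("no overlapping features between table and blanks")
  sampleMean <- rowMeans(intensities(table))
  blankMean <- rep(0, nrow(table))
  names(blankMean) <- rownames(table)
  blankMean[shared] <- rowMeans(intensities(blanks))[shared]
  keep <- sampleMean >= ratioMin * blankMean
  keep <- keep | .isFlag(table)
  out <- table[keep, ]
  .logStep(out, "blank_filter", nrow(table), nrow(out))
}

#' Presence filter
#'
#' Retains features detected (intensity > 0) in at least `minPresence`
#' samples. The internal-standard feature is exempt.
#'
#' @param table a [FeatureTable-class].
#' @param minPresence minimum number of samples with a detection (default 2).
#' @return the filtered [FeatureTable-class].
#' @export
presenceFilter <- function(table, minPresence = 2) {
  stopifnot(is(table, "FeatureTable"))
  if (!is.numeric(minPresence) || minPresence < 1)
    stop("minPresence must be >= 1")
  if (minPresence > ncol(table))
    stop("minPresence (", minPresence, ") exceeds the number of samples (",
         ncol(table), ")")
  keep <- rowSums(intensities(table) > 0) >= minPresence
  keep <- keep | .isFlag(table)
  out <- table[keep, ]
  .logStep(out, "presence_filter", nrow(table), nrow(out))
}

#' Internal-standard normalisation
#'
#' Divides every feature intensity by the sample's internal-standard
#' intensity, then removes the internal-standard feature from the table.
#' Exactly one feature must be flagged `is_internal_standard` and it must be
#' positive in every sample.
#'
#' @param table a [FeatureTable-class].
#' @return the normalised [FeatureTable-class] without the IS feature.
#' @export
isNormalize <- function(table) {
  stopifnot(is(table, "FeatureTable"))
  isIdx <- which(.isFlag(table))
  if (length(isIdx) != 1)
    stop("exactly one feature must be flagged is_internal_standard (found ",
         length(isIdx), ")")
  isRow <- intensities(table)[isIdx, ]
  bad <- colnames(table)[!is.finite(isRow) | isRow <= 0]
  if (length(bad))
    stop("internal standard is zero or missing in sample(s): ",
         paste(bad, collapse = ", "))
  m <- sweep(intensities(table), 2, isRow, `/`)
  out <- table
  intensities(out) <- m
  out <- out[-isIdx, ]
  .logStep(out, "is_normalize", nrow(table), nrow(out))
}

#' Dry-weight normalisation
#'
#' Divides each sample's intensities by its dry weight
#' (`sampleData(table)$dry_weight_mg`).
#'
#' @param table a [FeatureTable-class] with a `dry_weight_mg` sample column.
#' @return the normalised [FeatureTable-class].
#' @export
dryWeightNormalize <- function(table) {
  stopifnot(is(table, "FeatureTable"))
  if (!"dry_weight_mg" %in% colnames(colData(table)))
    stop("sample metadata lacks dry_weight_mg")
  dw <- colData(table)$dry_weight_mg
  if (any(!is.finite(dw)) || any(dw <= 0))
    stop("non-positive dry weight in sample(s): ",
         paste(colnames(table)[!is.finite(dw) | dw <= 0], collapse = ", "))
  out <- table
  intensities(out) <- sweep(intensities(table), 2, dw, `/`)
  .logStep(out, "dry_weight_normalize", nrow(table), nrow(out))
}

#' Median normalisation
#'
#' Divides each sample by its median over features and rescales by the grand
#' median of per-sample medians, so all per-sample medians are equal
#' afterwards and the overall intensity scale is preserved.
#'
#' @param table a [FeatureTable-class]; every sample must have a positive
#'   median.
#' @return the normalised [FeatureTable-class].
#' @export
medianNormalize <- function(table) {
  stopifnot(is(table, "FeatureTable"))
  med <- apply(intensities(table), 2, stats::median)
  bad <- colnames(table)[!is.finite(med) | med <= 0]
  if (length(bad))
    stop("non-positive sample median in sample(s): ",
         paste(bad, collapse = ", "))
  grand <- stats::median(med)
  out <- table
  intensities(out) <- sweep(intensities(table), 2, grand / med, `*`)
  .logStep(out, "median_normalize", nrow(table), nrow(out))
}

#' Cube-root transformation
#'
#' Elementwise `x^(1/3)`; monotone, maps 0 to 0. Errors on negative input
#' (the canonical normalisation order guarantees non-negativity here).
#'
#' @param table a [FeatureTable-class] with non-negative intensities.
#' @return the transformed [FeatureTable-class].
#' @export
cubeRoot <- function(table) {
  stopifnot(is(table, "FeatureTable"))
  m <- intensities(table)
  if (any(m < 0))
    stop("cube-root transformation requires non-negative intensities")
  out <- table
  intensities(out) <- m^(1 / 3)
  .logStep(out, "cube_root", nrow(table), nrow(out))
}

#' Pareto scaling
#'
#' Per feature: centre by the mean and divide by the square root of the
#' sample (n-1) standard deviation. Constant features map to all zeros.
#'
#' @param table a [FeatureTable-class] with at least two samples.
#' @return the scaled [FeatureTable-class].
#' @export
paretoScale <- function(table) {
  stopifnot(is(table, "FeatureTable"))
  if (ncol(table) < 2)
    stop("Pareto scaling requires at least two samples")
  m <- intensities(table)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  centred <- m - mu
  scl <- sqrt(sdv)
  scl[sdv == 0] <- 1  # constant features: centred row is already all zeros
  out <- table
  intensities(out) <- centred / scl
  .logStep(out, "pareto_scale", nrow(table), nrow(out))
}

#' Preprocessing configuration
#'
#' @param blankRatioMin blank-rule threshold (default 50).
#' @param minPresence presence-rule threshold (default 2).
#' @param steps ordered step names, a subset of `blank_filter`,
#'   `presence_filter`, `is_normalize`, `dry_weight_normalize`,
#'   `median_normalize`, `cube_root`, `pareto_scale`. The default is the
#'   canonical full chain in that order.
#' @return a `PreprocessConfig` list.
#' @export
preprocessConfig <- function(blankRatioMin = 50, minPresence = 2,
                             steps = c("blank_filter", "presence_filter",
                                       "is_normalize", "dry_weight_normalize",
                                       "median_normalize", "cube_root",
                                       "pareto_scale")) {
  known <- c("blank_filter", "presence_filter", "is_normalize",
             "dry_weight_normalize", "median_normalize", "cube_root",
             "pareto_scale")
  if (!all(steps %in% known))
    stop("unknown preprocessing step(s): ",
         paste(setdiff(steps, known), collapse = ", "))
  if (blankRatioMin <= 0) stop("blankRatioMin must be > 0")
  if (minPresence < 1) stop("minPresence must be >= 1")
  structure(list(blankRatioMin = blankRatioMin, minPresence = minPresence,
                 steps = steps), class = "PreprocessConfig")
}

#' Run the preprocessing chain
#'
#' Applies the configured steps in the given order. Steps that need blanks
#' or metadata are skipped with a message when the requirement is absent
#' (e.g. no blank table, no flagged internal standard, no dry weights), so
#' the same config serves tables of differing provenance.
#'
#' @param table a [FeatureTable-class].
#' @param blanks optional blank [FeatureTable-class] for the blank filter.
#' @param config a [preprocessConfig()].
#' @return the preprocessed [FeatureTable-class]; the per-step feature counts
#'   are recorded in `metadata(result)$preprocessLog`.
#' @examples
#' cfg <- simulationConfig(nChemotypes = 3, nGenotypes = 6,
#'                         nSamplesPerGenotype = 4, nFeatures = 40)
#' sim <- generateDataset(cfg)
#' pp <- preprocess(sim$table, blanks = generateBlanks(cfg, 3))
#' metadata(pp)$preprocessLog
#' @export
preprocess <- function(table, blanks = NULL, config = preprocessConfig()) {
  stopifnot(is(table, "FeatureTable"))
  for (step in config$steps) {
    table <- switch(step,
      blank_filter = {
        if (is.null(blanks)) {
          message("no blank table supplied; skipping blank_filter")
          table
        } else blankFilter(table, blanks, config$blankRatioMin)
      },
      presence_filter = presenceFilter(table, config$minPresence),
      is_normalize = {
        if (!any(.isFlag(table))) {
          message("no internal standard flagged; skipping is_normalize")
          table
        } else isNormalize(table)
      },
      dry_weight_normalize = {
        if (!"dry_weight_mg" %in% colnames(colData(table))) {
          message("no dry weights in metadata; skipping dry_weight_normalize")
          table
        } else dryWeightNormalize(table)
      },
      median_normalize = medianNormalize(table),
      cube_root = cubeRoot(table),
      pareto_scale = paretoScale(table))
  }
  table
}
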