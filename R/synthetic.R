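#' @include AllClasses.R
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulation configuration for the synthetic metabolomics generator
#'
#' Defines the study design the generator emulates: a set of chemotypes each
#' derived from several maternal genotypes, a mostly quantitative (log-scale
#' multiplicative) difference structure between classes with a minority of
#' class-exclusive (structural-zero) features, an internal-standard channel,
#' per-sample dry weights, blank signals, and an optional complementary batch
#' with a per-feature log shift.
#'
#' Defaults mirror the field design the package models: 5 chemotypes derived
#' from 14 maternal genotypes (2-3 genotypes per chemotype), 13 samples per
#' genotype (182 samples), and a marker structure whose class-exclusive share
#' (`fracChemotypeMarkers * fracClassExclusive` = 21% of features) leaves 79%
#' of features present in every chemotype.
#'
#' @param nChemotypes number of chemotype classes.
#' @param nGenotypes number of maternal genotypes.
#' @param genotypeToChemotype integer vector of length `nGenotypes` assigning
#'   each genotype to a chemotype, or `NULL` for an automatic balanced
#'   (round-robin) nesting.
#' @param nSamplesPerGenotype samples per genotype (>= 3).
#' @param nFeatures number of metabolite features (excluding the internal
#'   standard, which is appended as an extra flagged feature).
#' @param fracChemotypeMarkers,fracGenotypeMarkers fractions of features
#'   carrying chemotype / genotype effects (disjoint sets; sum <= 1).
#' @param effectSizeChemo,effectSizeGeno planted log-scale mean shifts in
#'   multiples of `noiseSigma`.
#' @param noiseSigma log-scale SD of the multiplicative intensity noise.
#' @param fracClassExclusive fraction of chemotype markers that are structural
#'   zeros outside their chemotype.
#' @param baselineLogMean log intensity location of a typical feature.
#' @param blankFractionWeak fraction of features whose blank signal is strong
#'   enough to violate the 50x blank rule.
#' @param isIntensityCV coefficient of variation of the per-sample technical
#'   factor carried by the internal-standard channel.
#' @param dryWeightMeanMg,dryWeightCV per-sample dry weight distribution (mg).
#' @param batchShiftSigma SD of the per-feature log shift applied to the
#'   complementary batch (0 = no batch effect).
#' @param seed RNG seed; identical configs give byte-identical tables.
#' @return a `SimulationConfig` (validated named list).
#' @seealso [generateDataset()], [generateBlanks()],
#'   [generateComplementarySet()]
#' @export
simulationConfig <- function(nChemotypes = 5,
                             nGenotypes = 14,
                             genotypeToChemotype = NULL,
                             nSamplesPerGenotype = 13,
                             nFeatures = 500,
                             fracChemotypeMarkers = 0.30,
                             fracGenotypeMarkers = 0.10,
                             effectSizeChemo = 2,
                             effectSizeGeno = 2,
                             noiseSigma = 0.4,
                             fracClassExclusive = 0.70,
                             baselineLogMean = 10,
                             blankFractionWeak = 0.05,
                             isIntensityCV = 0.15,
                             dryWeightMeanMg = 8,
                             dryWeightCV = 0.25,
                             batchShiftSigma = 0,
                             seed = 1L) {
  if (is.null(genotypeToChemotype))
    genotypeToChemotype <- rep(seq_len(nChemotypes), length.out = nGenotypes)
  cfg <- list(nChemotypes = nChemotypes, nGenotypes = nGenotypes,
              genotypeToChemotype = as.integer(genotypeToChemotype),
              nSamplesPerGenotype = nSamplesPerGenotype,
              nFeatures = nFeatures,
              fracChemotypeMarkers = fracChemotypeMarkers,
              fracGenotypeMarkers = fracGenotypeMarkers,
              effectSizeChemo = effectSizeChemo,
              effectSizeGeno = effectSizeGeno,
              noiseSigma = noiseSigma,
              fracClassExclusive = fracClassExclusive,
              baselineLogMean = baselineLogMean,
              blankFractionWeak = blankFractionWeak,
              isIntensityCV = isIntensityCV,
              dryWeightMeanMg = dryWeightMeanMg,
              dryWeightCV = dryWeightCV,
              batchShiftSigma = batchShiftSigma,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

#' Validate a SimulationConfig, naming the offending field
#' @param config a `SimulationConfig`.
#' @return the config, invisibly; errors name the invalid field.
#' @export
validateSimulationConfig <- function(config) {
  bad <- function(field, why)
    stop("invalid SimulationConfig: field '", field, "' ", why, call. = FALSE)
  num1 <- function(field) {
    v <- config[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      bad(field, "must be a finite number")
    v
  }
  for (f in c("fracChemotypeMarkers", "fracGenotypeMarkers",
              "fracClassExclusive", "blankFractionWeak"))
    if (num1(f) < 0 || config[[f]] > 1) bad(f, "must lie in [0, 1]")
  if (config$fracChemotypeMarkers + config$fracGenotypeMarkers > 1)
    bad("fracChemotypeMarkers", "+ fracGenotypeMarkers must be <= 1")
  if (num1("nChemotypes") < 1) bad("nChemotypes", "must be >= 1")
  if (num1("nGenotypes") < 1) bad("nGenotypes", "must be >= 1")
  if (num1("nSamplesPerGenotype") < 3)
    bad("nSamplesPerGenotype", "must be >= 3")
  if (num1("nFeatures") < 1) bad("nFeatures", "must be >= 1")
  for (f in c("noiseSigma", "isIntensityCV", "dryWeightCV", "batchShiftSigma",
              "effectSizeChemo", "effectSizeGeno"))
    if (num1(f) < 0) bad(f, "must be >= 0")
  if (num1("dryWeightMeanMg") <= 0) bad("dryWeightMeanMg", "must be > 0")
  num1("baselineLogMean")
  map <- config$genotypeToChemotype
  if (length(map) != config$nGenotypes)
    bad("genotypeToChemotype", "must have one entry per genotype")
  if (!all(map %in% seq_len(config$nChemotypes)))
    bad("genotypeToChemotype", "must map into 1..nChemotypes")
  if (!all(seq_len(config$nChemotypes) %in% map))
    bad("genotypeToChemotype", "must cover every chemotype")
  if (config$nGenotypes >= 2 * config$nChemotypes &&
      any(table(factor(map, levels = seq_len(config$nChemotypes))) < 2))
    bad("genotypeToChemotype", "must give every chemotype >= 2 genotypes")
  invisible(config)
}

# Deterministic structural layout shared by all generator entry points:
# marker assignment, exclusivity, blank behaviour, batch shift, feature
# metadata. Drawn from config$seed so dataset, blanks and complementary set
# agree feature-by-feature.
.simLayout <- function(config) {
  .withSeed(config$seed, {
    p <- config$nFeatures
    K <- config$nChemotypes
    G <- config$nGenotypes
    ids <- sprintf("F%04d", seq_len(p))
    nChemoM <- round(config$fracChemotypeMarkers * p)
    nGenoM <- round(config$fracGenotypeMarkers * p)
    markerIdx <- sample.int(p, nChemoM + nGenoM)
    chemoIdx <- markerIdx[seq_len(nChemoM)]
    genoIdx <- setdiff(markerIdx, chemoIdx)

    chemoEffects <- matrix(0, p, K, dimnames = list(ids, .chemoLabels(K)))
    upClass <- rep(seq_len(K), length.out = nChemoM)
    for (m in seq_along(chemoIdx))
      chemoEffects[chemoIdx[m], upClass[m]] <-
        config$effectSizeChemo * config$noiseSigma

    genoEffects <- matrix(0, p, G, dimnames = list(ids, .genoLabels(G)))
    upGeno <- rep(seq_len(G), length.out = nGenoM)
    for (m in seq_along(genoIdx))
      genoEffects[genoIdx[m], upGeno[m]] <-
        config$effectSizeGeno * config$noiseSigma

    nExcl <- round(config$fracClassExclusive * nChemoM)
    exclusiveClass <- rep(NA_character_, p)
    names(exclusiveClass) <- ids
    if (nExcl > 0) {
      exclPick <- sample(seq_len(nChemoM), nExcl)
      exclusiveClass[chemoIdx[exclPick]] <- .chemoLabels(K)[upClass[exclPick]]
    }

    nWeak <- round(config$blankFractionWeak * p)
    weakBlankIds <- if (nWeak > 0) sample(ids, nWeak) else character(0)

    batchShift <- stats::rnorm(p, 0, config$batchShiftSigma)
    names(batchShift) <- ids

    featureMeta <- DataFrame(
      platform = sample(c("GC", "LC"), p, replace = TRUE, prob = c(0.1, 0.9)),
      retention_time_min = round(stats::runif(p, 1.25, 29), 3),
      mz = round(stats::runif(p, 90, 1300), 4),
      is_internal_standard = FALSE,
      row.names = ids)

    list(ids = ids, chemoEffects = chemoEffects, genoEffects = genoEffects,
         chemoMarkerIds = ids[sort(chemoIdx)], genoMarkerIds = ids[sort(genoIdx)],
         exclusiveClass = exclusiveClass, weakBlankIds = sort(weakBlankIds),
         batchShift = batchShift, featureMeta = featureMeta)
  })
}

.chemoLabels <- function(K) sprintf("CT%d", seq_len(K))
.genoLabels <- function(G) sprintf("G%02d", seq_len(G))

# Internal-standard nominal intensity: well above typical features, as a
# spiked chemical standard would be.
.isBase <- function(config) exp(config$baselineLogMean + 1)

# Draw one batch of samples given the structural layout. The per-sample
# technical factor (extraction/injection) multiplies every feature AND the
# internal standard; the dry-weight factor multiplies features only (the IS
# is spiked into the solvent, not the tissue).
.drawBatch <- function(config, layout, nPerGenotype, batchLabel, sampleOffset,
                       batchShift = NULL) {
  K <- config$nChemotypes
  G <- config$nGenotypes
  geno <- rep(seq_len(G), each = nPerGenotype)
  chemo <- config$genotypeToChemotype[geno]
  n <- length(geno)
  p <- config$nFeatures

  techFactor <- exp(stats::rnorm(n, 0, sqrt(log(1 + config$isIntensityCV^2))))
  dw <- config$dryWeightMeanMg *
    exp(stats::rnorm(n, -log(1 + config$dryWeightCV^2) / 2,
                     sqrt(log(1 + config$dryWeightCV^2))))

  logMu <- matrix(config$baselineLogMean, p, n)
  logMu <- logMu + layout$chemoEffects[, chemo, drop = FALSE]
  logMu <- logMu + layout$genoEffects[, geno, drop = FALSE]
  if (!is.null(batchShift)) logMu <- logMu + batchShift
  eps <- matrix(stats::rnorm(p * n, 0, config$noiseSigma), p, n)
  intens <- exp(logMu + eps)

  excl <- !is.na(layout$exclusiveClass)
  if (any(excl)) {
    chemoLab <- .chemoLabels(K)[chemo]
    for (j in which(excl))
      intens[j, chemoLab != layout$exclusiveClass[j]] <- 0
  }

  intens <- sweep(intens, 2, techFactor * dw / config$dryWeightMeanMg, `*`)
  isRow <- .isBase(config) * techFactor
  intens <- rbind(intens, IS_hydrocortisone = isRow)
  sampleIds <- sprintf("S%04d", sampleOffset + seq_len(n))
  colnames(intens) <- sampleIds
  rownames(intens) <- c(layout$ids, "IS_hydrocortisone")

  sampleMeta <- DataFrame(
    chemotype = .chemoLabels(K)[chemo],
    genotype = .genoLabels(G)[geno],
    batch = batchLabel,
    dry_weight_mg = dw,
    plot_type = rep_len(c("homogeneous", "heterogeneous"), n),
    row.names = sampleIds)

  featureMeta <- rbind(
    layout$featureMeta,
    DataFrame(platform = "LC", retention_time_min = 12.5, mz = 407.2075,
              is_internal_standard = TRUE,
              row.names = "IS_hydrocortisone"))

  featureTable(intens, sampleData = sampleMeta, featureData = featureMeta)
}

#' Generate a synthetic feature table with a planted ground truth
#'
#' Intensities follow a log-normal model:
#' `intensity = exp(baseline + chemotype effect + genotype effect + noise)`,
#' scaled by a per-sample technical factor (shared with the appended
#' internal-standard channel) and a per-sample dry-weight factor.
#' Class-exclusive marker features are structural zeros outside their
#' chemotype. Genotype effects are nested within chemotypes (each genotype
#' belongs to one chemotype) but planted on an independent feature set, so
#' downstream variation partitioning has a non-trivial shared fraction.
#'
#' @param config a [simulationConfig()].
#' @return a list with elements `table` (a [FeatureTable-class], features x
#'   samples, internal standard included as the last flagged feature) and
#'   `truth` (a [GroundTruth-class] ledger).
#' @examples
#' cfg <- simulationConfig(nChemotypes = 3, nGenotypes = 6,
#'                         nSamplesPerGenotype = 4, nFeatures = 50)
#' sim <- generateDataset(cfg)
#' sim$table
#' sim$truth
#' @export
generateDataset <- function(config) {
  validateSimulationConfig(config)
  layout <- .simLayout(config)
  table <- .withSeed(config$seed + 1L,
    .drawBatch(config, layout, config$nSamplesPerGenotype,
               batchLabel = "reference", sampleOffset = 0L))
  truth <- new("GroundTruth",
               chemoMarkerIds = layout$chemoMarkerIds,
               genoMarkerIds = layout$genoMarkerIds,
               chemoEffects = as.matrix(layout$chemoEffects),
               genoEffects = as.matrix(layout$genoEffects),
               exclusiveClass = layout$exclusiveClass,
               weakBlankIds = layout$weakBlankIds,
               batchShift = layout$batchShift,
               config = unclass(config))
  list(table = table, truth = truth)
}

#' Generate blank samples matching a configuration
#'
#' Blank intensities are low for most features (sample/blank ratio around
#' 5000x); for the configured `blankFractionWeak` of features the blank mean
#' is set high enough that the sample/blank ratio falls well below 50. The
#' internal standard is present in blanks at its nominal level, as a
#' solvent-spiked standard is.
#'
#' @param config a [simulationConfig()]; must be the one used for
#'   [generateDataset()] so the weak-blank feature set aligns.
#' @param nBlanks number of blank samples (>= 1).
#' @return a [FeatureTable-class] of blanks (batch `"blank"`).
#' @export
generateBlanks <- function(config, nBlanks) {
  validateSimulationConfig(config)
  if (!is.numeric(nBlanks) || length(nBlanks) != 1 || nBlanks < 1)
    stop("nBlanks must be >= 1")
  nBlanks <- as.integer(nBlanks)
  layout <- .simLayout(config)
  .withSeed(config$seed + 2L, {
    p <- config$nFeatures
    blankMean <- rep(exp(config$baselineLogMean) / 5000, p)
    names(blankMean) <- layout$ids
    blankMean[layout$weakBlankIds] <- exp(config$baselineLogMean) / 10
    intens <- matrix(blankMean, p, nBlanks) *
      exp(matrix(stats::rnorm(p * nBlanks, 0, 0.3), p, nBlanks))
    intens <- rbind(intens, .isBase(config) *
                      exp(stats::rnorm(nBlanks, 0, 0.05)))
    rownames(intens) <- c(layout$ids, "IS_hydrocortisone")
    colnames(intens) <- sprintf("BLK%02d", seq_len(nBlanks))
    sampleMeta <- DataFrame(batch = rep("blank", nBlanks),
                            row.names = colnames(intens))
    featureMeta <- rbind(
      layout$featureMeta,
      DataFrame(platform = "LC", retention_time_min = 12.5, mz = 407.2075,
                is_internal_standard = TRUE,
                row.names = "IS_hydrocortisone"))
    featureTable(intens, sampleData = sampleMeta, featureData = featureMeta)
  })
}

#' Generate a complementary (validation-batch) sample set
#'
#' New samples share the ground truth's effect structure; every feature
#' receives the ledger's per-feature log batch shift (drawn with
#' `batchShiftSigma` at dataset generation), and a configurable random subset
#' of features is dropped entirely, mimicking markers that are not refound
#' when a later batch is processed independently.
#'
#' @param config the [simulationConfig()] used for [generateDataset()].
#' @param truth the matching [GroundTruth-class].
#' @param nSamplesPerGenotype samples per genotype in the new batch
#'   (default: as in `config`).
#' @param dropFraction fraction of features (uniformly at random) absent from
#'   the new batch.
#' @return a [FeatureTable-class] (batch `"complementary"`).
#' @export
generateComplementarySet <- function(config, truth,
                                     nSamplesPerGenotype = NULL,
                                     dropFraction = 0) {
  validateSimulationConfig(config)
  if (!is(truth, "GroundTruth"))
    stop("truth must be a GroundTruth object")
  if (!identical(truth@config$seed, config$seed) ||
      !identical(truth@config$nFeatures, config$nFeatures) ||
      !identical(truth@config$nGenotypes, config$nGenotypes))
    stop("config does not match the GroundTruth ledger ",
         "(seed, nFeatures and nGenotypes must agree)")
  if (dropFraction < 0 || dropFraction >= 1)
    stop("dropFraction must lie in [0, 1)")
  if (is.null(nSamplesPerGenotype))
    nSamplesPerGenotype <- config$nSamplesPerGenotype
  layout <- .simLayout(config)
  tab <- .withSeed(config$seed + 3L, {
    t0 <- .drawBatch(config, layout, nSamplesPerGenotype,
                     batchLabel = "complementary",
                     sampleOffset = 100000L,
                     batchShift = truth@batchShift)
    nDrop <- round(dropFraction * config$nFeatures)
    if (nDrop > 0) {
      dropped <- sample(layout$ids, nDrop)
      t0 <- t0[setdiff(rownames(t0), dropped), ]
    }
    t0
  })
  tab
}

#' Generate a balanced crossed two-factor response with known unique variance
#'
#' Builds a response matrix `Y = effect(factor1) + effect(factor2) + noise`
#' on a balanced crossed design. Level effects are centred and rescaled so
#' the between-level sum of squares of each factor is exactly the requested
#' share of the expected total, making the raw redundancy-analysis R2 of each
#' factor land on `varFrac1`/`varFrac2` up to realised noise variance. In a
#' balanced crossed design the two (centred) effect vectors are exactly
#' orthogonal, so the planted shared fraction is zero.
#'
#' Used to validate [variationPartition()] by generative recovery.
#'
#' @param nLevels1,nLevels2 factor level counts.
#' @param nPerCell replicates per cell of the crossed design.
#' @param nFeatures response columns.
#' @param varFrac1,varFrac2 planted unique variance fractions (sum < 1).
#' @param seed RNG seed.
#' @return list with `Y` (n x nFeatures), `factor1`, `factor2` and `truth`
#'   (the planted unique fractions).
#' @export
generateCrossedResponse <- function(nLevels1 = 5, nLevels2 = 4, nPerCell = 5,
                                    nFeatures = 60, varFrac1 = 0.3,
                                    varFrac2 = 0.2, seed = 1L) {
  stopifnot(varFrac1 >= 0, varFrac2 >= 0, varFrac1 + varFrac2 < 1)
  .withSeed(seed, {
    f1 <- factor(rep(rep(seq_len(nLevels1), each = nLevels2), each = nPerCell))
    f2 <- factor(rep(rep(seq_len(nLevels2), times = nLevels1), each = nPerCell))
    n <- length(f1)
    noiseVar <- 1 - varFrac1 - varFrac2
    scaleTo <- function(levelEff, fac, targetSS) {
      e <- levelEff - mean(levelEff)  # balanced: sample mean = level mean
      v <- e[as.integer(fac)]
      ss <- sum(v^2)
      if (ss == 0) return(v)
      v * sqrt(targetSS / ss)
    }
    Y <- vapply(seq_len(nFeatures), function(j) {
      scaleTo(stats::rnorm(nLevels1), f1, varFrac1 * n) +
        scaleTo(stats::rnorm(nLevels2), f2, varFrac2 * n) +
        stats::rnorm(n, 0, sqrt(noiseVar))
    }, numeric(n))
    colnames(Y) <- sprintf("Y%03d", seq_len(nFeatures))
    list(Y = Y, factor1 = f1, factor2 = f2,
         truth = c(unique1 = varFrac1, unique2 = varFrac2))
  })
}
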