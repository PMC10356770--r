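#' @include AllClasses.R accessors.R preprocess.R ensemble.R varpart.R univariate.R
NULL

.fmtNum <- function(x) {
  # full-precision decimal rendering so write -> read round-trips bit-exactly
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

#' Write a FeatureTable as delimited text
#'
#' The intensity table is written samples-in-rows with a `sample_id` first
#' column; numbers are rendered at full precision so a write/read round trip
#' preserves values exactly. Sample and feature metadata are written
#' alongside when paths are given.
#'
#' @param table a [FeatureTable-class].
#' @param path CSV path for the intensity table.
#' @param sampleMetaPath,featureMetaPath optional CSV paths for metadata.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(table, path, sampleMetaPath = NULL,
                              featureMetaPath = NULL) {
  stopifnot(is(table, "FeatureTable"))
  m <- t(intensities(table))
  df <- data.frame(sample_id = rownames(m), check.names = FALSE)
  for (j in colnames(m)) df[[j]] <- .fmtNum(m[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(sampleMetaPath)) {
    sm <- as.data.frame(colData(table))
    sm <- cbind(sample_id = colnames(table), sm)
    if ("dry_weight_mg" %in% colnames(sm))
      sm$dry_weight_mg <- .fmtNum(sm$dry_weight_mg)
    utils::write.csv(sm, sampleMetaPath, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(featureMetaPath)) {
    fm <- as.data.frame(rowData(table))
    fm <- cbind(feature_id = rownames(table), fm)
    utils::write.csv(fm, featureMetaPath, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a FeatureTable from delimited text
#'
#' Expects a header row and a `sample_id` first column (samples in rows).
#' Samples present in the table but missing from the metadata are an error;
#' metadata rows for unknown samples are ignored with a warning.
#'
#' @param path CSV intensity table.
#' @param sampleMetaPath optional CSV of per-sample metadata keyed by
#'   `sample_id`.
#' @param featureMetaPath optional CSV of per-feature metadata keyed by
#'   `feature_id`.
#' @return a [FeatureTable-class].
#' @export
readFeatureTable <- function(path, sampleMetaPath = NULL,
                             featureMetaPath = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("empty or malformed feature table: ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicated sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  m <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(df) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, colnames(vals)))
  if (any(is.na(m) & !(vals == "NA" | vals == "")))
    stop("non-numeric intensity cell(s) in ", path)
  rownames(m) <- ids
  intens <- t(m)
  sampleMeta <- NULL
  if (!is.null(sampleMetaPath)) {
    sm <- utils::read.csv(sampleMetaPath, check.names = FALSE)
    if (!"sample_id" %in% colnames(sm))
      stop("sample metadata lacks a sample_id column")
    if (anyDuplicated(sm$sample_id)) stop("duplicated sample ids in metadata")
    unknown <- setdiff(sm$sample_id, ids)
    if (length(unknown)) {
      warning("ignoring metadata for unknown sample(s): ",
              paste(unknown, collapse = ", "))
      sm <- sm[!sm$sample_id %in% unknown, , drop = FALSE]
    }
    missing <- setdiff(ids, sm$sample_id)
    if (length(missing))
      stop("no metadata for sample(s): ", paste(missing, collapse = ", "))
    rownames(sm) <- sm$sample_id
    sampleMeta <- DataFrame(sm[ids, setdiff(colnames(sm), "sample_id"),
                               drop = FALSE])
  }
  featureMeta <- NULL
  if (!is.null(featureMetaPath)) {
    fm <- utils::read.csv(featureMetaPath, check.names = FALSE)
    if (!"feature_id" %in% colnames(fm))
      stop("feature metadata lacks a feature_id column")
    rownames(fm) <- fm$feature_id
    missingF <- setdiff(rownames(intens), fm$feature_id)
    if (length(missingF))
      stop("no metadata for feature(s): ",
           paste(utils::head(missingF, 5), collapse = ", "))
    featureMeta <- DataFrame(fm[rownames(intens),
                                setdiff(colnames(fm), "feature_id"),
                                drop = FALSE])
  }
  featureTable(intens, sampleData = sampleMeta, featureData = featureMeta)
}

#' Assemble a pipeline run configuration
#'
#' Defaults follow the full-scale analysis (500 models, 500 permutations,
#' 60/20/20 splits, alpha 0.05, four genotype classes); desk-scale runs
#' override `ensemble` sizes.
#'
#' @param task `"chemotype"` or `"genotype"`.
#' @param seed base seed governing every stochastic stage.
#' @param simulation arguments for [simulationConfig()] (used when no input
#'   paths are given), or `NULL`.
#' @param paths optional list with `table`, `sampleMeta`, `featureMeta`,
#'   `blanks` file paths.
#' @param preprocess arguments for [preprocessConfig()].
#' @param ensemble list: `nModels`, `nPerm`, `alphaGridSize`, `nLambda`.
#' @param stats list: `alpha`.
#' @param varpart list: `nPerm`.
#' @param cluster list: `k` genotype classes.
#' @param markers list: `fraction` (or `k`).
#' @return a `RunConfig` list.
#' @export
runConfig <- function(task = c("chemotype", "genotype"), seed = 1L,
                      simulation = list(), paths = NULL,
                      preprocess = list(),
                      ensemble = list(nModels = 500, nPerm = 500,
                                      alphaGridSize = 1000, nLambda = 30),
                      stats = list(alpha = 0.05),
                      varpart = list(nPerm = 199),
                      cluster = list(k = 4),
                      markers = list(fraction = 0.05)) {
  task <- match.arg(task)
  if (!is.null(paths))
    for (p in unlist(paths))
      if (!file.exists(p)) stop("configured path does not exist: ", p)
  structure(list(task = task, seed = as.integer(seed),
                 simulation = simulation, paths = paths,
                 preprocess = preprocess, ensemble = ensemble,
                 stats = stats, varpart = varpart, cluster = cluster,
                 markers = markers),
            class = "RunConfig")
}

#' Read a RunConfig from a YAML file
#'
#' @param path YAML file whose keys mirror the [runConfig()] arguments.
#' @return a `RunConfig` list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(runConfig, yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' Executes preprocess -> univariate statistics -> ensemble (+ permutation
#' null) -> marker selection -> variation partitioning on either a synthetic
#' dataset (generated from `config$simulation`) or tables read from
#' `config$paths`, writing every intermediate table, a machine-readable
#' `summary.json` and a log with the resolved seed to `outDir`. Identical
#' config and seed give byte-identical summaries.
#'
#' @param config a [runConfig()] or path to a YAML config.
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
runPipeline <- function(config, outDir = tempfile("metabomark_run_")) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- try({
    if (is.null(config$paths)) {
      simArgs <- config$simulation
      simArgs$seed <- config$seed
      simCfg <- do.call(simulationConfig, simArgs)
      sim <- generateDataset(simCfg)
      table <- sim$table
      blanks <- generateBlanks(simCfg, 4)
    } else {
      table <- readFeatureTable(config$paths$table, config$paths$sampleMeta,
                                config$paths$featureMeta)
      blanks <- if (!is.null(config$paths$blanks))
        readFeatureTable(config$paths$blanks) else NULL
    }

    stage <- "preprocess"
    ppCfg <- do.call(preprocessConfig, config$preprocess)
    pp <- preprocess(table, blanks = blanks, config = ppCfg)
    writeFeatureTable(pp, file.path(outDir, "preprocessed.csv"),
                      file.path(outDir, "sample_meta.csv"),
                      file.path(outDir, "feature_meta.csv"))
    utils::write.csv(metadata(pp)$preprocessLog,
                     file.path(outDir, "preprocess_report.csv"),
                     row.names = FALSE)

    stage <- "labels"
    if (config$task == "chemotype") {
      labels <- .resolveLabels(pp, "chemotype")
      grouping <- NULL
    } else {
      grouping <- groupGenotypes(pp, "genotype", k = config$cluster$k)
      labels <- grouping$classLabels
      utils::write.csv(
        data.frame(genotype = names(classAssignments(grouping$cut)),
                   class = paste0("MC", classAssignments(grouping$cut))),
        file.path(outDir, "genotype_classes.csv"), row.names = FALSE)
    }

    stage <- "univariate"
    tests <- anovaTukey(pp, labels, alpha = config$stats$alpha)
    utils::write.csv(tests[, c("feature_id", "anova_F", "anova_p", "fdr_q",
                               "significant")],
                     file.path(outDir, "univariate_tests.csv"),
                     row.names = FALSE)
    occ <- occupancy(table, as.character(labels))

    stage <- "ensemble"
    ctrl <- ensembleControl(
      nModels = config$ensemble$nModels,
      alphaGrid = seq(0, 1, length.out = config$ensemble$alphaGridSize),
      nLambda = config$ensemble$nLambda,
      baseSeed = config$seed)
    ens <- runEnsemble(pp, labels, ctrl)
    utils::write.csv(data.frame(model = seq_along(testScores(ens)),
                                score = testScores(ens),
                                alpha = ens@alphas, lambda = ens@lambdas),
                     file.path(outDir, "ensemble_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(feature_id = names(occurrence(ens)),
                                occurrence = occurrence(ens)),
                     file.path(outDir, "occurrence.csv"), row.names = FALSE)

    stage <- "permutation"
    nullScores <- permutationNull(pp, labels, config$ensemble$nPerm, ctrl)
    cmp <- compareScores(testScores(ens), nullScores)

    stage <- "markers"
    ms <- if (!is.null(config$markers$k))
      selectMarkers(ens, k = config$markers$k)
    else selectMarkers(ens, fraction = config$markers$fraction)
    utils::write.csv(data.frame(feature_id = featureIds(ms),
                                occurrence = occurrence(ms)),
                     file.path(outDir, "markers.csv"), row.names = FALSE)

    stage <- "varpart"
    vp <- variationPartition(t(intensities(pp)),
                             colData(pp)$chemotype, colData(pp)$genotype,
                             nPerm = config$varpart$nPerm, seed = config$seed)
    utils::write.csv(data.frame(fraction = names(fractions(vp)),
                                adj_r2 = as.numeric(fractions(vp)),
                                p_value = c(vp@pValues["a"], NA,
                                            vp@pValues["c"], NA)),
                     file.path(outDir, "varpart.csv"), row.names = FALSE)

    stage <- "summary"
    summary <- list(
      task = config$task, seed = config$seed,
      n_samples = ncol(table), n_features_raw = nrow(table),
      n_features_preprocessed = nrow(pp),
      n_significant_features = sum(tests$significant),
      frac_in_all_classes = occ$fracInAllClasses,
      mean_test_accuracy = mean(testScores(ens)),
      sd_test_accuracy = stats::sd(testScores(ens)),
      mean_null_accuracy = mean(nullScores),
      score_t = cmp$statistic, score_p = cmp$p.value,
      n_markers = length(featureIds(ms)),
      top_markers = utils::head(featureIds(ms), 10),
      varpart = as.list(fractions(vp)),
      varpart_p = list(a = vp@pValues[["a"]], c = vp@pValues[["c"]]))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(paste("metabomark version:",
                       as.character(utils::packageVersion("metabomark"))),
                 paste("base seed:", config$seed),
                 paste("task:", config$task),
                 "config:",
                 yaml::as.yaml(unclass(config))),
               file.path(outDir, "run_log.txt"))
    outDir
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("pipeline failed at stage '", stage, "': ",
         attr(res, "condition")$message, call. = FALSE)
  invisible(outDir)
}
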