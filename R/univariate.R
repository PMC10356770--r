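#' @include AllClasses.R accessors.R
NULL

.resolveLabels <- function(table, labels) {
  if (length(labels) == 1 && is.character(labels)) {
    if (!labels %in% colnames(colData(table)))
      stop("sample metadata has no column '", labels, "'")
    labels <- colData(table)[[labels]]
  }
  if (length(labels) != ncol(table))
    stop("labels must have one entry per sample")
  droplevels(factor(labels))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in rank, capped at 1), computed via
#' [stats::p.adjust()].
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
fdrBH <- function(pvalues) {
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues < 0 | pvalues > 1))
    stop("p-values must be finite numbers in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# One-way ANOVA + Tukey HSD for a single feature, with degenerate-variance
# conventions: all values identical -> F = 0, p = 1; zero residual variance
# with differing means -> p = 0.
.featureAnova <- function(x, labels) {
  groupMeans <- tapply(x, labels, mean)
  lv <- levels(labels)
  pairs <- utils::combn(lv, 2)
  pairNames <- paste(pairs[2, ], pairs[1, ], sep = "-")
  pairDiff <- groupMeans[pairs[2, ]] - groupMeans[pairs[1, ]]

  ssWithin <- sum(tapply(x, labels, function(v) sum((v - mean(v))^2)))
  if (ssWithin < .Machine$double.eps * sum(x^2) || ssWithin == 0) {
    if (max(groupMeans) - min(groupMeans) == 0)
      return(list(F = 0, p = 1,
                  pairwise = data.frame(contrast = pairNames,
                                        mean_diff = unname(pairDiff),
                                        adj_p = 1)))
    return(list(F = Inf, p = 0,
                pairwise = data.frame(contrast = pairNames,
                                      mean_diff = unname(pairDiff),
                                      adj_p = as.numeric(pairDiff == 0))))
  }
  df <- data.frame(y = x, g = labels)
  fit <- stats::aov(y ~ g, data = df)
  an <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit)$g
  # align Tukey contrasts with our canonical ordering
  ord <- match(pairNames, rownames(tk))
  list(F = an[1, "F value"], p = an[1, "Pr(>F)"],
       pairwise = data.frame(contrast = pairNames,
                             mean_diff = unname(tk[ord, "diff"]),
                             adj_p = unname(tk[ord, "p adj"])))
}

#' Per-feature ANOVA with Tukey HSD and BH-FDR
#'
#' For each feature: a one-way fixed-effects ANOVA across the classes, BH-FDR
#' adjustment of the omnibus p-values across features, and Tukey HSD pairwise
#' comparisons (Tukey-Kramer correction for unequal group sizes, via
#' [stats::TukeyHSD()]). A feature is declared significant when its FDR q is
#' below `alpha` and at least one Tukey-adjusted pairwise p is below `alpha`
#' (the standard two-stage screening behaviour).
#'
#' @param table a [FeatureTable-class] (typically fully preprocessed).
#' @param labels class per sample: a vector, or the name of a
#'   `sampleData(table)` column (e.g. `"chemotype"`).
#' @param alpha significance level (default 0.05).
#' @return a `data.frame` with one row per feature (`feature_id`, `anova_F`,
#'   `anova_p`, `fdr_q`, `significant`) and a list column `pairwise` of
#'   per-pair `(contrast, mean_diff, adj_p)` frames.
#' @export
anovaTukey <- function(table, labels, alpha = 0.05) {
  stopifnot(is(table, "FeatureTable"))
  labels <- .resolveLabels(table, labels)
  if (nlevels(labels) < 2)
    stop("at least two classes are required")
  small <- names(which(table(labels) < 2))
  if (length(small))
    stop("class(es) with fewer than 2 samples: ", paste(small, collapse = ", "))
  m <- intensities(table)
  res <- apply(m, 1, .featureAnova, labels = labels)
  p <- vapply(res, `[[`, numeric(1), "p")
  q <- fdrBH(p)
  anyPair <- vapply(res, function(r) any(r$pairwise$adj_p < alpha), logical(1))
  out <- data.frame(feature_id = rownames(m),
                    anova_F = vapply(res, `[[`, numeric(1), "F"),
                    anova_p = p, fdr_q = q,
                    significant = q < alpha & anyPair,
                    row.names = NULL)
  out$pairwise <- unname(lapply(res, `[[`, "pairwise"))
  out
}

#' Class-occupancy summary
#'
#' A feature counts as present in a class iff its intensity is > 0 in at
#' least one sample of that class. Fractions are computed over all features;
#' an all-zero feature is present in no class and so contributes to neither
#' numerator.
#'
#' @param table a [FeatureTable-class] (raw or filtered intensities).
#' @param labels class per sample (vector or `sampleData` column name).
#' @return an `OccupancySummary` list: `presence` (feature x class logical
#'   matrix), `nClassesPresent`, `fracInAllClasses`, `fracInMultipleClasses`.
#' @export
occupancy <- function(table, labels) {
  stopifnot(is(table, "FeatureTable"))
  labels <- .resolveLabels(table, labels)
  m <- intensities(table)
  presence <- vapply(levels(labels), function(cl)
    rowSums(m[, labels == cl, drop = FALSE] > 0) > 0,
    logical(nrow(m)))
  nPresent <- rowSums(presence)
  structure(list(presence = presence,
                 nClassesPresent = nPresent,
                 fracInAllClasses = mean(nPresent == nlevels(labels)),
                 fracInMultipleClasses = mean(nPresent >= 2)),
            class = "OccupancySummary")
}

#' @export
print.OccupancySummary <- function(x, ...) {
  cat("OccupancySummary:", nrow(x$presence), "features,",
      ncol(x$presence), "classes\n")
  cat(sprintf("  present in all classes: %.1f%%\n", 100 * x$fracInAllClasses))
  cat(sprintf("  present in >1 class:    %.1f%%\n",
              100 * x$fracInMultipleClasses))
  invisible(x)
}

#' Intersection counts of per-class top-k marker lists
#'
#' Takes the top `k` of each class's ranked marker list and counts, for every
#' non-empty class combination, the features whose top-k membership is
#' exactly that combination (the counts an upset plot displays). Counts over
#' all combinations sum to the size of the union of the top-k sets.
#'
#' @param markerLists named list of ranked feature-id vectors, one per class.
#' @param k how many top markers per class to consider.
#' @return a `data.frame` with columns `combination` (class names joined by
#'   `"+"`), `degree` and `count`, sorted by decreasing count.
#' @export
markerIntersections <- function(markerLists, k) {
  stopifnot(is.list(markerLists), length(markerLists) >= 1)
  if (is.null(names(markerLists)))
    names(markerLists) <- paste0("class", seq_along(markerLists))
  for (nm in names(markerLists)) {
    if (anyDuplicated(markerLists[[nm]]))
      stop("duplicate feature ids in marker list '", nm, "'")
    if (k > length(markerLists[[nm]]))
      stop("k exceeds the length of marker list '", nm, "'")
  }
  tops <- lapply(markerLists, utils::head, n = k)
  union <- unique(unlist(tops))
  membership <- vapply(tops, function(s) union %in% s, logical(length(union)))
  if (length(union) == 1) membership <- matrix(membership, nrow = 1,
                                               dimnames = list(NULL, names(tops)))
  combo <- apply(membership, 1, function(row)
    paste(names(tops)[row], collapse = "+"))
  tab <- table(combo)
  out <- data.frame(combination = names(tab),
                    degree = vapply(strsplit(names(tab), "\\+"), length,
                                    integer(1)),
                    count = as.integer(tab), row.names = NULL)
  out[order(-out$count, out$combination), , drop = FALSE]
}
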