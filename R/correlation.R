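# Feature columns compared across thresholds / against MTV
featureColumns <- function() {
  c("suv_max", "suv_mean", "mtv_ml", "cov", "entropy", "correlation",
    "contrast", "busyness", "coarseness")
}

#' Feature stability across segmentation thresholds
#'
#' Pairs two feature tables computed on the same lesions under different
#' VOI definitions (e.g. SUV 2.0 vs 2.5 isocontours) and reports, per
#' feature, the Pearson correlation with its two-sided p-value, plus the
#' range and mean +/- SD under each definition. A feature with zero
#' variance on either side gets `r = NA` and is flagged.
#'
#' @param featuresA,featuresB feature `data.frame`s (one row per lesion,
#'   same lesions in the same order), as from [extractAllFeatures()].
#' @param columns feature columns to compare (default the nine PET
#'   parameters).
#' @return `data.frame`: `feature`, `r`, `p`, `min_a`, `max_a`, `mean_a`,
#'   `sd_a`, `min_b`, `max_b`, `mean_b`, `sd_b`, `degenerate`.
#' @examples
#' coh <- generateCohort(6, seed = 4)
#' f25 <- do.call(rbind, lapply(coh$volumes, extractAllFeatures,
#'                              thresholdSUV = 2.5))
#' pearsonTable(coh$features, f25)[, c("feature", "r")]
#' @export
pearsonTable <- function(featuresA, featuresB, columns = featureColumns()) {
  if (nrow(featuresA) != nrow(featuresB))
    stop("feature tables must describe the same lesions")
  if (nrow(featuresA) < 3L) stop("at least 3 paired lesions required")
  columns <- intersect(columns, intersect(names(featuresA), names(featuresB)))
  if (length(columns) == 0L) stop("no shared feature columns")
  rows <- lapply(columns, function(cn) {
    a <- featuresA[[cn]]; b <- featuresB[[cn]]
    degenerate <- stats::sd(a) == 0 || stats::sd(b) == 0
    if (degenerate) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(a, b, method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(feature = cn, r = r, p = p,
               min_a = min(a), max_a = max(a), mean_a = mean(a),
               sd_a = stats::sd(a),
               min_b = min(b), max_b = max(b), mean_b = mean(b),
               sd_b = stats::sd(b), degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Feature dependency on metabolic tumor volume
#'
#' Pearson correlation of each PET parameter against MTV across lesions,
#' quantifying how much of an apparent texture signal is a tumor-size
#' effect.
#'
#' @param features feature `data.frame` with an `mtv_ml` column.
#' @param columns features to correlate against MTV (default the
#'   remaining eight parameters).
#' @return `data.frame`: `feature`, `r`, `p`, `degenerate`.
#' @export
sizeDependency <- function(features,
                           columns = setdiff(featureColumns(), "mtv_ml")) {
  if (nrow(features) < 3L) stop("at least 3 lesions required")
  if (is.null(features$mtv_ml)) stop("features must contain 'mtv_ml'")
  mtv <- features$mtv_ml
  rows <- lapply(intersect(columns, names(features)), function(cn) {
    x <- features[[cn]]
    degenerate <- stats::sd(x) == 0 || stats::sd(mtv) == 0
    if (degenerate) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(x, mtv, method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(feature = cn, r = r, p = p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
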