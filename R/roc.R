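#' ROC analysis of a continuous marker against a binary endpoint
#'
#' AUC is the Mann-Whitney probability that a random positive scores above
#' a random negative (ties counted one half), with a 95% DeLong
#' confidence interval. The curve is evaluated at all distinct score
#' thresholds, and the optimal cutoff minimizes the Euclidean distance
#' between the ROC curve and the upper-left corner of the unit square.
#'
#' @param scores numeric marker values (higher = more positive).
#' @param labels binary endpoint (0/1 or logical), same length.
#' @param ciMethod `"delong"` (default) or `"hanley"` (Hanley-McNeil
#'   normal-theory interval).
#' @return list of class `ROCResult`: `auc`, `ci_low`, `ci_high`, `curve`
#'   (`data.frame` threshold / fpr / sens / spec), `optimal_cutoff`,
#'   `optimal_sens`, `optimal_spec`, `n_pos`, `n_neg`.
#' @examples
#' r <- rocAnalysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' r$auc
#' @export
rocAnalysis <- function(scores, labels, ciMethod = c("delong", "hanley")) {
  ciMethod <- match.arg(ciMethod)
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("missing values not supported")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L) stop("no positive labels present")
  if (nNeg == 0L) stop("no negative labels present")
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  auc <- as.numeric(r$auc)
  ci <- tryCatch(suppressWarnings({
    if (ciMethod == "delong") {
      v <- as.numeric(pROC::ci.auc(r, method = "delong"))
      c(v[1], v[3])
    } else {
      # Hanley-McNeil standard error
      q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
      se <- sqrt((auc * (1 - auc) + (nPos - 1) * (q1 - auc^2) +
                  (nNeg - 1) * (q2 - auc^2)) / (nPos * nNeg))
      pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
    }
  }), error = function(e) c(NA_real_, NA_real_))
  curve <- data.frame(threshold = r$thresholds,
                      fpr = 1 - r$specificities,
                      sens = r$sensitivities,
                      spec = r$specificities)
  res <- structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2],
                        curve = curve, n_pos = nPos, n_neg = nNeg),
                   class = "ROCResult")
  opt <- optimalCutoff(res)
  res$optimal_cutoff <- opt
  i <- which(curve$threshold == opt)[1]
  res$optimal_sens <- curve$sens[i]
  res$optimal_spec <- curve$spec[i]
  res
}

#' Optimal ROC cutoff by minimum distance to the upper-left corner
#'
#' Returns the threshold whose operating point minimizes
#' `sqrt((1 - sens)^2 + (1 - spec)^2)`; ties are broken toward higher
#' specificity. A subject scoring at or above the cutoff is classified
#' high-risk.
#'
#' @param roc an `ROCResult` from [rocAnalysis()].
#' @return scalar threshold (possibly infinite for degenerate markers,
#'   in which case the reported sensitivity/specificity describe the
#'   corner reached).
#' @export
optimalCutoff <- function(roc) {
  stopifnot(inherits(roc, "ROCResult"))
  cv <- roc$curve
  d <- sqrt((1 - cv$sens)^2 + (1 - cv$spec)^2)
  best <- which(d <= min(d) + 1e-12)
  best <- best[which.max(cv$spec[best])]
  cv$threshold[best]
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  cat(sprintf("  optimal cutoff %.4g (sens %.3f, spec %.3f)\n",
              x$optimal_cutoff, x$optimal_sens, x$optimal_spec))
  invisible(x)
}
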