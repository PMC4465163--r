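#' Kaplan-Meier curves with a two-sample log-rank comparison
#'
#' Product-limit survival curves per group, the two-sample log-rank
#' chi-square p-value, and per-group summaries: event counts, median
#' survival (first time the curve drops to 0.5 or below; `NA` when not
#' reached) and the restricted mean over the common follow-up.
#'
#' @param times positive follow-up times (months).
#' @param events event indicators (0 = censored, 1 = event).
#' @param group binary group labels (anything coercible to a two-level
#'   factor; a single level is tolerated, in which case no test is run
#'   and `logrank_p` is `NA`).
#' @return list of class `SurvivalComparison`: `groups` (summary
#'   `data.frame`), `curves` (per-group step functions as `data.frame`s
#'   with `time`, `surv`), `logrank_chisq`, `logrank_p`.
#' @examples
#' s <- kmLogrank(c(5, 8, 12, 20, 30, 40), c(1, 1, 0, 1, 0, 1),
#'                c(0, 0, 0, 1, 1, 1))
#' s$logrank_p
#' @export
kmLogrank <- function(times, events, group) {
  if (any(times <= 0)) stop("times must be > 0")
  n <- length(times)
  if (length(events) != n || length(group) != n)
    stop("times, events, group must have equal length")
  g <- factor(group)
  if (any(table(g) == 0L) || nlevels(g) > 2L)
    stop("group must define one or two non-empty groups")
  fit <- survival::survfit(survival::Surv(times, events) ~ g)
  smry <- summary(fit, rmean = "common")$table
  if (is.null(dim(smry))) smry <- matrix(smry, 1L,
                                         dimnames = list("all", names(smry)))
  groups <- data.frame(group = levels(g),
                       n = as.numeric(smry[, "records"]),
                       events = as.numeric(smry[, "events"]),
                       median = as.numeric(smry[, "median"]),
                       rmean = as.numeric(smry[, "rmean"]),
                       stringsAsFactors = FALSE)
  strata <- if (is.null(fit$strata)) rep(1L, length(fit$time)) else
    rep(seq_along(fit$strata), fit$strata)
  curves <- lapply(seq_len(nlevels(g)), function(k) {
    sel <- strata == k
    data.frame(time = fit$time[sel], surv = fit$surv[sel])
  })
  names(curves) <- levels(g)
  if (nlevels(g) == 2L && sum(events) > 0) {
    sd <- survival::survdiff(survival::Surv(times, events) ~ g)
    chisq <- as.numeric(sd$chisq)
    p <- as.numeric(stats::pchisq(chisq, df = 1L, lower.tail = FALSE))
  } else {
    chisq <- NA_real_; p <- NA_real_
  }
  structure(list(groups = groups, curves = curves,
                 logrank_chisq = chisq, logrank_p = p),
            class = "SurvivalComparison")
}

#' @export
print.SurvivalComparison <- function(x, ...) {
  print(x$groups)
  if (!is.na(x$logrank_p))
    cat(sprintf("log-rank chi-square %.3f, p = %.4g\n",
                x$logrank_chisq, x$logrank_p))
  invisible(x)
}

#' Cox proportional-hazards regression with Efron tie handling
#'
#' Univariate (one covariate) or restricted multivariate (at most three
#' covariates, reflecting the low event counts typical of small SBRT
#' cohorts) partial-likelihood fit. Hazard ratios are per covariate unit,
#' with Wald 95% confidence intervals and p-values. Covariates can be
#' log-transformed in place (the usual convention for metabolic tumor
#' volume).
#'
#' @param covariates `data.frame` of 1-3 numeric covariates; no constant
#'   columns.
#' @param times positive follow-up times.
#' @param events event indicators (0/1).
#' @param logTransform character vector of covariate names to analyze on
#'   the log scale.
#' @return `data.frame` of class `CoxResult` with columns `covariate`,
#'   `hr`, `ci_low`, `ci_high`, `p`, `model` (`"univariate"` or
#'   `"multivariate"`), plus attribute `"fit"` holding the `coxph` object.
#' @examples
#' set.seed(1)
#' x <- rbinom(80, 1, 0.5)
#' t <- rexp(80, 0.05 * exp(log(2) * x))
#' coxFit(data.frame(x = x), t, rep(1, 80))
#' @export
coxFit <- function(covariates, times, events, logTransform = character()) {
  covariates <- as.data.frame(covariates)
  k <- ncol(covariates)
  if (k < 1L) stop("at least one covariate required")
  if (k > 3L)
    stop("multivariate models are restricted to three covariates ",
         "(low event numbers)")
  if (nrow(covariates) != length(times) || length(times) != length(events))
    stop("covariates, times and events must agree in length")
  for (nm in names(covariates)) {
    if (nm %in% logTransform) {
      if (any(covariates[[nm]] <= 0))
        stop(sprintf("cannot log-transform '%s': non-positive values", nm))
      covariates[[nm]] <- log(covariates[[nm]])
    }
    if (stats::var(covariates[[nm]]) == 0)
      stop(sprintf("constant covariate '%s'", nm))
  }
  dat <- cbind(covariates, .time = times, .event = events)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(covariates)),
                                       collapse = " + ")))
  warns <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(grepl("converge|infinite|beta may be", warns, ignore.case = TRUE)))
    stop("Cox fit did not converge (possible separation): ",
         paste(unique(warns), collapse = "; "))
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  res <- data.frame(covariate = rownames(co),
                    hr = unname(co[, "exp(coef)"]),
                    ci_low = unname(ci[, "lower .95"]),
                    ci_high = unname(ci[, "upper .95"]),
                    p = unname(co[, "Pr(>|z|)"]),
                    model = if (k == 1L) "univariate" else "multivariate",
                    stringsAsFactors = FALSE)
  class(res) <- c("CoxResult", "data.frame")
  attr(res, "fit") <- fit
  res
}
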