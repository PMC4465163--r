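#' Parameters linking texture to simulated clinical outcomes
#'
#' The outcome model drives local recurrence and disease-specific death
#' from GLCM entropy, the package's reference heterogeneity feature; other
#' features share its texture and correlate with it implicitly. Local
#' recurrence is Bernoulli with a logistic link on mean-centered entropy;
#' disease-specific death time is exponential with a proportional-hazards
#' log-link on the same covariate; an independent texture-free
#' exponential clock models death from comorbidity; administrative
#' censoring is uniform over the follow-up window. Nodal and distant
#' recurrence are drawn independently of texture.
#'
#' @param betaLr log-odds of local recurrence per unit entropy (default 2).
#' @param betaDss log-hazard of disease-specific death per unit entropy
#'   (default 1.3).
#' @param baselineHazard disease-specific death hazard at mean entropy,
#'   events/month (default 0.012).
#' @param otherCauseHazard comorbidity death hazard, events/month,
#'   texture-independent (default 0.015).
#' @param followupWindowMonths censoring window, ordered positive pair
#'   (default `c(3, 72)`).
#' @param lrBaseRate cohort local-recurrence rate at mean entropy
#'   (default 7/45).
#' @param lnRate,dmRate marginal nodal/distant recurrence rates
#'   (default 11/45 each), independent of texture.
#' @param seed integer RNG seed.
#' @return validated list of class `OutcomeParams`.
#' @seealso [simulateOutcomes()]
#' @export
outcomeParams <- function(betaLr = 2, betaDss = 1.3,
                          baselineHazard = 0.012, otherCauseHazard = 0.015,
                          followupWindowMonths = c(3, 72),
                          lrBaseRate = 7 / 45, lnRate = 11 / 45,
                          dmRate = 11 / 45, seed = 1L) {
  if (baselineHazard < 0 || otherCauseHazard < 0)
    stop("hazards must be >= 0")
  if (length(followupWindowMonths) != 2L ||
      followupWindowMonths[1] <= 0 ||
      followupWindowMonths[2] < followupWindowMonths[1])
    stop("follow-up window must be a positive ordered pair")
  structure(list(betaLr = betaLr, betaDss = betaDss,
                 baselineHazard = baselineHazard,
                 otherCauseHazard = otherCauseHazard,
                 followupWindowMonths = followupWindowMonths,
                 lrBaseRate = lrBaseRate, lnRate = lnRate, dmRate = dmRate,
                 seed = as.integer(seed)),
            class = "OutcomeParams")
}

#' Simulate per-patient outcomes from a feature table
#'
#' See [outcomeParams()] for the generating model. The observed survival
#' time is the minimum of the disease-death, comorbidity-death and
#' censoring clocks, with the death cause recorded from the earliest;
#' `death_cause == "none"` if and only if `os_event == 0`. The time to
#' local recurrence is a uniform fraction (0.3-0.9) of the observed
#' survival time for recurrence cases and is censored at the observed
#' survival time otherwise. T stage is assigned from `diameter_mm`
#' (T1 <= 30 mm < T2) when the column is present.
#'
#' @param features `data.frame` with at least an `entropy` column, one row
#'   per patient (e.g. from [extractAllFeatures()]); an optional
#'   `diameter_mm` column drives T staging and an optional `id` column is
#'   carried through.
#' @param params an `OutcomeParams` list from [outcomeParams()].
#' @return `data.frame` with columns `id`, `lr_event`, `ln_event`,
#'   `dm_event`, `time_to_lr_months`, `os_time_months`, `os_event`,
#'   `death_cause`, `t_stage`.
#' @examples
#' feats <- data.frame(entropy = rnorm(45, 6.5, 0.8))
#' head(simulateOutcomes(feats, outcomeParams(seed = 2)))
#' @export
simulateOutcomes <- function(features, params = outcomeParams()) {
  stopifnot(inherits(params, "OutcomeParams"))
  if (!is.data.frame(features) || nrow(features) == 0L)
    stop("features must be a non-empty data.frame")
  if (is.null(features$entropy)) stop("features must contain 'entropy'")
  n <- nrow(features)
  ec <- features$entropy - mean(features$entropy)
  withSeed(params$seed, {
    pLr <- stats::plogis(stats::qlogis(params$lrBaseRate) + params$betaLr * ec)
    lr <- stats::rbinom(n, 1L, pLr)
    hDis <- params$baselineHazard * exp(params$betaDss * ec)
    tDis <- ifelse(hDis > 0, stats::rexp(n, rate = pmax(hDis, 1e-300)), Inf)
    tOth <- if (params$otherCauseHazard > 0)
      stats::rexp(n, rate = params$otherCauseHazard) else rep(Inf, n)
    cens <- stats::runif(n, params$followupWindowMonths[1],
                         params$followupWindowMonths[2])
    osTime <- pmin(tDis, tOth, cens)
    osEvent <- as.integer(osTime < cens)
    cause <- ifelse(osEvent == 0L, "none",
                    ifelse(tDis <= tOth, "disease", "other"))
    tLr <- ifelse(lr == 1L, osTime * stats::runif(n, 0.3, 0.9), osTime)
    ln <- stats::rbinom(n, 1L, params$lnRate)
    dm <- stats::rbinom(n, 1L, params$dmRate)
    tStage <- if (!is.null(features$diameter_mm))
      ifelse(features$diameter_mm <= 30, "T1", "T2") else NA_character_
    data.frame(
      id = if (!is.null(features$id)) features$id else as.character(seq_len(n)),
      lr_event = lr, ln_event = ln, dm_event = dm,
      time_to_lr_months = tLr, os_time_months = osTime, os_event = osEvent,
      death_cause = cause, t_stage = tStage, stringsAsFactors = FALSE)
  })
}
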