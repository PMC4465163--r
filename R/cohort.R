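#' Sampling distribution for per-patient phantom parameters
#'
#' Describes how tumor geometry and texture vary across a synthetic
#' cohort. Diameters are log-normal, truncated to the clinical range;
#' tumor mean SUV is uniform over a clinically plausible range; the
#' texture correlation length varies per patient (the scale-free driver
#' of entropy variation under min-max discretization), and the texture
#' amplitude is capped per patient so the bulk of the tumor stays above
#' the segmentation threshold.
#'
#' @param diameterMeanLog,diameterSdLog log-normal parameters for tumor
#'   diameter in mm (defaults `log(32)`, 0.35).
#' @param diameterRangeMm truncation range (default `c(17, 68)`).
#' @param meanSuvRange uniform range of tumor mean SUV (default
#'   `c(4.5, 13)`).
#' @param amplitudeRange uniform range of heterogeneity amplitude before
#'   capping (default `c(0.3, 2)`).
#' @param amplitudeCapSuvMargin per-patient amplitude cap:
#'   `(tumorMeanSuv - margin) / 3` keeps 3-SD texture dips above the
#'   margin SUV (default 2.6, just above the 2.5 stability isocontour).
#' @param lengthRangeMm uniform range of texture correlation length in mm
#'   (default `c(4, 14)`).
#' @param backgroundSuv lung background (default 0.5).
#' @param noiseSd independent voxel noise (default 0).
#' @return list of class `CohortDistribution`.
#' @seealso [generateCohort()]
#' @export
cohortDistribution <- function(diameterMeanLog = log(32), diameterSdLog = 0.35,
                               diameterRangeMm = c(17, 68),
                               meanSuvRange = c(4.5, 13),
                               amplitudeRange = c(0.3, 2),
                               amplitudeCapSuvMargin = 2.6,
                               lengthRangeMm = c(4, 14),
                               backgroundSuv = 0.5, noiseSd = 0) {
  structure(as.list(environment()), class = "CohortDistribution")
}

#' Generate a synthetic cohort of tumor volumes and outcomes
#'
#' Samples per-patient phantom parameters from `distribution`, builds the
#' volumes, extracts the nine PET parameters at the given segmentation
#' threshold, then simulates outcomes from the extracted entropy values.
#' Fully reproducible under the master seed: per-patient phantom seeds
#' and the outcome seed are drawn from one seeded stream.
#'
#' @param nPatients cohort size (>= 2).
#' @param distribution a `CohortDistribution` (see [cohortDistribution()]).
#' @param outcome an `OutcomeParams`; its `seed` element is overridden by
#'   a seed derived from `seed`.
#' @param seed master integer seed.
#' @param thresholdSUV segmentation threshold used for the feature table
#'   driving the outcomes (default 2.0).
#' @param keepVolumes return the volumes (default TRUE; set FALSE to save
#'   memory when only features/outcomes are needed).
#' @return list with elements `volumes` (list of [PETVolume-class] or
#'   `NULL`), `features` (per-patient feature table with `diameter_mm`),
#'   and `outcomes` (see [simulateOutcomes()]).
#' @examples
#' coh <- generateCohort(5, seed = 11)
#' coh$features[, c("id", "mtv_ml", "entropy")]
#' @export
generateCohort <- function(nPatients, distribution = cohortDistribution(),
                           outcome = outcomeParams(), seed = 1L,
                           thresholdSUV = 2.0, keepVolumes = TRUE) {
  if (nPatients < 2L) stop("nPatients must be at least 2")
  stopifnot(inherits(distribution, "CohortDistribution"),
            inherits(outcome, "OutcomeParams"))
  ds <- distribution
  draws <- withSeed(seed, {
    diam <- numeric(nPatients)
    for (i in seq_len(nPatients)) {
      repeat {
        x <- stats::rlnorm(1, ds$diameterMeanLog, ds$diameterSdLog)
        if (x >= ds$diameterRangeMm[1] && x <= ds$diameterRangeMm[2]) break
      }
      diam[i] <- x
    }
    msuv <- stats::runif(nPatients, ds$meanSuvRange[1], ds$meanSuvRange[2])
    ampCap <- pmax((msuv - ds$amplitudeCapSuvMargin) / 3, 0.05)
    amp <- pmin(stats::runif(nPatients, ds$amplitudeRange[1],
                             ds$amplitudeRange[2]), ampCap)
    len <- stats::runif(nPatients, ds$lengthRangeMm[1], ds$lengthRangeMm[2])
    seeds <- sample.int(.Machine$integer.max - 1L, nPatients + 1L)
    list(diam = diam, msuv = msuv, amp = amp, len = len, seeds = seeds)
  })
  volumes <- if (keepVolumes) vector("list", nPatients) else NULL
  feats <- vector("list", nPatients)
  for (i in seq_len(nPatients)) {
    p <- phantomParams(tumorDiameterMm = draws$diam[i],
                       tumorMeanSuv = draws$msuv[i],
                       backgroundSuv = ds$backgroundSuv,
                       heterogeneityAmplitude = draws$amp[i],
                       heterogeneityLengthMm = draws$len[i],
                       noiseSd = ds$noiseSd, seed = draws$seeds[i])
    vol <- generateTumorPhantom(p)
    vol@patientId <- sprintf("P%03d", i)
    f <- extractAllFeatures(vol, thresholdSUV = thresholdSUV,
                            diameter_mm = draws$diam[i])
    feats[[i]] <- f
    if (keepVolumes) volumes[[i]] <- vol
  }
  features <- do.call(rbind, feats)
  outcome$seed <- draws$seeds[nPatients + 1L]
  outcomes <- simulateOutcomes(features, outcome)
  list(volumes = volumes, features = features, outcomes = outcomes)
}
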