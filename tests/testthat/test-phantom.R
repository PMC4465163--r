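test_that("degenerate texture gives a perfectly flat tumor", {
  p <- phantomParams(tumorDiameterMm = 24, heterogeneityAmplitude = 0,
                     noiseSd = 0, seed = 1)
  vol <- generateTumorPhantom(p)
  suv <- suvGrid(vol)
  tum <- suv > p$backgroundSuv
  expect_true(any(tum))
  expect_equal(unique(suv[tum]), p$tumorMeanSuv)
  expect_equal(unique(suv[!tum]), p$backgroundSuv)
})

test_that("identical seeds give bit-identical volumes", {
  p <- phantomParams(heterogeneityAmplitude = 1.5, noiseSd = 0.3, seed = 99)
  v1 <- generateTumorPhantom(p)
  v2 <- generateTumorPhantom(p)
  expect_identical(suvGrid(v1), suvGrid(v2))
  p2 <- phantomParams(heterogeneityAmplitude = 1.5, noiseSd = 0.3, seed = 100)
  expect_false(identical(suvGrid(v1), suvGrid(generateTumorPhantom(p2))))
})

test_that("segmented MTV of a 30 mm sphere is near the analytic volume", {
  p <- phantomParams(tumorDiameterMm = 30, heterogeneityAmplitude = 0,
                     noiseSd = 0, tumorMeanSuv = 8, seed = 5)
  vol <- generateTumorPhantom(p)
  mask <- segmentIsocontour(vol, thresholdSUV = 2)
  st <- suvStatistics(vol, mask)
  analytic_ml <- 4 / 3 * pi * 15^3 / 1000
  expect_lt(abs(st$mtv_ml - analytic_ml) / analytic_ml, 0.25)
  # voxel-count oracle: the analytic sphere mask itself
  d <- dim(suvGrid(vol)); sp <- voxelSpacing(vol); ctr <- (d + 1) / 2
  cnt <- 0
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3])
    if (sum((((c(x, y, z) - ctr) * sp) / 15)^2) <= 1) cnt <- cnt + 1
  expect_equal(nVoxels(mask), cnt)
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantomParams(gridShape = c(6, 6, 6), tumorDiameterMm = 60),
               "does not fit")
  expect_error(phantomParams(voxelSpacingMm = c(4, -1, 5)), "positive")
  expect_error(phantomParams(tumorMeanSuv = 0.4, backgroundSuv = 0.5),
               "exceed")
  expect_error(phantomParams(heterogeneityAmplitude = -1), ">= 0")
})

test_that("SUV never drops below zero even with heavy noise", {
  p <- phantomParams(tumorMeanSuv = 3, backgroundSuv = 0.2, noiseSd = 2,
                     heterogeneityAmplitude = 1, seed = 17)
  expect_true(all(suvGrid(generateTumorPhantom(p)) >= 0))
})

test_that("null outcome effect gives chance-level discrimination", {
  feats <- data.frame(entropy = rnorm(2000, 6.5, 0.8))
  out <- simulateOutcomes(feats, outcomeParams(betaLr = 0, betaDss = 0,
                                               seed = 21))
  r <- rocAnalysis(feats$entropy, out$lr_event)
  expect_lt(abs(r$auc - 0.5), 0.03)
})

test_that("all deaths are disease deaths when the comorbidity clock is off", {
  feats <- data.frame(entropy = rnorm(300, 6.5, 0.8))
  out <- simulateOutcomes(feats, outcomeParams(otherCauseHazard = 0,
                                               seed = 8))
  expect_gt(sum(out$os_event), 0)
  expect_true(all(out$death_cause[out$os_event == 1] == "disease"))
  expect_true(all(out$death_cause[out$os_event == 0] == "none"))
})

test_that("Cox recovers a planted per-SD hazard ratio of 2 without bias", {
  logHr <- vapply(31:35, function(s) {
    set.seed(s)
    ent <- rnorm(1000, 6.5, 0.8)
    prm <- outcomeParams(betaLr = 0, betaDss = log(2) / sd(ent),
                         baselineHazard = 0.03, otherCauseHazard = 0,
                         seed = s)
    out <- simulateOutcomes(data.frame(entropy = ent), prm)
    z <- (ent - mean(ent)) / sd(ent)
    fit <- coxFit(data.frame(z = z), out$os_time_months, out$os_event)
    expect_gt(fit$hr, 1.6)
    expect_lt(fit$hr, 2.5)
    log(fit$hr)
  }, numeric(1))
  # unbiased within Monte-Carlo error (SE of log HR ~ 0.045 per replicate)
  expect_lt(abs(mean(logHr) - log(2)), 3 * 0.045 / sqrt(5))
})

test_that("outcome invariants hold: times positive, cause consistent", {
  feats <- data.frame(entropy = rnorm(200, 6.5, 0.8),
                      diameter_mm = runif(200, 17, 68))
  out <- simulateOutcomes(feats, outcomeParams(seed = 4))
  expect_true(all(out$os_time_months > 0))
  expect_true(all(out$time_to_lr_months > 0))
  expect_true(all(out$time_to_lr_months <= out$os_time_months))
  expect_identical(out$death_cause == "none", out$os_event == 0L)
  expect_identical(out$t_stage, ifelse(feats$diameter_mm <= 30, "T1", "T2"))
  expect_error(simulateOutcomes(data.frame(), outcomeParams()), "non-empty")
})

test_that("median-split log-rank rejects at the nominal 5% level under the null", {
  prm0 <- outcomeParams(betaLr = 0, betaDss = 0, baselineHazard = 0.03)
  rej <- vapply(1:500, function(i) {
    prm <- prm0; prm$seed <- i
    ent <- withr::with_seed(i + 5000, rnorm(40, 6.5, 0.8))
    out <- simulateOutcomes(data.frame(entropy = ent), prm)
    g <- ent >= median(ent)
    km <- kmLogrank(out$os_time_months, out$os_event, g)
    km$logrank_p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("generateCohort is reproducible and stages the cohort correctly", {
  c1 <- generateCohort(6, seed = 77, keepVolumes = FALSE)
  c2 <- generateCohort(6, seed = 77, keepVolumes = FALSE)
  expect_identical(c1$outcomes, c2$outcomes)
  expect_identical(c1$features, c2$features)
  expect_equal(nrow(c1$features), 6)
  expect_true(all(c1$features$diameter_mm >= 17 &
                  c1$features$diameter_mm <= 68))
  expect_identical(c1$outcomes$t_stage,
                   ifelse(c1$features$diameter_mm <= 30, "T1", "T2"))
  expect_error(generateCohort(1), "at least 2")
})

test_that("a small-diameter cohort is entirely T1", {
  ds <- cohortDistribution(diameterMeanLog = log(22), diameterSdLog = 0.1,
                           diameterRangeMm = c(17, 30))
  coh <- generateCohort(5, distribution = ds, seed = 13, keepVolumes = FALSE)
  expect_true(all(coh$outcomes$t_stage == "T1"))
})
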