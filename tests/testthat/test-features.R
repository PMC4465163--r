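test_that("conventional SUV metrics match hand arithmetic", {
  vol <- vol3d(c(2, 4, 6), dim = c(3, 1, 1))
  st <- suvStatistics(vol, fullMask(vol))
  expect_equal(st$suv_max, 6)
  expect_equal(st$suv_mean, 4)
  expect_equal(st$mtv_ml, 3 * 4.06 * 4.06 * 5 / 1000)
  expect_equal(st$cov, sqrt(8 / 3) / 4)     # population SD / mean
})

test_that("constant and single-voxel regions give degenerate SUV metrics", {
  vol <- vol3d(rep(3, 8), dim = c(2, 2, 2))
  expect_equal(suvStatistics(vol, fullMask(vol))$cov, 0)
  v1 <- vol3d(5, dim = c(1, 1, 1))
  st <- suvStatistics(v1, fullMask(v1))
  expect_equal(st$suv_max, st$suv_mean)
  expect_equal(st$cov, 0)
  expect_equal(st$mtv_ml, prod(c(4.06, 4.06, 5)) / 1000)
})

test_that("mask/volume shape mismatch and zero mean are rejected", {
  vol <- vol3d(rep(1, 8), dim = c(2, 2, 2))
  bad <- fullMask(vol3d(rep(1, 27), dim = c(3, 3, 3)))
  expect_error(suvStatistics(vol, bad), "differ")
  z <- vol3d(rep(0, 8), dim = c(2, 2, 2))
  expect_error(suvStatistics(z, fullMask(z)), "COV undefined")
})

test_that("SUV discretization follows the 64-bin resampling rule", {
  vol <- vol3d(c(2, 4, 6), dim = c(3, 1, 1))
  disc <- discretizeSUV(vol, fullMask(vol))
  expect_identical(as.integer(binGrid(disc)), c(1L, 33L, 64L))
  flat <- vol3d(rep(3.7, 12), dim = c(3, 2, 2))
  expect_true(all(binGrid(discretizeSUV(flat, fullMask(flat))) == 1L,
                  na.rm = TRUE))
  set.seed(2)
  rnd <- vol3d(runif(60, 0, 20), dim = c(5, 4, 3))
  b <- binGrid(discretizeSUV(rnd, fullMask(rnd)))
  expect_gte(min(b, na.rm = TRUE), 1L)
  expect_lte(max(b, na.rm = TRUE), 64L)
  expect_equal(max(b, na.rm = TRUE), 64L)   # the VOI max lands in the top bin
})

test_that("GLCM of a 1D strip matches exhaustive pair enumeration", {
  bins <- array(NA_integer_, c(3, 1, 1)); bins[] <- c(1L, 1L, 2L)
  g <- computeGLCM(discFromBins(bins))
  p <- g@p
  expect_equal(p[1, 1], 0.5)
  expect_equal(p[1, 2], 0.25)
  expect_equal(p[2, 1], 0.25)
  expect_equal(p[2, 2], 0)
  expect_equal(sum(p), 1)
})

test_that("GLCM is symmetric, normalized, and diagonal for constant VOIs", {
  bins <- array(5L, c(3, 3, 3))
  g <- computeGLCM(discFromBins(bins))
  expect_equal(g@p[5, 5], 1)
  set.seed(9)
  rb <- array(sample(1:6, 64, replace = TRUE), c(4, 4, 4))
  g2 <- computeGLCM(discFromBins(rb))
  expect_equal(sum(g2@p), 1)
  expect_equal(g2@p, t(g2@p))
  single <- array(NA_integer_, c(3, 3, 3)); single[2, 2, 2] <- 1L
  expect_error(computeGLCM(discFromBins(single)), "no co-occurrences")
})

test_that("GLCM features match hand-derived values and bounds", {
  bins <- array(NA_integer_, c(3, 1, 1)); bins[] <- c(1L, 1L, 2L)
  f <- glcmFeatures(computeGLCM(discFromBins(bins)))
  expect_equal(f$entropy, 1.5)     # -(0.5 log2 0.5 + 2 * 0.25 log2 0.25)
  expect_equal(f$contrast, 0.5)
  const <- array(3L, c(3, 3, 3))
  expect_warning(fc <- glcmFeatures(computeGLCM(discFromBins(const))),
                 "correlation")
  expect_equal(fc$entropy, 0)
  expect_equal(fc$contrast, 0)
  expect_equal(fc$correlation, 1)
  set.seed(11)
  rb <- array(sample(1:64, 125, replace = TRUE), c(5, 5, 5))
  fr <- glcmFeatures(computeGLCM(discFromBins(rb)))
  expect_gte(fr$entropy, 0); expect_lte(fr$entropy, 2 * log2(64))
  expect_gte(fr$contrast, 0)
  expect_gte(fr$correlation, -1); expect_lte(fr$correlation, 1)
})

test_that("NGTDM matches hand enumeration on a 1D strip", {
  bins <- array(NA_integer_, c(3, 1, 1)); bins[] <- c(1L, 2L, 1L)
  t <- computeNGTDM(discFromBins(bins))
  i2 <- which(t@levels == 2L)
  expect_equal(t@s[i2], 1)                      # |2 - mean(1,1)|
  expect_equal(t@p, c(2 / 3, 1 / 3))
  expect_equal(sum(t@p), 1)
})

test_that("NGTDM of a constant VOI is deviation-free", {
  t <- computeNGTDM(discFromBins(array(4L, c(3, 3, 3))))
  expect_identical(t@levels, 4L)
  expect_equal(t@s, 0)
  expect_equal(t@p, 1)
})

test_that("coarseness and busyness follow the regularized definitions", {
  # two-level table with p = {1/2, 1/2}, s = {1, 1}
  t <- new("NGTDMTable", levels = c(1L, 2L), p = c(0.5, 0.5), s = c(1, 1),
           nValid = 4L)
  f <- ngtdmFeatures(t)
  expect_equal(f$coarseness, 1 / (1e-6 + 1))
  expect_equal(f$busyness, 1)                   # denominator 2*|0.5 - 1.0|
  const <- computeNGTDM(discFromBins(array(4L, c(3, 3, 3))))
  fc <- ngtdmFeatures(const)
  expect_equal(fc$coarseness, 1e6)              # capped at 1/eps
  expect_equal(fc$busyness, 0)
})

test_that("GLCM and NGTDM match brute-force enumeration on random grids", {
  set.seed(123)
  for (i in 1:30) {
    d <- sample(2:8, 3, replace = TRUE)
    nb <- sample(2:8, 1)
    bins <- array(sample(seq_len(nb), prod(d), replace = TRUE), d)
    bins[runif(prod(d)) < 0.2] <- NA              # holes in the VOI
    if (sum(!is.na(bins)) < 4) next
    g <- tryCatch(computeGLCM(discFromBins(bins)), error = function(e) NULL)
    if (!is.null(g)) {
      expect_equal(g@p[1:nb, 1:nb], naiveGLCM(bins, 64L)[1:nb, 1:nb])
      expect_true(all(g@p[-(1:nb), ] == 0))
    }
    t <- tryCatch(computeNGTDM(discFromBins(bins)), error = function(e) NULL)
    o <- tryCatch(naiveNGTDM(bins), error = function(e) NULL)
    if (!is.null(t) && !is.null(o)) {
      expect_identical(t@levels, as.integer(o$levels))
      expect_equal(t@p, o$p)
      expect_equal(t@s, o$s)
    }
  }
})

test_that("merged GLCM features are invariant to 90-degree rotations", {
  set.seed(7)
  a <- array(runif(5 * 5 * 5, 1, 9), c(5, 5, 5))
  feat <- function(arr) {
    v <- vol3d(arr, spacing = c(1, 1, 1))
    f <- glcmFeatures(computeGLCM(discretizeSUV(v, fullMask(v))))
    unlist(f[c("entropy", "correlation", "contrast")])
  }
  base <- feat(a)
  rotations <- list(
    aperm(a[, 5:1, ], c(2, 1, 3)),     # 90 deg about z
    aperm(a[, , 5:1], c(1, 3, 2)),     # 90 deg about x
    aperm(a[5:1, , ], c(3, 2, 1)))     # 90 deg about y
  for (r in rotations) expect_equal(feat(r), base)
})

test_that("extractAllFeatures composes the degenerate cases", {
  p <- phantomParams(tumorDiameterMm = 24, heterogeneityAmplitude = 0,
                     noiseSd = 0, seed = 2)
  vol <- generateTumorPhantom(p)
  f <- suppressWarnings(extractAllFeatures(vol))
  expect_equal(f$entropy, 0)
  expect_equal(f$contrast, 0)
  expect_equal(f$cov, 0)
  expect_equal(f$busyness, 0)
  expect_equal(f$coarseness, 1e6)
  expect_equal(f$correlation, 1)
})

test_that("SUVmax is invariant to the isocontour threshold", {
  for (s in 1:5) {
    p <- phantomParams(tumorMeanSuv = 7, heterogeneityAmplitude = 1.2,
                       heterogeneityLengthMm = 6, seed = s)
    vol <- generateTumorPhantom(p)
    f20 <- extractAllFeatures(vol, thresholdSUV = 2.0)
    f25 <- extractAllFeatures(vol, thresholdSUV = 2.5)
    expect_identical(f20$suv_max, f25$suv_max)
  }
})

test_that("every feature on a crafted 5^3 volume equals its brute-force value", {
  set.seed(55)
  a <- array(runif(125, 0.2, 12), c(5, 5, 5))
  vol <- vol3d(a, spacing = c(4.06, 4.06, 5))
  f <- extractAllFeatures(vol, thresholdSUV = 2)
  # oracle path: flood fill -> manual discretization -> naive matrices
  m <- bfsComponent(a >= 2, hottestVoxel(vol), 26L)
  vals <- a[m]
  expect_equal(f$suv_max, max(vals))
  expect_equal(f$suv_mean, mean(vals))
  expect_equal(f$mtv_ml, sum(m) * 4.06 * 4.06 * 5 / 1000)
  expect_equal(f$cov, sqrt(mean((vals - mean(vals))^2)) / mean(vals))
  bins <- array(NA_integer_, dim(a))
  bins[m] <- pmin(pmax(floor(64 * (a[m] - min(vals)) /
                               (max(vals) - min(vals))) + 1, 1), 64)
  p <- naiveGLCM(bins)
  nz <- p[p > 0]
  expect_equal(f$entropy, -sum(nz * log2(nz)))
  ii <- matrix(1:64, 64, 64); jj <- t(ii)
  expect_equal(f$contrast, sum((ii - jj)^2 * p))
  marg <- rowSums(p); mu <- sum(1:64 * marg)
  s2 <- sum((1:64 - mu)^2 * marg)
  expect_equal(f$correlation, sum((ii - mu) * (jj - mu) * p) / s2)
  o <- naiveNGTDM(bins)
  ps <- sum(o$p * o$s)
  expect_equal(f$coarseness, min(1 / (1e-6 + ps), 1e6))
  ip <- o$levels * o$p
  expect_equal(f$busyness, ps / sum(abs(outer(ip, ip, "-"))))
})
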