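#' Conventional SUV metrics over a VOI
#'
#' SUVmax, SUVmean, metabolic tumor volume and coefficient of variation,
#' computed on floating-point SUV data. MTV is voxel count times physical
#' voxel volume; COV is the population standard deviation divided by the
#' mean.
#'
#' @param volume a [PETVolume-class].
#' @param mask a congruent [VOIMask-class].
#' @return named list: `suv_max`, `suv_mean`, `mtv_ml`, `cov`.
#' @examples
#' a <- array(0, dim = c(3, 1, 1)); a[] <- c(2, 4, 6)
#' m <- new("VOIMask", mask = array(TRUE, dim(a)), thresholdSUV = 1,
#'          connectivity = 26L, seedVoxel = c(3L, 1L, 1L))
#' suvStatistics(PETVolume(a), m)
#' @export
suvStatistics <- function(volume, mask) {
  stopifnot(is(volume, "PETVolume"), is(mask, "VOIMask"))
  if (!identical(dim(suvGrid(volume)), dim(maskArray(mask))))
    stop("mask and volume shapes differ")
  vals <- suvGrid(volume)[maskArray(mask)]
  m <- mean(vals)
  if (m == 0) stop("COV undefined: mean SUV over the VOI is 0")
  sdpop <- sqrt(mean((vals - m)^2))
  voxml <- prod(voxelSpacing(volume)) / 1000
  list(suv_max = max(vals), suv_mean = m,
       mtv_ml = length(vals) * voxml, cov = sdpop / m)
}

#' Resample VOI SUV values to discrete gray tones
#'
#' VOI SUV values are min-max normalized and discretized to `nBins` gray
#' tones: `R(x) = nBins * (I(x) - SUVmin) / (SUVmax - SUVmin)` with
#' `bin(x) = clamp(floor(R(x)) + 1, 1, nBins)`, so the VOI minimum maps to
#' bin 1 and the maximum into bin `nBins`. A flat VOI (SUVmin = SUVmax)
#' maps entirely to bin 1.
#'
#' @param volume a [PETVolume-class].
#' @param mask a congruent [VOIMask-class].
#' @param nBins number of gray tones (default 64).
#' @return a [DiscretizedVolume-class].
#' @export
discretizeSUV <- function(volume, mask, nBins = 64L) {
  stopifnot(is(volume, "PETVolume"), is(mask, "VOIMask"))
  suv <- suvGrid(volume)
  msk <- maskArray(mask)
  if (!identical(dim(suv), dim(msk))) stop("mask and volume shapes differ")
  nBins <- as.integer(nBins)
  vals <- suv[msk]
  mn <- min(vals); mx <- max(vals)
  bins <- array(NA_integer_, dim(suv))
  if (mx == mn) {
    bins[msk] <- 1L
  } else {
    r <- nBins * (vals - mn) / (mx - mn)
    bins[msk] <- pmin.int(pmax.int(as.integer(floor(r)) + 1L, 1L), nBins)
  }
  new("DiscretizedVolume", bins = bins, nBins = nBins, suvMin = mn, suvMax = mx)
}

#' 3D gray-level co-occurrence matrix over 13 directions
#'
#' For each of the 13 unique 3D unit offsets (the nonzero elements of
#' `{-1,0,1}^3` modulo sign), ordered co-occurrences of gray tones between
#' VOI voxel pairs are counted and symmetrized by adding the transpose.
#' `"merged"` aggregation pools counts across directions before
#' normalizing to total probability 1; `"averaged"` normalizes each
#' direction separately and averages the 13 matrices. Offsets are one
#' voxel in index space regardless of the anisotropic physical spacing.
#'
#' @param disc a [DiscretizedVolume-class] (the VOI is its non-`NA` support).
#' @param aggregation `"merged"` (default) or `"averaged"`.
#' @return a [GLCMatrix-class].
#' @export
computeGLCM <- function(disc, aggregation = c("merged", "averaged")) {
  stopifnot(is(disc, "DiscretizedVolume"))
  aggregation <- match.arg(aggregation)
  bins <- binGrid(disc)
  n <- disc@nBins
  d <- dim(bins)
  dirs <- glcmDirections()
  pooled <- matrix(0, n, n)
  avg <- matrix(0, n, n)
  nDirUsed <- 0L
  for (r in seq_len(nrow(dirs))) {
    sr <- shiftRanges(d, dirs[r, ])
    cnt <- matrix(0, n, n)
    if (!is.null(sr)) {
      a <- bins[sr$src[[1]], sr$src[[2]], sr$src[[3]]]
      b <- bins[sr$dst[[1]], sr$dst[[2]], sr$dst[[3]]]
      ok <- !is.na(a) & !is.na(b)
      if (any(ok)) {
        tab <- tabulate((a[ok] - 1L) * n + b[ok], nbins = n * n)
        cnt <- matrix(tab, n, n, byrow = TRUE)  # rows = first voxel's level
      }
    }
    cnt <- cnt + t(cnt)
    s <- sum(cnt)
    if (s > 0) {
      pooled <- pooled + cnt
      avg <- avg + cnt / s
      nDirUsed <- nDirUsed + 1L
    }
  }
  if (sum(pooled) == 0)
    stop("no co-occurrences: fewer than 2 VOI voxels are mutual neighbors")
  p <- if (aggregation == "merged") pooled / sum(pooled) else avg / nDirUsed
  new("GLCMatrix", p = p, offsets = dirs, aggregation = aggregation)
}

#' Second-order texture features from a co-occurrence matrix
#'
#' Entropy `-sum p log p` over nonzero cells (base 2 by default, so the
#' value is in bits), contrast `sum (i-j)^2 p(i,j)` in squared bins, and
#' correlation `sum (i-mu)(j-mu) p(i,j) / sigma^2` with `mu`, `sigma` the
#' marginal mean and population SD (the two marginals coincide by
#' symmetry). A degenerate matrix with `sigma = 0` (single occupied gray
#' level) has correlation defined as 1, with a warning.
#'
#' @param g a [GLCMatrix-class].
#' @param base logarithm base for entropy (default 2).
#' @return named list: `entropy`, `correlation`, `contrast`,
#'   `entropy_log_base`.
#' @export
glcmFeatures <- function(g, base = 2) {
  stopifnot(is(g, "GLCMatrix"))
  p <- g@p
  if (abs(sum(p) - 1) > 1e-8) stop("co-occurrence matrix is not normalized")
  nz <- p[p > 0]
  entropy <- -sum(nz * log(nz, base = base))
  n <- nrow(p)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  contrast <- sum((i - j)^2 * p)
  marg <- rowSums(p)
  mu <- sum(seq_len(n) * marg)
  sig2 <- sum((seq_len(n) - mu)^2 * marg)
  if (sig2 == 0) {
    warning("single occupied gray level: correlation defined as 1")
    correlation <- 1
  } else {
    correlation <- sum((i - mu) * (j - mu) * p) / sig2
  }
  list(entropy = entropy, correlation = correlation, contrast = contrast,
       entropy_log_base = base)
}

#' Neighborhood gray-tone difference table
#'
#' For every VOI voxel with at least one in-mask 26-neighbor, the
#' neighborhood average gray tone is the mean bin of its in-mask
#' neighbors (the center voxel excluded; no padding with background --
#' the VOI boundary is tissue, not image border). `s_i` accumulates
#' `|i - Abar|` over voxels of level `i`; `p_i` is the fraction of valid
#' voxels at level `i`.
#'
#' @param disc a [DiscretizedVolume-class].
#' @return an [NGTDMTable-class].
#' @export
computeNGTDM <- function(disc) {
  stopifnot(is(disc, "DiscretizedVolume"))
  bins <- binGrid(disc)
  d <- dim(bins)
  msk <- !is.na(bins)
  bz <- bins; bz[!msk] <- 0L
  nbSum <- array(0, d)
  nbCnt <- array(0L, d)
  offs <- offsets26()
  for (r in seq_len(nrow(offs))) {
    sr <- shiftRanges(d, offs[r, ])
    if (is.null(sr)) next
    nbSum[sr$src[[1]], sr$src[[2]], sr$src[[3]]] <-
      nbSum[sr$src[[1]], sr$src[[2]], sr$src[[3]]] +
      bz[sr$dst[[1]], sr$dst[[2]], sr$dst[[3]]]
    nbCnt[sr$src[[1]], sr$src[[2]], sr$src[[3]]] <-
      nbCnt[sr$src[[1]], sr$src[[2]], sr$src[[3]]] +
      msk[sr$dst[[1]], sr$dst[[2]], sr$dst[[3]]]
  }
  valid <- msk & nbCnt > 0L
  if (!any(valid)) stop("no VOI voxel has an in-mask neighbor")
  lev <- bins[valid]
  dev <- abs(lev - nbSum[valid] / nbCnt[valid])
  levels <- sort(unique(lev))
  s <- vapply(levels, function(l) sum(dev[lev == l]), numeric(1))
  cnt <- vapply(levels, function(l) sum(lev == l), numeric(1))
  new("NGTDMTable", levels = as.integer(levels), p = cnt / sum(cnt), s = s,
      nValid = as.integer(sum(valid)))
}

#' Coarseness and busyness from a gray-tone difference table
#'
#' Coarseness is `1 / (eps + sum_i p_i s_i)` with `eps = 1e-6`, reported
#' capped at `1/eps` (a perfectly uniform VOI). Busyness is
#' `sum_i p_i s_i / sum_{i != j} |i p_i - j p_j|` over ordered pairs of
#' occupied levels, defined as 0 when only one level is occupied.
#'
#' @param t an [NGTDMTable-class].
#' @param eps regularizer for coarseness (default `1e-6`).
#' @return named list: `coarseness`, `busyness`.
#' @export
ngtdmFeatures <- function(t, eps = 1e-6) {
  stopifnot(is(t, "NGTDMTable"))
  ps <- sum(t@p * t@s)
  coarseness <- min(1 / (eps + ps), 1 / eps)
  ip <- t@levels * t@p
  denom <- sum(abs(outer(ip, ip, "-")))
  busyness <- if (denom == 0) 0 else ps / denom
  list(coarseness = coarseness, busyness = busyness)
}

#' Extract the full PET parameter set from a volume
#'
#' Segments the tumor at the given SUV isocontour threshold and computes
#' the nine PET parameters: SUVmax, SUVmean, MTV, COV on floating-point
#' SUV data, and entropy, correlation, contrast (GLCM) plus coarseness,
#' busyness (NGTDM) on the 64-bin discretized VOI.
#'
#' @param volume a [PETVolume-class].
#' @param thresholdSUV SUV isocontour level (default 2.0).
#' @param connectivity component connectivity (default 26).
#' @param nBins gray tones for discretization (default 64).
#' @param aggregation GLCM direction aggregation (default `"merged"`).
#' @param entropyLogBase logarithm base for entropy (default 2, bits).
#' @param diameter_mm optional known tumor diameter, carried through for
#'   T-stage subgrouping.
#' @param override optional segmentation override mask (see
#'   [segmentIsocontour()]).
#' @return one-row `data.frame` with columns `id`, `suv_max`, `suv_mean`,
#'   `mtv_ml`, `cov`, `entropy`, `correlation`, `contrast`, `coarseness`,
#'   `busyness`, `voi_threshold`, `entropy_log_base`, `diameter_mm`.
#' @examples
#' vol <- generateTumorPhantom(phantomParams(seed = 7))
#' extractAllFeatures(vol)
#' @export
extractAllFeatures <- function(volume, thresholdSUV = 2.0, connectivity = 26L,
                               nBins = 64L,
                               aggregation = c("merged", "averaged"),
                               entropyLogBase = 2, diameter_mm = NA_real_,
                               override = NULL) {
  aggregation <- match.arg(aggregation)
  mask <- segmentIsocontour(volume, thresholdSUV = thresholdSUV,
                            connectivity = connectivity, override = override)
  sstat <- suvStatistics(volume, mask)
  disc <- discretizeSUV(volume, mask, nBins = nBins)
  gfeat <- glcmFeatures(computeGLCM(disc, aggregation = aggregation),
                        base = entropyLogBase)
  nfeat <- ngtdmFeatures(computeNGTDM(disc))
  data.frame(id = patientId(volume),
             suv_max = sstat$suv_max, suv_mean = sstat$suv_mean,
             mtv_ml = sstat$mtv_ml, cov = sstat$cov,
             entropy = gfeat$entropy, correlation = gfeat$correlation,
             contrast = gfeat$contrast, coarseness = nfeat$coarseness,
             busyness = nfeat$busyness, voi_threshold = thresholdSUV,
             entropy_log_base = entropyLogBase, diameter_mm = diameter_mm,
             stringsAsFactors = FALSE)
}
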