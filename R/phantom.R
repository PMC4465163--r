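#' Parameters for a synthetic tumor phantom
#'
#' Describes one spherical (optionally mildly ellipsoidal) tumor embedded
#' in lung background on the clinical PET grid. Intratumoral heterogeneity
#' is an additive, spatially correlated Gaussian random field whose
#' standard deviation is `heterogeneityAmplitude` (SUV units) and whose
#' correlation structure is set by `heterogeneityLengthMm` (the SD, in mm,
#' of the Gaussian smoothing kernel applied to white noise). Independent
#' voxel noise can be added on top; the default phantom is noise-free so
#' texture is entirely the correlated field.
#'
#' @param gridShape integer(3) voxel grid; `NULL` (default) sizes the grid
#'   to the tumor diameter plus a 20 mm margin per side.
#' @param voxelSpacingMm voxel spacing in mm (default `c(4.06, 4.06, 5)`).
#' @param tumorDiameterMm tumor diameter in mm (clinical range roughly
#'   17-68 mm).
#' @param tumorMeanSuv mean tumor SUV; must exceed `backgroundSuv`.
#' @param backgroundSuv lung background SUV (>= 0).
#' @param heterogeneityAmplitude SD of the correlated texture field, SUV
#'   units (>= 0; 0 gives a perfectly flat tumor).
#' @param heterogeneityLengthMm correlation length of the texture field,
#'   mm (> 0).
#' @param noiseSd SD of independent voxelwise noise (>= 0, default 0).
#' @param axisRatios length-3 multipliers turning the sphere into an
#'   ellipsoid (default `c(1, 1, 1)`).
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   volumes.
#' @return validated list of class `PhantomParams`.
#' @seealso [generateTumorPhantom()]
#' @export
phantomParams <- function(gridShape = NULL,
                          voxelSpacingMm = c(4.06, 4.06, 5.0),
                          tumorDiameterMm = 30,
                          tumorMeanSuv = 8,
                          backgroundSuv = 0.5,
                          heterogeneityAmplitude = 1,
                          heterogeneityLengthMm = 8,
                          noiseSd = 0,
                          axisRatios = c(1, 1, 1),
                          seed = 1L) {
  if (any(voxelSpacingMm <= 0)) stop("voxel spacing must be positive")
  if (tumorDiameterMm <= 0) stop("tumor diameter must be positive")
  if (tumorMeanSuv <= backgroundSuv)
    stop("tumorMeanSuv must exceed backgroundSuv")
  if (backgroundSuv < 0 || heterogeneityAmplitude < 0 || noiseSd < 0)
    stop("backgroundSuv, heterogeneityAmplitude and noiseSd must be >= 0")
  if (heterogeneityLengthMm <= 0) stop("heterogeneityLengthMm must be > 0")
  if (is.null(gridShape)) {
    ext <- tumorDiameterMm * max(axisRatios) + 40  # 20 mm margin per side
    gridShape <- as.integer(ceiling(ext / voxelSpacingMm))
  }
  gridShape <- as.integer(gridShape)
  if (any(gridShape < 3L)) stop("grid too small")
  if (any(tumorDiameterMm * axisRatios > gridShape * voxelSpacingMm))
    stop("tumor does not fit inside the grid")
  structure(list(gridShape = gridShape, voxelSpacingMm = voxelSpacingMm,
                 tumorDiameterMm = tumorDiameterMm,
                 tumorMeanSuv = tumorMeanSuv, backgroundSuv = backgroundSuv,
                 heterogeneityAmplitude = heterogeneityAmplitude,
                 heterogeneityLengthMm = heterogeneityLengthMm,
                 noiseSd = noiseSd, axisRatios = axisRatios,
                 seed = as.integer(seed)),
            class = "PhantomParams")
}

# run expr with a private, seed-determined RNG stream; restores global state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# separable Gaussian smoothing of a 3D array; sdVox = kernel SD per axis
# in voxel units. Applied by banded matrix products along each unfolding.
gaussianSmooth3D <- function(x, sdVox) {
  d <- dim(x)
  for (ax in 1:3) {
    s <- sdVox[ax]
    if (s <= 0) next
    n <- d[ax]
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, "-")^2 / (2 * s^2))
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    xp <- aperm(x, perm)
    dm <- dim(xp)
    xp <- K %*% matrix(xp, nrow = n)
    dim(xp) <- dm
    x <- aperm(xp, order(perm))
  }
  x
}

# analytic ellipsoid membership mask for a phantom's tumor
analyticTumorMask <- function(params) {
  d <- params$gridShape
  sp <- params$voxelSpacingMm
  ctr <- (d + 1) / 2
  semi <- params$tumorDiameterMm / 2 * params$axisRatios
  cx <- (seq_len(d[1]) - ctr[1]) * sp[1]
  cy <- (seq_len(d[2]) - ctr[2]) * sp[2]
  cz <- (seq_len(d[3]) - ctr[3]) * sp[3]
  q <- outer(outer((cx / semi[1])^2, (cy / semi[2])^2, "+"),
             (cz / semi[3])^2, "+")
  q <= 1
}

#' Generate a synthetic tumor phantom
#'
#' Places an ellipsoidal tumor of the requested physical diameter at the
#' grid center: voxels whose centers fall inside the analytic ellipsoid
#' take `tumorMeanSuv` plus the correlated texture field (smoothed white
#' noise, normalized to zero mean and unit SD over the tumor, scaled to
#' `heterogeneityAmplitude`); background voxels take `backgroundSuv`.
#' Optional independent voxel noise is added everywhere, and SUV is
#' clipped at 0. The result is a pure function of the parameters,
#' including the seed.
#'
#' @param params a `PhantomParams` list from [phantomParams()].
#' @return a [PETVolume-class], with the generating parameters attached as
#'   attribute `"params"`.
#' @examples
#' vol <- generateTumorPhantom(phantomParams(tumorDiameterMm = 24, seed = 3))
#' vol
#' @export
generateTumorPhantom <- function(params) {
  stopifnot(inherits(params, "PhantomParams"))
  d <- params$gridShape
  tumor <- analyticTumorMask(params)
  suv <- withSeed(params$seed, {
    out <- array(params$backgroundSuv, d)
    out[tumor] <- params$tumorMeanSuv
    if (params$heterogeneityAmplitude > 0) {
      wn <- array(stats::rnorm(prod(d)), d)
      fld <- gaussianSmooth3D(wn, params$heterogeneityLengthMm /
                                    params$voxelSpacingMm)
      tv <- fld[tumor]
      sdt <- stats::sd(tv)
      if (sdt > 0)
        out[tumor] <- out[tumor] +
          params$heterogeneityAmplitude * (tv - mean(tv)) / sdt
    }
    if (params$noiseSd > 0)
      out <- out + array(stats::rnorm(prod(d), sd = params$noiseSd), d)
    out
  })
  suv[suv < 0] <- 0
  vol <- PETVolume(suv, params$voxelSpacingMm)
  attr(vol, "params") <- params
  vol
}
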