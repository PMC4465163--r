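#' @import methods
NULL

#' PETVolume: a 3D SUV image with physical voxel spacing
#'
#' Container for a body-weight-normalized standardized uptake value (SUV)
#' grid. Every downstream stage (segmentation, feature extraction, the
#' study pipeline) consumes this class.
#'
#' @slot suv 3D numeric array of non-negative, finite SUV values.
#' @slot spacing numeric(3), voxel edge lengths in mm (x, y, z); strictly
#'   positive. The default clinical grid is 4.06 x 4.06 x 5.0 mm.
#' @slot patientId optional identifier, `NA` when unknown.
#'
#' @seealso [PETVolume()] for construction, [segmentIsocontour()],
#'   [extractAllFeatures()]
#' @export
setClass("PETVolume",
  representation(suv = "array", spacing = "numeric", patientId = "character"),
  prototype(patientId = NA_character_)
)

setValidity("PETVolume", function(object) {
  msgs <- character()
  if (length(dim(object@suv)) != 3L)
    msgs <- c(msgs, "suv must be a 3D array")
  if (!all(is.finite(object@suv)))
    msgs <- c(msgs, "all SUV values must be finite")
  else if (any(object@suv < 0))
    msgs <- c(msgs, "all SUV values must be >= 0")
  if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be three strictly positive values (mm)")
  if (length(object@patientId) != 1L)
    msgs <- c(msgs, "patientId must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PETVolume
#'
#' @param suv 3D numeric array of SUV values (finite, non-negative).
#' @param spacing voxel spacing in mm, length 3. Default `c(4.06, 4.06, 5)`.
#' @param patientId optional patient identifier.
#' @return A [PETVolume-class] object.
#' @examples
#' vol <- PETVolume(array(1, dim = c(4, 4, 4)))
#' voxelSpacing(vol)
#' @export
PETVolume <- function(suv, spacing = c(4.06, 4.06, 5.0),
                      patientId = NA_character_) {
  if (is.null(dim(suv))) dim(suv) <- c(length(suv), 1L, 1L)
  new("PETVolume", suv = suv, spacing = as.numeric(spacing),
      patientId = as.character(patientId))
}

#' VOIMask: a segmented tumor volume of interest
#'
#' Boolean grid congruent with its parent [PETVolume-class], produced by
#' [segmentIsocontour()]: the connected supra-threshold component that
#' contains the hottest voxel. The mask records the SUV threshold, the
#' connectivity used for component growth and the seed voxel, so that a
#' feature value can always be traced to its segmentation settings.
#'
#' @slot mask logical 3D array; non-empty.
#' @slot thresholdSUV the SUV isocontour level (voxels with SUV >= threshold
#'   are eligible).
#' @slot connectivity 6, 18 or 26 (face, face+edge, full 3D neighborhood).
#' @slot seedVoxel integer(3) 1-based voxel index of the seed (hottest) voxel;
#'   always inside the mask.
#' @export
setClass("VOIMask",
  representation(mask = "array", thresholdSUV = "numeric",
                 connectivity = "integer", seedVoxel = "integer")
)

setValidity("VOIMask", function(object) {
  msgs <- character()
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    msgs <- c(msgs, "mask must be a logical 3D array")
  else {
    if (!any(object@mask)) msgs <- c(msgs, "mask must be non-empty")
    if (length(object@seedVoxel) != 3L)
      msgs <- c(msgs, "seedVoxel must have length 3")
    else if (any(object@seedVoxel < 1L) ||
             any(object@seedVoxel > dim(object@mask)))
      msgs <- c(msgs, "seedVoxel out of bounds")
    else if (!object@mask[matrix(object@seedVoxel, 1L)])
      msgs <- c(msgs, "seedVoxel must lie inside the mask")
  }
  if (!(object@connectivity %in% c(6L, 18L, 26L)))
    msgs <- c(msgs, "connectivity must be 6, 18 or 26")
  if (length(object@thresholdSUV) != 1L || !is.finite(object@thresholdSUV))
    msgs <- c(msgs, "thresholdSUV must be a finite scalar")
  if (length(msgs)) msgs else TRUE
})

#' DiscretizedVolume: VOI gray tones after 64-bin SUV resampling
#'
#' Holds the resampled gray-tone grid used by the texture matrices. Voxels
#' outside the VOI are `NA`; VOI voxels carry an integer bin in
#' `1..nBins`. The VOI SUV extrema used for scaling are retained.
#'
#' @slot bins integer 3D array, `NA` outside the VOI.
#' @slot nBins number of gray levels (default 64).
#' @slot suvMin,suvMax the VOI SUV extrema used in the resampling formula.
#' @seealso [discretizeSUV()]
#' @export
setClass("DiscretizedVolume",
  representation(bins = "array", nBins = "integer",
                 suvMin = "numeric", suvMax = "numeric")
)

setValidity("DiscretizedVolume", function(object) {
  msgs <- character()
  v <- object@bins[!is.na(object@bins)]
  if (length(v) == 0L) msgs <- c(msgs, "no VOI voxels")
  else if (any(v < 1L) || any(v > object@nBins))
    msgs <- c(msgs, sprintf("bins must lie in [1, %d]", object@nBins))
  if (object@suvMin > object@suvMax)
    msgs <- c(msgs, "suvMin must be <= suvMax")
  if (length(msgs)) msgs else TRUE
})

#' GLCMatrix: symmetric 3D gray-level co-occurrence probabilities
#'
#' Joint probability matrix of gray-level pairs at unit voxel offset,
#' pooled (or averaged) over the 13 unique 3D directions and symmetrized.
#'
#' @slot p `nBins x nBins` matrix; non-negative, sums to 1, symmetric.
#' @slot offsets 13 x 3 integer matrix of the direction set.
#' @slot aggregation `"merged"` (counts pooled before normalization) or
#'   `"averaged"` (per-direction probabilities averaged).
#' @seealso [computeGLCM()], [glcmFeatures()]
#' @export
setClass("GLCMatrix",
  representation(p = "matrix", offsets = "matrix", aggregation = "character")
)

setValidity("GLCMatrix", function(object) {
  msgs <- character()
  if (any(object@p < 0)) msgs <- c(msgs, "probabilities must be >= 0")
  if (abs(sum(object@p) - 1) > 1e-12)
    msgs <- c(msgs, "probabilities must sum to 1")
  if (max(abs(object@p - t(object@p))) > 1e-12)
    msgs <- c(msgs, "matrix must be symmetric")
  if (!object@aggregation %in% c("merged", "averaged"))
    msgs <- c(msgs, "aggregation must be 'merged' or 'averaged'")
  if (length(msgs)) msgs else TRUE
})

#' NGTDMTable: neighborhood gray-tone difference summaries
#'
#' Per occupied gray level `i`: the occupancy probability `p_i` among VOI
#' voxels that have at least one in-mask 26-neighbor, and the accumulated
#' absolute deviation `s_i` of level-`i` voxels from their neighborhood
#' mean gray tone.
#'
#' @slot levels integer vector of occupied gray levels.
#' @slot p occupancy probabilities, summing to 1.
#' @slot s non-negative deviation sums, one per level.
#' @slot nValid number of VOI voxels with a valid neighborhood.
#' @seealso [computeNGTDM()], [ngtdmFeatures()]
#' @export
setClass("NGTDMTable",
  representation(levels = "integer", p = "numeric", s = "numeric",
                 nValid = "integer")
)

setValidity("NGTDMTable", function(object) {
  msgs <- character()
  k <- length(object@levels)
  if (length(object@p) != k || length(object@s) != k)
    msgs <- c(msgs, "levels, p, s must have equal length")
  if (k == 0L) msgs <- c(msgs, "table must have at least one occupied level")
  else {
    if (abs(sum(object@p) - 1) > 1e-12) msgs <- c(msgs, "p must sum to 1")
    if (any(object@s < 0)) msgs <- c(msgs, "s must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' StudyReport: the full analysis output of [runStudy()]
#'
#' Bundles the five report tables (ROC, Kaplan-Meier/log-rank, Cox,
#' threshold-stability, size-dependency) with a provenance block (config,
#' seed, config hash, package version) that makes a run reproducible.
#'
#' @slot rocTable AUC + 95% CI per parameter x endpoint, with a
#'   significance flag.
#' @slot survivalTable cutoff, per-group event counts, restricted-mean and
#'   median survival, log-rank p per parameter x endpoint.
#' @slot coxTable hazard ratios, 95% CI and p for univariate and
#'   multivariate Cox fits.
#' @slot stabilityTable per-feature Pearson r between isocontour thresholds,
#'   with ranges and mean +/- SD per threshold.
#' @slot sizeTable per-feature Pearson r against metabolic tumor volume.
#' @slot provenance list: config, seed, configHash, packageVersion, warnings.
#' @export
setClass("StudyReport",
  representation(rocTable = "data.frame", survivalTable = "data.frame",
                 coxTable = "data.frame", stabilityTable = "data.frame",
                 sizeTable = "data.frame", provenance = "list")
)

setValidity("StudyReport", function(object) {
  if (is.null(object@provenance$seed) || is.null(object@provenance$configHash))
    "provenance must record seed and configHash" else TRUE
})
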