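# Accessor generics and show() methods for the core containers.

#' Accessors for PETVolume and VOIMask
#'
#' @param object a [PETVolume-class], [VOIMask-class] or
#'   [DiscretizedVolume-class] object.
#' @return `suvGrid()` the SUV array; `voxelSpacing()` the mm spacing
#'   triple; `patientId()` the identifier; `maskArray()` the logical grid;
#'   `thresholdSUV()` the isocontour level; `seedVoxel()` the 1-based seed
#'   index; `nVoxels()` the VOI voxel count; `binGrid()` the gray-tone
#'   array.
#' @name accessors
#' @aliases suvGrid voxelSpacing patientId maskArray thresholdSUV seedVoxel
#'   nVoxels binGrid
#' @examples
#' vol <- PETVolume(array(3, dim = c(3, 3, 3)))
#' m <- segmentIsocontour(vol, thresholdSUV = 2)
#' nVoxels(m)
NULL

#' @rdname accessors
#' @export
setGeneric("suvGrid", function(object) standardGeneric("suvGrid"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("thresholdSUV", function(object) standardGeneric("thresholdSUV"))
#' @rdname accessors
#' @export
setGeneric("seedVoxel", function(object) standardGeneric("seedVoxel"))
#' @rdname accessors
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setGeneric("binGrid", function(object) standardGeneric("binGrid"))

#' @rdname accessors
setMethod("suvGrid", "PETVolume", function(object) object@suv)
#' @rdname accessors
setMethod("voxelSpacing", "PETVolume", function(object) object@spacing)
#' @rdname accessors
setMethod("patientId", "PETVolume", function(object) object@patientId)
#' @rdname accessors
setMethod("maskArray", "VOIMask", function(object) object@mask)
#' @rdname accessors
setMethod("thresholdSUV", "VOIMask", function(object) object@thresholdSUV)
#' @rdname accessors
setMethod("seedVoxel", "VOIMask", function(object) object@seedVoxel)
#' @rdname accessors
setMethod("nVoxels", "VOIMask", function(object) sum(object@mask))
#' @rdname accessors
setMethod("binGrid", "DiscretizedVolume", function(object) object@bins)

#' @export
setMethod("show", "PETVolume", function(object) {
  d <- dim(object@suv)
  cat(sprintf("PETVolume %dx%dx%d voxels, spacing %.2fx%.2fx%.2f mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  SUV range [%.3g, %.3g]", min(object@suv), max(object@suv)))
  if (!is.na(object@patientId))
    cat(sprintf("  patient %s", object@patientId))
  cat("\n")
})

#' @export
setMethod("show", "VOIMask", function(object) {
  cat(sprintf(
    "VOIMask: %d voxels at SUV >= %.2f (connectivity %d), seed (%d,%d,%d)\n",
    sum(object@mask), object@thresholdSUV, object@connectivity,
    object@seedVoxel[1], object@seedVoxel[2], object@seedVoxel[3]))
})

#' @export
setMethod("show", "GLCMatrix", function(object) {
  occ <- which(rowSums(object@p) + colSums(object@p) > 0)
  cat(sprintf("GLCMatrix %dx%d (%s over %d directions), %d occupied levels\n",
              nrow(object@p), ncol(object@p), object@aggregation,
              nrow(object@offsets), length(occ)))
})

#' @export
setMethod("show", "NGTDMTable", function(object) {
  cat(sprintf("NGTDMTable: %d occupied levels over %d valid voxels\n",
              length(object@levels), object@nValid))
})

#' @export
setMethod("show", "StudyReport", function(object) {
  cat("StudyReport\n")
  cat(sprintf("  ROC table:       %d rows\n", nrow(object@rocTable)))
  cat(sprintf("  survival table:  %d rows\n", nrow(object@survivalTable)))
  cat(sprintf("  Cox table:       %d rows\n", nrow(object@coxTable)))
  cat(sprintf("  stability table: %d rows\n", nrow(object@stabilityTable)))
  cat(sprintf("  size table:      %d rows\n", nrow(object@sizeTable)))
  cat(sprintf("  seed %s, config %s\n", object@provenance$seed,
              object@provenance$configHash))
})
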