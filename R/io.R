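#' Read a PET SUV volume from NIfTI
#'
#' Reads a 3D NIfTI image already in SUV units and its voxel spacing from
#' the header. DICOM series are not ingested: convert to an SUV-scaled
#' NIfTI first (body-weight SUV requires injected dose, decay interval
#' and patient weight, which live in the DICOM headers of the conversion
#' tool's input).
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param patientId optional identifier to attach.
#' @return a [PETVolume-class].
#' @export
readVolume <- function(path, patientId = NA_character_) {
  if (dir.exists(path))
    stop("directory input (DICOM series) is not supported; ",
         "convert to an SUV-scaled NIfTI volume first")
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) {
    stop(structure(class = c("pettexParseError", "error", "condition"),
                   list(message = paste0("cannot parse NIfTI '", path, "': ",
                                         conditionMessage(e)),
                        call = sys.call(-1))))
  })
  a <- array(as.vector(img), dim(img))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) dim(a) <- dim(a)[1:3]
  if (length(dim(a)) != 3L)
    stop(structure(class = c("pettexParseError", "error", "condition"),
                   list(message = paste0("'", path, "' is not a 3D volume"),
                        call = sys.call(-1))))
  sp <- RNifti::pixdim(img)[1:3]
  PETVolume(a, spacing = sp, patientId = patientId)
}

#' Write a PET volume (or VOI mask) as NIfTI
#'
#' Voxel spacing is stored in the header; SUV data are written at double
#' precision so a volume round-trips bit-identically.
#'
#' @param volume a [PETVolume-class], or a [VOIMask-class] (written as
#'   0/1 at the spacing given by `spacing`).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing spacing override, required when writing a bare mask.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path, spacing = NULL) {
  if (is(volume, "VOIMask")) {
    if (is.null(spacing)) stop("spacing required when writing a VOIMask")
    a <- array(as.double(maskArray(volume)), dim(maskArray(volume)))
  } else {
    stopifnot(is(volume, "PETVolume"))
    a <- suvGrid(volume)
    spacing <- voxelSpacing(volume)
  }
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
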