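#' Locate the hottest voxel of a PET volume
#'
#' Returns the 1-based voxel index of the maximum SUV, optionally
#' restricted to a search box. Ties are broken toward the
#' lexicographically smallest coordinate (x, then y, then z).
#'
#' @param volume a [PETVolume-class].
#' @param searchBox optional 2 x 3 matrix `rbind(lo, hi)` of inclusive
#'   1-based bounds per axis.
#' @return integer(3) voxel index.
#' @examples
#' a <- array(1, dim = c(4, 4, 4)); a[2, 3, 1] <- 5
#' hottestVoxel(PETVolume(a))
#' @export
hottestVoxel <- function(volume, searchBox = NULL) {
  stopifnot(is(volume, "PETVolume"))
  suv <- suvGrid(volume)
  d <- dim(suv)
  if (!is.null(searchBox)) {
    searchBox <- matrix(as.integer(searchBox), nrow = 2L)
    if (any(searchBox[1, ] > searchBox[2, ]))
      stop("empty search box")
    if (any(searchBox[1, ] < 1L) || any(searchBox[2, ] > d))
      stop("search box out of bounds")
    sub <- suv[searchBox[1, 1]:searchBox[2, 1],
               searchBox[1, 2]:searchBox[2, 2],
               searchBox[1, 3]:searchBox[2, 3], drop = FALSE]
    idx <- hottestVoxel(PETVolume(sub, voxelSpacing(volume)))
    return(idx + searchBox[1, ] - 1L)
  }
  mx <- max(suv)
  hits <- which(suv == mx)
  co <- arrayInd(hits, d)
  co <- co[order(co[, 1], co[, 2], co[, 3]), , drop = FALSE]
  as.integer(co[1L, ])
}

#' Segment a tumor VOI as an SUV isocontour around the hottest voxel
#'
#' The volume of interest is the connected component, under the chosen
#' connectivity, of the supra-threshold set `{SUV >= thresholdSUV}` that
#' contains the seed voxel (by default the hottest voxel of the volume).
#' The comparison is closed: a voxel exactly at the threshold is included.
#' Because the seed is always contained in its own component, SUVmax over
#' the VOI is invariant to the threshold.
#'
#' @param volume a [PETVolume-class].
#' @param thresholdSUV SUV isocontour level, > 0. The conventional level is
#'   2.0; 2.5 is used for stability comparison.
#' @param connectivity 6, 18 or 26 (default) neighborhood for component
#'   growth.
#' @param seed optional integer(3) seed voxel; defaults to
#'   [hottestVoxel()].
#' @param override optional logical array: a user-supplied mask accepted
#'   verbatim (in place of manual contour correction); must be non-empty
#'   and congruent with the volume.
#' @return a [VOIMask-class].
#' @examples
#' a <- array(1, dim = c(5, 5, 5)); a[3, 3, 3] <- 5
#' segmentIsocontour(PETVolume(a), thresholdSUV = 2)
#' @export
segmentIsocontour <- function(volume, thresholdSUV = 2.0,
                              connectivity = c(26L, 18L, 6L),
                              seed = NULL, override = NULL) {
  stopifnot(is(volume, "PETVolume"))
  connectivity <- as.integer(connectivity)[1L]
  if (!thresholdSUV > 0) stop("thresholdSUV must be > 0")
  suv <- suvGrid(volume)
  d <- dim(suv)
  if (!is.null(override)) {
    stopifnot(is.logical(override), identical(dim(override), d))
    sv <- if (is.null(seed)) hottestVoxel(volume) else as.integer(seed)
    if (!override[matrix(sv, 1L)]) {
      co <- arrayInd(which(override), d)
      sub <- suv[override]
      sv <- as.integer(co[which.max(sub), ])
    }
    return(new("VOIMask", mask = override, thresholdSUV = thresholdSUV,
               connectivity = connectivity, seedVoxel = sv))
  }
  sv <- if (is.null(seed)) hottestVoxel(volume) else as.integer(seed)
  stopifnot(length(sv) == 3L, all(sv >= 1L), all(sv <= d))
  thr <- suv >= thresholdSUV
  if (!thr[matrix(sv, 1L)])
    stop(sprintf("no lesion at threshold: seed voxel SUV %.3g < %.3g",
                 suv[matrix(sv, 1L)], thresholdSUV))
  comp <- connectedComponent(thr, sv, connectivity)
  new("VOIMask", mask = comp, thresholdSUV = thresholdSUV,
      connectivity = connectivity, seedVoxel = sv)
}

# Connected component of `thr` containing `seed`, by iterative dilation
# restricted to the supra-threshold set (converges in O(component diameter)).
connectedComponent <- function(thr, seed, connectivity) {
  d <- dim(thr)
  offs <- connectivityOffsets(connectivity)
  comp <- array(FALSE, d)
  comp[matrix(as.integer(seed), 1L)] <- TRUE
  repeat {
    grown <- comp
    for (r in seq_len(nrow(offs))) {
      sr <- shiftRanges(d, offs[r, ])
      if (is.null(sr)) next
      grown[sr$dst[[1]], sr$dst[[2]], sr$dst[[3]]] <-
        grown[sr$dst[[1]], sr$dst[[2]], sr$dst[[3]]] |
        comp[sr$src[[1]], sr$src[[2]], sr$src[[3]]]
    }
    grown <- grown & thr
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}
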