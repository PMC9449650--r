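# PVS segmentation: threshold the vesselness response inside a region of
# interest, label 26-connected components, apply the 3-50 mm length rule.

.componentTable <- function(comps, spacing, insideWmh = FALSE) {
  if (!length(comps)) {
    return(data.frame(id = integer(0), volumeMl = numeric(0),
                      lengthMm = numeric(0), widthMm = numeric(0),
                      centroidX = numeric(0), centroidY = numeric(0),
                      centroidZ = numeric(0), insideWmh = logical(0),
                      voxels = I(list())))
  }
  meas <- lapply(comps, measureComponent, spacingMm = spacing)
  df <- data.frame(
    id = seq_along(comps),
    volumeMl = vapply(meas, `[[`, numeric(1), "volumeMl"),
    lengthMm = vapply(meas, `[[`, numeric(1), "lengthMm"),
    widthMm = vapply(meas, `[[`, numeric(1), "widthMm"),
    centroidX = vapply(meas, function(m) m$centroidMm[1], numeric(1)),
    centroidY = vapply(meas, function(m) m$centroidMm[2], numeric(1)),
    centroidZ = vapply(meas, function(m) m$centroidMm[3], numeric(1)),
    insideWmh = insideWmh)
  df$voxels <- I(comps)
  df
}

#' Apply the PVS length filter
#'
#' Drops components whose principal-axis length falls outside the
#' admissible PVS length range (default 3--50 mm).  Idempotent.
#'
#' @param components a PVS component table (see \code{\link{segmentPVS}}).
#' @param lengthRangeMm numeric(2), default \code{c(3, 50)}.
#' @return The filtered table, ids unchanged.
#' @export
filterByLength <- function(components, lengthRangeMm = c(3, 50)) {
  keep <- components$lengthMm >= lengthRangeMm[1] &
    components$lengthMm <= lengthRangeMm[2]
  components[keep, , drop = FALSE]
}

#' Segment PVS from a vesselness response
#'
#' Voxels with vesselness at or above the binarisation threshold inside the
#' region of interest are labelled by 26-connected component analysis;
#' components with principal-axis length outside 3--50 mm are discarded
#' (tubular PVS are identified as structures with lengths in that range).
#' Components are returned sorted by descending volume with stable ids.
#'
#' @param vesselness \code{\linkS4class{VoxelGrid}} in [0,1].
#' @param roi logical array or 0/1 \code{VoxelGrid}: region of interest.
#' @param params \code{\linkS4class{FrangiParams}}.
#' @return A data.frame with columns id, volumeMl, lengthMm, widthMm,
#'   centroidX/Y/Z, insideWmh and a list-column \code{voxels} of 1-based
#'   n x 3 index matrices.
#' @export
segmentPVS <- function(vesselness, roi, params = frangiParams()) {
  stopifnot(is(vesselness, "VoxelGrid"))
  roiArr <- if (is(roi, "VoxelGrid")) gridValues(roi) > 0 else roi > 0
  if (!identical(dim(roiArr), dim(vesselness)))
    stop("vesselness and roi must share a grid")
  if (!any(roiArr)) stop("empty region of interest")
  mask <- (gridValues(vesselness) >= params@vesselnessThreshold) & roiArr
  comps <- .labelComponents(mask, params@connectivity)
  tab <- .componentTable(comps, gridSpacing(vesselness))
  tab <- filterByLength(tab, params@lengthRangeMm)
  tab <- tab[order(-tab$volumeMl), , drop = FALSE]
  if (nrow(tab)) tab$id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Bias-field correction hook
#'
#' Pass-through placeholder in the analysis chain where acquired data would
#' be corrected for intensity inhomogeneity before T2/FLAIR fusion.  The
#' synthetic generator emits bias-free volumes, so the default is the
#' identity; supply your own function for real data.
#'
#' @param vol A \code{\linkS4class{VoxelGrid}}.
#' @param method only \code{"none"} is built in.
#' @return The (corrected) volume.
#' @export
biasFieldCorrect <- function(vol, method = "none") {
  match.arg(method, "none")
  vol
}

#' Fuse T2 and FLAIR into a PVS-in-WMH contrast image
#'
#' Each input is z-normalised over the brain mask (subtract mean, divide by
#' SD) and the fused image is normalised T2 minus normalised FLAIR.  PVS
#' are bright on T2 and iso/hypointense on FLAIR while WMH are bright on
#' FLAIR, so PVS running through WMH attain the highest fused values.
#'
#' @param t2,flair \code{\linkS4class{VoxelGrid}}s on the same grid.
#' @param brain logical array or 0/1 \code{VoxelGrid}; normalisation
#'   statistics are computed over this mask (default: whole volume).
#' @return The fused \code{VoxelGrid}.
#' @export
fuseT2Flair <- function(t2, flair, brain = NULL) {
  .checkSameGrid(t2, flair)
  bm <- if (is.null(brain)) array(TRUE, dim(t2))
        else if (is(brain, "VoxelGrid")) gridValues(brain) > 0 else brain > 0
  zn <- function(v) {
    x <- gridValues(v)
    mu <- mean(x[bm]); sd <- stats::sd(x[bm])
    if (!is.finite(sd) || sd == 0) stop("zero intensity SD; cannot normalise")
    (x - mu) / sd
  }
  voxelGrid(zn(t2) - zn(flair), gridSpacing(t2), gridOrigin(t2))
}

#' Segment baseline PVS combining the T2 and fused routes
#'
#' PVS are segmented from the T2 vesselness inside the region of interest;
#' PVS running through WMH (where T2 contrast drops) are segmented from the
#' fused T2-FLAIR image inside the dilated WMH mask.  The two binary masks
#' are united before connected-component analysis and the length rule, so a
#' tube crossing a WMH cluster stays one component.
#'
#' @param t2,flair isotropic \code{\linkS4class{VoxelGrid}}s (one grid).
#' @param brain,roi,wmhMask logical arrays or 0/1 \code{VoxelGrid}s.
#' @param params \code{\linkS4class{FrangiParams}}.
#' @param fusedFloor minimum fused (z-unit) intensity for fused-route
#'   voxels: PVS within WMH are strongly positive on T2 minus FLAIR, while
#'   WMH-rim gradients are not, so the floor suppresses rim artefacts.
#' @param hysteresis weak-threshold fraction: voxels with response at
#'   least \code{hysteresis * vesselnessThreshold} are kept when their
#'   connected component contains at least one supra-threshold voxel,
#'   bridging response dips along a tube without admitting free-standing
#'   weak responses (set to 1 to disable).
#' @return A PVS component table; components intersecting the WMH mask are
#'   flagged \code{insideWmh}.
#' @export
segmentBaselinePVS <- function(t2, flair, brain, roi, wmhMask,
                               params = frangiParams(), fusedFloor = 1.0,
                               hysteresis = 0.5) {
  roiArr <- .asLogicalArr(roi)
  vess <- frangiVesselness(t2, params, roi = roiArr)
  thr <- params@vesselnessThreshold
  vv <- gridValues(vess)
  strong <- (vv >= thr) & roiArr
  weak <- (vv >= hysteresis * thr) & roiArr
  wm <- .asLogicalArr(wmhMask)
  if (any(wm)) {
    fused <- fuseT2Flair(t2, flair, brain)
    # two-voxel dilation overlaps the T2 route across the WMH boundary;
    # intersecting with the analysis ROI keeps CSF rims (which are as
    # bright as PVS on the fused image) out
    roiW <- .dilate(wm, params@connectivity, 2L) & roiArr
    vessW <- gridValues(frangiVesselness(fused, params, roi = roiW))
    okF <- roiW & (gridValues(fused) >= fusedFloor)
    strong <- strong | ((vessW >= thr) & okF)
    weak <- weak | ((vessW >= hysteresis * thr) & okF)
  }
  comps <- .labelComponents(weak, params@connectivity)
  comps <- Filter(function(v) any(strong[rbind(v)]), comps)
  contactMask <- strong
  tab <- .componentTable(comps, gridSpacing(t2))
  tab <- filterByLength(tab, params@lengthRangeMm)
  tab <- tab[order(-tab$volumeMl), , drop = FALSE]
  if (nrow(tab)) {
    tab$id <- seq_len(nrow(tab))
    tab$insideWmh <- vapply(tab$voxels, function(v) any(wm[rbind(v)]),
                            logical(1))
  }
  rownames(tab) <- NULL
  # supra-threshold voxels only: the tight mask used for contact tests
  # (sub-threshold hysteresis voxels keep tubes whole but are too fuzzy a
  # boundary to decide contiguity against)
  attr(tab, "contactMask") <- contactMask
  tab
}

#' Segment PVS inside WMH from the fused image
#'
#' Identical pipeline to \code{\link{segmentPVS}} (Frangi response of the
#' fused image, thresholding, connected components, length rule) with the
#' region of interest set to the WMH mask dilated by one voxel; returned
#' components carry \code{insideWmh = TRUE}.
#'
#' @param fused fused T2-FLAIR \code{\linkS4class{VoxelGrid}} (already
#'   vesselness-filtered if \code{prefiltered = TRUE}, otherwise the filter
#'   is applied here).
#' @param wmhMask logical array or 0/1 \code{VoxelGrid}.
#' @param params \code{\linkS4class{FrangiParams}}.
#' @param prefiltered set TRUE if \code{fused} is already a vesselness map.
#' @return A PVS component table (possibly empty) with insideWmh = TRUE.
#' @export
segmentPVSInWMH <- function(fused, wmhMask, params = frangiParams(),
                            prefiltered = FALSE) {
  wm <- if (is(wmhMask, "VoxelGrid")) gridValues(wmhMask) > 0 else wmhMask > 0
  if (!any(wm)) return(.componentTable(list(), gridSpacing(fused), TRUE))
  roi <- .dilate(wm, connectivity = params@connectivity, iterations = 1L)
  vess <- if (prefiltered) fused else frangiVesselness(fused, params)
  tab <- segmentPVS(vess, roi, params)
  tab$insideWmh <- rep(TRUE, nrow(tab))
  tab
}
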