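# WMH segmentation: statistical FLAIR thresholding, prior-based refinement,
# cluster extraction, deep vs periventricular classification.

.asLogicalArr <- function(x) {
  if (is(x, "VoxelGrid")) gridValues(x) > 0 else x > 0
}

#' Threshold FLAIR hyperintensities
#'
#' Marks voxels whose FLAIR intensity is at least \code{mean + kSd * SD},
#' both statistics computed over the brain mask (default kSd = 1.69).  On
#' pure Gaussian noise the marked fraction converges to
#' \eqn{1 - \Phi(1.69) \approx 0.0455}, the analytic anchor of the recipe.
#'
#' @param flair \code{\linkS4class{VoxelGrid}}.
#' @param brain logical array or 0/1 \code{VoxelGrid}, non-empty.
#' @param params \code{\linkS4class{WMHSegParams}}.
#' @return Logical 3-D array: the raw hyperintensity mask.
#' @export
thresholdWMH <- function(flair, brain, params = wmhSegParams()) {
  stopifnot(is(flair, "VoxelGrid"))
  bm <- .asLogicalArr(brain)
  if (!identical(dim(bm), dim(flair))) stop("flair and brain grids differ")
  if (!any(bm)) stop("empty brain mask")
  x <- gridValues(flair)
  mu <- mean(x[bm]); sd <- stats::sd(x[bm])
  if (!is.finite(sd) || sd == 0) {
    warning("constant image: zero SD, returning empty mask")
    return(array(FALSE, dim(x)))
  }
  (x >= mu + params@kSd * sd) & bm
}

#' Refine a raw WMH mask
#'
#' The raw mask is intersected with a spatial-plausibility prior (lesion
#' distribution template stand-in, e.g. the white-matter region), the
#' resulting 0/1 field is Gaussian-smoothed at \code{smoothSigmaMm}, voxels
#' whose smoothed value falls below \code{intensityFloor} are removed
#' (this deletes isolated voxels: a single marked voxel smoothed at 1 mm
#' peaks at about 0.063), voxels whose brain-normalised FLAIR z-score is
#' below \code{zMin} are removed, and the result is re-binarised.
#'
#' @param raw logical array from \code{\link{thresholdWMH}}.
#' @param flair \code{\linkS4class{VoxelGrid}} used for the z-score rule.
#' @param brain,prior logical arrays or 0/1 \code{VoxelGrid}s.
#' @param params \code{\linkS4class{WMHSegParams}}.
#' @return Logical 3-D array: the refined mask (a subset of the smoothed
#'   support of raw & prior).
#' @export
refineWMH <- function(raw, flair, brain, prior, params = wmhSegParams()) {
  bm <- .asLogicalArr(brain); pm <- .asLogicalArr(prior)
  rawm <- .asLogicalArr(raw)
  if (!any(pm)) stop("empty prior mask")
  m <- rawm & pm
  if (!any(m)) return(m)
  sm <- .smoothArray(m + 0, params@smoothSigmaMm, gridSpacing(flair))
  keep <- m & (sm >= params@intensityFloor)
  x <- gridValues(flair)
  mu <- mean(x[bm]); sd <- stats::sd(x[bm])
  z <- (x - mu) / sd
  keep & (z >= params@zMin)
}

#' Extract WMH clusters from a binary mask
#'
#' Labels 26-connected components and discards those whose maximum
#' principal-axis extent is below the minimum cluster diameter (default
#' 3 mm).  Ids are stable: components are numbered by the position of
#' their first voxel in (x fastest, then y, then z) scan order.
#'
#' @param mask logical array or 0/1 \code{VoxelGrid}.
#' @param params \code{\linkS4class{WMHSegParams}}.
#' @param wave integer wave index the mask belongs to.
#' @param spacingMm numeric(3); required when \code{mask} is a plain array.
#' @param bridge optional logical array of connector voxels (typically PVS
#'   voxels inside/adjacent to the WMH mask): components are labelled on
#'   \code{mask | bridge} and then restricted to \code{mask}, so a cluster
#'   pierced by a PVS (which is dark on FLAIR and leaves a tubular hole)
#'   stays one cluster instead of splintering.
#' @return A data.frame with columns id, wave, volumeMl, diameterMm,
#'   depthClass, region, topologyLabel, changeLabel and a list-column
#'   \code{voxels}.
#' @export
extractClusters <- function(mask, params = wmhSegParams(), wave = 1L,
                            spacingMm = NULL, bridge = NULL) {
  if (is(mask, "VoxelGrid")) {
    spacingMm <- gridSpacing(mask)
    mask <- gridValues(mask) > 0
  }
  if (is.null(spacingMm)) stop("spacingMm required for plain-array masks")
  if (is.null(bridge)) {
    comps <- .labelComponents(mask, params@connectivity)
  } else {
    comps <- .labelComponents(mask | bridge, params@connectivity)
    comps <- lapply(comps, function(v) v[mask[rbind(v)], , drop = FALSE])
    comps <- Filter(nrow, comps)
  }
  if (length(comps)) {
    meas <- lapply(comps, measureComponent, spacingMm = spacingMm)
    diam <- vapply(meas, `[[`, numeric(1), "lengthMm")
    keep <- diam >= params@minClusterDiameterMm
    comps <- comps[keep]; meas <- meas[keep]; diam <- diam[keep]
  } else meas <- list()
  df <- data.frame(
    id = seq_along(comps),
    wave = if (length(comps)) as.integer(wave) else integer(0),
    volumeMl = vapply(meas, `[[`, numeric(1), "volumeMl"),
    diameterMm = if (length(comps)) diam else numeric(0),
    depthClass = rep(NA_character_, length(comps)),
    region = rep(NA_character_, length(comps)),
    topologyLabel = rep("unset", length(comps)),
    changeLabel = rep("unset", length(comps)))
  df$voxels <- I(comps)
  df
}

#' Periventricular WMH lining
#'
#' The set of WMH voxels 26-connected (as components) to the ventricular
#' surface: every WMH component containing a voxel in the 26-neighbourhood
#' of a ventricle voxel belongs to the lining.
#'
#' @param wmhMask,ventricles logical arrays or 0/1 \code{VoxelGrid}s.
#' @param connectivity 26 (default) or 6.
#' @return Logical array: the lining.
#' @export
pvLining <- function(wmhMask, ventricles, connectivity = 26) {
  wm <- .asLogicalArr(wmhMask); vm <- .asLogicalArr(ventricles)
  if (!any(vm)) stop("empty ventricle mask")
  touch <- .dilate(vm, connectivity, 1L)
  comps <- .labelComponents(wm, connectivity)
  out <- array(FALSE, dim(wm))
  for (cp in comps) {
    if (any(touch[cp])) out[cp] <- TRUE
  }
  out
}

#' Classify clusters as deep or periventricular
#'
#' A cluster is periventricular when it is contiguous with the
#' periventricular WMH lining and no voxel of it lies farther than the cap
#' extension (13 mm) from the ventricular surface; detached clusters, and
#' attached caps extending beyond 13 mm into the deep white matter, are
#' deep.
#'
#' @param clusters cluster table from \code{\link{extractClusters}}.
#' @param ventricles logical array or 0/1 \code{VoxelGrid}.
#' @param lining logical array from \code{\link{pvLining}} (computed from
#'   the same wave's WMH mask).
#' @param params \code{\linkS4class{WMHSegParams}}.
#' @param spacingMm numeric(3) voxel spacing.
#' @return The cluster table with \code{depthClass} filled in.
#' @export
classifyDepth <- function(clusters, ventricles, lining, params = wmhSegParams(),
                          spacingMm) {
  vm <- .asLogicalArr(ventricles)
  if (!any(vm)) stop("empty ventricle mask")
  surf <- .surfaceVoxels(vm)
  lin <- .asLogicalArr(lining)
  cls <- character(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    vox <- clusters$voxels[[i]]
    inLining <- any(lin[vox])
    if (!inLining) { cls[i] <- "deep"; next }
    dmax <- max(.minDistanceMm(vox, surf, spacingMm))
    cls[i] <- if (dmax <= params@capExtensionMm) "periventricular" else "deep"
  }
  clusters$depthClass <- cls
  clusters
}
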