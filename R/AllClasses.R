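#' @import methods
NULL

#' VoxelGrid: a 3-D scalar lattice with physical spacing
#'
#' The basic image container of the package: a 3-D numeric array together
#' with per-axis voxel spacing in millimetres and a world origin.  All
#' volumes, masks and derived maps travel as \code{VoxelGrid}s.  World
#' coordinates follow the voxel-centre convention
#' \code{world = origin + (index - 1) * spacing} (1-based indices).
#'
#' @slot values 3-D numeric (or logical) array of voxel values.
#' @slot spacing numeric(3), strictly positive voxel size in mm per axis.
#' @slot origin numeric(3), world position (mm) of voxel (1,1,1).
#'
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(values = array(0, dim = c(1, 1, 1)),
            spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("VoxelGrid", function(object) {
  msg <- character(0)
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid
#'
#' @param values 3-D array.
#' @param spacing numeric(3) voxel size in mm (default 1 mm isotropic).
#' @param origin numeric(3) world origin in mm.
#' @return A \code{\linkS4class{VoxelGrid}}.
#' @examples
#' g <- voxelGrid(array(0, c(8, 8, 4)), spacing = c(1, 1, 2))
#' dim(g)
#' @export
voxelGrid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.logical(values)) storage.mode(values) <- "double"
  new("VoxelGrid", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @describeIn voxelGrid Array of voxel values.
#' @param x,object A VoxelGrid.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname voxelGrid
#' @export
setMethod("gridValues", "VoxelGrid", function(x) x@values)

#' @describeIn voxelGrid Voxel spacing in mm.
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname voxelGrid
#' @export
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)

#' @describeIn voxelGrid World origin in mm.
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname voxelGrid
#' @export
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)

#' @rdname voxelGrid
#' @export
setMethod("dim", "VoxelGrid", function(x) dim(x@values))

#' @describeIn voxelGrid Volume of one voxel in mm^3.
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname voxelGrid
#' @export
setMethod("voxelVolume", "VoxelGrid", function(x) prod(x@spacing))

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelGrid %d x %d x %d, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              min(object@values), max(object@values)))
})

.checkSameGrid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)) ||
      max(abs(gridSpacing(a) - gridSpacing(b))) > 1e-6)
    stop("grid mismatch between co-analysed ", what,
         " (shape/spacing must agree; registration is out of scope)")
  invisible(TRUE)
}

#' Frangi vesselness parameters
#'
#' Parameters of the multiscale 3-D Frangi filter used for PVS enhancement
#' and of the downstream thresholding/length filter.  The filter is tuned
#' for thin bright tubes: with the default scales it enhances structures
#' with widths between roughly 0.5 and 2.5 voxels on the 1 mm isotropic
#' analysis grid.
#'
#' @slot scalesMm positive ascending smoothing scales sigma in mm.
#' @slot alpha plate-vs-line sensitivity (> 0).
#' @slot beta blob sensitivity (> 0).
#' @slot c structureness sensitivity; \code{NA} means "auto": half the
#'   maximum Hessian Frobenius norm over the volume at each scale.
#' @slot vesselnessThreshold binarisation cutoff on the [0,1] response.
#' @slot lengthRangeMm admissible PVS length (mm), default 3--50.
#' @slot connectivity 26 (default) or 6.
#' @exportClass FrangiParams
setClass("FrangiParams",
  representation(scalesMm = "numeric", alpha = "numeric", beta = "numeric",
                 c = "numeric", vesselnessThreshold = "numeric",
                 lengthRangeMm = "numeric", connectivity = "numeric"),
  prototype(scalesMm = c(1, 1.5, 2), alpha = 0.5, beta = 0.5,
            c = NA_real_, vesselnessThreshold = 0.2,
            lengthRangeMm = c(3, 50), connectivity = 26))

setValidity("FrangiParams", function(object) {
  msg <- character(0)
  s <- object@scalesMm
  if (!length(s) || any(s <= 0) || is.unsorted(s))
    msg <- c(msg, "scalesMm must be positive and ascending")
  if (object@alpha <= 0 || object@beta <= 0)
    msg <- c(msg, "alpha and beta must be > 0")
  if (!is.na(object@c) && object@c <= 0)
    msg <- c(msg, "c must be > 0 or NA for auto")
  th <- object@vesselnessThreshold
  if (th <= 0 || th >= 1)
    msg <- c(msg, "vesselnessThreshold must lie in (0,1)")
  if (length(object@lengthRangeMm) != 2 || diff(object@lengthRangeMm) < 0)
    msg <- c(msg, "lengthRangeMm must be (min, max) with min <= max")
  if (!object@connectivity %in% c(6, 26))
    msg <- c(msg, "connectivity must be 6 or 26")
  if (length(msg)) msg else TRUE
})

#' @rdname FrangiParams-class
#' @param ... named slot overrides, e.g. \code{frangiParams(alpha = 0.4)}.
#' @return A validated \code{FrangiParams} object.
#' @export
frangiParams <- function(...) new("FrangiParams", ...)

#' WMH segmentation parameters
#'
#' Parameters of the statistical FLAIR thresholding recipe: voxels are
#' marked above \code{mean + kSd * SD} of the brain intensities, the mask
#' is refined by a spatial prior, Gaussian smoothing with removal of weak
#' (\code{< intensityFloor}) and low z-score (\code{< zMin}) voxels, and the
#' surviving 26-connected clusters below \code{minClusterDiameterMm} are
#' dropped.  Clusters contiguous with the periventricular WMH lining are
#' periventricular unless they extend more than \code{capExtensionMm} from
#' the ventricular surface.
#'
#' @slot kSd threshold multiplier, default 1.69.
#' @slot smoothSigmaMm Gaussian smoothing scale in mm, default 1.
#' @slot intensityFloor cutoff on the smoothed 0-1 mask field, default 0.1.
#' @slot zMin FLAIR z-score cutoff, default 0.95.
#' @slot minClusterDiameterMm minimum cluster extent, default 3 mm.
#' @slot capExtensionMm periventricular cap rule, default 13 mm.
#' @slot connectivity 26 (default) or 6.
#' @exportClass WMHSegParams
setClass("WMHSegParams",
  representation(kSd = "numeric", smoothSigmaMm = "numeric",
                 intensityFloor = "numeric", zMin = "numeric",
                 minClusterDiameterMm = "numeric", capExtensionMm = "numeric",
                 connectivity = "numeric"),
  prototype(kSd = 1.69, smoothSigmaMm = 1.0, intensityFloor = 0.1,
            zMin = 0.95, minClusterDiameterMm = 3, capExtensionMm = 13,
            connectivity = 26))

setValidity("WMHSegParams", function(object) {
  msg <- character(0)
  if (object@kSd <= 0) msg <- c(msg, "kSd must be > 0")
  if (object@zMin < 0) msg <- c(msg, "zMin must be >= 0")
  if (object@minClusterDiameterMm <= 0 || object@capExtensionMm <= 0)
    msg <- c(msg, "minClusterDiameterMm and capExtensionMm must be positive")
  if (!object@connectivity %in% c(6, 26))
    msg <- c(msg, "connectivity must be 6 or 26")
  if (length(msg)) msg else TRUE
})

#' @rdname WMHSegParams-class
#' @param ... named slot overrides.
#' @return A validated \code{WMHSegParams} object.
#' @export
wmhSegParams <- function(...) new("WMHSegParams", ...)

#' Longitudinal change-classification parameters
#'
#' @slot sizeChangeFactor minimum multiplicative volume change for a
#'   cluster to count as changed (the doubled-or-more rule), default 2.
#' @slot contactConnectivity 26 (default) or 6: what "contiguous" means.
#' @slot matchOverlapMin minimum voxel-overlap fraction for wave-to-wave
#'   cluster identity; default 0 = any overlap.
#' @exportClass ChangeParams
setClass("ChangeParams",
  representation(sizeChangeFactor = "numeric",
                 contactConnectivity = "numeric",
                 matchOverlapMin = "numeric"),
  prototype(sizeChangeFactor = 2.0, contactConnectivity = 26,
            matchOverlapMin = 0))

setValidity("ChangeParams", function(object) {
  msg <- character(0)
  if (object@sizeChangeFactor < 1)
    msg <- c(msg, "sizeChangeFactor must be >= 1")
  if (!object@contactConnectivity %in% c(6, 26))
    msg <- c(msg, "contactConnectivity must be 6 or 26")
  if (object@matchOverlapMin < 0 || object@matchOverlapMin >= 1)
    msg <- c(msg, "matchOverlapMin must lie in [0,1)")
  if (length(msg)) msg else TRUE
})

#' @rdname ChangeParams-class
#' @param ... named slot overrides.
#' @return A validated \code{ChangeParams} object.
#' @export
changeParams <- function(...) new("ChangeParams", ...)
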