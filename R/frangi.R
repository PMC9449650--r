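# Multiscale 3-D Frangi vesselness.  The Hessian is computed per scale by
# separable Gaussian-derivative convolution with gamma = 2 normalisation
# (second derivatives multiplied by sigma^2), eigenvalues come from the
# closed-form solution for symmetric 3x3 matrices (fully vectorised), and
# the response is the maximum over scales.

# Eigenvalues of many symmetric 3x3 matrices, given the six unique entries
# as vectors.  Returns a 3-column matrix sorted by |lambda| ascending per
# row.  Trigonometric closed form (stable for symmetric matrices).
.eigSym3 <- function(a11, a12, a13, a22, a23, a33) {
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  degen <- p < .Machine$double.eps * (abs(q) + 1)
  ps <- ifelse(degen, 1, p)              # placeholder to avoid 0/0
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(1, pmax(-1, detB / 2))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  E <- cbind(e1, e2, e3)
  E[degen, ] <- q[degen]
  # sort each row by |lambda| ascending without per-row loops
  A <- abs(E)
  i3 <- max.col(A, ties.method = "first")
  n <- nrow(E)
  l3 <- E[cbind(seq_len(n), i3)]
  A[cbind(seq_len(n), i3)] <- -Inf
  i2 <- max.col(A, ties.method = "first")
  l2 <- E[cbind(seq_len(n), i2)]
  A[cbind(seq_len(n), i2)] <- -Inf
  i1 <- max.col(A, ties.method = "first")
  l1 <- E[cbind(seq_len(n), i1)]
  cbind(l1, l2, l3)
}

# Hessian components of arr smoothed at sigma (mm), as a named list of six
# arrays; derivatives are in mm^-2 and multiplied by sigma^2 (scale
# normalisation).
.hessianAtScale <- function(arr, sigma, spacing) {
  d <- dim(arr)
  K <- lapply(1:3, function(ax) list(
    g0 = .convMatrix(d[ax], .gaussKernel(sigma, spacing[ax], 0L)),
    g1 = .convMatrix(d[ax], .gaussKernel(sigma, spacing[ax], 1L)),
    g2 = .convMatrix(d[ax], .gaussKernel(sigma, spacing[ax], 2L))))
  der <- function(ox, oy, oz) {
    pick <- function(ax, o) K[[ax]][[c("g0", "g1", "g2")[o + 1L]]]
    out <- .applyAxisOperator(arr, pick(1, ox), 1)
    out <- .applyAxisOperator(out, pick(2, oy), 2)
    .applyAxisOperator(out, pick(3, oz), 3)
  }
  s2 <- sigma^2
  list(xx = s2 * der(2, 0, 0), yy = s2 * der(0, 2, 0), zz = s2 * der(0, 0, 2),
       xy = s2 * der(1, 1, 0), xz = s2 * der(1, 0, 1), yz = s2 * der(0, 1, 1))
}

.frangiAtScale <- function(arr, sigma, spacing, alpha, beta, cval,
                           cmask = NULL) {
  H <- .hessianAtScale(arr, sigma, spacing)
  E <- .eigSym3(as.vector(H$xx), as.vector(H$xy), as.vector(H$xz),
                as.vector(H$yy), as.vector(H$yz), as.vector(H$zz))
  l1 <- E[, 1]; l2 <- E[, 2]; l3 <- E[, 3]
  S <- sqrt(l1^2 + l2^2 + l3^2)
  if (is.na(cval)) {
    # auto mode without a precomputed constant (single-scale call)
    cval <- if (is.null(cmask)) max(S) / 2 else max(S[as.vector(cmask)]) / 2
  }
  if (cval <= 0) return(array(0, dim(arr)))
  a3 <- abs(l3); a2 <- abs(l2)
  Ra2 <- ifelse(a3 > 0, (a2 / a3)^2, 0)
  Rb2 <- ifelse(a2 * a3 > 0, l1^2 / (a2 * a3), 0)
  v <- (1 - exp(-Ra2 / (2 * alpha^2))) * exp(-Rb2 / (2 * beta^2)) *
    (1 - exp(-S^2 / (2 * cval^2)))
  v[l2 > 0 | l3 > 0] <- 0                # bright tubes: lambda2, lambda3 < 0
  # a Hessian at floating-point roundoff level is no structure at all
  v[S < 1e-10 * (1 + max(abs(arr)))] <- 0
  array(v, dim(arr))
}

#' Multiscale 3-D Frangi vesselness filter
#'
#' Enhances bright tubular structures (MRI-visible perivascular spaces on
#' T2-weighted images).  Per voxel and scale sigma, the Hessian of the
#' sigma-smoothed image (with sigma^2-normalised second derivatives) is
#' eigen-decomposed as |lambda1| <= |lambda2| <= |lambda3|; the bright-tube
#' response is 0 where lambda2 > 0 or lambda3 > 0 and otherwise
#' \deqn{(1 - e^{-R_A^2/2\alpha^2})\, e^{-R_B^2/2\beta^2}\,
#'       (1 - e^{-S^2/2c^2})}
#' with \eqn{R_A = |\lambda_2|/|\lambda_3|} (plate vs line),
#' \eqn{R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}} (blobness) and
#' \eqn{S} the Frobenius norm of the Hessian (structureness).  The output
#' is the maximum response over \code{scalesMm}, bounded in [0, 1].
#'
#' @param vol An isotropic \code{\linkS4class{VoxelGrid}}.
#' @param params A \code{\linkS4class{FrangiParams}} object.
#' @param roi optional logical array or 0/1 \code{VoxelGrid}: when
#'   \code{c = "auto"}, the maximum Hessian norm is taken over this region
#'   so that structureness is calibrated to the tissue of interest rather
#'   than to the much stronger brain/ventricle boundary edges.
#' @param perScale return the per-scale responses (a named list of
#'   \code{VoxelGrid}s, sharing one structureness constant) instead of
#'   their maximum; useful for inspecting scale selectivity.
#' @return A \code{VoxelGrid} with the vesselness response in [0, 1], or a
#'   list of them when \code{perScale = TRUE}.
#' @export
frangiVesselness <- function(vol, params = frangiParams(), roi = NULL,
                             perScale = FALSE) {
  stopifnot(is(vol, "VoxelGrid"), is(params, "FrangiParams"))
  sp <- gridSpacing(vol)
  if (max(sp) / min(sp) > 1.01)
    stop("frangiVesselness expects an isotropic grid; resample first")
  if (!length(params@scalesMm)) stop("empty scale list")
  cmask <- if (is.null(roi)) NULL else .asLogicalArr(roi)
  arr <- gridValues(vol)
  cval <- params@c
  if (is.na(cval)) {
    # one structureness constant for every scale (half the maximum
    # Hessian norm at the smallest scale): a per-scale constant would let
    # each scale saturate against its own maximum and destroy the
    # scale-selectivity of the normalised response
    H <- .hessianAtScale(arr, params@scalesMm[1], sp)
    S <- sqrt(H$xx^2 + H$yy^2 + H$zz^2 + 2 * (H$xy^2 + H$xz^2 + H$yz^2))
    cval <- if (is.null(cmask)) max(S) / 2 else max(S[cmask]) / 2
    if (cval <= 0) cval <- NA_real_      # flat image: every response is 0
  }
  out <- lapply(params@scalesMm, function(s) {
    if (is.na(cval)) return(array(0, dim(arr)))
    .frangiAtScale(arr, s, sp, params@alpha, params@beta, cval, cmask)
  })
  if (perScale) {
    names(out) <- as.character(params@scalesMm)
    return(lapply(out, voxelGrid, spacing = sp, origin = gridOrigin(vol)))
  }
  voxelGrid(Reduce(pmax, out), sp, gridOrigin(vol))
}

#' Geometric measurements of a voxel component
#'
#' Principal-axis measurements of a connected voxel set: volume in ml,
#' length as the extent of the voxel centres projected on the first
#' principal axis plus a one-voxel correction along that axis, width as the
#' mean corrected extent on the two minor axes, and the centroid in mm.
#'
#' @param voxelIndices n x 3 matrix of 1-based voxel indices.
#' @param spacingMm numeric(3) voxel spacing in mm.
#' @return A list with \code{volumeMl}, \code{lengthMm}, \code{widthMm},
#'   \code{centroidMm}.
#' @examples
#' line <- cbind(1:11, 1, 1)
#' measureComponent(line, c(1, 1, 1))$lengthMm   # ~11 mm
#' @export
measureComponent <- function(voxelIndices, spacingMm) {
  voxelIndices <- rbind(voxelIndices)
  if (!nrow(voxelIndices)) stop("empty voxel set")
  n <- nrow(voxelIndices)
  volumeMl <- n * prod(spacingMm) / 1000
  mmc <- sweep(voxelIndices - 1, 2, spacingMm, `*`)
  centroid <- colMeans(mmc)
  if (n == 1L) {
    ext <- max(spacingMm)
    return(list(volumeMl = volumeMl, lengthMm = ext, widthMm = ext,
                centroidMm = centroid))
  }
  cc <- sweep(mmc, 2, centroid)
  ev <- eigen(crossprod(cc) / n, symmetric = TRUE)
  axes <- ev$vectors                      # columns, major first
  proj <- cc %*% axes
  correction <- abs(t(axes)) %*% spacingMm   # one-voxel footprint per axis
  extents <- apply(proj, 2, function(p) diff(range(p))) + as.vector(correction)
  list(volumeMl = volumeMl, lengthMm = extents[1],
       widthMm = mean(extents[2:3]), centroidMm = centroid)
}
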