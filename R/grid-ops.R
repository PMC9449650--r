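# Low-level lattice operations: separable convolution, Gaussian smoothing,
# cubic-spline resampling, morphology, connected components, distances.
# All operate on plain 3-D arrays; VoxelGrid wrappers live alongside.

# Apply an n_out x n_in linear operator along one axis of a 3-D array.
# Implemented as a dense matrix product on the unfolded array; axis sizes in
# this package are small (<= a few hundred) so this is fast and exact.
.applyAxisOperator <- function(arr, W, axis) {
  d <- dim(arr)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  r <- W %*% m
  out <- array(r, dim = c(nrow(W), da[2], da[3]))
  aperm(out, order(perm))
}

# Convolution matrix for a symmetric-support kernel with replicated
# (clamped) boundary: row sums equal the kernel sum everywhere, so
# zero-sum derivative kernels annihilate constants exactly at the edges.
.convMatrix <- function(n, kernel) {
  half <- (length(kernel) - 1L) / 2L
  W <- matrix(0, n, n)
  for (o in -half:half) {
    w <- kernel[o + half + 1L]
    if (w == 0) next
    j <- pmin(pmax(seq_len(n) + o, 1L), n)
    W[cbind(seq_len(n), j)] <- W[cbind(seq_len(n), j)] + w
  }
  W
}

# Sampled Gaussian kernel and its first/second derivatives on a unit-step
# lattice scaled to physical spacing h (mm).  order 0 kernels are
# normalised to unit sum; derivative kernels carry units mm^-order.
.gaussKernel <- function(sigma_mm, h_mm, order = 0L) {
  s <- sigma_mm / h_mm                    # sigma in voxel units
  half <- max(1L, ceiling(4 * s))
  x <- (-half):half                       # voxel offsets
  g <- exp(-x^2 / (2 * s^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -x / s^2 * g / h_mm        # odd: sums to zero exactly
  } else {
    k <- (x^2 - s^2) / s^4 * g / h_mm^2
    k <- k - sum(k) / length(k)     # annihilate constants exactly
  }
  k
}

.smoothArray <- function(arr, sigma_mm, spacing) {
  out <- arr
  for (ax in 1:3) {
    k <- .gaussKernel(sigma_mm, spacing[ax], 0L)
    out <- .applyAxisOperator(out, .convMatrix(dim(out)[ax], k), ax)
  }
  out
}

#' Gaussian smoothing of a volume
#'
#' Separable discrete Gaussian smoothing with reflected boundaries.  The
#' physical scale \code{sigmaMm} is converted to voxel units per axis, so
#' anisotropic grids are smoothed isotropically in world space.
#'
#' @param vol A \code{\linkS4class{VoxelGrid}}.
#' @param sigmaMm smoothing scale in mm.
#' @return A \code{VoxelGrid} of the same geometry.
#' @export
gaussianSmooth <- function(vol, sigmaMm) {
  stopifnot(is(vol, "VoxelGrid"), sigmaMm > 0)
  voxelGrid(.smoothArray(gridValues(vol), sigmaMm, gridSpacing(vol)),
            gridSpacing(vol), gridOrigin(vol))
}

# Natural-cubic-spline interpolation matrix mapping samples at x_in to
# values at x_out.  Spline interpolation is linear in the data, so the
# operator is assembled column-by-column from unit impulses.
.splineMatrix <- function(x_in, x_out) {
  n <- length(x_in)
  if (n == 1L) return(matrix(1, length(x_out), 1))
  W <- matrix(0, length(x_out), n)
  e <- numeric(n)
  for (j in seq_len(n)) {
    e[j] <- 1
    W[, j] <- stats::splinefun(x_in, e, method = "natural")(x_out)
    e[j] <- 0
  }
  W
}

#' Resample a volume to (by default isotropic) voxel spacing
#'
#' Separable cubic-spline interpolation, the standard preparation step for
#' PVS filtering: anisotropic acquisitions (e.g. 1 x 1 x 2 mm) are
#' resampled to a 1 mm isotropic analysis grid.  The new shape per axis is
#' \code{round(n * spacing / target)} (half-up).  Natural splines are used,
#' which reproduce linear trends exactly and do not overshoot at the edges.
#'
#' @param vol A \code{\linkS4class{VoxelGrid}}.
#' @param targetSpacingMm numeric(1) or numeric(3), default 1 mm isotropic.
#' @param method \code{"spline"} (volumes) or \code{"nearest"} (masks and
#'   label maps, which must stay categorical).
#' @return A resampled \code{VoxelGrid}.
#' @export
resampleIsotropic <- function(vol, targetSpacingMm = 1, method = c("spline", "nearest")) {
  method <- match.arg(method)
  stopifnot(is(vol, "VoxelGrid"))
  target <- rep(as.numeric(targetSpacingMm), length.out = 3)
  if (any(target <= 0)) stop("target spacing must be positive")
  arr <- gridValues(vol)
  sp <- gridSpacing(vol)
  d <- dim(arr)
  newd <- as.integer(floor(d * sp / target + 0.5))
  if (any(newd < 2)) stop("resampling would leave an axis with < 2 voxels")
  for (ax in 1:3) {
    if (newd[ax] == d[ax] && abs(sp[ax] - target[ax]) < 1e-12) next
    x_in <- (seq_len(dim(arr)[ax]) - 1) * sp[ax]
    x_out <- (seq_len(newd[ax]) - 1) * target[ax]
    if (method == "spline") {
      W <- .splineMatrix(x_in, x_out)
    } else {
      idx <- vapply(x_out, function(x) which.min(abs(x_in - x)), integer(1))
      W <- matrix(0, newd[ax], dim(arr)[ax])
      W[cbind(seq_len(newd[ax]), idx)] <- 1
    }
    arr <- .applyAxisOperator(arr, W, ax)
  }
  voxelGrid(arr, target, gridOrigin(vol))
}

# ---- morphology on logical arrays ----------------------------------------

.neighbourOffsets <- function(connectivity = 26) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6)
    g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  as.matrix(g)
}

# Shift a logical array by (dx,dy,dz), zero-filling; used for dilation and
# adjacency tests.
.shiftLogical <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  sx <- max(1, 1 + off[1]):min(d[1], d[1] + off[1])
  sy <- max(1, 1 + off[2]):min(d[2], d[2] + off[2])
  sz <- max(1, 1 + off[3]):min(d[3], d[3] + off[3])
  out[sx, sy, sz] <- mask[sx - off[1], sy - off[2], sz - off[3]]
  out
}

.dilate <- function(mask, connectivity = 26, iterations = 1L) {
  offs <- .neighbourOffsets(connectivity)
  out <- mask
  for (i in seq_len(iterations)) {
    acc <- out
    for (r in seq_len(nrow(offs)))
      acc <- acc | .shiftLogical(out, offs[r, ])
    out <- acc
  }
  out
}

.erode <- function(mask, connectivity = 26, iterations = 1L) {
  !.dilate(!mask, connectivity, iterations)
}

# box dilation with a per-axis reach in voxels (separable); used where a
# physical (mm) Chebyshev margin must be honoured on anisotropic grids
.dilateBox <- function(mask, reach) {
  out <- mask
  for (ax in 1:3) {
    if (reach[ax] < 1) next
    off <- c(0, 0, 0)
    acc <- out
    for (k in seq_len(reach[ax])) {
      off[ax] <- k
      acc <- acc | .shiftLogical(out, off) | .shiftLogical(out, -off)
    }
    out <- acc
  }
  out
}

# number of TRUE neighbours (given connectivity) of every voxel
.neighbourCount <- function(mask, connectivity = 26) {
  offs <- .neighbourOffsets(connectivity)
  cnt <- array(0L, dim(mask))
  for (r in seq_len(nrow(offs)))
    cnt <- cnt + .shiftLogical(mask, offs[r, ])
  cnt
}

# ---- connected components ------------------------------------------------

# Label TRUE voxels of a logical 3-D array into connected components.
# Returns a list of index matrices (n_i x 3, 1-based), in input order of the
# first (smallest linear index, i.e. x fastest) voxel of each component.
.labelComponents <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lin <- which(mask)
  if (!length(lin)) return(list())
  coord <- arrayInd(lin, d)
  key <- lin                                   # linear index doubles as key
  pos <- integer(0)
  offs <- .neighbourOffsets(connectivity)
  # only half the offsets needed for an undirected edge list
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
           (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    nb <- coord + matrix(off, nrow(coord), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nkey <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
    j <- match(nkey, key)
    keep <- ok & !is.na(j)
    if (any(keep))
      edges[[r]] <- cbind(which(keep), j[keep])
  }
  edges <- do.call(rbind, edges)
  n <- length(lin)
  if (is.null(edges)) {
    memb <- seq_len(n)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  }
  comp <- split(seq_len(n), memb)
  # order components by smallest linear index (x fastest, then y, then z)
  ordc <- order(vapply(comp, function(ix) min(lin[ix]), numeric(1)))
  lapply(comp[ordc], function(ix) coord[ix, , drop = FALSE])
}

# Minimum Euclidean distance (mm) from each query voxel centre to any
# target voxel centre; brute force in chunks (target sets here are small
# ventricular-surface shells).
.minDistanceMm <- function(query, target, spacing) {
  if (!nrow(target)) return(rep(Inf, nrow(query)))
  qs <- sweep(query, 2, spacing, `*`)
  ts <- sweep(target, 2, spacing, `*`)
  out <- numeric(nrow(qs))
  step <- max(1L, floor(2e6 / nrow(ts)))
  for (s in seq(1L, nrow(qs), by = step)) {
    e <- min(nrow(qs), s + step - 1L)
    block <- qs[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(ts^2), `+`) -
      2 * block %*% t(ts)
    out[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

# Boundary voxels of a mask: mask voxels with a 6-neighbour outside it.
.surfaceVoxels <- function(mask) {
  inner <- .erode(mask, connectivity = 6)
  which(mask & !inner, arr.ind = TRUE)
}
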