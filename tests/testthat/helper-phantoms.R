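# Phantom builders shared across tests: analytic cylinders, spheres and
# small random masks, built in code at test time.

# isotropic grid filled with a bright cylinder along `axis` through the
# centre; returns a VoxelGrid
cylinderPhantom <- function(n = 40, radius = 1, axis = 3, background = 0,
                            peak = 100, spacing = c(1, 1, 1)) {
  arr <- array(background, c(n, n, n))
  cen <- (n + 1) / 2
  co <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  d2 <- switch(axis,
    (co$y - cen)^2 + (co$z - cen)^2,
    (co$x - cen)^2 + (co$z - cen)^2,
    (co$x - cen)^2 + (co$y - cen)^2)
  arr[d2 <= radius^2] <- peak
  voxelGrid(arr, spacing)
}

spherePhantom <- function(n = 40, radius = 1, background = 0, peak = 100) {
  arr <- array(background, c(n, n, n))
  cen <- (n + 1) / 2
  co <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  d2 <- (co$x - cen)^2 + (co$y - cen)^2 + (co$z - cen)^2
  arr[d2 <= radius^2] <- peak
  voxelGrid(arr, spacing = c(1, 1, 1))
}

# random sparse logical mask on a small grid
randomMask <- function(dims, p = 0.1) {
  array(stats::runif(prod(dims)) < p, dims)
}

# brute-force contact count: cluster voxels with Chebyshev distance <= 1
# (26-connectivity) or <= 1 in exactly one axis (6-connectivity) to any
# PVS voxel -- the independent oracle for contactVoxels
bruteContact <- function(clusterVox, pvsVox, connectivity = 26) {
  if (!nrow(pvsVox)) return(0L)
  cnt <- 0L
  for (i in seq_len(nrow(clusterVox))) {
    d <- abs(sweep(pvsVox, 2, clusterVox[i, ]))
    hit <- if (connectivity == 26) any(apply(d, 1, max) <= 1)
           else any(rowSums(d) <= 1)
    if (hit) cnt <- cnt + 1L
  }
  cnt
}

voxelsOfMask <- function(mask) which(mask, arr.ind = TRUE)

# a minimal cluster table row as produced by extractClusters
clusterRow <- function(voxels, id = 1L, wave = 1L, spacing = c(1, 1, 1)) {
  m <- measureComponent(voxels, spacing)
  df <- data.frame(id = id, wave = wave, volumeMl = m$volumeMl,
                   diameterMm = m$lengthMm, depthClass = "deep",
                   region = NA_character_, topologyLabel = "unset",
                   changeLabel = "unset")
  df$voxels <- I(list(voxels))
  df
}
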