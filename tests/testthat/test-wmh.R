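test_that("thresholding marks mean + 1.69 SD hyperintensities only", {
  # constant image: zero SD, empty mask with a warning
  flat <- voxelGrid(array(5, c(12, 12, 12)))
  brain <- array(TRUE, c(12, 12, 12))
  expect_warning(m <- thresholdWMH(flat, brain), "constant")
  expect_false(any(m))
  # phantom: lesion contrast far above mean + 2 SD is fully marked
  set.seed(2)
  arr <- array(rnorm(40^3, 100, 5), c(40, 40, 40))
  lesion <- array(FALSE, c(40, 40, 40)); lesion[15:20, 15:20, 15:20] <- TRUE
  arr[lesion] <- 200
  m2 <- thresholdWMH(voxelGrid(arr), array(TRUE, c(40, 40, 40)))
  expect_true(all(m2[lesion]))
})

test_that("the marked fraction of pure Gaussian noise matches 1 - Phi(1.69)", {
  set.seed(99)
  n3 <- c(100, 100, 100)
  g <- voxelGrid(array(rnorm(prod(n3)), n3))
  m <- thresholdWMH(g, array(TRUE, n3))
  pExp <- 1 - pnorm(1.69)                # 0.04551
  se <- sqrt(pExp * (1 - pExp) / prod(n3))
  expect_lt(abs(mean(m) - pExp), 3 * se)
})

test_that("refinement removes isolated voxels but keeps solid blocks", {
  dims <- c(24, 24, 24)
  brain <- array(TRUE, dims)
  prior <- array(TRUE, dims)
  # flair built so z-scores inside the block are high
  flair <- array(rnorm(prod(dims), 100, 5), dims)
  block <- array(FALSE, dims); block[8:17, 8:17, 8:17] <- TRUE
  flair[block] <- 200
  fg <- voxelGrid(flair)
  expect_false(any(refineWMH(array(FALSE, dims), fg, brain, prior)))
  # a single isolated marked voxel: peak smoothed value ~0.063 < 0.1
  single <- array(FALSE, dims); single[4, 4, 20] <- TRUE
  flair[4, 4, 20] <- 200
  expect_false(any(refineWMH(single, voxelGrid(flair), brain, prior)))
  # the 10^3 block survives (interior smoothed ~1, z >> 0.95)
  ref <- refineWMH(block, fg, brain, prior)
  expect_true(any(ref))
  expect_true(all(ref[10:15, 10:15, 10:15]))
  # monotonicity: never adds voxels beyond raw & prior
  expect_true(all(which(ref) %in% which(block & prior)))
  expect_error(refineWMH(block, fg, brain, array(FALSE, dims)), "empty prior")
})

test_that("cluster extraction enforces the 3 mm diameter rule", {
  dims <- c(20, 20, 20)
  expect_equal(nrow(extractClusters(array(FALSE, dims),
                                    spacingMm = c(1, 1, 1))), 0L)
  # two single voxels separated by a gap: both discarded at 1 mm spacing
  m <- array(FALSE, dims); m[5, 5, 5] <- TRUE; m[5, 5, 9] <- TRUE
  expect_equal(nrow(extractClusters(m, spacingMm = c(1, 1, 1))), 0L)
  # five well-separated 2.5 mm radius spheres: exactly five clusters
  m2 <- array(FALSE, dims)
  co <- expand.grid(x = 1:20, y = 1:20, z = 1:20)
  centres <- rbind(c(4, 4, 4), c(15, 4, 4), c(4, 15, 4), c(15, 15, 4),
                   c(10, 10, 15))
  for (i in 1:5) {
    d2 <- (co$x - centres[i, 1])^2 + (co$y - centres[i, 2])^2 +
      (co$z - centres[i, 3])^2
    m2[d2 <= 2.5^2] <- TRUE
  }
  cl <- extractClusters(m2, spacingMm = c(1, 1, 1))
  expect_equal(nrow(cl), 5L)
  # every surviving voxel belongs to exactly one cluster
  expect_equal(sum(vapply(cl$voxels, nrow, integer(1))), sum(m2))
})

test_that("depth classification follows the lining and the 13 mm cap rule", {
  dims <- c(30, 30, 40)
  vent <- array(FALSE, dims); vent[13:18, 13:18, 1:6] <- TRUE
  # cap attached to the ventricle reaching 20 mm out: deep
  cap <- array(FALSE, dims); cap[14:17, 14:17, 7:26] <- TRUE
  # rim hugging the ventricle within 5 mm: periventricular
  rim <- array(FALSE, dims); rim[14:17, 14:17, 7:10] <- TRUE
  # detached cluster far away: deep regardless of distance
  far <- array(FALSE, dims); far[25:28, 25:28, 30:34] <- TRUE
  wmh <- cap | far
  lin <- pvLining(wmh, vent)
  expect_true(all(lin[cap]))
  expect_false(any(lin[far]))
  cl <- extractClusters(wmh, spacingMm = c(1, 1, 1))
  cl <- classifyDepth(cl, vent, lin, spacingMm = c(1, 1, 1))
  vol <- vapply(cl$voxels, nrow, integer(1))
  expect_equal(cl$depthClass[which.max(vol)], "deep")      # the 20 mm cap
  expect_equal(cl$depthClass[which.min(vol)], "deep")      # detached
  wmh2 <- rim | far
  lin2 <- pvLining(wmh2, vent)
  cl2 <- extractClusters(wmh2, spacingMm = c(1, 1, 1))
  cl2 <- classifyDepth(cl2, vent, lin2, spacingMm = c(1, 1, 1))
  # the attached rim (voxels starting at z = 7) is periventricular,
  # the detached cluster deep
  isRim <- vapply(cl2$voxels, function(v) min(v[, 3]) < 15, logical(1))
  expect_equal(cl2$depthClass[isRim], "periventricular")
  expect_equal(cl2$depthClass[!isRim], "deep")
  expect_error(classifyDepth(cl2, array(FALSE, dims), lin2,
                             spacingMm = c(1, 1, 1)), "empty ventricle")
})

test_that("WMH recovery against truth reaches the published Dice scale", {
  dices <- c()
  for (s in 1:5) {
    res <- analyzeSubject(sceneParams(seed = s), growthParams(seed = s),
                          waves = 2L)
    dices <- c(dices, res$dice)
  }
  expect_true(all(dices >= 0.6))
})
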