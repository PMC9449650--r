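test_that("contact counting matches the brute-force Chebyshev oracle", {
  set.seed(31)
  for (trial in 1:60) {
    dims <- c(sample(5:10, 1), sample(5:10, 1), sample(5:10, 1))
    cl <- randomMask(dims, 0.15)
    pv <- randomMask(dims, 0.10)
    cv <- voxelsOfMask(cl)
    if (!nrow(cv)) next
    for (conn in c(26, 6)) {
      got <- contactVoxels(cv, pv, conn)
      want <- bruteContact(cv, voxelsOfMask(pv), conn)
      expect_equal(got, want)
    }
  }
  # trivial anchors
  dims <- c(6, 6, 6)
  cl <- randomMask(dims, 0.2); cv <- voxelsOfMask(cl)
  expect_equal(contactVoxels(cv, array(FALSE, dims)), 0L)
  expect_equal(contactVoxels(cv, cl), nrow(cv))
})

test_that("close/not-close follows 26-contiguity including corners", {
  dims <- c(10, 10, 10)
  pv <- array(FALSE, dims); pv[5, 5, 5] <- TRUE
  corner <- clusterRow(cbind(6, 6, 6))
  touching <- classifyCrossSectional(corner, pv)
  expect_equal(touching$topologyLabel, "close")
  away <- classifyCrossSectional(clusterRow(cbind(8, 8, 8)), pv)
  expect_equal(away$topologyLabel, "not_close")
  pvr <- corner; pvr$depthClass <- "periventricular"
  expect_error(classifyCrossSectional(pvr, pv), "deep")
})

test_that("region assignment uses majority, centroid tie-break, fixed order", {
  lab <- array(0L, c(10, 10, 10))
  lab[1:5, , ] <- 1L   # frontal
  lab[6:10, , ] <- 2L  # parietal
  inF <- clusterRow(cbind(2:4, 5, 5))
  expect_equal(assignRegion(inF, lab)$region, "frontal")
  # 60/40 split
  vox <- rbind(cbind(3:5, 5, 5), cbind(6:7, 5, 5))
  expect_equal(assignRegion(clusterRow(vox), lab)$region, "frontal")
  # exact 50/50 with centroid on the parietal side
  vox2 <- rbind(cbind(4:5, 5, 5), cbind(6:7, 5, 5))
  r2 <- assignRegion(clusterRow(vox2), lab)
  expect_equal(r2$region, "parietal")
  # 50/50 with centroid outside both winners: fixed order wins
  lab2 <- array(0L, c(10, 10, 10))
  lab2[1, , ] <- 3L; lab2[3, , ] <- 2L; lab2[2, , ] <- 4L
  vox3 <- rbind(cbind(1, 1:3, 5), cbind(3, 1:3, 5))
  expect_equal(assignRegion(clusterRow(vox3), lab2)$region, "parietal")
  out <- clusterRow(cbind(9, 9, 9))
  lab[9, 9, 9] <- 0L
  expect_error(assignRegion(out, lab), "outside")
})

test_that("cluster matching is identity on equal masks and handles shifts", {
  dims <- c(12, 12, 12)
  a1 <- cbind(2:4, 2, 2); a2 <- cbind(8:10, 8, 8)
  ca <- rbind(clusterRow(a1, id = 1L), clusterRow(a2, id = 2L))
  m <- matchClusters(ca, ca, dims)
  expect_equal(m$map$idA, m$map$idB)
  expect_equal(length(m$unmatchedNew), 0L)
  # non-overlapping shift: nothing matches, the new cluster is reported
  cb <- clusterRow(sweep(a1, 2, c(5, 5, 5), `+`), id = 1L)
  m2 <- matchClusters(ca, cb, dims)
  expect_equal(nrow(m2$map), 0L)
  expect_equal(m2$unmatchedNew, 1L)
  # coalescence: both wave-a clusters map to the engulfing wave-b cluster
  big <- clusterRow(voxelsOfMask(array(TRUE, dims)), id = 7L)
  m3 <- matchClusters(ca, big, dims)
  expect_equal(sort(m3$map$idA), c(1L, 2L))
  expect_true(all(m3$map$idB == 7L))
})

test_that("the growth mask is the set difference of wave masks", {
  dims <- c(8, 8, 8)
  set.seed(12)
  a <- randomMask(dims, 0.3)
  b <- a | randomMask(dims, 0.2)
  expect_false(any(changeMask(a, a)))
  expect_equal(which(changeMask(array(FALSE, dims), b)), which(b))
  # |change| = |B| - |A intersect B| on random masks
  for (i in 1:10) {
    x <- randomMask(dims, 0.3); y <- randomMask(dims, 0.3)
    expect_equal(sum(changeMask(x, y)), sum(y) - sum(x & y))
  }
})

test_that("four-way change labels follow the doubling and contact rules", {
  dims <- c(20, 20, 20)
  pv <- array(FALSE, dims); pv[10, 10, 1:20] <- TRUE
  mkpair <- function(voxA, voxB, idA = 1L, idB = 1L) {
    a <- classifyCrossSectional(clusterRow(voxA, id = idA), pv)
    b <- classifyCrossSectional(clusterRow(voxB, id = idB), pv)
    m <- matchClusters(a, b, dims)
    classifyChange(m, a, b)
  }
  # ratio 1.4: below the doubling rule
  r <- mkpair(cbind(2:6, 2, 2), cbind(2:8, 2, 2))
  expect_equal(r$changeLabel, "no_increase")
  # attached tripling with contact rising: increase around
  co <- expand.grid(x = 1:20, y = 1:20, z = 1:20)
  sph <- function(c0, rad) {
    m <- (co$x - c0[1])^2 + (co$y - c0[2])^2 + (co$z - c0[3])^2 <= rad^2
    voxelsOfMask(array(m, dims))
  }
  r2 <- mkpair(sph(c(11, 11, 10), 2), sph(c(11, 11, 10), 4))
  expect_gt(r2$contactB, r2$contactA)
  expect_equal(r2$changeLabel, "increase_around")
  # detached tripling, never in contact: increase not close
  r3 <- mkpair(sph(c(16, 16, 10), 2), sph(c(16, 16, 10), 3.2))
  expect_equal(r3$contactB, 0L)
  expect_equal(r3$changeLabel, "increase_not_close")
  # doubling with frozen contact: increase close
  a4 <- sph(c(11, 11, 10), 3)
  extra <- sph(c(16, 11, 10), 3.2)
  r4 <- mkpair(a4, unique(rbind(a4, extra)))
  expect_equal(r4$contactB, r4$contactA)
  expect_equal(r4$changeLabel, "increase_close")
  # disappeared cluster: no_increase, flagged halved
  a5 <- classifyCrossSectional(clusterRow(cbind(2:6, 2, 2), id = 1L), pv)
  b5 <- classifyCrossSectional(clusterRow(cbind(15:19, 18, 18), id = 9L), pv)
  m5 <- matchClusters(a5, b5, dims)
  r5 <- classifyChange(m5, a5, b5)
  expect_equal(r5$changeLabel, "no_increase")
  expect_true(r5$halved)
})

test_that("every deep cluster gets exactly one label per wave pair", {
  for (s in 1:3) {
    res <- analyzeSubject(sceneParams(seed = s), growthParams(seed = s),
                          waves = 2L)
    cl <- res$clusters
    expect_true(all(cl$topologyLabel %in% c("close", "not_close")))
    pr <- res$pairs
    expect_true(all(pr$changeLabel %in% c("increase_around", "increase_close",
                                          "increase_not_close", "no_increase")))
    expect_equal(anyDuplicated(pr$idA), 0L)
    # consistency: increase_around implies close at the later wave,
    # increase_not_close implies no contact at the later wave
    expect_true(all(pr$contactB[pr$changeLabel == "increase_around"] > 0))
    expect_true(all(pr$contactB[pr$changeLabel == "increase_not_close"] == 0))
  }
})
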