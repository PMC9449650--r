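test_that("parameter objects validate their invariants", {
  expect_error(sceneParams(pAttached = 1.2), "probabilities")
  expect_error(sceneParams(pvsLengthRangeMm = c(50, 3)), "ranges")
  expect_error(growthParams(growthFactorRange = c(1.5, 3)), "doubling")
  expect_error(generateScene(sceneParams(gridShape = c(8, 64, 64))),
               "degenerate grid")
})

test_that("no tubes means no attachments; forced attachment attaches all", {
  sc0 <- generateScene(sceneParams(seed = 5, nPvs = 0, nWmh = 6,
                                   pPeriventricular = 0))
  expect_equal(nrow(sc0@tubes), 0L)
  expect_true(all(!sc0@clusters$attached))
  sc1 <- generateScene(sceneParams(seed = 11, nPvs = 20, nWmh = 6,
                                   pAttached = 1, pPeriventricular = 0))
  expect_true(nrow(sc1@tubes) > 0)
  expect_true(all(sc1@clusters$attached))
})

test_that("generation and rendering are deterministic given the seed", {
  p <- sceneParams(seed = 17)
  a <- generateScene(p); b <- generateScene(p)
  expect_identical(a@tubes, b@tubes)
  expect_identical(a@clusters, b@clusters)
  va <- renderVolumes(a, p); vb <- renderVolumes(b, p)
  expect_identical(gridValues(va$t2), gridValues(vb$t2))
  expect_identical(gridValues(va$flair), gridValues(vb$flair))
})

test_that("tube geometry respects the admissible length range and masks", {
  for (s in 1:5) {
    sc <- generateScene(sceneParams(seed = s))
    if (!nrow(sc@tubes)) next
    expect_true(all(sc@tubes$lengthMm >= 3 & sc@tubes$lengthMm <= 50))
    # attached seeds sit within one voxel of their tube's surface
    at <- sc@clusters[sc@clusters$attached, ]
    for (i in seq_len(nrow(at))) {
      tb <- sc@tubes[at$tubeId[i], ]
      d <- pvstopo:::.pointSegDist(matrix(c(at$cx[i], at$cy[i], at$cz[i]), 1),
                                   c(tb$ax, tb$ay, tb$az),
                                   c(tb$bx, tb$by, tb$bz))
      expect_lt(abs(d - tb$radiusMm), max(sc@voxelSizeMm) + 1e-9)
    }
  }
})

test_that("no-growth evolution only advances the wave counter", {
  p <- sceneParams(seed = 3)
  g <- growthParams(pGrow = 0, pNewCluster = 0, seed = 3)
  sc1 <- generateScene(p)
  sc2 <- evolveScene(sc1, g, 1, p)
  expect_equal(sc2@wave, 2L)
  expect_identical(sc1@tubes, sc2@tubes)
  expect_identical(sc1@shapes, sc2@shapes)
  expect_true(all(sc2@clusters$changeLabel[!sc2@clusters$pv] == "no_increase"))
})

test_that("forced growth around labels every attached pre-existing cluster", {
  p <- sceneParams(seed = 11, nPvs = 20, nWmh = 6, pAttached = 1,
                   pPeriventricular = 0)
  g <- growthParams(pGrow = 1, pGrowAround = 1, pNewCluster = 0, seed = 11)
  sc1 <- generateScene(p)
  sc2 <- evolveScene(sc1, g, 1, p)
  pre <- sc2@clusters$waveOfBirth == 1 & !sc2@clusters$pv
  expect_true(all(sc2@clusters$changeLabel[pre] == "increase_around"))
})

test_that("the grown fraction is calibrated to pGrow across seeds", {
  lab <- character(0)
  for (s in 1:20) {
    p <- sceneParams(seed = s)
    g <- growthParams(seed = s)
    sc2 <- evolveScene(generateScene(p), g, 1, p)
    pre <- !sc2@clusters$pv & !is.na(sc2@clusters$changeLabel)
    lab <- c(lab, sc2@clusters$changeLabel[pre])
  }
  n <- length(lab)
  frac <- mean(lab != "no_increase")
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(frac - 0.70), 3 * se)
})

test_that("the attached fraction is calibrated to pAttached across seeds", {
  att <- logical(0)
  for (s in 1:25) {
    sc <- generateScene(sceneParams(seed = s))
    deep <- !sc@clusters$pv
    att <- c(att, sc@clusters$attached[deep])
  }
  n <- length(att)
  se <- sqrt(0.77 * 0.23 / n)
  expect_lt(abs(mean(att) - 0.77), 3 * se)
})

test_that("cluster ids are conserved across waves", {
  p <- sceneParams(seed = 2); g <- growthParams(seed = 2)
  sc1 <- generateScene(p)
  sc2 <- evolveScene(sc1, g, 1, p)
  sc3 <- evolveScene(sc2, g, 2, p)
  expect_true(all(sc1@clusters$id %in% sc2@clusters$id))
  expect_true(all(sc2@clusters$id %in% sc3@clusters$id))
})

test_that("a rasterised 1 mm tube approximates the analytic cylinder volume", {
  p <- sceneParams(seed = 1)
  sc <- generateScene(p)
  # replace the tubes by one generic oblique 28 mm tube of radius 1,
  # placed away from the ventricles (a lattice-aligned line through voxel
  # centres is the worst case for binary rasterisation and not the
  # generic situation the volume identity describes)
  cen <- sc@brainCenter + c(0, 14, 4)
  u <- c(1.7, 1, 0.37); u <- u / sqrt(sum(u^2))
  A <- cen - 14 * u; B <- cen + 14 * u
  sc@tubes <- data.frame(id = 1L, ax = A[1], ay = A[2], az = A[3],
                         bx = B[1], by = B[2], bz = B[3],
                         radiusMm = 1, lengthMm = 28)
  sc@clusters <- sc@clusters[0, ]; sc@shapes <- list()
  ras <- rasterizeScene(sc, spacing = c(1, 1, 1))
  vol <- sum(ras$truthPvs)               # mm^3 at 1 mm^3 voxels
  expect_lt(abs(vol - pi * 1^2 * 28) / (pi * 28), 0.20)
})

test_that("rendered volumes honour the contrast table and noise model", {
  p <- sceneParams(seed = 4, noiseSd = 0, nPvs = 0, nWmh = 0,
                   pPeriventricular = 0)
  sc <- generateScene(p)
  v <- renderVolumes(sc, p)
  t2 <- gridValues(v$t2)
  brain <- gridValues(v$brain) > 0
  vent <- gridValues(v$ventricles) > 0
  expect_true(all(t2[brain & !vent] == 100))
  expect_true(all(t2[!brain] == 0))
  bad <- sceneParams(seed = 4)
  bad@contrast$wmh <- NULL
  expect_error(renderVolumes(sc, bad), "contrast table")
})

test_that("fixtures round-trip through NIfTI, CSV and JSON", {
  p <- sceneParams(seed = 6, gridShape = c(32, 32, 16))
  g <- growthParams(seed = 6)
  sc1 <- generateScene(p)
  sc2 <- evolveScene(sc1, g, 1, p)
  dir <- withr::local_tempdir()
  files <- writeFixture(list(sc1, sc2), p, dir, growth = g)
  expect_true(all(file.exists(files)))
  t2 <- readVolume(file.path(dir, "wave1_t2.nii.gz"))
  ref <- renderVolumes(sc1, p)$t2
  expect_equal(gridValues(t2), gridValues(ref), tolerance = 1e-6)
  expect_equal(gridSpacing(t2), gridSpacing(ref))
  msk <- readMask(file.path(dir, "wave1_brain.nii.gz"))
  expect_true(all(gridValues(msk) %in% c(0, 1)))
  truth <- read.csv(file.path(dir, "truth_clusters.csv"))
  expect_true(all(c("id", "wave", "attached", "changeLabel") %in% names(truth)))
  pj <- jsonlite::read_json(file.path(dir, "params.json"))
  expect_equal(pj$pAttached, 0.77)
})
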