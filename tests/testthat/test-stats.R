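test_that("cross-sectional tables preserve partition identities", {
  set.seed(5)
  df <- expand.grid(wave = 1:2, region = c("frontal", "parietal", "temporal",
                                           "occipital"),
                    topologyLabel = c("close", "not_close"))
  df$count <- rpois(nrow(df), 20) + 1L
  tab <- tabulateCrossSectional(df)
  for (w in 1:2) {
    ov <- tab[tab$wave == w & tab$region == "overall", ]
    expect_equal(ov$close + ov$notClose, ov$total)
    expect_equal(ov$closePct + ov$notClosePct, 100, tolerance = 0.02)
    regional <- tab[tab$wave == w & tab$region != "overall", ]
    expect_equal(sum(regional$total), ov$total)
  }
  expect_error(tabulateCrossSectional(
    data.frame(wave = 1, region = "frontal", topologyLabel = "unset")),
    "unlabelled")
  empty <- tabulateCrossSectional(
    data.frame(wave = integer(0), region = character(0),
               topologyLabel = character(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("longitudinal tables derive increase percentages correctly", {
  df <- data.frame(wavePair = "1-2",
                   region = "frontal",
                   changeLabel = c("increase_around", "increase_close",
                                   "increase_not_close", "no_increase"),
                   count = c(30, 10, 10, 50))
  tab <- tabulateLongitudinal(df)
  ov <- tab[tab$region == "overall", ]
  expect_equal(ov$total, 100)
  expect_equal(ov$pctIncreased, 50)
  expect_equal(ov$aroundOfIncreased, 60)
  # all no-increase: conditional percentages undefined and flagged
  df2 <- data.frame(wavePair = "1-2", region = "frontal",
                    changeLabel = "no_increase", count = 10)
  ov2 <- tabulateLongitudinal(df2)
  ov2 <- ov2[ov2$region == "overall", ]
  expect_equal(ov2$pctIncreased, 0)
  expect_true(is.na(ov2$aroundOfIncreased))
  expect_true(ov2$undefined)
})

test_that("the change indicator is 1 only for strict count increases", {
  cc <- changeIndicator(data.frame(
    participant = 1:3, category = "close",
    countEarlier = c(5, 5, 5), countLater = c(7, 5, 3)))
  expect_equal(cc$increase, c(1L, 0L, 0L))
})

test_that("the random-intercept logistic model recovers a known odds ratio", {
  simulate <- function(or, n, seed) {
    set.seed(seed)
    b1 <- log(or)
    u <- rnorm(n, 0, 0.5)
    rows <- NULL
    for (i in seq_len(n)) {
      for (cat in c("close", "not_close")) {
        eta <- -0.3 + b1 * (cat == "close") + u[i]
        rows <- rbind(rows, data.frame(
          participant = i, category = cat,
          increase = rbinom(1, 1, plogis(eta))))
      }
    }
    rows
  }
  fit <- fitChangeModel(simulate(3, 150, 42))
  expect_gt(fit$or, 1)
  expect_true(fit$ciLow < 3 && fit$ciHigh > 1)
  expect_true(fit$ciLow < fit$or & fit$or < fit$ciHigh)
  expect_error(fitChangeModel(
    data.frame(participant = 1:4, category = "close", increase = c(0, 1, 0, 1))),
    "inestimable")
})

test_that("PVS density splits by contiguity with deep clusters", {
  dims <- c(15, 15, 15)
  roi <- array(TRUE, dims)
  pvs <- rbind(clusterRow(cbind(2:7, 2, 2), id = 1L),
               clusterRow(cbind(10:14, 12, 12), id = 2L))
  # one deep cluster adjacent to the first PVS only
  wmh <- clusterRow(cbind(2:5, 3, 3), id = 1L)
  rec <- pvsDensity(pvs, wmh, roi, c(1, 1, 1))
  expect_equal(rec$nClose, 1L)
  expect_equal(rec$nNotClose, 1L)
  expect_equal(rec$roiVolumeMl, prod(dims) / 1000)
  expect_equal(rec$nClose + rec$nNotClose, nrow(pvs))
  # no WMH: nothing close
  none <- pvsDensity(pvs, wmh[0, ], roi, c(1, 1, 1))
  expect_equal(none$nClose, 0L)
  expect_equal(none$densityClose, 0)
})

test_that("the paired density test is symmetric and handles ties", {
  rec <- data.frame(densityClose = c(0.12, 0.10, 0.15, 0.09),
                    densityNotClose = c(0.05, 0.06, 0.04, 0.05))
  tt <- pairedDensityTest(rec)
  sw <- pairedDensityTest(data.frame(densityClose = rec$densityNotClose,
                                     densityNotClose = rec$densityClose))
  expect_equal(tt$meanDiff, -sw$meanDiff)
  expect_equal(tt$p, sw$p)
  same <- pairedDensityTest(data.frame(densityClose = rec$densityClose,
                                       densityNotClose = rec$densityClose))
  expect_equal(same$p, 1)
  expect_equal(same$meanDiff, 0)
  expect_error(pairedDensityTest(rec[1, , drop = FALSE]), "2 participants")
})

test_that("univariate R2 matches OLS identities", {
  x <- 1:20
  expect_equal(univariateR2(x, 2 * x), 1)
  set.seed(10)
  xi <- rnorm(1000); yi <- rnorm(1000)
  expect_lt(univariateR2(xi, yi), 0.01)
  # affine invariance
  y <- 3 * x + rnorm(20, 0, 2)
  expect_equal(univariateR2(x, y), univariateR2(10 * x - 4, 0.1 * y + 7),
               tolerance = 1e-12)
  expect_error(univariateR2(rep(1, 5), 1:5), "constant")
})

test_that("agreement metrics behave on identical, disjoint and half masks", {
  dims <- c(10, 10, 4)
  a <- array(FALSE, dims); a[1:5, , ] <- TRUE
  expect_equal(diceCoefficient(a, a), 1)
  b <- array(FALSE, dims); b[6:10, , ] <- TRUE
  expect_equal(diceCoefficient(a, b), 0)
  a4 <- array(FALSE, dims); a4[1:4, , ] <- TRUE
  h <- array(FALSE, dims); h[3:6, , ] <- TRUE   # half overlap, equal size
  expect_equal(diceCoefficient(a4, h), 0.5)
  expect_warning(dd <- diceCoefficient(array(FALSE, dims), array(FALSE, dims)),
                 "undefined")
  expect_true(is.na(dd))
  v <- c(10, 12, 9, 14, 11)
  ag <- maskAgreement(volumesA = v, volumesB = v)
  expect_equal(ag$baMeanDiff, 0)
  expect_equal(ag$icc, 1)
  set.seed(3)
  w <- v + rnorm(5, 0.5, 0.2)
  ag2 <- maskAgreement(volumesA = v, volumesB = w)
  expect_equal(ag2$baMeanDiff, mean(v - w))
  expect_true(ag2$icc < 1 && ag2$icc > 0.9)
})

test_that("icc21 agrees with the two-way ANOVA derivation on known data", {
  # independent oracle: explicit mean squares from a long-format aov
  set.seed(8)
  a <- rnorm(12, 10, 2); b <- a + rnorm(12, 0.3, 0.5)
  d <- data.frame(y = c(a, b),
                  subj = factor(rep(1:12, 2)),
                  rater = factor(rep(1:2, each = 12)))
  ms <- anova(lm(y ~ subj + rater, data = d))
  MSR <- ms["subj", "Mean Sq"]; MSC <- ms["rater", "Mean Sq"]
  MSE <- ms["Residuals", "Mean Sq"]
  want <- (MSR - MSE) / (MSR + MSE + 2 * (MSC - MSE) / 12)
  expect_equal(icc21(a, b), want, tolerance = 1e-10)
})
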