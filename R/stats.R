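# Cohort-level statistics: count/percentage tables, the random-intercept
# logistic change model, PVS density comparisons, univariate R^2 and
# mask-agreement metrics.

.regions <- c("frontal", "parietal", "temporal", "occipital")

.roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cross-sectional close/not-close counts table
#'
#' Aggregates labelled deep clusters into counts and percentages per wave
#' and lobar region, plus the overall row.  Percentages of the wave total
#' are reported to 2 decimal places; the close/not-close shares of each
#' region's own total are additionally reported to the nearest integer.
#'
#' @param clusters data.frame with columns wave, region, topologyLabel and
#'   optionally count (pre-aggregated rows; default 1 per row).
#' @return data.frame: wave, region ("overall" included), close, notClose,
#'   total, closePct, notClosePct, totalPct (percent of wave total, 2 dp),
#'   closeShare, notCloseShare (percent of the region total, integer).
#' @export
tabulateCrossSectional <- function(clusters) {
  if (nrow(clusters) && any(clusters$topologyLabel == "unset"))
    stop("unlabelled cluster encountered")
  cnt <- if ("count" %in% names(clusters)) clusters$count else
    rep(1L, nrow(clusters))
  out <- NULL
  for (w in sort(unique(clusters$wave))) {
    cw <- clusters$wave == w
    total <- sum(cnt[cw])
    rows <- lapply(c(.regions, "overall"), function(rg) {
      sel <- cw & (rg == "overall" | clusters$region == rg)
      cl <- sum(cnt[sel & clusters$topologyLabel == "close"])
      nc <- sum(cnt[sel & clusters$topologyLabel == "not_close"])
      tt <- cl + nc
      pct <- function(x) if (total > 0) .roundHalfUp(100 * x / total, 2) else 0
      share <- function(x) if (tt > 0) .roundHalfUp(100 * x / tt) else 0
      data.frame(wave = w, region = rg, close = cl, notClose = nc,
                 total = tt, closePct = pct(cl), notClosePct = pct(nc),
                 totalPct = pct(tt), closeShare = share(cl),
                 notCloseShare = share(nc),
                 undefined = total == 0)
    })
    out <- rbind(out, do.call(rbind, rows))
  }
  if (is.null(out))
    return(data.frame(wave = integer(0), region = character(0),
                      close = integer(0), notClose = integer(0),
                      total = integer(0), closePct = numeric(0),
                      notClosePct = numeric(0), totalPct = numeric(0),
                      closeShare = numeric(0), notCloseShare = numeric(0),
                      undefined = logical(0)))
  # partition identity: close + not_close = total, regions sum to overall
  for (w in unique(out$wave)) {
    ov <- out[out$wave == w & out$region == "overall", ]
    stopifnot(ov$close + ov$notClose == ov$total)
    stopifnot(sum(out$total[out$wave == w & out$region != "overall"]) ==
                ov$total)
  }
  rownames(out) <- NULL
  out
}

#' Longitudinal four-way change counts table
#'
#' Counts of the four change categories per wave-pair and region, with
#' derived text-style summaries: percent increased of the total and
#' conditional percentages of increasers per category, both rounded
#' half-up to integers.
#'
#' @param pairs data.frame with columns wavePair (e.g. "1-2"), region,
#'   changeLabel and optionally count.
#' @return data.frame with per-region and overall counts, category
#'   percentages of the pair total (2 dp), pctIncreased and conditional
#'   aroundOfIncreased / closeOfIncreased / notCloseOfIncreased (integer
#'   percent, NA when no cluster increased).
#' @export
tabulateLongitudinal <- function(pairs) {
  cats <- c("increase_around", "increase_close", "increase_not_close",
            "no_increase")
  if (nrow(pairs) && any(!pairs$changeLabel %in% cats))
    stop("unlabelled cluster pair encountered")
  cnt <- if ("count" %in% names(pairs)) pairs$count else rep(1L, nrow(pairs))
  out <- NULL
  for (wp in unique(pairs$wavePair)) {
    pw <- pairs$wavePair == wp
    total <- sum(cnt[pw])
    rows <- lapply(c(.regions, "overall"), function(rg) {
      sel <- pw & (rg == "overall" | pairs$region == rg)
      n <- vapply(cats, function(cc)
        sum(cnt[sel & pairs$changeLabel == cc]), numeric(1))
      tt <- sum(n)
      inc <- tt - n[["no_increase"]]
      pct <- function(x) if (total > 0) .roundHalfUp(100 * x / total, 2) else 0
      data.frame(wavePair = wp, region = rg,
                 increaseAround = n[[1]], increaseClose = n[[2]],
                 increaseNotClose = n[[3]], noIncrease = n[[4]], total = tt,
                 increaseAroundPct = pct(n[[1]]), increaseClosePct = pct(n[[2]]),
                 increaseNotClosePct = pct(n[[3]]), noIncreasePct = pct(n[[4]]),
                 pctIncreased = if (tt > 0) .roundHalfUp(100 * inc / tt) else 0,
                 aroundOfIncreased = if (inc > 0)
                   .roundHalfUp(100 * n[[1]] / inc) else NA_real_,
                 closeOfIncreased = if (inc > 0)
                   .roundHalfUp(100 * n[[2]] / inc) else NA_real_,
                 notCloseOfIncreased = if (inc > 0)
                   .roundHalfUp(100 * n[[3]] / inc) else NA_real_,
                 undefined = inc == 0)
    })
    out <- rbind(out, do.call(rbind, rows))
  }
  for (wp in unique(out$wavePair)) {
    ov <- out[out$wavePair == wp & out$region == "overall", ]
    stopifnot(ov$increaseAround + ov$increaseClose + ov$increaseNotClose +
                ov$noIncrease == ov$total)
  }
  rownames(out) <- NULL
  out
}

#' Binary change indicator per participant and closeness category
#'
#' 1 when the count of deep clusters in that category increased between
#' the two waves, 0 otherwise (no change or a decrease).  Two rows per
#' participant: close and not_close.
#'
#' @param counts data.frame with columns participant, category ("close" /
#'   "not_close"), countEarlier, countLater.
#' @return The input with an \code{increase} column added.
#' @export
changeIndicator <- function(counts) {
  counts$increase <- as.integer(counts$countLater > counts$countEarlier)
  counts
}

#' Random-intercept logistic model of cluster-count change
#'
#' Fits logit P(increase) = b0 + b1 [close] (+ up to two adjustment
#' covariates; at most 3 predictors in total) with a participant random
#' intercept, via \code{lme4::glmer}, and reports the odds ratio for close
#' vs not close with its Wald 95% CI.
#'
#' @param indicators data.frame from \code{\link{changeIndicator}} (or with
#'   columns participant, category, increase, plus covariates).
#' @param adjust character vector of covariate column names (max 2).
#' @return list: or, ciLow, ciHigh, p, randomInterceptVar, model,
#'   converged, adjusted.
#' @export
fitChangeModel <- function(indicators, adjust = character(0)) {
  if (length(unique(indicators$participant)) < 2)
    stop("need at least 2 participants")
  if (length(unique(indicators$category)) < 2)
    stop("inestimable contrast: only one closeness category present")
  if (length(adjust) > 2)
    stop("at most 3 predictors per model (close + 2 covariates)")
  indicators$close <- as.integer(indicators$category == "close")
  rhs <- paste(c("close", adjust, "(1 | participant)"), collapse = " + ")
  f <- stats::as.formula(paste("increase ~", rhs))
  fit <- lme4::glmer(f, data = indicators, family = stats::binomial())
  co <- summary(fit)$coefficients
  msgs <- fit@optinfo$conv$lme4$messages
  conv <- is.null(msgs)
  b <- co["close", "Estimate"]; se <- co["close", "Std. Error"]
  list(or = exp(b), ciLow = exp(b - 1.96 * se), ciHigh = exp(b + 1.96 * se),
       p = co["close", "Pr(>|z|)"],
       randomInterceptVar = as.numeric(lme4::VarCorr(fit)$participant),
       converged = conv,
       convergenceMessages = if (conv) character(0) else unlist(msgs),
       adjusted = adjust, model = fit)
}

#' PVS density close / not close to deep WMH
#'
#' A PVS is "close" when any of its voxels is contiguous (26-neighbourhood)
#' with any deep WMH cluster; densities are counts per ml of the region of
#' interest.
#'
#' @param pvsComponents PVS component table (see \code{\link{segmentPVS}}).
#' @param deepClusters deep cluster table with voxel sets.
#' @param roi logical array or 0/1 \code{VoxelGrid} (density denominator).
#' @param spacingMm numeric(3).
#' @param participant id copied into the record.
#' @param wave wave index copied into the record.
#' @return one-row data.frame: participant, wave, nClose, nNotClose,
#'   roiVolumeMl, densityClose, densityNotClose.
#' @export
pvsDensity <- function(pvsComponents, deepClusters, roi, spacingMm,
                       participant = 1L, wave = 1L) {
  roiArr <- .asLogicalArr(roi)
  wmh <- array(FALSE, dim(roiArr))
  for (v in deepClusters$voxels) wmh[rbind(v)] <- TRUE
  touch <- if (any(wmh)) wmh | .dilate(wmh, 26, 1L) else wmh
  isClose <- vapply(pvsComponents$voxels,
                    function(v) any(touch[rbind(v)]), logical(1))
  roiMl <- sum(roiArr) * prod(spacingMm) / 1000
  data.frame(participant = participant, wave = wave,
             nClose = sum(isClose), nNotClose = sum(!isClose),
             roiVolumeMl = roiMl,
             densityClose = sum(isClose) / roiMl,
             densityNotClose = sum(!isClose) / roiMl)
}

#' Paired t-test on close vs not-close PVS densities
#'
#' @param records data.frame of \code{\link{pvsDensity}} rows (one wave).
#' @return list: meanClose, meanNotClose, meanDiff, p (two-tailed), n.
#' @export
pairedDensityTest <- function(records) {
  if (nrow(records) < 2) stop("need at least 2 participants for the test")
  d <- records$densityClose - records$densityNotClose
  if (stats::sd(d) == 0) {
    # degenerate: all paired differences equal (e.g. identical columns)
    return(list(meanClose = mean(records$densityClose),
                meanNotClose = mean(records$densityNotClose),
                meanDiff = mean(d), p = if (all(d == 0)) 1 else NA_real_,
                n = nrow(records)))
  }
  tt <- stats::t.test(records$densityClose, records$densityNotClose,
                      paired = TRUE)
  list(meanClose = mean(records$densityClose),
       meanNotClose = mean(records$densityNotClose),
       meanDiff = unname(tt$estimate), p = tt$p.value, n = nrow(records))
}

#' Univariate OLS R-squared
#'
#' @param x per-participant predictor (e.g. count of PVS close to WMH).
#' @param y per-participant response (e.g. WMH volume in ml).
#' @return R^2 = 1 - SS_res / SS_tot of the simple linear regression.
#' @export
univariateR2 <- function(x, y) {
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant x or y")
  fit <- stats::lm(y ~ x)
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

#' Dice coefficient of two masks
#'
#' @param maskA,maskB logical arrays or 0/1 \code{VoxelGrid}s on one grid.
#' @return 2|A and B| / (|A| + |B|); NA with a warning when both empty.
#' @export
diceCoefficient <- function(maskA, maskB) {
  a <- .asLogicalArr(maskA); b <- .asLogicalArr(maskB)
  if (!identical(dim(a), dim(b))) stop("grids differ")
  s <- sum(a) + sum(b)
  if (s == 0) { warning("both masks empty: Dice undefined"); return(NA_real_) }
  2 * sum(a & b) / s
}

#' ICC(2,1): two-way random, single measure, absolute agreement
#'
#' @param a,b paired measurements (e.g. volumes from two raters/methods).
#' @return The intraclass correlation coefficient.
#' @export
icc21 <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a); k <- 2
  Y <- cbind(a, b)
  grand <- mean(Y)
  MSR <- k * stats::var(rowMeans(Y))
  MSC <- n * sum((colMeans(Y) - grand)^2) / (k - 1)
  MSE <- (sum((Y - outer(rowMeans(Y), rep(1, k)) -
                 outer(rep(1, n), colMeans(Y)) + grand)^2)) /
    ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

#' Mask and volume agreement metrics
#'
#' Dice overlap of two masks plus Bland-Altman mean difference (SD) and
#' ICC(2,1) of paired per-participant volumes.
#'
#' @param maskA,maskB masks for Dice (may be NULL to skip).
#' @param volumesA,volumesB paired volume vectors (may be NULL to skip).
#' @return list: dice, baMeanDiff, baSdDiff, icc.
#' @export
maskAgreement <- function(maskA = NULL, maskB = NULL,
                          volumesA = NULL, volumesB = NULL) {
  out <- list(dice = NA_real_, baMeanDiff = NA_real_, baSdDiff = NA_real_,
              icc = NA_real_)
  if (!is.null(maskA) && !is.null(maskB))
    out$dice <- diceCoefficient(maskA, maskB)
  if (!is.null(volumesA) && !is.null(volumesB)) {
    d <- volumesA - volumesB
    out$baMeanDiff <- mean(d)
    out$baSdDiff <- stats::sd(d)
    out$icc <- icc21(volumesA, volumesB)
  }
  out
}
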