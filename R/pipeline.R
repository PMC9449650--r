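# End-to-end orchestration: per-subject analysis of synthetic (or loaded)
# longitudinal volumes, truth scoring, and cohort aggregation.

#' Match segmented clusters to truth clusters by voxel overlap
#'
#' @param segVoxels list of n x 3 voxel index matrices (segmented).
#' @param truthVoxels list of n x 3 voxel index matrices (truth).
#' @param dims integer(3) grid dimensions.
#' @return integer vector: for each segmented cluster the truth cluster id
#'   with maximal overlap, or NA when none overlaps.
#' @export
matchToTruth <- function(segVoxels, truthVoxels, dims) {
  key <- function(v) {
    v <- rbind(v)
    if (!nrow(v)) return(numeric(0))
    v[, 1] + dims[1] * (v[, 2] - 1) + dims[1] * dims[2] * (v[, 3] - 1)
  }
  tk <- lapply(truthVoxels, key)
  vapply(segVoxels, function(sv) {
    ks <- key(sv)
    ov <- vapply(tk, function(k) sum(ks %in% k), numeric(1))
    if (!length(ov) || max(ov) == 0) NA_integer_ else which.max(ov)
  }, integer(1))
}

.pvsMaskFromTable <- function(tab, dims) {
  m <- array(FALSE, dims)
  for (v in tab$voxels) m[rbind(v)] <- TRUE
  m
}

#' Analyse one synthetic subject end to end
#'
#' Generates a seeded subject (scene plus longitudinal growth), renders
#' native 1 x 1 x 2 mm volumes per wave, resamples them to the 1 mm
#' isotropic analysis grid, segments baseline PVS (multiscale Frangi,
#' threshold, 3--50 mm length rule), segments WMH per wave (1.69 SD
#' threshold, prior refinement, 3 mm cluster rule, deep/periventricular
#' split), classifies every deep cluster close/not-close to baseline PVS
#' with its lobar region, matches clusters across consecutive waves and
#' assigns the four-way change label, and scores everything against the
#' generator truth.
#'
#' @param params \code{\linkS4class{SceneParams}} (its seed identifies the
#'   subject).
#' @param growth \code{\linkS4class{GrowthParams}}.
#' @param frangi \code{\linkS4class{FrangiParams}}.
#' @param wmhP \code{\linkS4class{WMHSegParams}}.
#' @param changeP \code{\linkS4class{ChangeParams}}.
#' @param waves number of waves (default 3).
#' @return list: clusters (deep cluster table over waves with labels),
#'   pairs (longitudinal labels per wave pair), pvs (baseline component
#'   table), density (per-wave density records), dice (per-wave WMH Dice
#'   vs truth), truthAgreement (cross-sectional and longitudinal),
#'   counts (per category/wave counts for the change model), scenes.
#' @export
analyzeSubject <- function(params = sceneParams(), growth = growthParams(),
                           frangi = frangiParams(), wmhP = wmhSegParams(),
                           changeP = changeParams(), waves = 3L) {
  scenes <- vector("list", waves)
  scenes[[1]] <- generateScene(params)
  for (w in seq_len(waves - 1))
    scenes[[w + 1]] <- evolveScene(scenes[[w]], growth, w, params)

  iso <- c(1, 1, 1)
  truthIso <- lapply(scenes, rasterizeScene, spacing = iso)
  dims <- truthIso[[1]]$shape
  brain <- truthIso[[1]]$brain
  vent <- truthIso[[1]]$ventricles
  lobes <- truthIso[[1]]$lobes
  roi <- .erode(brain, 6, 3L) & !.dilate(vent, 26, 2L)
  prior <- .erode(brain, 6, 2L) & !vent

  rendered <- lapply(seq_len(waves), function(w)
    renderVolumes(scenes[[w]], params, w))
  t2iso <- resampleIsotropic(rendered[[1]]$t2, 1)
  flairIso <- lapply(rendered, function(r) resampleIsotropic(r$flair, 1))

  # WMH masks per wave (wave 1 needed before PVS: the fused route runs
  # inside the baseline WMH mask)
  refinedByWave <- lapply(seq_len(waves), function(w) {
    raw <- thresholdWMH(flairIso[[w]], brain, wmhP)
    refineWMH(raw, flairIso[[w]], brain, prior, wmhP)
  })

  # baseline PVS: T2 route plus fused T2-FLAIR route inside wave-1 WMH
  pvsTab <- segmentBaselinePVS(t2iso, flairIso[[1]], brain, roi,
                               refinedByWave[[1]], frangi)
  pvsFull <- .pvsMaskFromTable(pvsTab, dims)       # whole components
  pvsMask <- attr(pvsTab, "contactMask")           # tight contact mask

  clustersByWave <- vector("list", waves)
  dice <- numeric(waves)
  density <- NULL
  truthIdByWave <- vector("list", waves)
  for (w in seq_len(waves)) {
    refined <- refinedByWave[[w]]
    # a PVS voxel bridges cluster components only when it is mostly
    # surrounded by WMH (a hole pierced through a cluster), not when it
    # merely runs tangent to one -- tangent bridging would chain distinct
    # clusters attached to the same tube
    bridge <- pvsFull & (.neighbourCount(refined, 26) >= 14L)
    cl <- extractClusters(refined, wmhP, wave = w, spacingMm = iso,
                          bridge = bridge)
    if (nrow(cl)) {
      lin <- pvLining(refined, vent, wmhP@connectivity)
      cl <- classifyDepth(cl, vent, lin, wmhP, iso)
    }
    deep <- cl[cl$depthClass %in% "deep", , drop = FALSE]
    if (nrow(deep)) {
      deep <- classifyCrossSectional(deep, pvsMask, changeP)
      deep <- assignRegion(deep, lobes)
    } else {
      deep$contact <- integer(0)
    }
    clustersByWave[[w]] <- deep
    dice[w] <- diceCoefficient(refined, truthIso[[w]]$truthWmh)
    density <- rbind(density,
                     pvsDensity(pvsTab, deep, roi, iso,
                                participant = params@seed, wave = w))
    truthIdByWave[[w]] <- matchToTruth(deep$voxels,
                                       truthIso[[w]]$clusterVoxels, dims)
  }

  # truth agreement, cross-sectional and truth-centric: each truth deep
  # cluster is judged by its maximal-overlap segmented representative
  repByWave <- lapply(seq_len(waves), function(w)
    matchToTruth(truthIso[[w]]$clusterVoxels,
                 clustersByWave[[w]]$voxels, dims))
  csOK <- 0L; csN <- 0L
  for (w in seq_len(waves)) {
    deep <- clustersByWave[[w]]
    rep <- repByWave[[w]]
    for (ti in seq_along(rep)) {
      if (scenes[[w]]@clusters$pv[ti] || is.na(rep[ti])) next
      csN <- csN + 1L
      truthClose <- scenes[[w]]@clusters$attached[ti]
      segClose <- deep$topologyLabel[rep[ti]] == "close"
      if (truthClose == segClose) csOK <- csOK + 1L
    }
  }

  # longitudinal labels per consecutive wave pair
  pairs <- NULL
  loOK <- 0L; loN <- 0L
  for (w in seq_len(waves - 1)) {
    a <- clustersByWave[[w]]; b <- clustersByWave[[w + 1]]
    if (!nrow(a)) next
    mt <- matchClusters(a, b, dims, changeP)
    ch <- classifyChange(mt, a, b, changeP)
    ch$wavePair <- paste0(w, "-", w + 1)
    pairs <- rbind(pairs, ch)
    # truth-centric agreement with the truth label of the transition into
    # wave w+1: each truth cluster is judged via its wave-w representative
    repA <- repByWave[[w]]
    for (ti in seq_along(repA)) {
      trueLab <- if (ti <= nrow(scenes[[w + 1]]@clusters))
        scenes[[w + 1]]@clusters$changeLabel[ti] else NA_character_
      if (is.na(trueLab) || is.na(repA[ti])) next
      segLab <- ch$changeLabel[match(a$id[repA[ti]], ch$idA)]
      if (is.na(segLab)) next
      loN <- loN + 1L
      if (identical(trueLab, segLab)) loOK <- loOK + 1L
    }
  }

  # per-category counts for the change-indicator model
  counts <- NULL
  for (w in seq_len(waves)) {
    deep <- clustersByWave[[w]]
    counts <- rbind(counts, data.frame(
      participant = params@seed, wave = w,
      close = sum(deep$topologyLabel == "close"),
      not_close = sum(deep$topologyLabel == "not_close")))
  }

  clustersFlat <- do.call(rbind, lapply(clustersByWave, function(d)
    d[, c("id", "wave", "volumeMl", "depthClass", "region",
          "topologyLabel", "contact")]))

  list(clusters = clustersFlat, clustersByWave = clustersByWave,
       pairs = pairs, pvs = pvsTab, density = density, dice = dice,
       truthAgreement = list(
         crossSectional = if (csN) csOK / csN else NA_real_,
         longitudinal = if (loN) loOK / loN else NA_real_,
         nCross = csN, nLong = loN),
       counts = counts, scenes = scenes,
       truthIso = truthIso, pvsMask = pvsMask)
}

#' Simulate and analyse a cohort of synthetic subjects
#'
#' Runs \code{\link{analyzeSubject}} for \code{nSubjects} seeds derived
#' from \code{baseSeed} and aggregates cluster tables, longitudinal pair
#' tables, per-participant counts, density records, Dice scores, truth
#' agreement and PVS count recovery.
#'
#' @param nSubjects number of subjects.
#' @param baseSeed integer; subject s uses seed baseSeed + s.
#' @param params,growth,frangi,wmhP,changeP parameter objects (the scene
#'   seed is overridden per subject).
#' @param waves number of waves.
#' @param verbose print one line per subject.
#' @return list of aggregated tables plus per-subject summaries.
#' @export
simulateCohort <- function(nSubjects = 20, baseSeed = 0,
                           params = sceneParams(), growth = growthParams(),
                           frangi = frangiParams(), wmhP = wmhSegParams(),
                           changeP = changeParams(), waves = 3L,
                           verbose = FALSE) {
  clusters <- NULL; pairs <- NULL; counts <- NULL; density <- NULL
  agreement <- NULL; pvsRecovery <- NULL; diceAll <- NULL
  for (s in seq_len(nSubjects)) {
    seed <- as.integer(baseSeed + s)
    p <- params; p@seed <- seed
    g <- growth; g@seed <- seed
    res <- analyzeSubject(p, g, frangi, wmhP, changeP, waves)
    clusters <- rbind(clusters, res$clusters)
    if (!is.null(res$pairs) && nrow(res$pairs))
      pairs <- rbind(pairs, cbind(participant = seed, res$pairs))
    counts <- rbind(counts, res$counts)
    density <- rbind(density, res$density)
    agreement <- rbind(agreement, data.frame(
      participant = seed,
      crossSectional = res$truthAgreement$crossSectional,
      longitudinal = res$truthAgreement$longitudinal,
      nCross = res$truthAgreement$nCross,
      nLong = res$truthAgreement$nLong))
    pvsRecovery <- rbind(pvsRecovery, data.frame(
      participant = seed, truthTubes = nrow(res$scenes[[1]]@tubes),
      segmented = nrow(res$pvs)))
    diceAll <- rbind(diceAll, data.frame(participant = seed,
                                         wave = seq_len(waves),
                                         dice = res$dice))
    if (verbose)
      message(sprintf("subject %d: %d tubes -> %d PVS, agreement cs=%.2f lo=%.2f",
                      seed, nrow(res$scenes[[1]]@tubes), nrow(res$pvs),
                      res$truthAgreement$crossSectional,
                      res$truthAgreement$longitudinal))
  }
  list(clusters = clusters, pairs = pairs, counts = counts,
       density = density, agreement = agreement,
       pvsRecovery = pvsRecovery, dice = diceAll)
}

#' Cohort summary fractions
#'
#' The three pipeline estimates compared with the generator parameters in
#' recovery tests: the fraction of deep clusters close to baseline PVS,
#' the fraction of clusters that increased between waves, and the
#' fraction of increasers that increased around a PVS.
#'
#' @param cohort result of \code{\link{simulateCohort}}.
#' @return list: fractionClose, fractionIncreased, fractionAroundOfIncreased,
#'   agreementCrossSectional, agreementLongitudinal (weighted means),
#'   pvsCountMae, meanDice.
#' @export
cohortSummary <- function(cohort) {
  cl <- cohort$clusters
  fracClose <- mean(cl$topologyLabel == "close")
  pr <- cohort$pairs
  inc <- pr$changeLabel != "no_increase"
  fracInc <- mean(inc)
  fracAround <- if (any(inc))
    mean(pr$changeLabel[inc] == "increase_around") else NA_real_
  ag <- cohort$agreement
  wmean <- function(x, w) if (sum(w) > 0) sum(x * w, na.rm = TRUE) / sum(w)
    else NA_real_
  list(fractionClose = fracClose,
       fractionIncreased = fracInc,
       fractionAroundOfIncreased = fracAround,
       nClusters = nrow(cl), nPairs = nrow(pr),
       agreementCrossSectional = wmean(ag$crossSectional, ag$nCross),
       agreementLongitudinal = wmean(ag$longitudinal, ag$nLong),
       pvsCountMae = mean(abs(cohort$pvsRecovery$truthTubes -
                                cohort$pvsRecovery$segmented)),
       meanDice = mean(cohort$dice$dice, na.rm = TRUE))
}

#' Change-model input from cohort counts
#'
#' Builds the two-rows-per-participant (close / not_close) binary change
#' indicators for one wave pair from the per-wave category counts.
#'
#' @param counts \code{cohort$counts} from \code{\link{simulateCohort}}.
#' @param waveA,waveB the wave pair (default 1 and 2).
#' @return data.frame ready for \code{\link{fitChangeModel}}.
#' @export
changeModelInput <- function(counts, waveA = 1L, waveB = 2L) {
  a <- counts[counts$wave == waveA, ]
  b <- counts[counts$wave == waveB, ]
  m <- merge(a, b, by = "participant", suffixes = c("A", "B"))
  long <- rbind(
    data.frame(participant = m$participant, category = "close",
               countEarlier = m$closeA, countLater = m$closeB),
    data.frame(participant = m$participant, category = "not_close",
               countEarlier = m$not_closeA, countLater = m$not_closeB))
  changeIndicator(long)
}

#' Run the full pipeline from a configuration
#'
#' simulate -> segment (PVS wave 1, WMH all waves) -> classify -> stats,
#' writing per-stage CSV tables and a manifest JSON with parameters and
#' seeds, so every run is reproducible from its manifest.
#'
#' @param config list from \code{\link{readPipelineConfig}} (or built by
#'   hand with the same fields).
#' @param outDir output directory (overrides the config's).
#' @return Invisibly, the cohort summary list.
#' @export
runPipeline <- function(config, outDir = config$outDir) {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  cohort <- simulateCohort(config$nSubjects, config$seed, config$scene,
                           config$growth, config$frangi, config$wmh,
                           config$change, config$waves)
  cs <- tabulateCrossSectional(cohort$clusters)
  lt <- tabulateLongitudinal(cohort$pairs)
  summ <- cohortSummary(cohort)
  utils::write.csv(cs, file.path(outDir, "cross_sectional_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(lt, file.path(outDir, "longitudinal_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$density, file.path(outDir, "pvs_density.csv"),
                   row.names = FALSE)
  cl <- cohort$clusters
  utils::write.csv(cl, file.path(outDir, "deep_clusters.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "pvstopo",
    version = as.character(utils::packageVersion("pvstopo")),
    seed = config$seed, waves = config$waves,
    nSubjects = config$nSubjects,
    summary = summ[c("fractionClose", "fractionIncreased",
                     "fractionAroundOfIncreased")])
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summ)
}
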