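# Synthetic longitudinal scene generator: seeded, ground-truth-annotated
# T2/FLAIR volume pairs with the statistical structure the analysis
# assumes.  Tubes (PVS) and spherical cluster unions (WMH) are placed
# geometrically in an ellipsoidal brain with a central ventricular pair;
# growth between waves is applied to the geometric description and truth
# change labels are recorded at the same time, so every downstream stage
# can be scored against a known answer.

#' Synthetic scene parameters
#'
#' Defaults encode the study conditions the generator emulates: a
#' 1 x 1 x 2 mm anisotropic native grid, tubular PVS 3--50 mm long and
#' 0.5--1.25 mm in radius, and WMH clusters seeded contiguous to a PVS
#' with probability 0.77 (the observed close fraction at baseline).
#'
#' @slot gridShape integer(3) voxels per axis (all >= 16).
#' @slot voxelSizeMm numeric(3) native spacing, default 1 x 1 x 2.
#' @slot nPvs expected tube count (Poisson mean).
#' @slot pvsLengthRangeMm tube length range, default (3, 50).
#' @slot pvsRadiusRangeMm tube radius range, default (0.5, 1.25).
#' @slot nWmh expected cluster count (Poisson mean).
#' @slot pAttached probability a cluster is seeded contiguous to a tube,
#'   default 0.77.
#' @slot pPeriventricular fraction of clusters seeded contiguous with the
#'   ventricular surface (gives the depth classifier both classes).
#' @slot wmhRadiusRangeMm cluster seed radius range in mm.
#' @slot noiseSd additive Gaussian noise SD (intensity units).
#' @slot contrast named list of per-class mean intensities, each a named
#'   vector \code{c(t2 = , flair = )}; classes tissue, pvs, wmh, csf,
#'   background.
#' @slot seed integer RNG seed; a fixed seed gives byte-identical output.
#' @exportClass SceneParams
setClass("SceneParams",
  representation(gridShape = "integer", voxelSizeMm = "numeric",
                 nPvs = "numeric", pvsLengthRangeMm = "numeric",
                 pvsRadiusRangeMm = "numeric", nWmh = "numeric",
                 pAttached = "numeric", pPeriventricular = "numeric",
                 wmhRadiusRangeMm = "numeric", noiseSd = "numeric",
                 contrast = "list", seed = "integer"),
  prototype(gridShape = c(64L, 64L, 32L), voxelSizeMm = c(1, 1, 2),
            nPvs = 8, pvsLengthRangeMm = c(3, 50),
            pvsRadiusRangeMm = c(0.5, 1.25), nWmh = 4,
            pAttached = 0.77, pPeriventricular = 0.25,
            wmhRadiusRangeMm = c(3.5, 4.5), noiseSd = 5,
            contrast = list(tissue = c(t2 = 100, flair = 100),
                            pvs = c(t2 = 180, flair = 40),
                            wmh = c(t2 = 130, flair = 200),
                            csf = c(t2 = 200, flair = 30),
                            background = c(t2 = 0, flair = 0)),
            seed = 1L))

setValidity("SceneParams", function(object) {
  msg <- character(0)
  if (length(object@gridShape) != 3 || any(object@gridShape <= 0))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (any(object@voxelSizeMm <= 0)) msg <- c(msg, "voxelSizeMm must be > 0")
  rngs <- list(object@pvsLengthRangeMm, object@pvsRadiusRangeMm,
               object@wmhRadiusRangeMm)
  if (any(vapply(rngs, function(r) length(r) != 2 || r[1] > r[2] ||
                   r[1] <= 0, logical(1))))
    msg <- c(msg, "ranges must be (min, max) with 0 < min <= max")
  for (p in c(object@pAttached, object@pPeriventricular))
    if (p < 0 || p > 1) msg <- c(msg, "probabilities must lie in [0,1]")
  if (object@nPvs < 0 || object@nWmh < 0)
    msg <- c(msg, "expected counts must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SceneParams-class
#' @param ... named slot overrides; \code{gridShape} and \code{seed} are
#'   coerced to integer.
#' @return A validated \code{SceneParams} object.
#' @export
sceneParams <- function(...) {
  args <- list(...)
  for (nm in c("gridShape", "seed"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c("SceneParams", args))
}

#' Longitudinal growth parameters
#'
#' Defaults mirror the observed between-wave dynamics: about 70% of deep
#' clusters grow between waves and about 73% of growing attached clusters
#' extend their PVS contact ("increase around").
#'
#' @slot pGrow probability a cluster grows between waves, default 0.70.
#' @slot pGrowAround probability a growing attached cluster extends its
#'   PVS contact, default 0.73.
#' @slot growthFactorRange multiplicative volume change for grown
#'   clusters; minimum >= 2 so grown clusters satisfy the doubling rule by
#'   construction.  Default (2, 4).
#' @slot pNewCluster Poisson rate of de-novo clusters per wave.
#' @slot seed integer RNG seed for the growth process.
#' @exportClass GrowthParams
setClass("GrowthParams",
  representation(pGrow = "numeric", pGrowAround = "numeric",
                 growthFactorRange = "numeric", pNewCluster = "numeric",
                 seed = "integer"),
  prototype(pGrow = 0.70, pGrowAround = 0.73,
            growthFactorRange = c(2, 4), pNewCluster = 1, seed = 1L))

setValidity("GrowthParams", function(object) {
  msg <- character(0)
  for (p in c(object@pGrow, object@pGrowAround))
    if (p < 0 || p > 1) msg <- c(msg, "probabilities must lie in [0,1]")
  g <- object@growthFactorRange
  if (length(g) != 2 || g[1] > g[2])
    msg <- c(msg, "growthFactorRange must be (min, max)")
  if (g[1] < 2)
    msg <- c(msg, "growthFactorRange minimum must be >= 2 (doubling rule)")
  if (object@pNewCluster < 0) msg <- c(msg, "pNewCluster must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname GrowthParams-class
#' @param ... named slot overrides; \code{seed} is coerced to integer.
#' @return A validated \code{GrowthParams} object.
#' @export
growthParams <- function(...) {
  args <- list(...)
  if (!is.null(args$seed)) args$seed <- as.integer(args$seed)
  do.call(new, c("GrowthParams", args))
}

#' Ground-truth scene
#'
#' Latent geometric description of one subject at one wave: tube
#' centrelines with radii, cluster shapes (unions of spheres grown over
#' waves), attachment flags and truth change labels, plus the brain /
#' ventricle / lobe geometry.  Used both to render volumes and to score
#' the pipeline in parameter-recovery tests.
#'
#' @slot tubes data.frame: id, ax..bz centreline endpoints (mm), radiusMm,
#'   lengthMm.
#' @slot clusters data.frame: id, cx, cy, cz seed centre (mm), radiusMm,
#'   attached, tubeId, pv (periventricular flag), waveOfBirth, region,
#'   changeLabel (truth label of the transition into this wave),
#'   lastGrowth (volume multiplier drawn, NA if not grown).
#' @slot shapes list over clusters: data.frame cx, cy, cz, r, noContact
#'   (spheres whose rasterisation must not create PVS contact).
#' @slot wave integer wave index (1-based).
#' @slot gridShape,voxelSizeMm native grid geometry.
#' @slot brainCenter,brainSemi,ventSemi,ventOffset mm geometry of the
#'   brain ellipsoid and the ventricular ellipsoid pair.
#' @exportClass GroundTruthScene
setClass("GroundTruthScene",
  representation(tubes = "data.frame", clusters = "data.frame",
                 shapes = "list", wave = "integer", gridShape = "integer",
                 voxelSizeMm = "numeric", brainCenter = "numeric",
                 brainSemi = "numeric", ventSemi = "numeric",
                 ventOffset = "numeric"))

setMethod("show", "GroundTruthScene", function(object) {
  cat(sprintf("GroundTruthScene wave %d: %d tubes, %d clusters (%d attached, %d periventricular)\n",
              object@wave, nrow(object@tubes), nrow(object@clusters),
              sum(object@clusters$attached), sum(object@clusters$pv)))
})

# ---- geometry helpers ----------------------------------------------------

.randUnit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

.inEllipsoid <- function(p, center, semi) {
  sum(((p - center) / semi)^2) <= 1
}

# distance from points P (n x 3, mm) to segment AB
.pointSegDist <- function(P, A, B) {
  u <- B - A
  L2 <- sum(u^2)
  W <- sweep(rbind(P), 2, A)
  t <- if (L2 > 0) pmin(1, pmax(0, (W %*% u) / L2)) else rep(0, nrow(W))
  D <- W - t %*% t(u)
  sqrt(rowSums(D^2))
}

# minimum distance between two segments, by dense sampling (adequate here)
.segSegDist <- function(A1, B1, A2, B2, n = 25) {
  t <- seq(0, 1, length.out = n)
  P1 <- outer(1 - t, A1) + outer(t, B1)
  min(vapply(seq_len(n), function(i)
    min(.pointSegDist(P1[i, , drop = FALSE] , A2, B2)), numeric(1)))
}

.ventCenters <- function(center, offset) {
  list(center + offset, center - offset)
}

.distToVentricles <- function(p, scene) {
  vc <- .ventCenters(scene$brainCenter, scene$ventOffset)
  # scaled pseudo-distance: positive outside; good enough for clearances
  min(vapply(vc, function(c0) {
    s <- sqrt(sum(((p - c0) / scene$ventSemi)^2))
    (s - 1) * min(scene$ventSemi)
  }, numeric(1)))
}

.distToTubes <- function(p, tubes) {
  if (!nrow(tubes)) return(Inf)
  min(vapply(seq_len(nrow(tubes)), function(i) {
    .pointSegDist(matrix(p, 1), c(tubes$ax[i], tubes$ay[i], tubes$az[i]),
                  c(tubes$bx[i], tubes$by[i], tubes$bz[i])) - tubes$radiusMm[i]
  }, numeric(1)))
}

.sampleBrainPoint <- function(geom, margin = 0) {
  semi <- pmax(geom$brainSemi - margin, 1)
  repeat {
    p <- geom$brainCenter + stats::runif(3, -1, 1) * semi
    if (.inEllipsoid(p, geom$brainCenter, semi)) return(p)
  }
}

# ---- scene generation ----------------------------------------------------

.sceneGeometry <- function(params) {
  extent <- params@gridShape * params@voxelSizeMm
  center <- extent / 2
  list(brainCenter = center,
       brainSemi = 0.44 * extent,
       ventSemi = c(3.5, 9, 5),
       ventOffset = c(6, 0, 0))
}

.placeTubes <- function(nT, params, geom) {
  tubes <- data.frame(id = integer(0), ax = numeric(0), ay = numeric(0),
                      az = numeric(0), bx = numeric(0), by = numeric(0),
                      bz = numeric(0), radiusMm = numeric(0),
                      lengthMm = numeric(0))
  if (!nT) return(tubes)
  for (i in seq_len(nT)) {
    L <- stats::runif(1, params@pvsLengthRangeMm[1],
                      min(params@pvsLengthRangeMm[2],
                          1.6 * min(geom$brainSemi)))
    r <- stats::runif(1, params@pvsRadiusRangeMm[1],
                      params@pvsRadiusRangeMm[2])
    placed <- FALSE
    for (try in 1:300) {
      if (try %% 60 == 0) L <- max(params@pvsLengthRangeMm[1], 0.8 * L)
      cen <- .sampleBrainPoint(geom, margin = L / 4)
      u <- .randUnit()
      A <- cen - u * L / 2; B <- cen + u * L / 2
      pts <- outer(1 - seq(0, 1, length.out = 9), A) +
        outer(seq(0, 1, length.out = 9), B)
      okBrain <- all(apply(pts, 1, .inEllipsoid,
                           center = geom$brainCenter,
                           semi = geom$brainSemi - (r + 1.5)))
      if (!okBrain) next
      okVent <- all(apply(pts, 1, function(p)
        .distToVentricles(p, geom) > r + 4.5))
      if (!okVent) next
      okSep <- TRUE
      if (nrow(tubes)) {
        for (j in seq_len(nrow(tubes))) {
          d <- .segSegDist(A, B, c(tubes$ax[j], tubes$ay[j], tubes$az[j]),
                           c(tubes$bx[j], tubes$by[j], tubes$bz[j]))
          if (d < r + tubes$radiusMm[j] + 4) { okSep <- FALSE; break }
        }
      }
      if (!okSep) next
      tubes <- rbind(tubes, data.frame(id = nrow(tubes) + 1L,
                                       ax = A[1], ay = A[2], az = A[3],
                                       bx = B[1], by = B[2], bz = B[3],
                                       radiusMm = r,
                                       lengthMm = sqrt(sum((B - A)^2))))
      placed <- TRUE
      break
    }
    if (!placed) next                    # brain too crowded; tube skipped
  }
  tubes
}

# clearance an unattached cluster needs so that compound inflated growth
# over two transitions (volume x 1.3*16 worst case) cannot reach a tube:
# radius headroom plus a contiguity margin.
.unattachedClearance <- function(r) max(4, ((1.3 * 16)^(1/3) - 1) * r + 3)

.placeCluster <- function(kind, r, params, geom, tubes, clusters) {
  # kind: "attached", "unattached", "pv"
  gapMargin <- function(p, shrink) {
    if (!nrow(clusters)) return(Inf)
    d <- sqrt(rowSums(sweep(as.matrix(clusters[, c("cx", "cy", "cz")]),
                            2, p)^2))
    min(d - (shrink * 2 * (r + clusters$radiusMm) + 2))
  }
  clusterGap <- function(p, shrink) gapMargin(p, shrink) > 0
  best <- NULL; bestScore <- -Inf
  for (relax in c(1, 0.75, 0.5)) {
    for (try in 1:400) {
      if (kind == "attached") {
        ti <- sample.int(nrow(tubes), 1)
        t0 <- stats::runif(1, 0.1, 0.9)
        A <- c(tubes$ax[ti], tubes$ay[ti], tubes$az[ti])
        B <- c(tubes$bx[ti], tubes$by[ti], tubes$bz[ti])
        pt <- A + t0 * (B - A)
        u <- .randUnit()
        ax <- (B - A) / sqrt(sum((B - A)^2))
        u <- u - sum(u * ax) * ax
        if (sqrt(sum(u^2)) < 1e-6) next
        u <- u / sqrt(sum(u^2))
        # seed centre within one voxel of the tube surface
        p <- pt + u * (tubes$radiusMm[ti] + stats::runif(1, 0, 0.8))
      } else if (kind == "pv") {
        vc <- .ventCenters(geom$brainCenter, geom$ventOffset)[[sample.int(2, 1)]]
        n <- .randUnit()
        surf <- vc + n * geom$ventSemi   # on the ellipsoid for unit n
        p <- surf + n * (0.5 * r)
      } else {
        p <- .sampleBrainPoint(geom, margin = r + 2)
      }
      if (!.inEllipsoid(p, geom$brainCenter,
                        pmax(geom$brainSemi - (1.6 * r + 2), 2)))
        next   # growth headroom: grown clusters must not hit the brain edge
      dv <- .distToVentricles(p, geom)
      dt <- .distToTubes(p, tubes)
      ok <- switch(kind,
        attached = dv > r + 4 && clusterGap(p, relax),
        unattached = dv > r + 4 && dt > r + .unattachedClearance(r) &&
          clusterGap(p, relax),
        pv = dv < r * 0.9 && dv > -r && dt > r + 2 && clusterGap(p, relax))
      score <- switch(kind,
        attached = min(dv, gapMargin(p, 1)),
        unattached = min(dv, dt - r, gapMargin(p, 1)),
        pv = min(dt, gapMargin(p, 1)))
      if (ok) return(list(p = p,
                          tubeId = if (kind == "attached") ti else NA_integer_))
      if (is.finite(score) && score > bestScore) {
        bestScore <- score
        best <- list(p = p,
                     tubeId = if (kind == "attached") ti else NA_integer_)
      }
    }
  }
  best    # fall back to the best candidate; mask carving keeps truth valid
}

#' Generate a ground-truth scene
#'
#' Places a Poisson number of tubes (rejection-sampled to lie inside the
#' brain and away from the ventricles) and a Poisson number of clusters:
#' with probability \code{pPeriventricular} a cluster is seeded contiguous
#' with the ventricular surface; otherwise it is a deep cluster, seeded
#' contiguous to a random tube with probability \code{pAttached} and
#' otherwise placed with enough clearance that later growth cannot reach a
#' tube.  Deterministic given \code{params@seed}.
#'
#' @param params \code{\linkS4class{SceneParams}}.
#' @return A \code{\linkS4class{GroundTruthScene}} at wave 1.
#' @export
generateScene <- function(params = sceneParams()) {
  validObject(params)
  if (any(params@gridShape < 16L))
    stop("degenerate grid: every axis needs >= 16 voxels to host a 3 mm tube")
  set.seed(params@seed)
  geom <- .sceneGeometry(params)
  nT <- stats::rpois(1, params@nPvs)
  tubes <- .placeTubes(nT, params, geom)
  # truncate the cluster draw: a 56 mm synthetic brain cannot host many
  # compound-growing clusters without wholesale coalescence
  nC <- min(stats::rpois(1, params@nWmh), 6L)
  clusters <- data.frame(id = integer(0), cx = numeric(0), cy = numeric(0),
                         cz = numeric(0), radiusMm = numeric(0),
                         attached = logical(0), tubeId = integer(0),
                         pv = logical(0), waveOfBirth = integer(0),
                         changeLabel = character(0), lastGrowth = numeric(0),
                         closeTarget = numeric(0))
  shapes <- list()
  for (i in seq_len(nC)) {
    r <- stats::runif(1, params@wmhRadiusRangeMm[1], params@wmhRadiusRangeMm[2])
    pv <- stats::runif(1) < params@pPeriventricular
    attached <- !pv && nrow(tubes) > 0 && stats::runif(1) < params@pAttached
    kind <- if (pv) "pv" else if (attached) "attached" else "unattached"
    pl <- .placeCluster(kind, r, params, geom, tubes, clusters)
    if (is.null(pl)) next
    clusters <- rbind(clusters, data.frame(
      id = nrow(clusters) + 1L, cx = pl$p[1], cy = pl$p[2], cz = pl$p[3],
      radiusMm = r, attached = attached, tubeId = pl$tubeId, pv = pv,
      waveOfBirth = 1L, changeLabel = NA_character_,
      lastGrowth = NA_real_, closeTarget = 1))
    shapes[[length(shapes) + 1L]] <- data.frame(
      cx = pl$p[1], cy = pl$p[2], cz = pl$p[3], r = r,
      noContact = !attached && !pv)
  }
  new("GroundTruthScene", tubes = tubes, clusters = clusters,
      shapes = shapes, wave = 1L, gridShape = params@gridShape,
      voxelSizeMm = params@voxelSizeMm, brainCenter = geom$brainCenter,
      brainSemi = geom$brainSemi, ventSemi = geom$ventSemi,
      ventOffset = geom$ventOffset)
}

#' Evolve a scene to the next wave
#'
#' Each existing cluster grows with probability \code{pGrow} by a volume
#' multiplier drawn from \code{growthFactorRange}.  A growing attached
#' cluster extends along/around its tube (isotropic similarity growth
#' about its seed, which lies on the tube surface, so PVS contact grows)
#' with probability \code{pGrowAround}; otherwise a growth lobe is added
#' on the far side of the tube and rasterised so that no new PVS contact
#' can arise, keeping contact exactly constant ("increase close" by
#' construction).  Unattached growing clusters grow isotropically.  New
#' clusters appear at Poisson rate \code{pNewCluster}.  Truth change
#' labels for the transition are recorded in \code{clusters$changeLabel}.
#' Cluster ids are conserved (growth/coalescence only, no disappearance).
#'
#' @param scene \code{\linkS4class{GroundTruthScene}}.
#' @param growth \code{\linkS4class{GrowthParams}}.
#' @param waveIndex transition index (>= 1); transition w -> w+1 has index
#'   w and must match \code{scene@wave}.
#' @param params the \code{\linkS4class{SceneParams}} the scene was built
#'   with (needed for seeding new clusters).
#' @return The scene at wave \code{scene@wave + 1}.
#' @export
evolveScene <- function(scene, growth = growthParams(), waveIndex = scene@wave,
                        params = sceneParams()) {
  if (waveIndex < 1) stop("waveIndex must be >= 1")
  if (waveIndex != scene@wave)
    stop("waveIndex (", waveIndex, ") does not match scene wave (",
         scene@wave, ")")
  set.seed(growth@seed + 7919L * waveIndex)
  geom <- list(brainCenter = scene@brainCenter, brainSemi = scene@brainSemi,
               ventSemi = scene@ventSemi, ventOffset = scene@ventOffset)
  clusters <- scene@clusters
  shapes <- scene@shapes
  tubes <- scene@tubes
  nPre <- nrow(clusters)
  for (i in seq_len(nPre)) {
    grow <- stats::runif(1) < growth@pGrow
    if (!grow) {
      clusters$changeLabel[i] <- "no_increase"
      clusters$lastGrowth[i] <- NA_real_
      next
    }
    m <- stats::runif(1, growth@growthFactorRange[1],
                      growth@growthFactorRange[2])
    # collision-aware cap: shrink the drawn multiplier (never below the
    # doubling minimum) when full growth would overlap a neighbouring
    # cluster, keeping coalescence the exception rather than the rule
    sh <- shapes[[i]]
    r0 <- max(sh$r)
    others <- setdiff(seq_len(nPre), i)
    if (length(others)) {
      d <- sqrt((clusters$cx[others] - clusters$cx[i])^2 +
                (clusters$cy[others] - clusters$cy[i])^2 +
                (clusters$cz[others] - clusters$cz[i])^2)
      rOther <- vapply(shapes[others], function(s) max(s$r), numeric(1))
      # reserve doubling headroom for the neighbours too
      rAllow <- min(d - 1.3 * rOther - 2)
      if (is.finite(rAllow) && rAllow > 0) {
        mAllow <- (rAllow / r0)^3 / 1.3
        m <- max(growth@growthFactorRange[1], min(m, mAllow))
      }
    }
    clusters$lastGrowth[i] <- m
    # rasterisation and mask refinement erode boundaries, so the latent
    # geometry is inflated by a margin: the drawn multiplier m targets the
    # volume ratio of the emitted masks, keeping the doubling rule true of
    # the data and not just of the geometry
    isoGrow <- function(sh) {
      f <- (1.3 * m)^(1 / 3)
      c0 <- as.numeric(sh[1, c("cx", "cy", "cz")])
      sh$r <- sh$r * f
      sh[, c("cx", "cy", "cz")] <-
        sweep(as.matrix(sh[, c("cx", "cy", "cz")]), 2, c0) * f +
        matrix(c0, nrow(sh), 3, byrow = TRUE)
      sh
    }
    if (clusters$pv[i]) {
      shapes[[i]] <- isoGrow(sh)
      clusters$changeLabel[i] <- NA_character_   # pv clusters not labelled
    } else if (clusters$attached[i]) {
      around <- stats::runif(1) < growth@pGrowAround
      if (around) {
        shapes[[i]] <- isoGrow(sh)
        clusters$changeLabel[i] <- "increase_around"
      } else {
        # contact-preserving growth: the sphere geometry is frozen and the
        # rasteriser dilates the cluster mask outside the PVS carve zone
        # until its voxel count reaches closeTarget times the sphere-only
        # count.  Contact is frozen exactly; the mask at least doubles.
        clusters$closeTarget[i] <- clusters$closeTarget[i] * m
        clusters$changeLabel[i] <- "increase_close"
      }
    } else {
      shapes[[i]] <- isoGrow(sh)
      clusters$changeLabel[i] <- "increase_not_close"
    }
  }
  # de-novo clusters (capped alongside the seeding truncation)
  nNew <- min(stats::rpois(1, growth@pNewCluster),
              max(0L, 7L - nrow(clusters)))
  for (k in seq_len(nNew)) {
    r <- stats::runif(1, params@wmhRadiusRangeMm[1], params@wmhRadiusRangeMm[2])
    attached <- nrow(tubes) > 0 && stats::runif(1) < params@pAttached
    kind <- if (attached) "attached" else "unattached"
    pl <- .placeCluster(kind, r, params, geom, tubes, clusters)
    if (is.null(pl)) next
    clusters <- rbind(clusters, data.frame(
      id = nrow(clusters) + 1L, cx = pl$p[1], cy = pl$p[2], cz = pl$p[3],
      radiusMm = r, attached = attached, tubeId = pl$tubeId, pv = FALSE,
      waveOfBirth = scene@wave + 1L, changeLabel = NA_character_,
      lastGrowth = NA_real_, closeTarget = 1))
    shapes[[length(shapes) + 1L]] <- data.frame(
      cx = pl$p[1], cy = pl$p[2], cz = pl$p[3], r = r,
      noContact = !attached)
  }
  new("GroundTruthScene", tubes = tubes, clusters = clusters,
      shapes = shapes, wave = scene@wave + 1L, gridShape = scene@gridShape,
      voxelSizeMm = scene@voxelSizeMm, brainCenter = scene@brainCenter,
      brainSemi = scene@brainSemi, ventSemi = scene@ventSemi,
      ventOffset = scene@ventOffset)
}

# ---- rasterisation -------------------------------------------------------

.coordArrays <- function(shape, spacing) {
  xs <- (seq_len(shape[1]) - 1) * spacing[1]
  ys <- (seq_len(shape[2]) - 1) * spacing[2]
  zs <- (seq_len(shape[3]) - 1) * spacing[3]
  list(x = array(rep(xs, times = shape[2] * shape[3]), shape),
       y = array(rep(rep(ys, each = shape[1]), times = shape[3]), shape),
       z = array(rep(zs, each = shape[1] * shape[2]), shape))
}

.rasterEllipsoid <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 <= 1
}

.rasterSphere <- function(co, center, r) {
  (co$x - center[1])^2 + (co$y - center[2])^2 + (co$z - center[3])^2 <= r^2
}

.rasterTube <- function(co, A, B, r, spacing) {
  reff <- max(r, 0.5 * max(spacing))     # keep thin tubes contiguous
  u <- B - A
  L2 <- sum(u^2)
  wx <- co$x - A[1]; wy <- co$y - A[2]; wz <- co$z - A[3]
  t <- (wx * u[1] + wy * u[2] + wz * u[3]) / L2
  t[t < 0] <- 0; t[t > 1] <- 1
  dx <- wx - t * u[1]; dy <- wy - t * u[2]; dz <- wz - t * u[3]
  dx * dx + dy * dy + dz * dz <= reff^2
}

#' Rasterise the truth geometry of a scene on an arbitrary grid
#'
#' Produces the anatomical masks (brain, ventricles, lobe label map) and
#' the noise-free truth masks for PVS and WMH, plus per-cluster truth
#' voxel sets.  Growth lobes flagged no-contact are carved away from the
#' 3-voxel Chebyshev neighbourhood of the PVS mask so that truth change
#' labels are true of the emitted masks by construction, with headroom for
#' the segmented PVS mask extending slightly beyond the truth tubes.
#'
#' @param scene \code{\linkS4class{GroundTruthScene}}.
#' @param spacing numeric(3); defaults to the scene's native spacing.
#' @return list: brain, ventricles, lobes (1 frontal, 2 parietal,
#'   3 temporal, 4 occipital), truthPvs, truthWmh (logical arrays),
#'   clusterVoxels (list over cluster ids), tubeVoxels (list over tubes),
#'   spacing, shape.
#' @export
rasterizeScene <- function(scene, spacing = scene@voxelSizeMm) {
  extent <- scene@gridShape * scene@voxelSizeMm
  shape <- as.integer(floor(extent / spacing + 0.5))
  co <- .coordArrays(shape, spacing)
  brain <- .rasterEllipsoid(co, scene@brainCenter, scene@brainSemi)
  vc <- .ventCenters(scene@brainCenter, scene@ventOffset)
  vent <- .rasterEllipsoid(co, vc[[1]], scene@ventSemi) |
    .rasterEllipsoid(co, vc[[2]], scene@ventSemi)
  cen <- scene@brainCenter
  lobes <- array(0L, shape)
  lobes[brain] <- ifelse(co$y[brain] > cen[2], 1L,
                    ifelse(co$z[brain] > cen[3], 2L,
                      ifelse(co$x[brain] <= cen[1], 3L, 4L)))
  pvs <- array(FALSE, shape)
  tubeVoxels <- vector("list", nrow(scene@tubes))
  for (i in seq_len(nrow(scene@tubes))) {
    tb <- scene@tubes[i, ]
    m <- .rasterTube(co, c(tb$ax, tb$ay, tb$az), c(tb$bx, tb$by, tb$bz),
                     tb$radiusMm, spacing) & brain & !vent
    tubeVoxels[[i]] <- which(m, arr.ind = TRUE)
    pvs <- pvs | m
  }
  # no-contact carve: a 3 mm Chebyshev margin around the PVS, honoured
  # per axis so anisotropic native grids carve the same physical distance
  carveReach <- pmax(1L, as.integer(ceiling(3 / spacing)))
  carve <- if (any(pvs)) .dilateBox(pvs, carveReach) else pvs
  wmh <- array(FALSE, shape)
  clusterVoxels <- vector("list", nrow(scene@clusters))
  for (i in seq_len(nrow(scene@clusters))) {
    sh <- scene@shapes[[i]]
    m <- array(FALSE, shape)
    for (s in seq_len(nrow(sh))) {
      ms <- .rasterSphere(co, as.numeric(sh[s, c("cx", "cy", "cz")]), sh$r[s])
      if (sh$noContact[s]) ms <- ms & !carve
      m <- m | ms
    }
    m <- m & brain & !vent
    ct <- scene@clusters$closeTarget[i]
    if (ct > 1 && any(m)) {
      # contact-preserving growth: dilate outside the carve until the
      # voxel count reaches the target multiple (with a margin for the
      # erosion that segmentation refinement applies at the rim)
      target <- ceiling(1.15 * ct * sum(m))
      cen <- as.numeric(scene@clusters[i, c("cx", "cy", "cz")])
      for (it in 1:10) {
        if (sum(m) >= target) break
        grown <- m | (.dilate(m, 26, 1L) & !carve & brain & !vent)
        if (sum(grown) == sum(m)) break           # nowhere left to grow
        if (sum(grown) > target) {
          # trim the final shell to the target count, keeping the voxels
          # nearest the seed centre (every shell voxel touches the
          # previous mask, so any subset stays connected)
          shell <- which(grown & !m, arr.ind = TRUE)
          need <- target - sum(m)
          dmm <- sweep(sweep(shell - 1, 2, spacing, `*`), 2, cen)
          ord <- order(rowSums(dmm^2), shell[, 3], shell[, 2], shell[, 1])
          keep <- shell[ord[seq_len(need)], , drop = FALSE]
          m[keep] <- TRUE
          break
        }
        m <- grown
      }
    }
    clusterVoxels[[i]] <- which(m, arr.ind = TRUE)
    wmh <- wmh | m
  }
  list(brain = brain, ventricles = vent, lobes = lobes, truthPvs = pvs,
       truthWmh = wmh, clusterVoxels = clusterVoxels,
       tubeVoxels = tubeVoxels, spacing = spacing, shape = shape)
}

#' Render T2/FLAIR volumes and masks for one wave
#'
#' Rasterises the scene on its native grid and fills per-class mean
#' intensities from the contrast table (tissue inside the brain, CSF in
#' the ventricles, WMH in clusters, PVS in tubes -- PVS take precedence
#' inside WMH, giving the bright-on-T2 / dark-on-FLAIR pattern the fused
#' image exploits), then adds zero-mean Gaussian noise of SD
#' \code{noiseSd}.  Truth masks are noise-free.  Deterministic given
#' \code{params@seed} and \code{waveIndex}.
#'
#' @param scene \code{\linkS4class{GroundTruthScene}}.
#' @param params \code{\linkS4class{SceneParams}}.
#' @param waveIndex wave being rendered (defaults to the scene's wave).
#' @return list of \code{\linkS4class{VoxelGrid}}s: t2, flair, brain,
#'   ventricles, lobes, truthPvs, truthWmh, plus the raster list.
#' @export
renderVolumes <- function(scene, params = sceneParams(),
                          waveIndex = scene@wave) {
  needed <- c("tissue", "pvs", "wmh", "csf", "background")
  missing <- setdiff(needed, names(params@contrast))
  if (length(missing))
    stop("contrast table missing tissue class(es): ",
         paste(missing, collapse = ", "))
  ras <- rasterizeScene(scene)
  sp <- scene@voxelSizeMm
  mk <- function(chan) {
    ct <- params@contrast
    v <- array(ct$background[[chan]], ras$shape)
    v[ras$brain] <- ct$tissue[[chan]]
    v[ras$ventricles] <- ct$csf[[chan]]
    v[ras$truthWmh] <- ct$wmh[[chan]]
    v[ras$truthPvs] <- ct$pvs[[chan]]
    v
  }
  t2 <- mk("t2"); flair <- mk("flair")
  set.seed(params@seed + 104729L * waveIndex + 17L)
  if (params@noiseSd > 0) {
    t2 <- t2 + array(stats::rnorm(length(t2), 0, params@noiseSd), ras$shape)
    flair <- flair + array(stats::rnorm(length(flair), 0, params@noiseSd),
                           ras$shape)
  }
  list(t2 = voxelGrid(t2, sp), flair = voxelGrid(flair, sp),
       brain = voxelGrid(ras$brain + 0, sp),
       ventricles = voxelGrid(ras$ventricles + 0, sp),
       lobes = voxelGrid(ras$lobes + 0, sp),
       truthPvs = voxelGrid(ras$truthPvs + 0, sp),
       truthWmh = voxelGrid(ras$truthWmh + 0, sp),
       raster = ras)
}

#' Write a longitudinal fixture to disk
#'
#' Writes, per wave, gzipped NIfTI-1 volumes and masks, one CSV of truth
#' clusters (id, wave, attached, pv, truth change label, volumeMl) and one
#' JSON file with the parameter set.
#'
#' @param scenes list of \code{\linkS4class{GroundTruthScene}}s (one per
#'   wave).
#' @param params \code{\linkS4class{SceneParams}}.
#' @param outDir output directory (created if absent).
#' @param growth optional \code{\linkS4class{GrowthParams}} echoed into
#'   the JSON.
#' @return Invisibly, the vector of files written.
#' @export
writeFixture <- function(scenes, params, outDir, growth = NULL) {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  files <- character(0)
  truth <- NULL
  for (scene in scenes) {
    vols <- renderVolumes(scene, params)
    w <- scene@wave
    for (nm in c("t2", "flair", "brain", "ventricles", "lobes",
                 "truthPvs", "truthWmh")) {
      path <- file.path(outDir, sprintf("wave%d_%s.nii.gz", w, nm))
      writeVolume(vols[[nm]], path)
      files <- c(files, path)
    }
    vox <- prod(scene@voxelSizeMm) / 1000
    cl <- scene@clusters
    vols_ml <- vapply(vols$raster$clusterVoxels,
                      function(v) nrow(rbind(v)) * vox, numeric(1))
    truth <- rbind(truth, data.frame(
      id = cl$id, wave = w, attached = cl$attached, pv = cl$pv,
      changeLabel = cl$changeLabel, volumeMl = vols_ml))
  }
  truthPath <- file.path(outDir, "truth_clusters.csv")
  utils::write.csv(truth, truthPath, row.names = FALSE)
  parPath <- file.path(outDir, "params.json")
  pj <- list(gridShape = params@gridShape, voxelSizeMm = params@voxelSizeMm,
             nPvs = params@nPvs, pvsLengthRangeMm = params@pvsLengthRangeMm,
             pvsRadiusRangeMm = params@pvsRadiusRangeMm, nWmh = params@nWmh,
             pAttached = params@pAttached,
             pPeriventricular = params@pPeriventricular,
             wmhRadiusRangeMm = params@wmhRadiusRangeMm,
             noiseSd = params@noiseSd, seed = params@seed)
  if (!is.null(growth))
    pj$growth <- list(pGrow = growth@pGrow, pGrowAround = growth@pGrowAround,
                      growthFactorRange = growth@growthFactorRange,
                      pNewCluster = growth@pNewCluster, seed = growth@seed)
  jsonlite::write_json(pj, parPath, auto_unbox = TRUE, digits = NA)
  invisible(c(files, truthPath, parPath))
}
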