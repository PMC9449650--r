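# Automated topology classification: close/not-close of deep WMH clusters
# to baseline PVS, lobar region assignment, wave-to-wave cluster matching,
# and the four-way longitudinal change label.

#' Count cluster voxels in contact with a PVS mask
#'
#' A cluster voxel is "in contact" when it is itself a PVS voxel (overlap)
#' or has a PVS voxel in its neighbourhood (contiguity; 26-neighbourhood by
#' default, so corner contact counts).
#'
#' @param voxels n x 3 matrix of 1-based cluster voxel indices.
#' @param pvsMask logical array or 0/1 \code{VoxelGrid}.
#' @param connectivity 26 (default) or 6.
#' @return Integer count.
#' @export
contactVoxels <- function(voxels, pvsMask, connectivity = 26) {
  pm <- .asLogicalArr(pvsMask)
  if (!any(pm)) return(0L)
  touch <- pm | .dilate(pm, connectivity, 1L)
  sum(touch[rbind(voxels)])
}

#' Cross-sectional close / not-close classification
#'
#' Each deep cluster is "close" to the baseline PVS when its mask overlaps
#' or is contiguous with a PVS, and "not close" otherwise.
#'
#' @param clusters cluster table with depthClass filled; periventricular
#'   rows are rejected.
#' @param baselinePvs logical array or 0/1 \code{VoxelGrid}: wave-1 PVS.
#' @param params \code{\linkS4class{ChangeParams}}.
#' @return The table with \code{topologyLabel} and \code{contact} filled.
#' @export
classifyCrossSectional <- function(clusters, baselinePvs,
                                   params = changeParams()) {
  if (nrow(clusters) && any(clusters$depthClass == "periventricular", na.rm = TRUE))
    stop("classifyCrossSectional expects deep clusters only")
  pm <- .asLogicalArr(baselinePvs)
  touch <- if (any(pm)) pm | .dilate(pm, params@contactConnectivity, 1L)
           else pm
  cnt <- vapply(clusters$voxels, function(v) sum(touch[rbind(v)]), numeric(1))
  clusters$contact <- as.integer(cnt)
  clusters$topologyLabel <- ifelse(cnt > 0, "close", "not_close")
  clusters
}

#' Assign a lobar region to each cluster
#'
#' Region = majority lobe label over the cluster's voxels; ties are broken
#' by the lobe containing the cluster centroid, then by the fixed order
#' frontal > parietal > temporal > occipital.
#'
#' @param clusters cluster table.
#' @param lobes integer array or \code{VoxelGrid} coding 1 = frontal,
#'   2 = parietal, 3 = temporal, 4 = occipital (0 = unlabelled).
#' @return The table with \code{region} filled.
#' @export
assignRegion <- function(clusters, lobes) {
  lab <- if (is(lobes, "VoxelGrid")) gridValues(lobes) else lobes
  lobeNames <- c("frontal", "parietal", "temporal", "occipital")
  reg <- character(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    vox <- clusters$voxels[[i]]
    lv <- lab[rbind(vox)]
    lv <- lv[lv >= 1 & lv <= 4]
    if (!length(lv)) stop("cluster ", clusters$id[i],
                          " lies entirely outside the labelled region")
    tab <- tabulate(lv, 4)
    winners <- which(tab == max(tab))
    if (length(winners) > 1L) {
      cen <- round(colMeans(rbind(clusters$voxels[[i]])))
      cen <- pmin(pmax(cen, 1), dim(lab))
      cl <- lab[cen[1], cen[2], cen[3]]
      if (cl %in% winners) winners <- cl
    }
    reg[i] <- lobeNames[min(winners)]
  }
  clusters$region <- reg
  clusters
}

#' Match clusters across consecutive waves
#'
#' Each earlier-wave cluster maps to the later-wave cluster with maximal
#' voxel overlap (above \code{matchOverlapMin} of the earlier cluster's
#' size); several earlier clusters may map to one later cluster
#' (coalescence).  Later-wave clusters with no overlap are new.
#'
#' @param clustersA,clustersB cluster tables at the earlier/later wave, on
#'   one grid.
#' @param dims grid dimensions (integer(3)).
#' @param params \code{\linkS4class{ChangeParams}}.
#' @return A list with \code{map} (data.frame idA, idB, overlap) and
#'   \code{unmatchedNew} (idB of de-novo clusters).
#' @export
matchClusters <- function(clustersA, clustersB, dims,
                          params = changeParams()) {
  keyOf <- function(v) {
    v <- rbind(v)
    v[, 1] + dims[1] * (v[, 2] - 1) + dims[1] * dims[2] * (v[, 3] - 1)
  }
  keysB <- lapply(clustersB$voxels, keyOf)
  map <- data.frame(idA = integer(0), idB = integer(0), overlap = integer(0))
  for (i in seq_len(nrow(clustersA))) {
    ka <- keyOf(clustersA$voxels[[i]])
    ov <- vapply(keysB, function(kb) sum(ka %in% kb), numeric(1))
    if (length(ov) && max(ov) > 0 &&
        max(ov) / length(ka) > params@matchOverlapMin) {
      j <- which.max(ov)
      map <- rbind(map, data.frame(idA = clustersA$id[i],
                                   idB = clustersB$id[j],
                                   overlap = as.integer(max(ov))))
    }
  }
  list(map = map,
       unmatchedNew = setdiff(clustersB$id, map$idB))
}

#' Between-wave WMH growth mask
#'
#' @param maskA,maskB logical arrays or 0/1 \code{VoxelGrid}s at the
#'   earlier and later wave.
#' @return Logical array: voxels hyperintense at the later wave only.
#' @export
changeMask <- function(maskA, maskB) {
  a <- .asLogicalArr(maskA); b <- .asLogicalArr(maskB)
  if (!identical(dim(a), dim(b))) stop("grids differ")
  b & !a
}

#' Longitudinal four-way change classification
#'
#' Volumes and PVS-contact counts at both waves are compared against the
#' same baseline (wave-1) PVS mask.  A cluster has "increased" when its
#' later-wave volume is at least \code{sizeChangeFactor} (default 2) times
#' its earlier volume; for coalesced many-to-one matches the earlier volume
#' and contact are summed over the merged parents.  Labels:
#' \itemize{
#'   \item increase_around: increased and contact grew;
#'   \item increase_close: increased, in contact, contact did not grow;
#'   \item increase_not_close: increased with no contact at the later wave;
#'   \item no_increase: everything else (clusters that shrank by half or
#'     more are labelled no_increase and flagged in the returned table).
#' }
#'
#' @param match result of \code{\link{matchClusters}}.
#' @param clustersA,clustersB cluster tables with \code{contact} filled
#'   (run \code{\link{classifyCrossSectional}} against the baseline PVS on
#'   both waves first).
#' @param params \code{\linkS4class{ChangeParams}}.
#' @return data.frame, one row per earlier-wave cluster: idA, idB, region,
#'   volumeA/B, contactA/B, changeLabel, halved.
#' @export
classifyChange <- function(match, clustersA, clustersB,
                           params = changeParams()) {
  m <- match$map
  out <- data.frame(idA = clustersA$id,
                    idB = NA_integer_,
                    region = clustersA$region,
                    volumeA = clustersA$volumeMl,
                    volumeB = NA_real_,
                    contactA = clustersA$contact,
                    contactB = NA_integer_,
                    changeLabel = NA_character_,
                    halved = FALSE)
  for (i in seq_len(nrow(out))) {
    row <- m[m$idA == out$idA[i], ]
    if (!nrow(row)) {
      # disappeared (not modelled by the generator, but handle gracefully)
      out$volumeB[i] <- 0; out$contactB[i] <- 0L
      out$changeLabel[i] <- "no_increase"; out$halved[i] <- TRUE
      next
    }
    idB <- row$idB[1]
    siblings <- m$idA[m$idB == idB]      # parents merged into the same child
    volA <- sum(clustersA$volumeMl[clustersA$id %in% siblings])
    conA <- sum(clustersA$contact[clustersA$id %in% siblings])
    jB <- which(clustersB$id == idB)
    volB <- clustersB$volumeMl[jB]
    conB <- clustersB$contact[jB]
    increased <- volB >= params@sizeChangeFactor * volA
    lab <- if (!increased) "no_increase"
      else if (conB > conA) "increase_around"
      else if (conB == 0) "increase_not_close"
      else "increase_close"
    out$idB[i] <- idB
    out$volumeB[i] <- volB
    out$contactB[i] <- as.integer(conB)
    out$changeLabel[i] <- lab
    out$halved[i] <- volB <= volA / params@sizeChangeFactor
  }
  # consistency assertions (run on every call)
  stopifnot(all(out$contactB[out$changeLabel == "increase_around"] > 0))
  stopifnot(all(out$contactB[out$changeLabel == "increase_not_close"] == 0))
  out
}
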