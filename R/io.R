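# NIfTI-1 I/O and configuration loading.

#' Read / write volumes, masks and label maps
#'
#' Thin wrappers around RNifti.  Spacing is taken from the header pixdim;
#' masks are validated to contain only 0/1 and label maps only values from
#' a known vocabulary.  Co-loaded grids can be checked for shape/spacing
#' equality with \code{\link{.checkSameGrid}} semantics via
#' \code{checkGrids}.
#'
#' @param path file path of a NIfTI-1 (.nii / .nii.gz) volume.
#' @return A \code{\linkS4class{VoxelGrid}}.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3-D volume: ", path)
  arr <- array(as.numeric(img), dim = dim(img))   # strip the niftiImage class
  sp <- RNifti::pixdim(img)[1:3]
  voxelGrid(arr, sp)
}

#' @rdname readVolume
#' @param vol \code{\linkS4class{VoxelGrid}} to write.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(gridValues(vol))
  RNifti::pixdim(img) <- gridSpacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname readVolume
#' @export
readMask <- function(path) {
  g <- readVolume(path)
  v <- gridValues(g)
  if (!all(v %in% c(0, 1)))
    stop("mask file contains non-binary values: ", path)
  g
}

#' @rdname readVolume
#' @param vocabulary admissible label values (0 = unlabelled allowed).
#' @export
readLabels <- function(path, vocabulary = 0:4) {
  g <- readVolume(path)
  v <- gridValues(g)
  bad <- setdiff(unique(as.vector(v)), vocabulary)
  if (length(bad))
    stop("label map ", path, " contains values outside the vocabulary: ",
         paste(bad, collapse = ", "))
  g
}

#' @rdname readVolume
#' @param ... \code{VoxelGrid}s that must share one grid.
#' @export
checkGrids <- function(...) {
  gs <- list(...)
  for (i in seq_along(gs)[-1]) .checkSameGrid(gs[[1]], gs[[i]])
  invisible(TRUE)
}

#' Load a pipeline configuration
#'
#' Reads a YAML configuration with optional blocks \code{scene},
#' \code{growth}, \code{frangi}, \code{wmh}, \code{change} (passed to the
#' corresponding parameter constructors, which validate their invariants),
#' plus \code{seed}, \code{waves}, \code{nSubjects} and \code{outDir}.
#'
#' @param path YAML file.
#' @return list with validated parameter objects and run settings.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  mk <- function(block, ctor) do.call(ctor, if (is.null(cfg[[block]]))
    list() else cfg[[block]])
  out <- list(
    scene = mk("scene", sceneParams),
    growth = mk("growth", growthParams),
    frangi = mk("frangi", frangiParams),
    wmh = mk("wmh", wmhSegParams),
    change = mk("change", changeParams),
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
    waves = if (is.null(cfg$waves)) 3L else as.integer(cfg$waves),
    nSubjects = if (is.null(cfg$nSubjects)) 1L else as.integer(cfg$nSubjects),
    outDir = if (is.null(cfg$outDir)) "." else cfg$outDir)
  if (out$waves < 2) stop("need at least 2 waves")
  out
}
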