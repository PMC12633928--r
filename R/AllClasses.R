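#' @import methods
NULL

#' RegionHierarchy: an atlas structure tree
#'
#' Holds the hierarchical region ontology of a brain atlas (the structure
#' tree): one row per region with its integer ID, short acronym, full name,
#' parent link, plus the precomputed ancestor path root -> self for every
#' node. Region IDs and acronyms are unique; the tree has exactly one root.
#'
#' @slot nodes data.frame with columns \code{id} (integer), \code{acronym}
#'   (character), \code{name} (character), \code{parent_id} (integer,
#'   \code{NA} for the root).
#' @slot paths named list, one integer vector per node (names are region IDs
#'   as character), giving the ID path from the root down to that node.
#'
#' @seealso [loadStructureTree()], [idPath()], [ancestorAtLevel()]
#' @export
setClass("RegionHierarchy",
  slots = c(nodes = "data.frame", paths = "list"))

setValidity("RegionHierarchy", function(object) {
  nd <- object@nodes
  msgs <- character()
  req <- c("id", "acronym", "name", "parent_id")
  if (!all(req %in% names(nd)))
    return(paste("nodes must have columns", paste(req, collapse = ", ")))
  if (anyDuplicated(nd$id))
    msgs <- c(msgs, "duplicate region IDs")
  if (anyDuplicated(nd$acronym))
    msgs <- c(msgs, "duplicate acronyms")
  if (sum(is.na(nd$parent_id)) != 1L)
    msgs <- c(msgs, "hierarchy must have exactly one root (parent_id NA)")
  orphan <- !is.na(nd$parent_id) & !(nd$parent_id %in% nd$id)
  if (any(orphan))
    msgs <- c(msgs, paste("parent_id not in tree for:",
                          paste(nd$acronym[orphan], collapse = ", ")))
  if (length(object@paths) != nrow(nd))
    msgs <- c(msgs, "paths must have one entry per node")
  else {
    for (i in seq_len(nrow(nd))) {
      p <- object@paths[[as.character(nd$id[i])]]
      if (is.null(p) || p[length(p)] != nd$id[i]) {
        msgs <- c(msgs, "each id_path must end with the node's own ID")
        break
      }
      if (!is.na(nd$parent_id[i])) {
        pp <- object@paths[[as.character(nd$parent_id[i])]]
        if (length(p) != length(pp) + 1L || !identical(p[seq_along(pp)], pp)) {
          msgs <- c(msgs, "id_path prefix must equal the parent's id_path")
          break
        }
      }
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' AnnotationVolume: a voxelized region-label image
#'
#' A 3D integer array in which each voxel carries the region ID of the atlas
#' structure occupying it (0 = unannotated background), together with the
#' physical voxel size in micrometers per axis. Point-to-region lookup
#' ([assignRegions()]) uses this volume with half-open voxels.
#'
#' @slot values 3D integer array of region IDs (0 = background).
#' @slot voxelSize numeric(3), strictly positive voxel edge length in um.
#'
#' @seealso [assignRegions()], [readNrrd()], [writeNrrd()]
#' @export
setClass("AnnotationVolume",
  slots = c(values = "array", voxelSize = "numeric"))

setValidity("AnnotationVolume", function(object) {
  if (length(dim(object@values)) != 3L)
    return("values must be a 3D array")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be 3 strictly positive finite numbers")
  if (any(object@values < 0, na.rm = TRUE))
    return("region IDs must be non-negative")
  TRUE
})

#' DensityMatrix: normalized inter-regional structural connection density
#'
#' A square region-by-region matrix of non-negative normalized connection
#' densities rho[A, B] (projection density from source region A to target
#' region B), as published in a mesoscopic projectome. Row/column order
#' follows the \code{regions} acronym vector.
#'
#' @slot regions character vector of region acronyms (row/column order).
#' @slot rho numeric matrix, square, non-negative, finite.
#'
#' @seealso [readDensityMatrix()], [buildActiveConnectivity()]
#' @export
setClass("DensityMatrix",
  slots = c(regions = "character", rho = "matrix"))

setValidity("DensityMatrix", function(object) {
  r <- object@rho
  if (nrow(r) != ncol(r)) return("rho must be square")
  if (length(object@regions) != nrow(r))
    return("regions length must match matrix dimension")
  if (anyDuplicated(object@regions)) return("duplicate region acronyms")
  if (any(!is.finite(r))) return("rho must be finite")
  if (any(r < 0)) return("rho must be non-negative")
  TRUE
})

#' ActiveConnectivity: directed weighted network of active communication
#'
#' The region-by-region active-connectivity matrix W for one brain (or a
#' per-condition average): W[A, B] = rho[A, B] * n[A] * n[B], the structural
#' connection density from A to B scaled by the number of active neurons in
#' both the source and the target region. Directed (generally asymmetric),
#' zero diagonal by construction.
#'
#' @slot regions character vector of region acronyms (row/column order).
#' @slot W numeric matrix of active connection strengths.
#' @slot brainId character scalar, the brain this matrix belongs to (or a
#'   label such as "average").
#' @slot condition character scalar, the experimental condition / time
#'   window (e.g. "ZT0-4").
#'
#' @seealso [buildActiveConnectivity()], [totalStrength()],
#'   [averageCondition()], [detectModules()], [betweennessCentrality()]
#' @export
setClass("ActiveConnectivity",
  slots = c(regions = "character", W = "matrix",
            brainId = "character", condition = "character"))

setValidity("ActiveConnectivity", function(object) {
  W <- object@W
  if (nrow(W) != ncol(W)) return("W must be square")
  if (length(object@regions) != nrow(W))
    return("regions length must match matrix dimension")
  if (any(!is.finite(W))) return("W must be finite")
  if (any(W < 0)) return("W must be non-negative")
  if (length(object@brainId) != 1L || length(object@condition) != 1L)
    return("brainId and condition must be length-1 character")
  TRUE
})

setMethod("show", "RegionHierarchy", function(object) {
  nd <- object@nodes
  root <- nd$acronym[is.na(nd$parent_id)]
  depth <- max(vapply(object@paths, length, 1L))
  cat(sprintf("RegionHierarchy: %d regions, root '%s', max depth %d\n",
              nrow(nd), root, depth))
})

setMethod("show", "AnnotationVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "AnnotationVolume: %d x %d x %d voxels (%g x %g x %g um), %d labels\n",
    d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
    object@voxelSize[3],
    length(setdiff(unique(as.vector(object@values)), 0L))))
})

setMethod("show", "DensityMatrix", function(object) {
  cat(sprintf("DensityMatrix: %d regions, %d nonzero densities\n",
              length(object@regions), sum(object@rho > 0)))
})

setMethod("show", "ActiveConnectivity", function(object) {
  cat(sprintf(
    "ActiveConnectivity: %d regions, brain '%s', condition '%s', total strength %.4g\n",
    length(object@regions), object@brainId, object@condition,
    sum(object@W) - sum(diag(object@W))))
})
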