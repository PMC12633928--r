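# Atlas handling: structure tree, annotation-volume lookup, hierarchy
# aggregation, cortical-layer parsing, exclusion sets.

#' Build a RegionHierarchy from a node table
#'
#' Computes and validates the root-to-self ID path for every node. Most
#' users will call [loadStructureTree()] on a structure-graph JSON file
#' instead of this constructor.
#'
#' @param nodes data.frame with columns \code{id}, \code{acronym},
#'   \code{name}, \code{parent_id} (\code{NA} for the root).
#' @return a [RegionHierarchy-class] object.
#' @export
RegionHierarchy <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  nodes$id <- as.integer(nodes$id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (anyDuplicated(nodes$id))
    stop("hierarchy integrity: duplicate region IDs: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  orphan <- !is.na(nodes$parent_id) & !(nodes$parent_id %in% nodes$id)
  if (any(orphan))
    stop("missing parent: parent_id not in tree for acronym(s): ",
         paste(nodes$acronym[orphan], collapse = ", "))
  paths <- .computePaths(nodes)
  new("RegionHierarchy", nodes = nodes, paths = paths)
}

.computePaths <- function(nodes) {
  parent <- stats::setNames(nodes$parent_id, as.character(nodes$id))
  paths <- vector("list", nrow(nodes))
  names(paths) <- as.character(nodes$id)
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$id[i]
    p <- id
    cur <- parent[[as.character(id)]]
    steps <- 0L
    while (!is.na(cur)) {
      p <- c(cur, p)
      cur <- parent[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > nrow(nodes))
        stop("hierarchy integrity: cycle detected in parent links")
    }
    paths[[i]] <- as.integer(p)
  }
  paths
}

#' Load an atlas structure tree from structure-graph JSON
#'
#' Reads a JSON array of node objects in the Allen structure-graph dialect
#' (keys \code{id}, \code{acronym}, \code{name}, \code{parent_structure_id},
#' and optionally \code{structure_id_path} as a "/"-delimited string or an
#' array). ID paths are always recomputed from the parent links; if the file
#' carries its own \code{structure_id_path}, the recomputed paths are
#' validated against it.
#'
#' @param path path to the JSON file.
#' @return a [RegionHierarchy-class] object.
#' @export
loadStructureTree <- function(path) {
  if (!file.exists(path)) stop("structure tree file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.data.frame(raw)) nodes <- raw
  else if (is.list(raw) && !is.null(raw$msg)) nodes <- raw$msg
  else stop("cannot parse structure-graph JSON: expected an array of nodes")
  req <- c("id", "acronym", "name", "parent_structure_id")
  if (!all(req %in% names(nodes)))
    stop("structure tree nodes need keys: ", paste(req, collapse = ", "))
  if (is.list(nodes$parent_structure_id))  # JSON null for the root
    nodes$parent_structure_id <- vapply(nodes$parent_structure_id,
      function(x) if (length(x) == 0L || all(is.na(unlist(x))))
        NA_integer_ else as.integer(x[[1]]), integer(1))
  h <- RegionHierarchy(data.frame(
    id = nodes$id, acronym = nodes$acronym, name = nodes$name,
    parent_id = nodes$parent_structure_id, stringsAsFactors = FALSE))
  if ("structure_id_path" %in% names(nodes)) {
    for (i in seq_len(nrow(nodes))) {
      declared <- nodes$structure_id_path[[i]]
      if (is.character(declared))
        declared <- as.integer(strsplit(gsub("^/|/$", "", declared),
                                        "/")[[1]])
      got <- h@paths[[as.character(nodes$id[i])]]
      if (!identical(as.integer(declared), got))
        stop("hierarchy integrity: structure_id_path of '",
             nodes$acronym[i], "' disagrees with parent links")
    }
  }
  h
}

#' ID path from the root to a region
#'
#' @param h a [RegionHierarchy-class].
#' @param regionId integer region ID present in the hierarchy.
#' @return integer vector of region IDs, root first, \code{regionId} last.
#' @export
idPath <- function(h, regionId) {
  p <- h@paths[[as.character(regionId)]]
  if (is.null(p)) stop("unknown region ID: ", regionId)
  p
}

#' Translate acronyms to region IDs (and back)
#'
#' @param h a [RegionHierarchy-class].
#' @param acronym character vector of acronyms.
#' @return integer vector of region IDs.
#' @export
acronymToId <- function(h, acronym) {
  idx <- match(acronym, h@nodes$acronym)
  if (anyNA(idx))
    stop("unknown acronym(s): ", paste(acronym[is.na(idx)], collapse = ", "))
  h@nodes$id[idx]
}

#' @rdname acronymToId
#' @param regionId integer vector of region IDs.
#' @export
idToAcronym <- function(h, regionId) {
  idx <- match(regionId, h@nodes$id)
  if (anyNA(idx))
    stop("unknown region ID(s): ",
         paste(regionId[is.na(idx)], collapse = ", "))
  h@nodes$acronym[idx]
}

#' Find the ancestor of a region within a target set
#'
#' Walks the region's root-to-self ID path and returns the unique member of
#' \code{targetSet} lying on it, or \code{NA} if none does. This is the
#' roll-up primitive used to aggregate leaf-level counts to major brain
#' regions (Isocortex, HPF, TH, ...) or to cortical areas (VIS, ACA, ...).
#'
#' @param regionId integer region ID (scalar or vector).
#' @param targetSet character vector of acronyms forming the target scope.
#' @param h a [RegionHierarchy-class].
#' @return character vector: the matching acronym per input ID, or \code{NA}.
#' @export
ancestorAtLevel <- function(regionId, targetSet, h) {
  targetIds <- acronymToId(h, targetSet)
  vapply(regionId, function(id) {
    p <- h@paths[[as.character(id)]]
    if (is.null(p)) stop("unknown region ID: ", id)
    hit <- targetIds[targetIds %in% p]
    if (length(hit) == 0L) return(NA_character_)
    if (length(hit) > 1L)
      stop("target set members are nested along the path of region ", id)
    idToAcronym(h, hit)
  }, character(1))
}

#' All descendant region IDs of a set of acronyms
#'
#' Returns the IDs of the named regions and every node below them; used to
#' implement acronym-based exclusion masks.
#'
#' @param h a [RegionHierarchy-class].
#' @param acronyms character vector of acronyms.
#' @return integer vector of region IDs (the regions plus all descendants).
#' @export
descendantIds <- function(h, acronyms) {
  ids <- acronymToId(h, acronyms)
  keep <- vapply(h@paths, function(p) any(ids %in% p), logical(1))
  as.integer(names(h@paths))[keep]
}

#' Parse the cortical layer from a region acronym
#'
#' Laminar cortical structures in the atlas carry a trailing layer token in
#' their acronym ("VISp5", "RSPagl2/3", ...). Returns the layer label
#' (one of L1, L2/3, L4, L5, L6a, L6b) or \code{NA} for acronyms without a
#' trailing layer token (non-laminar regions such as "TH").
#'
#' @param acronym character vector of acronyms.
#' @return character vector of layer labels or \code{NA}.
#' @export
parseLayer <- function(acronym) {
  tokens <- c("6a" = "L6a", "6b" = "L6b", "2/3" = "L2/3",
              "1" = "L1", "4" = "L4", "5" = "L5")
  out <- rep(NA_character_, length(acronym))
  for (tok in names(tokens)) {
    hit <- is.na(out) & endsWith(acronym, tok)
    # require a non-empty area stem before the layer token
    stem <- substr(acronym, 1L, nchar(acronym) - nchar(tok))
    out[hit & nchar(stem) > 0 & !grepl("[0-9/]$", stem)] <- tokens[[tok]]
  }
  out
}

#' Construct an AnnotationVolume
#'
#' @param values 3D integer array of voxel region IDs (0 = background).
#' @param voxelSize numeric(3) voxel edge lengths in micrometers (a scalar
#'   is recycled to all three axes).
#' @param h optional [RegionHierarchy-class]; if given, every nonzero voxel
#'   label must exist in the hierarchy.
#' @return an [AnnotationVolume-class].
#' @export
AnnotationVolume <- function(values, voxelSize, h = NULL) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  storage.mode(values) <- "integer"
  vol <- new("AnnotationVolume", values = values,
             voxelSize = as.numeric(voxelSize))
  if (!is.null(h)) {
    labs <- setdiff(unique(as.vector(values)), 0L)
    bad <- setdiff(labs, h@nodes$id)
    if (length(bad))
      stop("annotation labels not present in hierarchy: ",
           paste(bad, collapse = ", "))
  }
  vol
}

#' Assign an atlas region to each neuron coordinate
#'
#' Looks up each neuron's voxel in the annotation volume. Coordinates are
#' in micrometers in the volume's physical frame with the origin at the
#' corner of voxel (1,1,1); voxels are half-open intervals
#' \code{[i*s, (i+1)*s)}, so a point exactly on a boundary belongs to the
#' higher-index voxel. Points outside the volume get region 0 (unassigned).
#'
#' @param neurons data.frame with columns \code{neuron_id}, \code{x_um},
#'   \code{y_um}, \code{z_um} (other columns pass through untouched).
#' @param vol an [AnnotationVolume-class].
#' @return the input data.frame with a \code{region_id} column (integer,
#'   0 = unassigned), row order preserved.
#' @export
assignRegions <- function(neurons, vol) {
  xyz <- as.matrix(neurons[, c("x_um", "y_um", "z_um")])
  bad <- !is.finite(xyz)
  if (any(bad)) {
    who <- neurons$neuron_id[unique(which(bad, arr.ind = TRUE)[, 1])]
    stop("non-finite coordinate for neuron(s): ",
         paste(who, collapse = ", "))
  }
  vs <- vol@voxelSize
  idx <- floor(sweep(xyz, 2L, vs, "/")) + 1  # 1-based voxel index
  d <- dim(vol@values)
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
            idx[, 2] >= 1 & idx[, 2] <= d[2] &
            idx[, 3] >= 1 & idx[, 3] <= d[3]
  region <- integer(nrow(xyz))
  if (any(inside))
    region[inside] <- vol@values[cbind(idx[inside, 1], idx[inside, 2],
                                       idx[inside, 3])]
  neurons$region_id <- region
  neurons
}

#' Resolve an exclusion set against a hierarchy
#'
#' Brains cleared and imaged whole often have damaged olfactory areas,
#' cerebellum and medulla; those regions (and everything below them) are
#' dropped from all composition denominators. The default exclusion set is
#' \code{c("OLF", "CB", "MY")}.
#'
#' @param h a [RegionHierarchy-class].
#' @param acronyms character vector of excluded acronyms. Acronyms absent
#'   from the hierarchy raise an error.
#' @return integer vector of all excluded region IDs (regions +
#'   descendants). Acronyms absent from the hierarchy raise an error.
#' @export
exclusionIds <- function(h, acronyms = c("OLF", "CB", "MY")) {
  if (length(acronyms) == 0L) return(integer())
  acronymToId(h, acronyms)  # validates
  descendantIds(h, acronyms)
}

#' Read a neuron coordinate table
#'
#' CSV with header \code{neuron_id,brain_id,condition,x_um,y_um,z_um} and an
#' optional \code{region_id} column.
#'
#' @param path CSV file path.
#' @return data.frame of neuron records.
#' @export
readNeuronTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("neuron_id", "brain_id", "condition", "x_um", "y_um", "z_um")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("neuron table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(!nzchar(df$condition)))
    stop("empty condition label in ", path)
  df
}
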