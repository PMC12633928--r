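#' Region acronyms of an object
#'
#' @param x a RegionHierarchy, DensityMatrix or ActiveConnectivity.
#' @return character vector of region acronyms.
#' @export
setGeneric("regionAcronyms", function(x) standardGeneric("regionAcronyms"))

#' @rdname regionAcronyms
#' @export
setMethod("regionAcronyms", "RegionHierarchy", function(x) x@nodes$acronym)

#' @rdname regionAcronyms
#' @export
setMethod("regionAcronyms", "DensityMatrix", function(x) x@regions)

#' @rdname regionAcronyms
#' @export
setMethod("regionAcronyms", "ActiveConnectivity", function(x) x@regions)

#' Weight / density matrix of a network object
#'
#' @param x a DensityMatrix (returns rho) or ActiveConnectivity (returns W).
#' @return numeric matrix with region acronyms as dimnames.
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname weightMatrix
#' @export
setMethod("weightMatrix", "DensityMatrix", function(x) {
  m <- x@rho
  dimnames(m) <- list(x@regions, x@regions)
  m
})

#' @rdname weightMatrix
#' @export
setMethod("weightMatrix", "ActiveConnectivity", function(x) {
  m <- x@W
  dimnames(m) <- list(x@regions, x@regions)
  m
})

#' Brain and condition labels of an ActiveConnectivity
#'
#' @param x an ActiveConnectivity.
#' @return character scalar.
#' @export
setGeneric("brainId", function(x) standardGeneric("brainId"))

#' @rdname brainId
#' @export
setMethod("brainId", "ActiveConnectivity", function(x) x@brainId)

#' @rdname brainId
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname brainId
#' @export
setMethod("condition", "ActiveConnectivity", function(x) x@condition)

#' Voxel size of an annotation volume
#'
#' @param x an AnnotationVolume.
#' @return numeric(3), voxel edge lengths in micrometers.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "AnnotationVolume", function(x) x@voxelSize)

#' Voxel label array of an annotation volume
#'
#' @param x an AnnotationVolume.
#' @return 3D integer array of region IDs.
#' @export
setGeneric("annotationArray", function(x) standardGeneric("annotationArray"))

#' @rdname annotationArray
#' @export
setMethod("annotationArray", "AnnotationVolume", function(x) x@values)
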