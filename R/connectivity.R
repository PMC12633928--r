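# Active connectivity: W[A,B] = rho[A,B] * n[A] * n[B] for a structural
# connection-density matrix rho and per-region active-neuron counts n.

#' Construct a DensityMatrix
#'
#' @param rho square numeric matrix of non-negative densities.
#' @param regions character vector of acronyms in row/column order
#'   (defaults to the matrix rownames).
#' @return a [DensityMatrix-class].
#' @export
DensityMatrix <- function(rho, regions = rownames(rho)) {
  rho <- as.matrix(rho)
  if (is.null(regions)) stop("region acronyms required")
  new("DensityMatrix", regions = as.character(regions), rho = unname(rho))
}

#' Read a connection-density CSV
#'
#' First row and first column hold region acronyms; the body holds the
#' normalized densities.
#'
#' @param path CSV path.
#' @return a [DensityMatrix-class].
#' @export
readDensityMatrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!identical(rownames(m), colnames(m)))
    stop("density matrix row and column acronyms disagree")
  DensityMatrix(m, rownames(m))
}

#' Write a DensityMatrix (or ActiveConnectivity matrix) as CSV
#'
#' @param x a [DensityMatrix-class] or [ActiveConnectivity-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeMatrixCsv <- function(x, path) {
  m <- weightMatrix(x)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Build the active-connectivity matrix for one brain
#'
#' Scales the rows and the columns of the structural density matrix by the
#' per-region active-neuron counts: W = diag(n) rho diag(n), so that
#' W[A, B] = rho[A, B] * n[A] * n[B]. Communication from A to B requires
#' structural connectivity (rho), active source neurons (n[A]) and active
#' target neurons (n[B]); each factor of zero silences the edge. The
#' diagonal is zeroed by default (the network models inter-regional
#' communication only).
#'
#' @param rho a [DensityMatrix-class].
#' @param counts named integer vector of active-neuron counts by acronym,
#'   or the list returned by [countRegions()]. Regions of \code{rho} absent
#'   from the counts get n = 0 with a warning.
#' @param brainId,condition labels stored in the result (taken from
#'   \code{counts} when it is a [countRegions()] result).
#' @param keepDiagonal keep within-region entries rho[A,A] * n[A]^2
#'   (default FALSE).
#' @return an [ActiveConnectivity-class].
#' @export
buildActiveConnectivity <- function(rho, counts, brainId = NA_character_,
                                    condition = NA_character_,
                                    keepDiagonal = FALSE) {
  if (is.list(counts) && !is.null(counts$counts)) {
    if (is.na(brainId) && !is.null(counts$brain_id))
      brainId <- counts$brain_id
    if (is.na(condition) && !is.null(counts$condition))
      condition <- counts$condition
    counts <- counts$counts
  }
  if (is.null(names(counts)))
    stop("counts must be named by region acronym")
  n <- counts[rho@regions]
  missing <- rho@regions[is.na(n)]
  if (length(missing)) {
    warning("no counts for region(s) ", paste(missing, collapse = ", "),
            "; using n = 0")
    n[is.na(n)] <- 0
  }
  n <- as.numeric(n)
  W <- rho@rho * outer(n, n)
  if (!keepDiagonal) diag(W) <- 0
  new("ActiveConnectivity", regions = rho@regions, W = W,
      brainId = as.character(brainId), condition = as.character(condition))
}

#' Total active connection strength
#'
#' Sum of all off-diagonal entries of W; scales quadratically when all
#' counts are scaled by a common factor.
#'
#' @param ac an [ActiveConnectivity-class].
#' @return numeric scalar.
#' @export
totalStrength <- function(ac) {
  sum(ac@W) - sum(diag(ac@W))
}

#' Average active connectivity over brains of one condition
#'
#' @param acs list of [ActiveConnectivity-class] objects sharing region
#'   order and condition.
#' @return an [ActiveConnectivity-class] with \code{brainId = "average"}.
#' @export
averageCondition <- function(acs) {
  stopifnot(length(acs) >= 1L)
  regions <- acs[[1]]@regions
  cond <- acs[[1]]@condition
  for (ac in acs) {
    if (!identical(ac@regions, regions))
      stop("alignment error: region orders differ across matrices")
    if (!identical(ac@condition, cond))
      stop("grouping error: mixed conditions (", ac@condition, " vs ",
           cond, ")")
  }
  W <- Reduce(`+`, lapply(acs, function(a) a@W)) / length(acs)
  new("ActiveConnectivity", regions = regions, W = W,
      brainId = "average", condition = cond)
}
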