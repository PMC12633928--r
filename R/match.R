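# Molecular-identity inference: region-constrained exact 1-nearest-neighbor
# matching of active neurons against a spatial transcriptomic reference,
# hemisphere mirroring, match-distance QC, and neurotransmitter /
# excitatory-inhibitory composition.

#' Mirror neurons onto the reference hemisphere
#'
#' Spatial transcriptomic references often cover a single hemisphere; under
#' the assumption of left-right symmetry, neurons on the opposite side are
#' reflected across the midline plane before matching. Points exactly on
#' the midline are unchanged. A \code{mirrored} logical column records which
#' rows were reflected.
#'
#' @param neurons data.frame with \code{x_um}, \code{y_um}, \code{z_um}.
#' @param midlineUm midline coordinate (um) along the mirror axis.
#' @param axis axis index (1 = x, 2 = y, 3 = z) of the medio-lateral axis.
#' @param referenceSide "low" if the reference occupies coordinates below
#'   the midline, "high" otherwise.
#' @return the data.frame with reflected coordinates and a \code{mirrored}
#'   column.
#' @export
mirrorToReferenceHemisphere <- function(neurons, midlineUm, axis = 3L,
                                        referenceSide = c("low", "high")) {
  referenceSide <- match.arg(referenceSide)
  col <- c("x_um", "y_um", "z_um")[axis]
  x <- neurons[[col]]
  flip <- if (referenceSide == "low") x > midlineUm else x < midlineUm
  neurons[[col]][flip] <- 2 * midlineUm - x[flip]
  neurons$mirrored <- flip
  neurons
}

#' Validate a reference-cell table
#'
#' @param reference data.frame with columns \code{cell_id}, \code{x_um},
#'   \code{y_um}, \code{z_um}, \code{region_id}, \code{is_neuron},
#'   \code{neurotransmitter}.
#' @return the validated data.frame (invisibly the same object).
#' @export
checkReference <- function(reference) {
  req <- c("cell_id", "x_um", "y_um", "z_um", "region_id", "is_neuron",
           "neurotransmitter")
  miss <- setdiff(req, names(reference))
  if (length(miss))
    stop("reference table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(reference[, c("x_um", "y_um", "z_um")]))))
    stop("non-finite reference coordinates")
  reference
}

#' Read a reference-cell CSV
#'
#' @param path CSV with header
#'   \code{cell_id,x_um,y_um,z_um,region_id,is_neuron,neurotransmitter}.
#' @return data.frame of reference cells.
#' @export
readReferenceTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$is_neuron <- as.logical(df$is_neuron)
  checkReference(df)
}

#' Region-constrained 1-nearest-neighbor twin matching
#'
#' For every assigned neuron, finds the reference \emph{neuron} (non-
#' neuronal reference cells are excluded up front) with the same region ID
#' minimizing Euclidean distance — its "twin" — and inherits the twin's
#' neurotransmitter label. Matching never crosses a region boundary, which
#' avoids spurious assignments near borders. Exact search, no
#' approximation; distance ties are broken by the lexicographically
#' smallest \code{cell_id}. Neurons whose region has no reference neurons
#' (or that are unassigned) are returned unmatched with a reason code.
#'
#' @param neurons assigned (and, if applicable, mirrored) neuron
#'   data.frame with \code{neuron_id}, coordinates and \code{region_id}.
#' @param reference reference-cell data.frame (see [checkReference()]).
#' @param regionLevel optional character vector of acronyms; when given
#'   together with \code{h}, both datasets are rolled up to this scope
#'   before matching instead of using the finest assigned region.
#' @param h [RegionHierarchy-class], required when \code{regionLevel} is
#'   used.
#' @return data.frame with one row per input neuron: \code{neuron_id},
#'   \code{region_id} (the constraint region), \code{twin_cell_id},
#'   \code{distance_um}, \code{neurotransmitter}, \code{matched},
#'   \code{reason} ("ok", "unassigned", "no_reference_in_region").
#' @export
matchTwins <- function(neurons, reference, regionLevel = NULL, h = NULL) {
  checkReference(reference)
  reference <- reference[reference$is_neuron, , drop = FALSE]
  if (nrow(reference) == 0L)
    stop("reference contains no neurons")
  nrg <- neurons$region_id
  rrg <- reference$region_id
  if (!is.null(regionLevel)) {
    if (is.null(h)) stop("regionLevel requires a hierarchy")
    nrg <- ancestorAtLevel(nrg, regionLevel, h)
    rrg <- ancestorAtLevel(rrg, regionLevel, h)
  }
  nxyz <- as.matrix(neurons[, c("x_um", "y_um", "z_um")])
  rxyz <- as.matrix(reference[, c("x_um", "y_um", "z_um")])
  out <- data.frame(
    neuron_id = neurons$neuron_id, region_id = neurons$region_id,
    twin_cell_id = NA_character_, distance_um = NA_real_,
    neurotransmitter = NA_character_, matched = FALSE, reason = "ok",
    stringsAsFactors = FALSE)
  unas <- is.na(nrg) | nrg == 0
  out$reason[unas] <- "unassigned"
  refIdx <- split(seq_len(nrow(reference)), rrg)
  for (g in split(which(!unas), nrg[!unas])) {
    key <- as.character(nrg[g[1]])
    ri <- refIdx[[key]]
    if (is.null(ri)) {
      out$reason[g] <- "no_reference_in_region"
      next
    }
    R <- rxyz[ri, , drop = FALSE]
    ids <- as.character(reference$cell_id[ri])
    # order so that which.min's first-hit rule == smallest cell_id on ties
    ord <- order(ids)
    R <- R[ord, , drop = FALSE]; ids <- ids[ord]; ri <- ri[ord]
    rn2 <- rowSums(R^2)
    for (j in g) {
      d2 <- rn2 - 2 * drop(R %*% nxyz[j, ]) + sum(nxyz[j, ]^2)
      # recompute exactly for candidates near the minimum (guards fp error)
      cand <- which(d2 <= min(d2) + 1e-9 * max(1, min(d2)))
      dexact <- sqrt(colSums((t(R[cand, , drop = FALSE]) - nxyz[j, ])^2))
      k <- cand[which.min(dexact)]
      out$twin_cell_id[j] <- ids[k]
      out$distance_um[j] <- min(dexact)
      out$neurotransmitter[j] <- reference$neurotransmitter[ri[k]]
      out$matched[j] <- TRUE
    }
  }
  out
}

#' Match-distance quality control
#'
#' Summarizes twin-match distances: quantiles and the fraction of matches
#' beyond each threshold. In a dense reference nearly all matches should
#' fall within ~100 um, most within ~40 um.
#'
#' @param matches output of [matchTwins()].
#' @param probs quantile probabilities.
#' @param thresholdsUm distance thresholds (um).
#' @param breaks histogram break specification (passed to [hist()]).
#' @return list with \code{quantiles}, \code{fraction_above} (named by
#'   threshold), \code{n_matched}, \code{n_unmatched}, and \code{histogram}
#'   (counts/breaks, unplotted).
#' @export
distanceQC <- function(matches, probs = c(0.5, 0.9, 0.99),
                       thresholdsUm = c(40, 100), breaks = 30) {
  d <- matches$distance_um[matches$matched]
  if (length(d) == 0L) stop("no matched neurons")
  frac <- vapply(thresholdsUm, function(t) mean(d > t), numeric(1))
  list(quantiles = stats::quantile(d, probs = probs, names = TRUE),
       fraction_above = stats::setNames(frac, paste0(">", thresholdsUm, "um")),
       n_matched = length(d), n_unmatched = sum(!matches$matched),
       histogram = graphics::hist(d, breaks = breaks, plot = FALSE))
}

#' Neurotransmitter composition and E/I balance per region
#'
#' For each scope region and brain, the fraction of matched neurons per
#' neurotransmitter class, plus the excitatory/inhibitory ratio
#' (glutamatergic fraction / GABAergic fraction; \code{NA} and flagged when
#' there are no GABAergic matches). Unmatched neurons are excluded from
#' denominators and reported.
#'
#' @param matches output of [matchTwins()].
#' @param neurons the neuron table passed to [matchTwins()] (for brain and
#'   condition labels; row order must match).
#' @param scopeSet character vector of scope acronyms (a partition).
#' @param h a [RegionHierarchy-class].
#' @return list with \code{fractions} (data.frame: brain_id, condition,
#'   acronym, neurotransmitter, n, fraction), \code{ei} (data.frame:
#'   brain_id, condition, acronym, ei_ratio, ei_undefined), and
#'   \code{n_unmatched}.
#' @export
neurotransmitterComposition <- function(matches, neurons, scopeSet, h) {
  stopifnot(nrow(matches) == nrow(neurons))
  ok <- matches$matched
  scope <- rep(NA_character_, nrow(neurons))
  assigned <- neurons$region_id != 0
  scope[assigned] <- ancestorAtLevel(neurons$region_id[assigned], scopeSet, h)
  keep <- ok & !is.na(scope)
  df <- data.frame(brain_id = as.character(neurons$brain_id[keep]),
                   condition = as.character(neurons$condition[keep]),
                   acronym = scope[keep],
                   nt = matches$neurotransmitter[keep],
                   stringsAsFactors = FALSE)
  groups <- split(df, list(df$brain_id, df$acronym), drop = TRUE)
  fr <- do.call(rbind, lapply(groups, function(g) {
    tab <- table(g$nt)
    data.frame(brain_id = g$brain_id[1], condition = g$condition[1],
               acronym = g$acronym[1], neurotransmitter = names(tab),
               n = as.integer(tab), fraction = as.numeric(tab) / nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(fr) <- NULL
  ei <- do.call(rbind, lapply(groups, function(g) {
    e <- mean(g$nt == "glutamatergic")
    i <- mean(g$nt == "GABAergic")
    data.frame(brain_id = g$brain_id[1], condition = g$condition[1],
               acronym = g$acronym[1],
               ei_ratio = if (i > 0) e / i else NA_real_,
               ei_undefined = i == 0, stringsAsFactors = FALSE)
  }))
  rownames(ei) <- NULL
  list(fractions = fr, ei = ei, n_unmatched = sum(!ok))
}
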