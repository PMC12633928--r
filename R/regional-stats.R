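# Regional composition statistics: per-brain counts at a chosen anatomical
# scope, composition ratios, cross-condition z-scores, cortical layer
# ratios, and two-group comparisons.

.dropExcluded <- function(neurons, h, exclusions) {
  excl <- exclusionIds(h, exclusions)
  neurons[!(neurons$region_id %in% excl) & neurons$region_id != 0L, ,
          drop = FALSE]
}

.checkScopePartition <- function(h, scopeSet) {
  ids <- acronymToId(h, scopeSet)
  for (i in seq_along(ids)) {
    p <- h@paths[[as.character(ids[i])]]
    anc <- ids[ids %in% p & ids != ids[i]]
    if (length(anc))
      stop("scope partition error: '", scopeSet[i], "' is nested under '",
           idToAcronym(h, anc[1]), "'")
  }
  invisible(TRUE)
}

#' Count active neurons per region at a given anatomical scope
#'
#' Rolls each assigned neuron up to the unique member of \code{scopeSet} on
#' its ancestor path and tallies counts per scope region. Neurons that are
#' unassigned (region 0), fall in an excluded region, or match no scope
#' member are dropped from the counts and the total.
#'
#' @param neurons data.frame of assigned neurons (needs \code{region_id};
#'   \code{brain_id}/\code{condition} are carried into the result when all
#'   rows agree).
#' @param h a [RegionHierarchy-class].
#' @param scopeSet character vector of acronyms forming a partition (no
#'   member may be an ancestor of another).
#' @param exclusions character vector of excluded acronyms (with all their
#'   descendants); default \code{c("OLF", "CB", "MY")}. Use
#'   \code{character()} for none.
#' @return list with elements \code{brain_id}, \code{condition},
#'   \code{counts} (named integer vector over \code{scopeSet}), \code{total},
#'   and \code{n_dropped} (unassigned/excluded/out-of-scope neurons).
#' @export
countRegions <- function(neurons, h, scopeSet,
                         exclusions = c("OLF", "CB", "MY")) {
  .checkScopePartition(h, scopeSet)
  n0 <- nrow(neurons)
  kept <- .dropExcluded(neurons, h, exclusions)
  scope <- if (nrow(kept))
    ancestorAtLevel(kept$region_id, scopeSet, h) else character()
  scope <- scope[!is.na(scope)]
  counts <- table(factor(scope, levels = scopeSet))
  counts <- stats::setNames(as.integer(counts), scopeSet)
  one <- function(x) if (length(unique(x)) == 1L) unique(x) else NA_character_
  list(brain_id = one(as.character(neurons$brain_id)),
       condition = one(as.character(neurons$condition)),
       counts = counts, total = sum(counts),
       n_dropped = n0 - sum(counts))
}

#' Per-brain region counts for a multi-brain table
#'
#' @inheritParams countRegions
#' @return tidy data.frame with one row per brain x scope region:
#'   \code{brain_id}, \code{condition}, \code{acronym}, \code{n},
#'   \code{total}.
#' @export
countRegionsByBrain <- function(neurons, h, scopeSet,
                                exclusions = c("OLF", "CB", "MY")) {
  parts <- split(neurons, neurons$brain_id)
  out <- lapply(parts, function(df) {
    rc <- countRegions(df, h, scopeSet, exclusions)
    data.frame(brain_id = rc$brain_id, condition = rc$condition,
               acronym = names(rc$counts), n = unname(rc$counts),
               total = rc$total, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Composition ratios from region counts
#'
#' Divides each region's count by the brain's total over the scope, so the
#' ratios of one brain sum to 1. Works on the output of [countRegions()]
#' (single brain) or [countRegionsByBrain()] (tidy multi-brain table).
#'
#' @param counts output of [countRegions()] or [countRegionsByBrain()].
#' @return data.frame with columns \code{brain_id}, \code{condition},
#'   \code{acronym}, \code{ratio}.
#' @export
regionRatios <- function(counts) {
  if (is.data.frame(counts)) {
    if (any(counts$total == 0))
      stop("empty brain: zero total count for brain(s) ",
           paste(unique(counts$brain_id[counts$total == 0]), collapse = ", "))
    out <- counts[, c("brain_id", "condition", "acronym")]
    out$ratio <- counts$n / counts$total
    return(out)
  }
  if (counts$total == 0) stop("empty brain: zero total count")
  data.frame(brain_id = counts$brain_id, condition = counts$condition,
             acronym = names(counts$counts),
             ratio = unname(counts$counts) / counts$total,
             stringsAsFactors = FALSE)
}

#' Z-score composition ratios across brains
#'
#' For each region, centers and scales its ratios over all brains from all
#' conditions pooled (default), or within each region relative to the mean
#' of per-condition means (\code{pool = "condition-mean"}). Sample standard
#' deviation (denominator n - 1). Regions with zero variance get z = 0 and
#' are flagged.
#'
#' @param ratioTable data.frame from [regionRatios()].
#' @param pool "brains" (default) or "condition-mean".
#' @return the input with columns \code{z} and \code{zero_var} added.
#' @export
zscoreAcrossConditions <- function(ratioTable,
                                   pool = c("brains", "condition-mean")) {
  pool <- match.arg(pool)
  ratioTable$z <- NA_real_
  ratioTable$zero_var <- FALSE
  for (a in unique(ratioTable$acronym)) {
    i <- ratioTable$acronym == a
    x <- ratioTable$ratio[i]
    if (length(x) < 2L)
      stop("need at least 2 ratio values per region to z-score: ", a)
    if (pool == "brains") {
      mu <- mean(x); sdv <- stats::sd(x)
    } else {
      condMeans <- tapply(x, ratioTable$condition[i], mean)
      mu <- mean(condMeans); sdv <- stats::sd(x)
    }
    if (!is.finite(sdv) || sdv == 0) {
      ratioTable$z[i] <- 0
      ratioTable$zero_var[i] <- TRUE
      warning("zero variance for region ", a, "; z set to 0")
    } else {
      ratioTable$z[i] <- (x - mu) / sdv
    }
  }
  ratioTable
}

#' Layer composition of a cortical area (or the whole cortex)
#'
#' Among neurons assigned under \code{parentAcronym}, computes the fraction
#' in each cortical layer (L1, L2/3, L4, L5, L6a, L6b) per brain. With
#' \code{parentAcronym} set to the cortex root (e.g. "Isocortex") this gives
#' the layer composition of the whole cortical population.
#'
#' @param neurons assigned neuron data.frame.
#' @param parentAcronym acronym of the laminar cortical area (or cortex
#'   root) to restrict to.
#' @param h a [RegionHierarchy-class].
#' @return data.frame with \code{brain_id}, \code{condition}, \code{layer},
#'   \code{ratio}; ratios sum to 1 per brain over layers present.
#' @export
layerRatios <- function(neurons, parentAcronym, h) {
  under <- descendantIds(h, parentAcronym)
  sel <- neurons[neurons$region_id %in% under, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("no neurons under region ", parentAcronym)
  sel$layer <- parseLayer(idToAcronym(h, sel$region_id))
  sel <- sel[!is.na(sel$layer), , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("no laminar structures with neurons under region ", parentAcronym)
  layers <- c("L1", "L2/3", "L4", "L5", "L6a", "L6b")
  out <- lapply(split(sel, sel$brain_id), function(df) {
    tab <- table(factor(df$layer, levels = layers))
    data.frame(brain_id = df$brain_id[1],
               condition = as.character(df$condition[1]),
               layer = layers, ratio = as.numeric(tab) / nrow(df),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-group comparison of per-brain values
#'
#' Welch's two-sided t-test (unequal variances). When both groups are
#' constant, the test statistic is degenerate: equal constants give p = 1,
#' different constants are flagged with p = 0 (the limit of vanishing
#' within-group variance).
#'
#' @param valuesA,valuesB numeric vectors (>= 2 values each).
#' @return list with \code{statistic}, \code{p_value}, \code{degenerate}.
#' @export
compareGroups <- function(valuesA, valuesB) {
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    stop("insufficient data: each group needs at least 2 values")
  if (stats::sd(valuesA) == 0 && stats::sd(valuesB) == 0) {
    same <- isTRUE(all.equal(mean(valuesA), mean(valuesB)))
    return(list(statistic = if (same) 0 else Inf * sign(mean(valuesA) - mean(valuesB)),
                p_value = if (same) 1 else 0, degenerate = TRUE))
  }
  tt <- stats::t.test(valuesA, valuesB, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment for a multi-region screen
#'
#' @param pValues numeric vector of raw p-values.
#' @return numeric vector of BH-adjusted p-values.
#' @export
adjustBH <- function(pValues) stats::p.adjust(pValues, method = "BH")
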