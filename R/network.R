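# Network analysis of active-connectivity matrices: directed modularity
# with a resolution parameter, Louvain-style module detection, weighted
# directed betweenness centrality, hub ranking, and region-set centrality.

.acMatrix <- function(x) {
  if (is(x, "ActiveConnectivity")) weightMatrix(x)
  else if (is(x, "DensityMatrix")) weightMatrix(x)
  else {
    m <- as.matrix(x)
    if (is.null(rownames(m)))
      dimnames(m) <- list(paste0("R", seq_len(nrow(m))),
                          paste0("R", seq_len(nrow(m))))
    m
  }
}

#' Directed modularity with resolution parameter
#'
#' Newman-Leicht modularity for weighted directed networks,
#' \deqn{Q = \frac{1}{m}\sum_{ij}\left[W_{ij} -
#'   \gamma\,\frac{s_i^{out} s_j^{in}}{m}\right]\,\delta(c_i, c_j)}
#' with out-strengths \eqn{s^{out}}, in-strengths \eqn{s^{in}} and total
#' weight \eqn{m = \sum_{ij} W_{ij}}. \eqn{\gamma} tunes the size of the
#' modules favored: larger values favor smaller modules. At \eqn{\gamma=1}
#' the all-in-one partition scores exactly 0. Q is invariant to rescaling
#' W by any positive constant and non-increasing in \eqn{\gamma} for a
#' fixed partition.
#'
#' @param W an [ActiveConnectivity-class], [DensityMatrix-class] or
#'   non-negative square matrix.
#' @param membership integer/character vector of community labels, one per
#'   region (order of the matrix), or a named vector matched by acronym.
#' @param gamma resolution parameter (> 0), default 1.
#' @return numeric scalar Q.
#' @export
directedModularity <- function(W, membership, gamma = 1) {
  M <- .acMatrix(W)
  m <- sum(M)
  if (m <= 0) stop("degenerate network: total weight is zero")
  if (!is.null(names(membership)) && !is.null(rownames(M)))
    membership <- membership[rownames(M)]
  if (length(membership) != nrow(M))
    stop("membership must assign every region exactly once")
  comm <- as.integer(factor(membership))
  sout <- rowSums(M); sin <- colSums(M)
  q <- 0
  for (c in unique(comm)) {
    idx <- comm == c
    q <- q + sum(M[idx, idx]) - gamma * sum(sout[idx]) * sum(sin[idx]) / m
  }
  q / m
}

# Louvain local-moving + aggregation on the directed modularity, one run.
.louvainOnce <- function(M, gamma, order0) {
  n0 <- nrow(M)
  membership <- seq_len(n0)   # original node -> node index of current level
  level <- M
  repeat {
    n <- nrow(level)
    m <- sum(level)
    sout <- rowSums(level); sin <- colSums(level)
    comm <- seq_len(n)
    Sout <- sout; Sin <- sin       # community strength totals
    sweep_order <- if (n == n0) order0 else seq_len(n)
    improved_level <- FALSE
    repeat {
      moved <- FALSE
      for (i in sweep_order) {
        ci <- comm[i]
        # detach i
        Sout[ci] <- Sout[ci] - sout[i]; Sin[ci] <- Sin[ci] - sin[i]
        wi_out <- level[i, ]; wi_in <- level[, i]
        # links from/to each community (excluding i itself)
        nbr <- unique(comm[which((wi_out > 0 | wi_in > 0))])
        cand <- unique(c(ci, nbr))
        gain <- vapply(cand, function(cc) {
          idx <- comm == cc
          idx[i] <- FALSE
          kin <- sum(wi_out[idx]) + sum(wi_in[idx])
          (kin + level[i, i]) / m -
            gamma * (sout[i] * Sin[cc] + sin[i] * Sout[cc] +
                     sout[i] * sin[i]) / m^2
        }, numeric(1))
        best <- cand[which.max(gain)]
        if (gain[match(best, cand)] <= gain[match(ci, cand)] + 1e-12)
          best <- ci
        comm[i] <- best
        Sout[best] <- Sout[best] + sout[i]; Sin[best] <- Sin[best] + sin[i]
        if (best != ci) moved <- TRUE
      }
      if (!moved) break
      improved_level <- TRUE
    }
    if (!improved_level) break
    # aggregate communities into supernodes
    fac <- as.integer(factor(comm))
    k <- max(fac)
    agg <- matrix(0, k, k)
    for (a in seq_len(k)) for (b in seq_len(k))
      agg[a, b] <- sum(level[fac == a, fac == b])
    membership <- fac[membership]
    level <- agg
    if (k == n) break
  }
  membership
}

#' Detect network modules by Louvain-style modularity optimization
#'
#' Greedy local-moving with aggregation, optimizing
#' [directedModularity()] at the given resolution. The node sweep order is
#' shuffled from \code{seed}; \code{restarts} independent runs are scored
#' and the best Q kept (Q ties broken by the lexicographically smallest
#' canonical labeling). The returned partition never scores below either
#' trivial partition (all-singletons or all-in-one).
#'
#' @inheritParams directedModularity
#' @param gamma resolution parameter.
#' @param seed integer seed controlling sweep order.
#' @param restarts number of restarts (default 10).
#' @return list with \code{membership} (named integer vector, community
#'   IDs renumbered by first appearance), \code{Q}, \code{gamma},
#'   \code{n_modules}.
#' @export
detectModules <- function(W, gamma = 1, seed = 1L, restarts = 10L) {
  M <- .acMatrix(W)
  if (sum(M) <= 0) stop("degenerate network: total weight is zero")
  n <- nrow(M)
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  canon <- function(mem) as.integer(factor(mem, levels = unique(mem)))
  best <- NULL; bestQ <- -Inf
  for (r in seq_len(restarts)) {
    ord <- local({
      set.seed(as.integer(seed) + r - 1L)
      sample.int(n)
    })
    mem <- canon(.louvainOnce(M, gamma, ord))
    q <- directedModularity(M, mem, gamma)
    if (q > bestQ + 1e-12 ||
        (abs(q - bestQ) <= 1e-12 && !is.null(best) &&
         .lexLess(mem, best))) {
      best <- mem; bestQ <- q
    }
  }
  # never return worse than the trivial partitions
  for (triv in list(seq_len(n), rep(1L, n))) {
    qt <- directedModularity(M, triv, gamma)
    if (qt > bestQ + 1e-12) { best <- canon(triv); bestQ <- qt }
  }
  names(best) <- rownames(M)
  list(membership = best, Q = bestQ, gamma = gamma,
       n_modules = length(unique(best)))
}

.lexLess <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

#' Modularity across a resolution sweep
#'
#' Runs [detectModules()] on a grid of resolution values and reports the
#' optimized modularity at each, tracing how module structure depends on
#' the scale of modules sought.
#'
#' @inheritParams detectModules
#' @param gammas numeric vector of resolutions (default 21 points on
#'   [0.5, 2]).
#' @return data.frame with \code{gamma}, \code{Q}, \code{n_modules}.
#' @export
modularitySweep <- function(W, gammas = seq(0.5, 2, length.out = 21),
                            seed = 1L, restarts = 10L) {
  rows <- lapply(gammas, function(g) {
    res <- detectModules(W, gamma = g, seed = seed, restarts = restarts)
    data.frame(gamma = g, Q = res$Q, n_modules = res$n_modules)
  })
  do.call(rbind, rows)
}

#' Weighted directed betweenness centrality
#'
#' Node betweenness on the directed graph whose edges are the nonzero
#' entries of W, with edge length 1/W (strong connections = short paths;
#' \code{"neglog"} uses \eqn{\log(\max W / W)} instead). Shortest paths
#' are computed over all ordered source-target pairs and equal-length
#' paths share credit fractionally. Entries below \code{1e-12 * max(W)}
#' are treated as absent edges. Networks with fewer than 3 nodes have all
#' betweenness 0 by contract.
#'
#' @param W an [ActiveConnectivity-class] or non-negative square matrix.
#' @param lengthTransform "inverse" (default) or "neglog".
#' @return data.frame (one row per region): \code{brain_id},
#'   \code{condition} (NA unless W is an ActiveConnectivity),
#'   \code{acronym}, \code{betweenness} (raw path count),
#'   \code{betweenness_norm} (divided by (R-1)(R-2)), \code{rank}
#'   (descending betweenness, ties alphabetical).
#' @export
betweennessCentrality <- function(W, lengthTransform = c("inverse",
                                                         "neglog")) {
  lengthTransform <- match.arg(lengthTransform)
  bid <- if (is(W, "ActiveConnectivity")) W@brainId else NA_character_
  cond <- if (is(W, "ActiveConnectivity")) W@condition else NA_character_
  M <- .acMatrix(W)
  n <- nrow(M)
  M[M < 1e-12 * max(M)] <- 0
  if (n < 3 || max(M) == 0) {
    btw <- stats::setNames(numeric(n), rownames(M))
  } else {
    L <- M
    pos <- M > 0
    L[pos] <- switch(lengthTransform,
                     inverse = 1 / M[pos],
                     neglog = log(max(M) / M[pos]) + 1e-12)
    g <- igraph::graph_from_adjacency_matrix(L, mode = "directed",
                                             weighted = TRUE, diag = FALSE)
    btw <- igraph::betweenness(g, directed = TRUE,
                               weights = igraph::E(g)$weight)
    btw <- stats::setNames(as.numeric(btw), rownames(M))
  }
  norm <- if (n > 2) btw / ((n - 1) * (n - 2)) else btw
  ord <- order(-btw, names(btw))
  rank <- integer(n); rank[ord] <- seq_len(n)
  data.frame(brain_id = bid, condition = cond, acronym = names(btw),
             betweenness = unname(btw), betweenness_norm = unname(norm),
             rank = rank, stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank hub regions by mean betweenness
#'
#' Averages each region's betweenness over the brains in a centrality
#' table (typically one condition) and returns the top-k regions in
#' descending order; ties are broken alphabetically by acronym.
#'
#' @param ct centrality table ([betweennessCentrality()] output, possibly
#'   row-bound over brains).
#' @param k number of hubs to return.
#' @param useNormalized rank by normalized betweenness instead of raw.
#' @return data.frame with \code{acronym}, \code{mean_betweenness},
#'   \code{rank} (1..k).
#' @export
rankHubs <- function(ct, k, useNormalized = FALSE) {
  col <- if (useNormalized) "betweenness_norm" else "betweenness"
  mu <- tapply(ct[[col]], ct$acronym, mean)
  if (k > length(mu)) stop("k exceeds the number of regions")
  ord <- order(-mu, names(mu))
  data.frame(acronym = names(mu)[ord][seq_len(k)],
             mean_betweenness = as.numeric(mu[ord])[seq_len(k)],
             rank = seq_len(k), stringsAsFactors = FALSE)
}

#' Mean centrality of a named region set
#'
#' Averages betweenness over the members of a region set (e.g. the default
#' mode network) within each brain, then summarizes per condition
#' (mean and sd over brains).
#'
#' @param ct centrality table with \code{brain_id}, \code{condition},
#'   \code{acronym}, \code{betweenness}.
#' @param regionSet character vector of acronyms; members absent from the
#'   table are reported with a warning.
#' @return list with \code{per_brain} (brain_id, condition, mean
#'   betweenness over the set) and \code{per_condition} (condition, mean,
#'   sd, n_brains).
#' @export
setCentrality <- function(ct, regionSet) {
  present <- intersect(regionSet, unique(ct$acronym))
  if (length(present) == 0L)
    stop("none of the region-set members are in the network")
  missing <- setdiff(regionSet, present)
  if (length(missing))
    warning("region-set member(s) not in network: ",
            paste(missing, collapse = ", "))
  sub <- ct[ct$acronym %in% present, , drop = FALSE]
  pb <- do.call(rbind, lapply(split(sub, sub$brain_id), function(g)
    data.frame(brain_id = g$brain_id[1], condition = g$condition[1],
               set_mean = mean(g$betweenness), stringsAsFactors = FALSE)))
  rownames(pb) <- NULL
  pc <- do.call(rbind, lapply(split(pb, pb$condition), function(g)
    data.frame(condition = g$condition[1], mean = mean(g$set_mean),
               sd = stats::sd(g$set_mean), n_brains = nrow(g),
               stringsAsFactors = FALSE)))
  rownames(pc) <- NULL
  list(per_brain = pb, per_condition = pc)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a detected partition and a reference
#' (planted) partition; 1 = identical up to label permutation, ~0 = chance.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar in [-1, 1].
#' @export
ariIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sn <- choose(length(a), 2)
  expected <- si * sj / sn
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}
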