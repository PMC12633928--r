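# Fixtures built in code and independent brute-force oracles used across
# the suite.

# A 20-node hand-built hierarchy: cortex with laminar areas, thalamus,
# hypothalamus, midbrain, and the routinely excluded OLF/CB/MY.
fixtureHierarchy <- function() {
  n <- function(id, acr, parent) data.frame(
    id = id, acronym = acr, name = paste("fix", acr), parent_id = parent,
    stringsAsFactors = FALSE)
  RegionHierarchy(rbind(
    n(1L, "root", NA),
    n(2L, "Isocortex", 1L), n(3L, "VISp", 2L),
    n(4L, "VISp1", 3L), n(5L, "VISp2/3", 3L), n(6L, "VISp4", 3L),
    n(7L, "VISp5", 3L), n(8L, "VISp6a", 3L), n(9L, "VISp6b", 3L),
    n(10L, "ACA", 2L), n(11L, "ACA5", 10L),
    n(12L, "TH", 1L), n(13L, "RT", 12L), n(14L, "LGd", 12L),
    n(15L, "HY", 1L), n(16L, "PH", 15L),
    n(17L, "MB", 1L), n(18L, "VTA", 17L),
    n(19L, "OLF", 1L), n(20L, "MOB", 19L),
    n(21L, "CB", 1L), n(22L, "MY", 1L)))
}

# Two-region 4x4x4 volume: region 7 fills x-half [1,2], region 13 [3,4].
fixtureVolume <- function(voxelUm = 50) {
  v <- array(0L, dim = c(4L, 4L, 4L))
  v[1:2, , ] <- 7L
  v[3:4, , ] <- 13L
  AnnotationVolume(v, voxelUm)
}

# Oracle: per-point voxel lookup written independently of assignRegions.
oracleAssign <- function(xyz, vol) {
  d <- dim(annotationArray(vol)); vs <- voxelSize(vol)
  apply(xyz, 1L, function(p) {
    i <- floor(p / vs) + 1
    if (any(i < 1) || any(i > d)) return(0L)
    annotationArray(vol)[i[1], i[2], i[3]]
  })
}

# Oracle: linear scan of the parent chain for the scope ancestor.
oracleAncestor <- function(h, regionId, targetSet) {
  nd <- h@nodes
  cur <- regionId
  while (!is.na(cur)) {
    acr <- nd$acronym[nd$id == cur]
    if (acr %in% targetSet) return(acr)
    cur <- nd$parent_id[nd$id == cur]
  }
  NA_character_
}

# Oracle: exhaustive same-region 1-NN scan with smallest-cell_id ties.
oracleMatch <- function(neurons, reference) {
  reference <- reference[reference$is_neuron, ]
  out <- data.frame(twin = rep(NA_character_, nrow(neurons)),
                    dist = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(neurons))) {
    cand <- reference[reference$region_id == neurons$region_id[i], ]
    if (nrow(cand) == 0L || neurons$region_id[i] == 0) next
    d <- sqrt((cand$x_um - neurons$x_um[i])^2 +
              (cand$y_um - neurons$y_um[i])^2 +
              (cand$z_um - neurons$z_um[i])^2)
    best <- which(d == min(d))
    best <- best[order(as.character(cand$cell_id[best]))][1]
    out$twin[i] <- as.character(cand$cell_id[best])
    out$dist[i] <- d[best]
  }
  out
}

# Oracle: directed modularity evaluated with an explicit double loop.
oracleModularity <- function(W, comm, gamma = 1) {
  m <- sum(W)
  sout <- rowSums(W); sin <- colSums(W)
  q <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W)))
    if (comm[i] == comm[j])
      q <- q + W[i, j] - gamma * sout[i] * sin[j] / m
  q / m
}

# Oracle: betweenness by explicit enumeration of all simple paths.
# For every ordered pair (s, t), enumerates every simple path, keeps the
# ones attaining the minimum total length, and credits each intermediate
# node 1/(number of shortest paths).
oracleBetweenness <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  btw <- numeric(n)
  allPaths <- function(cur, t, visited, len) {
    if (cur == t) return(list(list(path = visited, len = len)))
    out <- list()
    for (nx in seq_len(n)) {
      if (is.finite(L[cur, nx]) && !(nx %in% visited)) {
        out <- c(out, allPaths(nx, t, c(visited, nx), len + L[cur, nx]))
      }
    }
    out
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- allPaths(s, t, s, 0)
    if (length(paths) == 0L) next
    lens <- vapply(paths, function(p) p$len, numeric(1))
    sp <- paths[abs(lens - min(lens)) < 1e-12]
    for (p in sp) {
      inner <- setdiff(p$path, c(s, t))
      btw[inner] <- btw[inner] + 1 / length(sp)
    }
  }
  btw
}

# Small assigned-neuron table sitting at given leaf acronyms of a
# hierarchy (coordinates are irrelevant for counting tests).
neuronsAt <- function(h, acronyms, brain = "b1", condition = "ZT0-4") {
  data.frame(neuron_id = sprintf("n%03d", seq_along(acronyms)),
             brain_id = brain, condition = condition,
             x_um = 0, y_um = 0, z_um = 0,
             region_id = acronymToId(h, acronyms),
             stringsAsFactors = FALSE)
}

# Shared small generator configuration to keep test runtime down.
smallSimConfig <- function(seed = 1L, ...) {
  simConfig(seed = seed, nNeuronsPerBrain = 600L, brainsPerCondition = 2L,
            refCellsTotal = 16000L, ...)
}
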