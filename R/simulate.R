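# Synthetic-data generator: a fixture atlas (hierarchy + annotation
# volume), activity-tagged neuron tables with planted per-condition
# region/layer effects, a spatial transcriptomic reference with planted
# per-region cell-type proportions, and block-structured connection-density
# matrices with planted modules and bridge hubs. Every planted parameter is
# recoverable by the corresponding analysis operation, which is what the
# validation suite exercises.

.simMajors <- c("Isocortex", "HPF", "CTXsp", "STR", "PAL", "TH", "HY",
                "MB", "P", "OLF", "CB", "MY")
.simAreas <- c("VISp", "RSPagl", "ACA", "PL", "TEa", "PTLp")
.simLayerTokens <- c("1", "2/3", "4", "5", "6a", "6b")
.simSubLeaves <- list(
  HPF = c("CA1", "DG"), CTXsp = c("CLA", "EPd"), STR = c("CP", "ACB"),
  PAL = c("GPe"), TH = c("RT", "LGd", "AV"), HY = c("PH", "VMH"),
  MB = c("VTA", "SCm"), P = c("PRNc"), OLF = c("MOB"), CB = c("CBX"),
  MY = c("GRN"))

#' Region acronyms of the synthetic connectivity network
#'
#' The cortical areas plus the subcortical leaf regions (excluded regions
#' OLF/CB/MY are not part of the network), the region set over which
#' synthetic density matrices and active-connectivity networks are built.
#'
#' @return character vector of 20 acronyms.
#' @export
simNetworkRegions <- function() {
  c(.simAreas, unlist(.simSubLeaves[c("HPF", "CTXsp", "STR", "PAL", "TH",
                                      "HY", "MB", "P")], use.names = FALSE))
}

#' Configuration for the synthetic-data generator
#'
#' Defaults represent the study conditions emulated throughout the test
#' suite: four 4-hour tagging windows across the day, a handful of brains
#' per window, a few thousand tagged neurons per brain (the most active ~1%
#' of neurons a TRAP experiment captures), a dense one-hemisphere
#' transcriptomic reference, and a 4-block structural density matrix.
#' Planted effects: a higher isocortex share at ZT0-4 than at ZT12-16, a
#' light-period-enriched visual area, a layer-5-enriched cortex at ZT20-24,
#' a near-pure GABAergic reticular nucleus (RT) and a dopaminergic VTA.
#'
#' @param seed integer master seed; every generator derives its own
#'   sub-stream from it, so identical configurations give byte-identical
#'   outputs.
#' @param nNeuronsPerBrain neurons drawn per brain.
#' @param brainsPerCondition brains per time window.
#' @param refCellsTotal total reference cells (neurons + non-neuronal).
#' @param nonNeuronalFraction fraction of reference cells that are
#'   non-neuronal (excluded by matching).
#' @param segregation in [0, 1]: 1 = cell types spatially segregated into
#'   per-type slabs inside each region, 0 = fully interleaved.
#' @param mirroredFraction fraction of neurons drawn on the hemisphere the
#'   reference does not cover.
#' @param withinDensity,betweenDensity block-model mean densities
#'   (within-block vs between-block).
#' @param nBlocks number of planted modules in the density matrix.
#' @param bridgeRegion acronym of a planted bridge hub given strong links
#'   into every block (NULL for none).
#' @param voxelSizeUm annotation voxel edge length (um).
#' @return a list of class \code{simConfig}.
#' @export
simConfig <- function(seed = 1L,
                      nNeuronsPerBrain = 5000L,
                      brainsPerCondition = 3L,
                      refCellsTotal = 60000L,
                      nonNeuronalFraction = 0.25,
                      segregation = 1,
                      mirroredFraction = 0.5,
                      withinDensity = 0.5,
                      betweenDensity = 0.05,
                      nBlocks = 4L,
                      bridgeRegion = NULL,
                      voxelSizeUm = 25) {
  conditions <- c("ZT0-4", "ZT8-12", "ZT12-16", "ZT20-24")
  base <- c(Isocortex = 0.32, HPF = 0.08, CTXsp = 0.04, STR = 0.10,
            PAL = 0.04, TH = 0.12, HY = 0.08, MB = 0.10, P = 0.06,
            OLF = 0.02, CB = 0.02, MY = 0.02)
  regionProbs <- list(
    # isocortex share planted high at ZT0-4, low at ZT12-16
    "ZT0-4"   = replace(base, c("Isocortex", "TH", "MB"),
                        c(0.40, 0.08, 0.06)),
    "ZT8-12"  = base,
    "ZT12-16" = replace(base, c("Isocortex", "TH", "MB"),
                        c(0.26, 0.15, 0.13)),
    "ZT20-24" = replace(base, c("Isocortex", "TH"), c(0.36, 0.08)))
  light <- c(VISp = 0.30, RSPagl = 0.14, ACA = 0.14, PL = 0.14,
             TEa = 0.14, PTLp = 0.14)
  dark <- c(VISp = 0.18, RSPagl = 0.17, ACA = 0.17, PL = 0.16,
            TEa = 0.16, PTLp = 0.16)
  areaProbs <- list("ZT0-4" = light, "ZT8-12" = light,
                    "ZT12-16" = dark, "ZT20-24" = dark)
  baseLayers <- c("L1" = 0.08, "L2/3" = 0.26, "L4" = 0.16, "L5" = 0.26,
                  "L6a" = 0.16, "L6b" = 0.08)
  layerProbs <- list(
    "ZT0-4" = baseLayers, "ZT8-12" = baseLayers, "ZT12-16" = baseLayers,
    # layer-5 enrichment at the end of the dark period
    "ZT20-24" = c("L1" = 0.07, "L2/3" = 0.20, "L4" = 0.12, "L5" = 0.38,
                  "L6a" = 0.15, "L6b" = 0.08))
  cortexTypes <- c(glutamatergic = 0.80, GABAergic = 0.18,
                   dopaminergic = 0, other = 0.02)
  defaultTypes <- c(glutamatergic = 0.60, GABAergic = 0.35,
                    dopaminergic = 0, other = 0.05)
  typeProbs <- list(
    RT = c(glutamatergic = 0.01, GABAergic = 0.98, dopaminergic = 0,
           other = 0.01),
    VTA = c(glutamatergic = 0.14, GABAergic = 0.20, dopaminergic = 0.65,
            other = 0.01),
    LGd = c(glutamatergic = 0.92, GABAergic = 0.06, dopaminergic = 0,
            other = 0.02),
    AV = c(glutamatergic = 0.92, GABAergic = 0.06, dopaminergic = 0,
           other = 0.02))
  cfg <- list(seed = as.integer(seed), conditions = conditions,
              nNeuronsPerBrain = as.integer(nNeuronsPerBrain),
              brainsPerCondition = as.integer(brainsPerCondition),
              refCellsTotal = as.integer(refCellsTotal),
              nonNeuronalFraction = nonNeuronalFraction,
              segregation = segregation,
              mirroredFraction = mirroredFraction,
              withinDensity = withinDensity,
              betweenDensity = betweenDensity,
              nBlocks = as.integer(nBlocks),
              bridgeRegion = bridgeRegion,
              voxelSizeUm = voxelSizeUm,
              regionProbs = regionProbs, areaProbs = areaProbs,
              layerProbs = layerProbs,
              cortexTypes = cortexTypes, defaultTypes = defaultTypes,
              typeProbs = typeProbs)
  for (p in cfg$regionProbs) stopifnot(abs(sum(p) - 1) < 1e-9)
  for (p in cfg$layerProbs) stopifnot(abs(sum(p) - 1) < 1e-9)
  for (p in cfg$typeProbs) stopifnot(abs(sum(p) - 1) < 1e-9)
  class(cfg) <- "simConfig"
  cfg
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

#' Generate the fixture atlas
#'
#' Builds a small but structurally faithful atlas: a hierarchy
#' root -> major regions -> (cortical areas -> layer leaves | subcortical
#' leaves), and an annotation volume of non-overlapping rectangular parcels
#' (one per leaf) laid out on a grid, mirrored across the mid-plane of the
#' third axis so that both hemispheres carry the same labels. The
#' transcriptomic reference covers only the low-z hemisphere.
#'
#' @param cfg a [simConfig()].
#' @return list with \code{hierarchy} ([RegionHierarchy-class]),
#'   \code{volume} ([AnnotationVolume-class]), \code{parcels} (data.frame
#'   of voxel extents per leaf, reference hemisphere), and
#'   \code{midlineUm} (midline coordinate along z in um).
#' @export
makeAtlas <- function(cfg) {
  nodes <- data.frame(id = 1L, acronym = "root", name = "root brain",
                      parent_id = NA_integer_, stringsAsFactors = FALSE)
  nextId <- 2L
  addNode <- function(acr, parent) {
    nodes <<- rbind(nodes, data.frame(
      id = nextId, acronym = acr, name = paste("synthetic", acr),
      parent_id = parent, stringsAsFactors = FALSE))
    nextId <<- nextId + 1L
    nextId - 1L
  }
  leafAcr <- character(); leafParentMajor <- character()
  for (maj in .simMajors) {
    mid <- addNode(maj, 1L)
    if (maj == "Isocortex") {
      for (area in .simAreas) {
        aid <- addNode(area, mid)
        for (tok in .simLayerTokens) {
          addNode(paste0(area, tok), aid)
          leafAcr <- c(leafAcr, paste0(area, tok))
          leafParentMajor <- c(leafParentMajor, maj)
        }
      }
    } else {
      for (lf in .simSubLeaves[[maj]]) {
        addNode(lf, mid)
        leafAcr <- c(leafAcr, lf)
        leafParentMajor <- c(leafParentMajor, maj)
      }
    }
  }
  h <- RegionHierarchy(nodes)
  # grid layout: cortical leaves at (area column, layer row); subcortical
  # leaves fill the remaining columns
  b <- 8L  # voxels per parcel edge
  nCort <- length(.simAreas) * length(.simLayerTokens)
  sub <- leafAcr[-seq_len(nCort)]
  gxCort <- length(.simAreas)
  gxSub <- ceiling(length(sub) / length(.simLayerTokens))
  gx <- gxCort + gxSub
  gy <- length(.simLayerTokens)
  parcels <- data.frame(acronym = leafAcr, x0 = NA_integer_,
                        y0 = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(leafAcr)) {
    if (i <= nCort) {
      ax <- (i - 1L) %/% gy; ly <- (i - 1L) %% gy
    } else {
      j <- i - nCort - 1L
      ax <- gxCort + j %/% gy; ly <- j %% gy
    }
    parcels$x0[i] <- ax * b; parcels$y0[i] <- ly * b
  }
  parcels$x1 <- parcels$x0 + b; parcels$y1 <- parcels$y0 + b
  parcels$z0 <- 0L; parcels$z1 <- b
  key <- paste(parcels$x0, parcels$y0)
  if (anyDuplicated(key)) stop("parcel construction error: overlap")
  vol <- array(0L, dim = c(gx * b, gy * b, 2L * b))
  for (i in seq_len(nrow(parcels))) {
    id <- acronymToId(h, parcels$acronym[i])
    xs <- (parcels$x0[i] + 1L):parcels$x1[i]
    ys <- (parcels$y0[i] + 1L):parcels$y1[i]
    zs <- (parcels$z0[i] + 1L):parcels$z1[i]
    if (any(vol[xs, ys, zs] != 0L))
      stop("parcel construction error: overlap at ", parcels$acronym[i])
    vol[xs, ys, zs] <- id
    vol[xs, ys, (2L * b + 1L) - zs] <- id  # mirrored hemisphere
  }
  volume <- AnnotationVolume(vol, cfg$voxelSizeUm, h)
  list(hierarchy = h, volume = volume, parcels = parcels,
       midlineUm = b * cfg$voxelSizeUm)
}

.leafTable <- function(atlas) {
  p <- atlas$parcels
  p$major <- ancestorAtLevel(acronymToId(atlas$hierarchy, p$acronym),
                             .simMajors, atlas$hierarchy)
  p
}

.drawInParcel <- function(parcel, n, voxelUm, mirrored) {
  lo <- c(parcel$x0, parcel$y0, parcel$z0) * voxelUm
  hi <- c(parcel$x1, parcel$y1, parcel$z1) * voxelUm
  pts <- cbind(stats::runif(n, lo[1], hi[1]),
               stats::runif(n, lo[2], hi[2]),
               stats::runif(n, lo[3], hi[3]))
  if (length(mirrored) == 1L) mirrored <- rep(mirrored, n)
  zmax <- 2 * parcel$z1 * voxelUm  # full volume z extent (parcel spans one half)
  pts[mirrored, 3] <- zmax - pts[mirrored, 3]
  pts
}

#' Generate activity-tagged neuron tables with planted effects
#'
#' Draws, per brain, each neuron's major region from the condition's
#' regional probabilities, a cortical area and layer (for isocortical
#' neurons) from the condition's area and layer probabilities, a uniform
#' leaf for subcortical neurons, a hemisphere (Bernoulli
#' \code{mirroredFraction}), and a uniform position inside the leaf's
#' parcel. Ground-truth labels travel with every row.
#'
#' @param cfg a [simConfig()].
#' @param atlas output of [makeAtlas()].
#' @return data.frame with \code{neuron_id}, \code{brain_id},
#'   \code{condition}, \code{x_um}, \code{y_um}, \code{z_um} and truth
#'   columns \code{true_leaf}, \code{true_major}, \code{true_layer},
#'   \code{true_type} (the neuron's neurotransmitter class, drawn from the
#'   region's type probabilities; under spatial segregation the neuron's x
#'   position is placed inside its type's core slab, mirroring the
#'   reference's layout), \code{hemisphere}.
#' @export
makeBrains <- function(cfg, atlas) {
  leaves <- .leafTable(atlas)
  out <- list()
  bi <- 0L
  for (cond in cfg$conditions) {
    for (bn in seq_len(cfg$brainsPerCondition)) {
      bi <- bi + 1L
      brain <- sprintf("%s_b%d", cond, bn)
      df <- .withSeed(cfg$seed + 1000L + bi * 97L, {
        n <- cfg$nNeuronsPerBrain
        majors <- sample(names(cfg$regionProbs[[cond]]), n, replace = TRUE,
                         prob = cfg$regionProbs[[cond]])
        leaf <- character(n)
        layer <- rep(NA_character_, n)
        cort <- majors == "Isocortex"
        if (any(cort)) {
          areas <- sample(names(cfg$areaProbs[[cond]]), sum(cort),
                          replace = TRUE, prob = cfg$areaProbs[[cond]])
          lays <- sample(names(cfg$layerProbs[[cond]]), sum(cort),
                         replace = TRUE, prob = cfg$layerProbs[[cond]])
          leaf[cort] <- paste0(areas, sub("^L", "", lays))
          layer[cort] <- lays
        }
        for (maj in setdiff(unique(majors), "Isocortex")) {
          i <- majors == maj
          pool <- leaves$acronym[leaves$major == maj]
          leaf[i] <- sample(pool, sum(i), replace = TRUE)
        }
        mirrored <- stats::runif(n) < cfg$mirroredFraction
        xyz <- matrix(NA_real_, n, 3)
        trueType <- character(n)
        for (lf in unique(leaf)) {
          i <- which(leaf == lf)
          p <- leaves[leaves$acronym == lf, ]
          xyz[i, ] <- .drawInParcel(p, length(i), cfg$voxelSizeUm,
                                    mirrored[i])
          probs <- .typeProbsFor(cfg, lf, p$major)
          trueType[i] <- sample(names(probs), length(i), replace = TRUE,
                                prob = probs)
          if (cfg$segregation > 0) {
            seg <- stats::runif(length(i)) < cfg$segregation
            relx <- .slabRelX(probs, trueType[i],
                              stats::runif(length(i)))
            x0 <- p$x0 * cfg$voxelSizeUm
            wx <- (p$x1 - p$x0) * cfg$voxelSizeUm
            xyz[i, 1][seg] <- (x0 + relx * wx)[seg]
          }
        }
        data.frame(
          neuron_id = sprintf("%s_n%05d", brain, seq_len(n)),
          brain_id = brain, condition = cond,
          x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
          true_leaf = leaf, true_major = majors, true_layer = layer,
          true_type = trueType,
          hemisphere = ifelse(mirrored, "far", "reference"),
          stringsAsFactors = FALSE)
      })
      out[[brain]] <- df
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.typeProbsFor <- function(cfg, acronym, major) {
  if (!is.null(cfg$typeProbs[[acronym]])) cfg$typeProbs[[acronym]]
  else if (major == "Isocortex") cfg$cortexTypes
  else cfg$defaultTypes
}

# Type slab boundaries along x inside a parcel: each type with positive
# probability owns a slab of width proportional to its probability, but
# cells are placed only in the central core of the slab, leaving gaps
# between neighboring type clusters so that the clusters are spatially
# disjoint (the regime where nearest-neighbor identity transfer is
# reliable).
.slabCoreFrac <- 0.6

.slabEdges <- function(probs) {
  present <- names(probs)[probs > 0]
  w <- probs[present] / sum(probs[present])
  list(types = present, edges = c(0, cumsum(w)), w = w)
}

# Relative x in [0, 1] for cells of the given types: uniform u mapped into
# the central core of each type's slab.
.slabRelX <- function(probs, types, u) {
  s <- .slabEdges(probs)
  ti <- match(types, s$types)
  lo <- s$edges[ti] + (1 - .slabCoreFrac) / 2 * s$w[ti]
  lo + u * .slabCoreFrac * s$w[ti]
}

#' Generate the spatial transcriptomic reference
#'
#' Populates every leaf parcel of the reference hemisphere with cells:
#' neurotransmitter types are drawn from the per-region type
#' probabilities; with \code{segregation = 1} each type occupies its own
#' slab of the parcel along x (spatially segregated types, the regime in
#' which nearest-neighbor identity transfer is accurate), with 0 the types
#' are fully interleaved. A configurable fraction of cells is
#' non-neuronal and must be excluded by the matching step.
#'
#' @param cfg a [simConfig()].
#' @param atlas output of [makeAtlas()].
#' @return reference data.frame (see [checkReference()]) with an extra
#'   truth column \code{true_type}.
#' @export
makeReference <- function(cfg, atlas) {
  leaves <- .leafTable(atlas)
  nLeaf <- nrow(leaves)
  perLeaf <- rep(cfg$refCellsTotal %/% nLeaf, nLeaf)
  perLeaf[seq_len(cfg$refCellsTotal %% nLeaf)] <-
    perLeaf[seq_len(cfg$refCellsTotal %% nLeaf)] + 1L
  .withSeed(cfg$seed + 20000L, {
    rows <- vector("list", nLeaf)
    cellCounter <- 0L
    for (i in seq_len(nLeaf)) {
      p <- leaves[i, ]
      n <- perLeaf[i]
      nNon <- floor(cfg$nonNeuronalFraction * n)
      nNeu <- n - nNon
      probs <- .typeProbsFor(cfg, p$acronym, p$major)
      types <- sample(names(probs), nNeu, replace = TRUE, prob = probs)
      xyz <- .drawInParcel(p, n, cfg$voxelSizeUm, FALSE)
      if (cfg$segregation > 0 && nNeu > 0) {
        # per-type core slabs along x, widths proportional to probability
        x0 <- p$x0 * cfg$voxelSizeUm
        wx <- (p$x1 - p$x0) * cfg$voxelSizeUm
        seg <- stats::runif(nNeu) < cfg$segregation
        relx <- .slabRelX(probs, types, stats::runif(nNeu))
        xyz[seq_len(nNeu), 1][seg] <- (x0 + relx * wx)[seg]
      }
      id <- acronymToId(atlas$hierarchy, p$acronym)
      rows[[i]] <- data.frame(
        cell_id = sprintf("C%07d", cellCounter + seq_len(n)),
        x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
        region_id = id,
        is_neuron = c(rep(TRUE, nNeu), rep(FALSE, nNon)),
        neurotransmitter = c(types, rep("none", nNon)),
        true_type = c(types, rep("none", nNon)),
        stringsAsFactors = FALSE)
      cellCounter <- cellCounter + n
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
  })
}

#' Generate a block-structured connection-density matrix
#'
#' A planted-partition (stochastic-block-style) density matrix over the
#' network regions: contiguous blocks of regions with mean within-block
#' density \code{withinDensity} and mean between-block density
#' \code{betweenDensity} (multiplicative uniform noise in [0.8, 1.2]),
#' zero diagonal. An optional bridge region receives within-level density
#' on all its links to every block, making it the dominant shortest-path
#' intermediary.
#'
#' @param cfg a [simConfig()].
#' @param regions character vector of region acronyms (defaults to
#'   [simNetworkRegions()]).
#' @return list with \code{density} ([DensityMatrix-class]) and
#'   \code{blocks} (named integer vector: planted module per region).
#' @export
makeDensity <- function(cfg, regions = simNetworkRegions()) {
  R <- length(regions)
  # contiguous assignment: first ~R/nBlocks regions in block 1, ...
  blocks <- stats::setNames(
    as.integer(cut(seq_len(R), breaks = cfg$nBlocks, labels = FALSE)),
    regions)
  rho <- .withSeed(cfg$seed + 30000L, {
    same <- outer(blocks, blocks, "==")
    mu <- ifelse(same, cfg$withinDensity, cfg$betweenDensity)
    noise <- matrix(stats::runif(R * R, 0.8, 1.2), R, R)
    m <- mu * noise
    if (!is.null(cfg$bridgeRegion)) {
      bi <- match(cfg$bridgeRegion, regions)
      if (is.na(bi)) stop("bridge region not in region set: ",
                          cfg$bridgeRegion)
      bn <- stats::runif(2L * R, 0.9, 1.1)
      m[bi, ] <- cfg$withinDensity * bn[seq_len(R)]
      m[, bi] <- cfg$withinDensity * bn[R + seq_len(R)]
    }
    diag(m) <- 0
    m
  })
  list(density = DensityMatrix(rho, regions), blocks = blocks)
}

#' Run the full generator and write all pipeline inputs to disk
#'
#' Emits the exact file formats consumed by the analysis modules:
#' \code{tree.json} (structure-graph JSON), \code{annotation.nrrd},
#' \code{neurons.csv}, \code{reference.csv}, \code{density.csv}, a
#' \code{dmn.txt} region-set file, and a \code{truth/} directory holding
#' the planted parameters (JSON).
#'
#' @param cfg a [simConfig()].
#' @param outDir output directory (created if needed).
#' @return \code{outDir}, invisibly.
#' @export
simulateAll <- function(cfg, outDir) {
  dir.create(file.path(outDir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  atlas <- makeAtlas(cfg)
  nd <- atlas$hierarchy@nodes
  tree <- lapply(seq_len(nrow(nd)), function(i) list(
    id = nd$id[i], acronym = nd$acronym[i], name = nd$name[i],
    parent_structure_id = if (is.na(nd$parent_id[i])) NA else
      nd$parent_id[i],
    structure_id_path = paste0("/", paste(idPath(atlas$hierarchy, nd$id[i]),
                                          collapse = "/"), "/")))
  jsonlite::write_json(tree, file.path(outDir, "tree.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeNrrd(atlas$volume, file.path(outDir, "annotation.nrrd"))
  neurons <- makeBrains(cfg, atlas)
  utils::write.csv(neurons, file.path(outDir, "neurons.csv"),
                   row.names = FALSE)
  reference <- makeReference(cfg, atlas)
  utils::write.csv(reference, file.path(outDir, "reference.csv"),
                   row.names = FALSE)
  dens <- makeDensity(cfg)
  writeMatrixCsv(dens$density, file.path(outDir, "density.csv"))
  writeLines(c("ACA", "PL", "RSPagl", "PTLp"),
             file.path(outDir, "dmn.txt"))
  jsonlite::write_json(
    list(seed = cfg$seed, blocks = as.list(dens$blocks),
         midline_um = atlas$midlineUm,
         region_probs = cfg$regionProbs, layer_probs = cfg$layerProbs),
    file.path(outDir, "truth", "planted.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(outDir)
}
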