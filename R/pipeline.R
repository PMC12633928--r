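# End-to-end pipeline: assign -> stats -> match -> connect -> network,
# driven by a single keyed configuration, with a deterministic manifest.

#' Major regions of a hierarchy (children of the root)
#'
#' @param h a [RegionHierarchy-class].
#' @return character vector of acronyms directly below the root.
#' @export
rootChildren <- function(h) {
  rootId <- h@nodes$id[is.na(h@nodes$parent_id)]
  h@nodes$acronym[!is.na(h@nodes$parent_id) & h@nodes$parent_id == rootId]
}

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or YAML/JSON file parsed into one)
#' with keys: \code{neurons}, \code{tree}, \code{annotation},
#' \code{reference}, \code{density}, \code{region_set} (file paths);
#' \code{out_dir}; and optional \code{exclusions} (default OLF/CB/MY),
#' \code{midline_um} (default: half the annotation extent along the mirror
#' axis), \code{mirror_axis} (default 3), \code{gamma_min}/\code{gamma_max}
#' /\code{gamma_steps} (default 0.5/2/21), \code{top_k} (default 10),
#' \code{seed} (default 1), \code{restarts} (default 10).
#'
#' @param config named list or path to a YAML (needs the yaml package) or
#'   JSON file.
#' @return the completed configuration list.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the yaml package")
      yaml::read_yaml(config)
    } else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  req <- c("neurons", "tree", "annotation", "reference", "density",
           "out_dir")
  miss <- setdiff(req, names(config))
  if (length(miss))
    stop("run config missing key(s): ", paste(miss, collapse = ", "))
  for (key in c("neurons", "tree", "annotation", "reference", "density",
                "region_set")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop("config path for '", key, "' does not exist: ", config[[key]])
  }
  defaults <- list(exclusions = c("OLF", "CB", "MY"), mirror_axis = 3L,
                   gamma_min = 0.5, gamma_max = 2, gamma_steps = 21L,
                   top_k = 10L, seed = 1L, restarts = 10L)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  config
}

#' Run the full analysis pipeline
#'
#' Executes the five stages in dependency order — region assignment,
#' regional statistics, transcriptomic matching, active-connectivity
#' construction, network analysis — writing every intermediate table as
#' CSV under \code{out_dir} and a \code{manifest.json} recording input
#' checksums, the seed, and per-stage status and row counts. A failed
#' stage is recorded and its downstream stages are skipped. Re-running
#' with identical inputs reproduces byte-identical outputs.
#'
#' @param config see [validateRunConfig()].
#' @return the manifest, invisibly (a named list).
#' @export
runPipeline <- function(config) {
  cfg <- validateRunConfig(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- c("neurons", "tree", "annotation", "reference", "density",
              "region_set")
  inputs <- inputs[!vapply(cfg[inputs], is.null, logical(1))]
  manifest <- list(
    package_version = as.character(utils::packageVersion("fosnet")),
    seed = cfg$seed,
    inputs = lapply(stats::setNames(cfg[inputs], inputs),
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    stages = list())
  state <- new.env(parent = emptyenv())
  failed <- character()
  stage <- function(name, deps, fun) {
    if (length(intersect(deps, failed))) {
      manifest$stages[[name]] <<- list(status = "skipped",
                                       blocked_by = intersect(deps, failed))
      failed <<- c(failed, name)
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      failed <<- c(failed, name)
      message("stage ", name, " failed: ", conditionMessage(res))
    } else {
      manifest$stages[[name]] <<- c(list(status = "ok"), res)
    }
    invisible(NULL)
  }

  stage("assign", character(), function() {
    state$h <- loadStructureTree(cfg$tree)
    state$vol <- readNrrd(cfg$annotation)
    neurons <- readNeuronTable(cfg$neurons)
    state$neurons <- assignRegions(neurons, state$vol)
    out <- file.path(cfg$out_dir, "assigned_neurons.csv")
    utils::write.csv(state$neurons, out, row.names = FALSE)
    list(rows = nrow(state$neurons),
         unassigned = sum(state$neurons$region_id == 0L))
  })

  stage("stats", "assign", function() {
    majors <- setdiff(rootChildren(state$h), cfg$exclusions)
    counts <- countRegionsByBrain(state$neurons, state$h, majors,
                                  cfg$exclusions)
    ratios <- regionRatios(counts)
    z <- zscoreAcrossConditions(ratios)
    utils::write.csv(counts, file.path(cfg$out_dir, "region_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(z, file.path(cfg$out_dir, "region_ratios.csv"),
                     row.names = FALSE)
    if ("Isocortex" %in% majors) {
      lr <- layerRatios(state$neurons, "Isocortex", state$h)
      utils::write.csv(lr, file.path(cfg$out_dir, "layer_ratios.csv"),
                       row.names = FALSE)
    }
    state$counts <- counts
    list(rows = nrow(counts))
  })

  stage("match", "assign", function() {
    reference <- readReferenceTable(cfg$reference)
    midline <- cfg$midline_um
    if (is.null(midline)) {
      ext <- dim(annotationArray(state$vol)) * voxelSize(state$vol)
      midline <- ext[cfg$mirror_axis] / 2
    }
    mirrored <- mirrorToReferenceHemisphere(state$neurons, midline,
                                            cfg$mirror_axis)
    matches <- matchTwins(mirrored, reference)
    utils::write.csv(matches, file.path(cfg$out_dir, "matches.csv"),
                     row.names = FALSE)
    majors <- setdiff(rootChildren(state$h), cfg$exclusions)
    comp <- neurotransmitterComposition(matches, mirrored, majors, state$h)
    utils::write.csv(comp$fractions,
                     file.path(cfg$out_dir, "nt_composition.csv"),
                     row.names = FALSE)
    utils::write.csv(comp$ei, file.path(cfg$out_dir, "ei_ratio.csv"),
                     row.names = FALSE)
    qc <- distanceQC(matches)
    list(rows = nrow(matches), matched = sum(matches$matched),
         median_distance_um = unname(qc$quantiles[1]))
  })

  stage("connect", "assign", function() {
    rho <- readDensityMatrix(cfg$density)
    acs <- list()
    for (b in unique(state$neurons$brain_id)) {
      sub <- state$neurons[state$neurons$brain_id == b, , drop = FALSE]
      rc <- countRegions(sub, state$h, regionAcronyms(rho), cfg$exclusions)
      ac <- buildActiveConnectivity(rho, rc)
      acs[[b]] <- ac
      writeMatrixCsv(ac, file.path(cfg$out_dir,
                                   paste0("connectivity_", gsub("[^A-Za-z0-9_-]", "_", b),
                                          ".csv")))
    }
    state$acs <- acs
    conds <- unique(vapply(acs, condition, character(1)))
    state$avg <- lapply(stats::setNames(conds, conds), function(cd) {
      avg <- averageCondition(acs[vapply(acs, condition,
                                         character(1)) == cd])
      writeMatrixCsv(avg, file.path(cfg$out_dir,
                                    paste0("connectivity_avg_", gsub("[^A-Za-z0-9_-]", "_", cd),
                                           ".csv")))
      avg
    })
    list(brains = length(acs), conditions = length(conds))
  })

  stage("network", "connect", function() {
    gammas <- seq(cfg$gamma_min, cfg$gamma_max,
                  length.out = cfg$gamma_steps)
    modRows <- list(); partRows <- list()
    for (cd in names(state$avg)) {
      sw <- modularitySweep(state$avg[[cd]], gammas, seed = cfg$seed,
                            restarts = cfg$restarts)
      sw$condition <- cd
      modRows[[cd]] <- sw
      det <- detectModules(state$avg[[cd]], gamma = 1, seed = cfg$seed,
                           restarts = cfg$restarts)
      partRows[[cd]] <- data.frame(condition = cd,
                                   acronym = names(det$membership),
                                   module = unname(det$membership),
                                   stringsAsFactors = FALSE)
    }
    utils::write.csv(do.call(rbind, modRows),
                     file.path(cfg$out_dir, "modularity.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, partRows),
                     file.path(cfg$out_dir, "partition.csv"),
                     row.names = FALSE)
    ct <- do.call(rbind, lapply(state$acs, betweennessCentrality))
    rownames(ct) <- NULL
    utils::write.csv(ct, file.path(cfg$out_dir, "centrality.csv"),
                     row.names = FALSE)
    hubs <- do.call(rbind, lapply(split(ct, ct$condition), function(g) {
      hk <- rankHubs(g, min(cfg$top_k, length(unique(g$acronym))))
      hk$condition <- g$condition[1]
      hk
    }))
    rownames(hubs) <- NULL
    utils::write.csv(hubs, file.path(cfg$out_dir, "hubs.csv"),
                     row.names = FALSE)
    if (!is.null(cfg$region_set)) {
      rs <- readLines(cfg$region_set)
      rs <- trimws(rs[nzchar(trimws(rs))])
      sc <- setCentrality(ct, rs)
      utils::write.csv(sc$per_condition,
                       file.path(cfg$out_dir, "region_set_centrality.csv"),
                       row.names = FALSE)
    }
    list(rows = nrow(ct))
  })

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
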