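# Synthetic-data generator: structure, determinism, planted-parameter
# recovery at fixture scale.

test_that("the fixture atlas is consistent: labels in hierarchy, parcels
           disjoint, volumes as configured", {
  cfg <- smallSimConfig()
  atlas <- makeAtlas(cfg)
  v <- annotationArray(atlas$volume)
  labs <- setdiff(unique(as.vector(v)), 0L)
  expect_true(all(labs %in% atlas$hierarchy@nodes$id))
  # each parcel occupies exactly its configured voxel count in each
  # hemisphere
  p <- atlas$parcels[1, ]
  nvox <- (p$x1 - p$x0) * (p$y1 - p$y0) * (p$z1 - p$z0)
  id <- acronymToId(atlas$hierarchy, p$acronym)
  expect_identical(sum(v == id), as.integer(2 * nvox))
  # hemispheres are mirror images
  nz <- dim(v)[3]
  expect_identical(v[, , 1:(nz / 2)], v[, , nz:(nz / 2 + 1)])
})

test_that("the generator is byte-deterministic in its seed", {
  cfg <- smallSimConfig(seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateAll(cfg, d1)
  simulateAll(cfg, d2)
  files <- sort(list.files(d1, recursive = TRUE))
  expect_identical(files, sort(list.files(d2, recursive = TRUE)))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  # a different seed changes the neuron draw
  d3 <- withr::local_tempdir()
  simulateAll(smallSimConfig(seed = 78), d3)
  expect_false(unname(tools::md5sum(file.path(d1, "neurons.csv"))) ==
                 unname(tools::md5sum(file.path(d3, "neurons.csv"))))
})

test_that("planted regional composition is recovered within binomial
           error", {
  cfg <- simConfig(seed = 41, nNeuronsPerBrain = 5000L,
                   brainsPerCondition = 1L, refCellsTotal = 1000L)
  atlas <- makeAtlas(cfg)
  neurons <- assignRegions(makeBrains(cfg, atlas), atlas$volume)
  for (cond in c("ZT0-4", "ZT12-16")) {
    sub <- neurons[neurons$condition == cond, ]
    rc <- countRegions(sub, atlas$hierarchy,
                       setdiff(rootChildren(atlas$hierarchy),
                               c("OLF", "CB", "MY")))
    # planted probability renormalized to the non-excluded scope
    p <- cfg$regionProbs[[cond]]
    pIso <- p[["Isocortex"]] / sum(p[setdiff(names(p),
                                             c("OLF", "CB", "MY"))])
    got <- rc$counts[["Isocortex"]] / rc$total
    se <- sqrt(pIso * (1 - pIso) / rc$total)
    expect_lt(abs(got - pIso), 3 * se)
  }
})

test_that("planted layer-5 enrichment is recovered and detected", {
  cfg <- simConfig(seed = 43, nNeuronsPerBrain = 5000L,
                   brainsPerCondition = 3L, refCellsTotal = 1000L)
  atlas <- makeAtlas(cfg)
  neurons <- assignRegions(makeBrains(cfg, atlas), atlas$volume)
  lr <- layerRatios(neurons, "Isocortex", atlas$hierarchy)
  l5 <- lr[lr$layer == "L5", ]
  late <- l5$ratio[l5$condition == "ZT20-24"]
  base <- l5$ratio[l5$condition == "ZT12-16"]
  expect_gt(mean(late), mean(base))
  # planted values inside binomial CI
  nCortex <- table(neurons$brain_id[!is.na(neurons$true_layer)])
  for (b in unique(l5$brain_id)) {
    cond <- unique(lr$condition[lr$brain_id == b])
    want <- cfg$layerProbs[[cond]][["L5"]]
    n <- as.integer(nCortex[[b]])
    se <- sqrt(want * (1 - want) / n)
    expect_lt(abs(l5$ratio[l5$brain_id == b] - want), 3 * se)
  }
  cmp <- compareGroups(late, base)
  expect_lt(cmp$p_value, 0.05)
})

test_that("planted per-region type proportions are recovered through the
           full matching path", {
  cfg <- smallSimConfig(seed = 47)
  atlas <- makeAtlas(cfg)
  neurons <- assignRegions(makeBrains(cfg, atlas), atlas$volume)
  ref <- makeReference(cfg, atlas)
  mir <- mirrorToReferenceHemisphere(neurons, atlas$midlineUm, 3L)
  m <- matchTwins(mir, ref)
  rtId <- acronymToId(atlas$hierarchy, "RT")
  rt <- m$neurotransmitter[m$matched & neurons$region_id == rtId]
  pGaba <- cfg$typeProbs$RT[["GABAergic"]]
  se <- sqrt(pGaba * (1 - pGaba) / length(rt))
  expect_lt(abs(mean(rt == "GABAergic") - pGaba), 3 * se + 0.02)
  vtaId <- acronymToId(atlas$hierarchy, "VTA")
  vta <- m$neurotransmitter[m$matched & neurons$region_id == vtaId]
  pDa <- cfg$typeProbs$VTA[["dopaminergic"]]
  seD <- sqrt(pDa * (1 - pDa) / length(vta))
  expect_lt(abs(mean(vta == "dopaminergic") - pDa), 3 * seD + 0.02)
})

test_that("non-neuronal reference rows are exactly the ones excluded from
           matching", {
  cfg <- smallSimConfig(seed = 51, nonNeuronalFraction = 0.3)
  atlas <- makeAtlas(cfg)
  ref <- makeReference(cfg, atlas)
  expect_equal(mean(!ref$is_neuron), 0.3, tolerance = 0.01)
  neurons <- assignRegions(makeBrains(cfg, atlas), atlas$volume)
  mir <- mirrorToReferenceHemisphere(
    neurons[neurons$brain_id == neurons$brain_id[1], ][1:150, ],
    atlas$midlineUm, 3L)
  m <- matchTwins(mir, ref)
  twinIsNeuron <- ref$is_neuron[match(m$twin_cell_id, ref$cell_id)]
  expect_true(all(twinIsNeuron[m$matched]))
})

test_that("the density generator plants the requested block structure", {
  cfg <- simConfig(seed = 53, withinDensity = 0.5, betweenDensity = 0.05)
  dens <- makeDensity(cfg)
  R <- weightMatrix(dens$density)
  expect_true(all(diag(R) == 0))
  expect_true(all(R >= 0))
  same <- outer(dens$blocks, dens$blocks, "==")
  diag(same) <- NA
  expect_gt(mean(R[same & !is.na(same)]), 5 * mean(R[!same & !is.na(same)]))
  expect_identical(length(unique(dens$blocks)), cfg$nBlocks)
})
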