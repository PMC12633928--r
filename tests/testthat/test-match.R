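# Hemisphere mirroring, region-constrained 1-NN matching, distance QC,
# neurotransmitter composition.

refCells <- function(x, y, z, region, nt = "glutamatergic",
                     neuron = TRUE, id = NULL) {
  n <- length(x)
  data.frame(cell_id = if (is.null(id)) sprintf("C%03d", seq_len(n)) else id,
             x_um = x, y_um = y, z_um = z, region_id = region,
             is_neuron = neuron,
             neurotransmitter = rep_len(nt, n), stringsAsFactors = FALSE)
}

test_that("mirroring reflects only the far hemisphere and is an involution", {
  df <- data.frame(neuron_id = c("a", "b", "c"), x_um = 0, y_um = 0,
                   z_um = c(40, 100, 160))
  m <- mirrorToReferenceHemisphere(df, 100, axis = 3L)
  expect_equal(m$z_um, c(40, 100, 40))
  expect_identical(m$mirrored, c(FALSE, FALSE, TRUE))
  # reflecting the reflected coordinate restores the original
  back <- 2 * 100 - m$z_um[3]
  expect_equal(back, df$z_um[3])
  # reference on the high side flips the other rows
  m2 <- mirrorToReferenceHemisphere(df, 100, axis = 3L,
                                    referenceSide = "high")
  expect_equal(m2$z_um, c(160, 100, 160))
})

test_that("twins minimize distance within the region, never across it", {
  # nearest cell overall is in region 13, but the neuron sits in region 7
  ref <- refCells(x = c(0, 2), y = 0, z = 0, region = c(7L, 13L),
                  nt = c("glutamatergic", "GABAergic"))
  neuron <- data.frame(neuron_id = "n1", x_um = 1.9, y_um = 0, z_um = 0,
                       region_id = 7L)
  m <- matchTwins(neuron, ref)
  expect_identical(m$twin_cell_id, "C001")
  expect_equal(m$distance_um, 1.9)
  expect_identical(m$neurotransmitter, "glutamatergic")
  # coincident cell gives distance zero
  m0 <- matchTwins(data.frame(neuron_id = "n2", x_um = 0, y_um = 0,
                              z_um = 0, region_id = 7L), ref)
  expect_equal(m0$distance_um, 0)
})

test_that("distance ties break on the smallest cell_id", {
  ref <- refCells(x = c(1, -1), y = 0, z = 0, region = 7L,
                  id = c("B", "A"))
  m <- matchTwins(data.frame(neuron_id = "n", x_um = 0, y_um = 0,
                             z_um = 0, region_id = 7L), ref)
  expect_identical(m$twin_cell_id, "A")
})

test_that("neurons without same-region reference are reported unmatched", {
  ref <- refCells(0, 0, 0, region = 7L)
  neurons <- data.frame(neuron_id = c("a", "b", "c"),
                        x_um = 0, y_um = 0, z_um = 0,
                        region_id = c(7L, 13L, 0L))
  m <- matchTwins(neurons, ref)
  expect_identical(m$matched, c(TRUE, FALSE, FALSE))
  expect_identical(m$reason, c("ok", "no_reference_in_region",
                               "unassigned"))
  expect_error(matchTwins(neurons, ref[ref$is_neuron == FALSE, ]),
               "no neurons")
})

test_that("non-neuronal reference cells are never chosen as twins", {
  ref <- rbind(refCells(0.1, 0, 0, 7L, neuron = FALSE, id = "NONNEU"),
               refCells(5, 0, 0, 7L, id = "NEU"))
  m <- matchTwins(data.frame(neuron_id = "n", x_um = 0, y_um = 0,
                             z_um = 0, region_id = 7L), ref)
  expect_identical(m$twin_cell_id, "NEU")
})

test_that("matching equals the exhaustive scan and respects regions on
           generated data", {
  cfg <- smallSimConfig(seed = 21)
  atlas <- makeAtlas(cfg)
  neurons <- assignRegions(makeBrains(cfg, atlas), atlas$volume)
  neurons <- neurons[neurons$brain_id == neurons$brain_id[1], ]
  ref <- makeReference(cfg, atlas)
  mir <- mirrorToReferenceHemisphere(neurons, atlas$midlineUm, 3L)
  m <- matchTwins(mir, ref)
  oracle <- oracleMatch(mir, ref)
  expect_identical(m$twin_cell_id, oracle$twin)
  expect_equal(m$distance_um, oracle$dist, tolerance = 1e-9)
  # hard constraint: twin region equals neuron region on every row
  twinRegion <- ref$region_id[match(m$twin_cell_id, ref$cell_id)]
  expect_true(all(twinRegion[m$matched] == m$region_id[m$matched]))
  # permutation invariance
  perm <- sample(nrow(mir))
  m2 <- matchTwins(mir[perm, ], ref)
  expect_identical(m2$twin_cell_id, m$twin_cell_id[perm])
})

test_that("planted mirrored pairs land on their counterparts after
           mirroring", {
  cfg <- smallSimConfig(seed = 5)
  atlas <- makeAtlas(cfg)
  neurons <- makeBrains(cfg, atlas)
  far <- neurons[neurons$hemisphere == "far", ][1:20, ]
  mir <- mirrorToReferenceHemisphere(far, atlas$midlineUm, 3L)
  # manually reflected copy must coincide exactly
  expect_equal(mir$z_um, 2 * atlas$midlineUm - far$z_um, tolerance = 1e-9)
  expect_true(all(mir$z_um <= atlas$midlineUm))
})

test_that("distance QC summarizes quantiles and threshold fractions", {
  m <- data.frame(matched = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                  distance_um = c(10, 20, 30, 200, NA))
  qc <- distanceQC(m)
  expect_equal(unname(qc$fraction_above[">100um"]), 0.25)
  expect_identical(qc$n_matched, 4L)
  expect_identical(qc$n_unmatched, 1L)
  zero <- distanceQC(data.frame(matched = TRUE, distance_um = c(0, 0)))
  expect_true(all(zero$quantiles == 0))
})

test_that("dense reference yields sub-40um median match distance", {
  cfg <- smallSimConfig(seed = 13)
  atlas <- makeAtlas(cfg)
  neurons <- assignRegions(makeBrains(cfg, atlas), atlas$volume)
  ref <- makeReference(cfg, atlas)
  mir <- mirrorToReferenceHemisphere(neurons, atlas$midlineUm, 3L)
  qc <- distanceQC(matchTwins(mir, ref))
  expect_lt(unname(qc$quantiles["50%"]), 40)
  expect_lt(unname(qc$fraction_above[">100um"]), 0.05)
})

test_that("composition fractions and E/I ratio follow the definition", {
  h <- fixtureHierarchy()
  neurons <- neuronsAt(h, rep("VISp5", 10))
  matches <- data.frame(
    neuron_id = neurons$neuron_id, region_id = neurons$region_id,
    twin_cell_id = "x", distance_um = 1,
    neurotransmitter = c(rep("glutamatergic", 8), rep("GABAergic", 2)),
    matched = TRUE, reason = "ok", stringsAsFactors = FALSE)
  comp <- neurotransmitterComposition(matches, neurons, "Isocortex", h)
  fr <- comp$fractions
  expect_equal(fr$fraction[fr$neurotransmitter == "glutamatergic"], 0.8)
  expect_equal(fr$fraction[fr$neurotransmitter == "GABAergic"], 0.2)
  expect_equal(comp$ei$ei_ratio, 4)
  # all-glutamatergic region flags undefined E/I
  matches$neurotransmitter <- "glutamatergic"
  comp2 <- neurotransmitterComposition(matches, neurons, "Isocortex", h)
  expect_true(comp2$ei$ei_undefined)
  expect_true(is.na(comp2$ei$ei_ratio))
})

test_that("segregated types are recovered accurately, interleaved types
           fall toward the chance baseline", {
  atlasOf <- function(cfg) makeAtlas(cfg)
  accuracyOf <- function(cfg) {
    atlas <- atlasOf(cfg)
    neurons <- assignRegions(makeBrains(cfg, atlas), atlas$volume)
    neurons <- neurons[neurons$brain_id == neurons$brain_id[1], ]
    ref <- makeReference(cfg, atlas)
    mir <- mirrorToReferenceHemisphere(neurons, atlas$midlineUm, 3L)
    m <- matchTwins(mir, ref)
    list(acc = mean(m$neurotransmitter[m$matched] ==
                      neurons$true_type[m$matched]),
         neurons = neurons, atlas = atlas)
  }
  seg <- accuracyOf(smallSimConfig(seed = 31, segregation = 1))
  expect_gte(seg$acc, 0.95)

  mix <- accuracyOf(smallSimConfig(seed = 31, segregation = 0))
  # chance baseline: agreement of two independent draws from the planted
  # per-region type proportions, averaged over the sampled neurons
  leaves <- fosnet:::.leafTable(mix$atlas)
  cfgMix <- smallSimConfig(seed = 31, segregation = 0)
  baseline <- mean(vapply(mix$neurons$true_leaf, function(a) {
    p <- fosnet:::.typeProbsFor(cfgMix, a,
                                leaves$major[leaves$acronym == a])
    sum(p^2)
  }, numeric(1)))
  expect_lt(abs(mix$acc - baseline), 0.1)
  expect_lt(mix$acc, seg$acc - 0.2)
})
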