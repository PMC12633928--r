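# fosnet

Regional, molecular, and network analysis of activity-tagged neurons in
the mouse brain.

## What problem this solves

Activity-tagging experiments (c-Fos–driven TRAP labeling combined with
whole-brain clearing and light-sheet imaging) yield, per animal, a table
of 3D coordinates of the neurons that were most active during a defined
time window, registered to the Allen Common Coordinate Framework (CCF).
`fosnet` is the downstream analysis layer for such data. It is written for
systems-neuroscience labs that already have segmented, atlas-registered
neuron coordinates and want to answer:

- **Where** was the brain active? Per-region counts and composition
  ratios at any anatomical scope (major regions, cortical areas,
  cortical layers), z-scored across conditions and compared between
  groups.
- **Which cell types** were active? Each tagged neuron inherits the
  molecular identity (neurotransmitter class) of its nearest neighbor
  *within the same atlas region* in a spatial transcriptomic reference —
  its "twin" — giving per-region neurotransmitter fractions and
  excitatory/inhibitory (E/I) ratios.
- **How do active regions communicate?** The **active connectivity**
  network combines a structural connection-density matrix ρ (mesoscopic
  projectome) with per-region active-neuron counts *n*:

  $$W_{AB} \;=\; \rho_{AB}\, n_A\, n_B$$

  a directed, weighted region×region matrix: communication from A to B
  needs a structural projection, active source neurons, and active
  target neurons. The network is characterized with directed
  Newman–Leicht modularity at resolution γ,

  $$Q(\gamma) \;=\; \frac{1}{m}\sum_{ij}\Big[W_{ij} - \gamma\,
  \frac{s^{out}_i s^{in}_j}{m}\Big]\,\delta(c_i, c_j),$$

  Louvain-style module detection, and weighted directed betweenness
  centrality (edge length 1/W) for hub ranking and region-set (e.g.
  default-mode-network) summaries.

A synthetic-data generator (`simConfig()`, `makeAtlas()`, `makeBrains()`,
`makeReference()`, `makeDensity()`, `simulateAll()`) emulates all four
inputs — atlas structure tree + annotation volume, neuron tables with
planted condition/layer/type effects, a one-hemisphere transcriptomic
reference, and a block-structured density matrix — so every stage is
testable against known ground truth.

## Worked example

```r
library(fosnet)

cfg   <- simConfig(seed = 1)            # 4 time windows x 3 brains x 5000 neurons
atlas <- makeAtlas(cfg)
neurons <- assignRegions(makeBrains(cfg, atlas), atlas$volume)

## regional composition: isocortex share per brain and condition
majors <- setdiff(rootChildren(atlas$hierarchy), c("OLF", "CB", "MY"))
ratios <- regionRatios(countRegionsByBrain(neurons, atlas$hierarchy, majors))
iso <- ratios[ratios$acronym == "Isocortex", ]
tapply(iso$ratio, iso$condition, mean)
#>     ZT0-4   ZT12-16   ZT20-24    ZT8-12
#> 0.4238690 0.2724698 0.3736078 0.3361509
compareGroups(iso$ratio[iso$condition == "ZT0-4"],
              iso$ratio[iso$condition == "ZT12-16"])$p_value
#> [1] 4.375229e-05

## molecular identity by region-constrained twin matching
ref <- makeReference(cfg, atlas)
m <- matchTwins(mirrorToReferenceHemisphere(neurons, atlas$midlineUm, 3L), ref)
distanceQC(m)$quantiles
#>      50%      90%      99%
#> 10.35116 16.24872 23.52217      # micrometers

## active connectivity and module structure
dens <- makeDensity(cfg)
acs <- lapply(split(neurons, neurons$brain_id), function(b)
  buildActiveConnectivity(dens$density,
                          countRegions(b, atlas$hierarchy,
                                       regionAcronyms(dens$density))))
avg <- averageCondition(acs[sapply(acs, condition) == "ZT12-16"])
det <- detectModules(avg, gamma = 1, seed = 1)
c(Q = det$Q, modules = det$n_modules)
#>         Q   modules
#> 0.4673317 4.0000000
```

The isocortex share is planted higher at ZT0-4 (0.40 of the included
scope) than at ZT12-16 (0.26); the recovered per-condition means above
sit on those values and the Welch test flags the difference. The median
twin distance of ~10 µm reflects the reference's density; the detected
four modules recover the density matrix's planted block structure
exactly (adjusted Rand index 1).

A thin command-line front end over the same functions is installed at
`inst/cli/abn.R` with subcommands
`simulate | assign | stats | match | connect | network | run`; `run`
executes the five-stage pipeline from a single YAML/JSON config and
writes a manifest with input checksums and per-stage status
(`runPipeline()`).

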