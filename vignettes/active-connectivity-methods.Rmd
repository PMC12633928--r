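---
title: "Methods: from activity-tagged neurons to active-connectivity networks"
author: "fosnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from activity-tagged neurons to active-connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosnet)
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## 1. The data and the atlas

The input is a table of segmented, atlas-registered neurons: one row per
activity-tagged neuron with a 3D coordinate in micrometers in the atlas
frame, a brain ID, and a condition label (here the four Zeitgeber-time
tagging windows ZT0-4, ZT8-12, ZT12-16, ZT20-24). Segmentation and
registration happen upstream; the package starts where they end.

**Region assignment** (`assignRegions()`) maps a coordinate to the voxel
of an integer annotation volume and inherits that voxel's region ID.
Voxels are half-open intervals $[i\,s, (i{+}1)\,s)$ with 0-based indexing
in physical units, so a point exactly on a voxel boundary belongs
deterministically to the higher-index voxel, and no interpolation is ever
performed: assignment is idempotent and order-invariant. Points outside
the volume, and points on annotation value 0 inside the volume (white
matter, ventricles, unannotated tissue), become region 0 ("unassigned").
Unassigned neurons are retained in tables but excluded from every
denominator, and their count is reported — imputing a region for
non-alignable material would silently bias composition ratios.

**The structure tree** is the atlas ontology: unique integer IDs, unique
acronyms, one root, and an ancestor path per node. All aggregation is
path-based: a neuron in `VISp5` counts toward `VISp`, `Isocortex`, and
the root, and `ancestorAtLevel()` rolls any region up to the unique
member of a scope set lying on its path. A scope set must be a partition
(no member an ancestor of another); this is validated, because an
overlapping scope would double-count.

**Exclusions.** Whole-brain clearing often damages the olfactory areas,
cerebellum, and medulla, so the default exclusion set is
`c("OLF", "CB", "MY")` — those regions and all their descendants
contribute to no count and no denominator. The set is configurable; the
package excludes by acronym rather than editing the annotation volume.

**Cortical layers** are parsed from the trailing token of laminar
acronyms (`VISp5` → L5, `RSPagl2/3` → L2/3; tokens 1, 2/3, 4, 5, 6a,
6b). Parsing is purely lexical; `layerRatios()` additionally restricts to
descendants of the requested cortical parent, which keeps structures like
`CA1` from leaking in.

## 2. Regional composition statistics

Per-brain counts at a scope are converted to ratios (counts divided by
the brain's in-scope total), which removes the large between-animal
variation in absolute label counts. Ratios are z-scored per region across
all brains of all conditions pooled (sample SD, denominator $n-1$); a
per-condition-mean centering variant is available via `pool =
"condition-mean"`. Regions with zero variance are flagged and set to
z = 0 rather than producing NaNs.

Two-group comparisons (`compareGroups()`) use Welch's two-sided t-test —
appropriate for small groups of per-brain ratios with no
equal-variance assumption — with no multiple-testing correction by
default and an optional Benjamini–Hochberg helper (`adjustBH()`) for
multi-region screens. Degenerate inputs (both groups constant) are
flagged explicitly: p = 1 for equal constants, p = 0 for different
constants, instead of erroring mid-pipeline. A note on calibration: the
test-suite null calibration draws groups of 10, where the
Welch–Satterthwaite approximation attains nominal size; at very small
group sizes (n ≈ 5, typical per-condition brain counts) Welch is
conservative by a few thousandths, which works against false positives.

## 3. Molecular identity by region-constrained twin matching

Each tagged neuron inherits the neurotransmitter class of its **twin**:
the nearest reference neuron *within the same atlas region* in a spatial
transcriptomic reference (MERFISH-style: coordinates, region, cell
class, neurotransmitter). The design choices:

- **k = 1 exactly, exact search.** The twin is the single closest
  same-region reference neuron; no approximate nearest-neighbor
  structures are used, so results are reproducible to the last bit.
  Distance ties break on the lexicographically smallest cell ID.
- **The region constraint** prevents identity transfer across anatomical
  boundaries, where molecularly different populations can be spatially
  adjacent. The constraint uses the finest assigned region by default; a
  coarser roll-up level can be supplied.
- **Hemisphere mirroring.** Single-hemisphere references are handled by
  reflecting neurons on the far side across a configurable midline plane
  (default: half the annotation extent along the ML axis), under a
  left–right symmetry assumption. Mirroring is recorded per neuron.
- **Non-neuronal reference cells are excluded before matching** (the
  tagging system captures neurons), and neurons in regions with no
  reference neurons are returned unmatched with a reason code — never
  silently dropped.

Match quality is summarized by distance quantiles and the fractions
beyond 40 and 100 µm (`distanceQC()`). In a dense reference, the median
twin distance scales like the reference's nearest-neighbor spacing; at
the generator's default density the median is ~10 µm.

**When identity transfer works.** Proximity implies identity only where
cell types are spatially organized. The generator makes this caveat
testable: with types segregated into disjoint per-type clusters, twin
matching recovers planted types at ≥ 95% accuracy; with types fully
interleaved, accuracy collapses to the chance-agreement baseline
$\sum_t p_t^2$ of the region's type proportions. Real regions span this
range — thalamic nuclei (e.g. the near-pure GABAergic reticular nucleus)
behave like the segregated regime, heavily intermixed territories like
cortical L2/3 like the interleaved one — so per-region results should be
read with that in mind.

## 4. Active connectivity

For regions A, B with structural connection density $\rho_{AB}$ and
active-neuron counts $n_A$, $n_B$:

$$W_{AB} = \rho_{AB}\, n_A\, n_B, \qquad W = \mathrm{diag}(n)\,\rho\,
\mathrm{diag}(n).$$

The rationale: effective communication requires a structural projection
($\rho_{AB}$), active senders ($n_A$), and active receivers ($n_B$); any
factor of zero silences the edge. Properties that follow by construction
and are asserted as tests: support(W) ⊆ support(ρ) off-diagonal (with
equality when all counts are positive), exact quadratic scaling under a
common count rescaling, and monotonicity in each count.

Choices made here (the construction admits variants):

- **Diagonal zeroed** by default — the object models *inter*-regional
  communication; `keepDiagonal = TRUE` retains within-region terms for
  sensitivity analysis.
- **No re-normalization of ρ**: the input is taken as an already
  normalized connection density, applied as published.
- **Raw per-brain counts**, not ratios, enter W. Composition ratios are
  the right object for comparing *where* activity sits; the network's
  edge strengths are meant to scale with how much activity there is.
  Because every structural metric below is scale-invariant, this choice
  affects total strength but not network structure.
- Per-condition summaries are entry-wise means over brains sharing a
  condition, with strict region-order and condition checks.

## 5. Network structure: modularity and hubs

**Directed modularity with resolution.** W is directed, so the package
uses the Newman–Leicht directed generalization with a resolution
parameter:

$$Q(\gamma) = \frac{1}{m}\sum_{ij}\Big[W_{ij} - \gamma\,
\frac{s^{out}_i s^{in}_j}{m}\Big]\,\delta(c_i,c_j)$$

with out/in strengths $s^{out}, s^{in}$ and $m = \sum_{ij} W_{ij}$.
Anchor values used as exact tests: the one-community partition at
γ = 1 scores 0; two disconnected reciprocal pairs partitioned by pair
score 1/2; for disconnected blocks the block partition scores
$1-\sum_b (m_b/m)^2$ at γ = 1. Q is non-increasing in γ at fixed
partition, and γ tunes the size of modules favored (larger γ, smaller
modules). The default sweep is 21 points on [0.5, 2].

**Module detection** is a Louvain-style greedy optimization of this
directed Q (local moving with both in- and out-link gains, then
aggregation), with the node sweep order shuffled from a seed, a
configurable number of restarts (default 10) scored by Q (ties broken by
the lexicographically smallest canonical labeling), and a guarantee that
the returned partition never scores below either trivial partition. An
undirected symmetrized variant can be had by passing $(W+W^\top)/2$.

**Betweenness centrality** uses edge length $\ell_{ij} = 1/W_{ij}$
(strong connections are short; the standard convention in weighted
brain-network analysis; a `neglog` transform $\log(\max W / W)$ is
available as a sensitivity flag). Shortest paths over all ordered pairs,
with equal-length paths sharing credit fractionally; both raw counts and
the $(R-1)(R-2)$-normalized values are reported. The shortest-path
computation is delegated to igraph; the test suite holds it to a
brute-force path-enumeration oracle at 1e-9. Entries below
$10^{-12}\max(W)$ are treated as absent edges to avoid pathological
near-zero lengths. Hub ranking averages per-region betweenness over the
brains of a condition (raw values; whether to normalize before averaging
is configurable via `useNormalized`), descending, ties alphabetical.
Region-set summaries (e.g. the default-mode-network list shipped in
`inst/extdata/dmn.txt`) average member centralities per brain, then per
condition.

**Scale invariance, by construction.** Rescaling W by any positive
constant changes no modularity value, no detected partition, no
betweenness value, and no ranking. This matters scientifically: a
condition with globally stronger activity (e.g. more tagged neurons late
in the dark period) has a larger total strength, but that alone cannot
change the *structure* of its network — structural differences between
conditions are therefore not artifacts of label counts.

## 6. The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions used throughout the test suite and the acceptance script:
four tagging windows, 3 brains per window, 5,000 neurons per brain
(roughly the "most active ~1%" scale a TRAP experiment captures per
region set of this size), 60,000 reference cells with 25% non-neuronal,
and a 4-block density matrix with 10:1 within/between contrast. These
sizes give stable ratios while keeping the full suite in seconds-scale
runs; the acceptance script uses the same defaults.

- **Atlas**: root → 12 major regions → 6 laminar cortical areas (6 layer
  leaves each) plus 17 subcortical/excluded leaves; each leaf owns a
  200 µm cubic parcel on a grid, mirrored across the z mid-plane so both
  hemispheres carry the same labels (the reference covers only the low-z
  hemisphere; midline 200 µm at the default 25 µm voxels). The
  connectivity network spans 21 regions: the cortical areas plus the
  included subcortical leaves.
- **Planted effects**: isocortex share 0.40 at ZT0-4 vs 0.26 at ZT12-16
  (emulating a rest-onset cortical activation difference); a visual area
  enriched in light-period windows; layer-5 share 0.38 at ZT20-24 vs
  0.26 elsewhere; a 98% GABAergic reticular nucleus and a 65%
  dopaminergic VTA against an 80/18 glutamatergic/GABAergic cortex.
  Effect sizes are several binomial SDs at the default counts, so
  recovery tests are sharp without being trivial.
- **Type segregation**: under `segregation = 1`, reference cells *and*
  tagged neurons of each type occupy the central 60% of a per-type slab
  of their parcel, leaving physical gaps between type clusters — the
  disjoint-cluster regime where nearest-neighbor identity transfer is
  reliable. `segregation = 0` interleaves types uniformly. Intermediate
  values mix the two per cell.
- **Determinism**: each artifact draws from its own sub-stream derived
  from the master seed (atlas layout is deterministic; brains use
  seed + 1000 + 97·brain-index, the reference seed + 20000, the density
  seed + 30000), so adding one generator never shifts another's output,
  and identical configurations produce byte-identical files.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: registration error and segmentation
false positives/negatives; anisotropic, curved region geometry (parcels
are axis-aligned boxes); within-region spatial gradients of activity;
correlated cell-type spatial statistics beyond the slab model; distance-
dependent structural connectivity; and between-animal variability beyond
binomial sampling. Results on real data inherit all of those effects.

## 7. Pipeline, formats, and reproducibility

`runPipeline()` executes assign → stats → match → connect → network from
one keyed configuration (YAML/JSON or an R list), writes every
intermediate as CSV, and emits `manifest.json` with input MD5 checksums,
the seed, the package version, and per-stage status and row counts. A
failed stage is recorded and its dependents are skipped; independent
stages still run. No output file contains timestamps or timings (those
go to stderr), so two runs from identical inputs are byte-identical —
checked by test. File formats are the contract between stages: Allen
structure-graph JSON for the tree, NRRD (raw or text encoding) for the
annotation volume, headered CSV for neurons, reference cells, and
matrices.

The package's own NRRD reader/writer covers the integer-volume subset
used for annotation images (3D, attached data, raw little-endian or
text encoding, `spacings`/diagonal `space directions`).

## 8. Known limitations

- Twin matching transfers labels, not expression: no imputation, no
  taxonomy assignment beyond the reference's labels, and accuracy
  degrades where types are intermixed (Section 3).
- The active-connectivity model treats activity within a window as one
  number per region; it cannot see temporal structure within a window,
  and counts from different brains enter separately rather than being
  pooled.
- Modularity optimization is greedy; the restart mechanism with seeded
  sweep orders makes it deterministic and well-behaved on block-
  structured networks, but global optimality is not guaranteed on
  adversarial inputs.
- Betweenness with $\ell = 1/W$ is sensitive to very small positive
  weights; the absent-edge threshold ($10^{-12}\max W$) guards the
  pathological end, but analyses should check robustness under the
  `neglog` transform when edge weights span many orders of magnitude.
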