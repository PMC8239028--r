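---
title: "Methods: zone- and layer-specific quantification of cortico-tectal projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zone- and layer-specific quantification of cortico-tectal projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters, and numerical choices behind
`tectomap`. It is a methods document: every empirical claim made here is
asserted by the test suite or recomputed by `scripts/acceptance.R`; nothing is
hard-coded from expectation.

## 1. Scientific problem

The mouse superior colliculus (SC) receives topographically organized input
from most of isocortex. Along the medio-lateral axis the intermediate and deep
SC layers can be partitioned into four zones — SC.m, SC.cm, SC.cl, SC.l
(medial to lateral) — each dominated by a distinct set of cortical areas and
each projecting to distinct downstream targets. The package provides the
quantitative machinery to (i) define those zones geometrically, (ii) quantify
anterograde tracer labeling within zone × layer compartments, (iii) validate
the zone boundaries from the angular distribution of labeling, (iv) recover
the zones *de novo* as communities of an injection-overlap network, and (v)
compare collicular neuron morphologies across zones and projection targets.

## 2. The atlas model (`R/atlas.R`)

The right-hemisphere SC at a coronal level is modeled as a quarter disc on a
300 × 300 pixel raster at 10 µm/pixel, with the origin (midline, ventral-most
point of the SC contour) at pixel (x = 15, y = 285), 0-based, and radius
`sc_radius` per level (86: 220, 90: 250, 96: 230, 100: 180 px).

**Angular coordinate.** For a pixel p, θ = atan2(dorsal offset, lateral
offset) in degrees, clamped to [0°, 90°]. θ = 90° is the midline
(dorsal-most), θ = 0° the lateral edge. The origin itself has no defined angle
and is rejected.

**Zones.** Zone boundaries are angular intervals per level:

| level | SC.m | SC.cm | SC.cl | SC.l |
|---|---|---|---|---|
| 86 | (75, 90] | (60, 75] | (45, 60] | (30, 45] |
| 90 | (75, 90] | (55, 75] | (35, 55] | (10, 35] |
| 96 | (75, 90] | (60, 75] | (45, 60] | (5, 45] |
| 100 | (75, 90] | (60, 75] | (45, 60] | [0, 45] |

Intervals are half-open, `(lower, upper]`: a boundary angle belongs to the
zone whose *upper* bound it equals (the more medial zone). The single special
case is θ = 0 at level 100, which is included in SC.l so the lateral edge is
not orphaned. Angles below the lateral-most bound (e.g. θ < 30° at level 86)
are outside any zone; `sc_mask()` therefore covers only the zone-spanned
sector of the quarter disc.

**Layers.** Laminar position is a depth fraction d = 1 − r/R (0 at the SC
surface, 1 at the deepest point), tiled by seven bands: zo 0–0.05, sg
0.05–0.25, op 0.25–0.40, ig 0.40–0.65, iw 0.65–0.75, dg 0.75–0.92, dw
0.92–1.0. These bands are package defaults chosen to respect relative laminar
thicknesses; they are configurable per level and validated to tile [0, 1]
without gaps or overlap. SC.l exists only for the intermediate and deep
layers: SC.l × {zo, sg, op} is empty and superficial depths in the SC.l sector
resolve to ig.

## 3. The synthetic generator (`R/synthetic.R`, `R/neurons.R`)

The generator emulates the thresholded tracer archive so every downstream
stage is testable without histology.

**Per case** (one cortical injection, e.g. PTLp → SC.m), at each atlas level:

- `n_terminal_pixels` (default 600) terminal pixels are split by a binomial
  draw with `purity` (default 0.85) into in-target and off-target pixels.
- In-target pixels land in the zone's target compartments (two layers with
  weights 0.6/0.4; e.g. SC.m → ig + iw), with angle drawn from a truncated
  normal at the zone mid-angle (sd = `dispersion`, default 4°) and radius
  uniform within the layer band. Sampling is batched rejection with uniqueness
  enforced after integer rounding; after half the round budget the angular
  kernel widens to uniform-over-zone, because deep-layer compartments sit near
  the disc origin and hold only a few hundred unique pixels (SC.cl × dg at
  level 90 holds 610).
- Off-target pixels are uniform over the zone-covered SC excluding the target
  compartments.
- Passage pixels — fibers of passage, `round(n · pf / (1 − pf))` with
  `passage_fraction` pf = 0.10 — form straight streaks entering from the
  dorsal/medial edge, disjoint from terminal pixels.

**Cohort.** The default roster has 86 cases with dominant zones 14/8/24/40
(SC.m/SC.cm/SC.cl/SC.l), i.e. the doubled confined-projection subset
7/4/12/20 that `confined_subset()` recovers. Each case is generated under
`substream_seed(master, "case-<roi>")`, a 31-base polynomial hash mod 2³¹ − 1,
so regeneration is bitwise reproducible and independent of cohort composition.

**Rendering.** `render_intensity_image()` draws labeled pixels at intensity
255 on a N(20, 5) background clipped to [0, 255]; the default fixed threshold
of 100 therefore recovers the planted pixel set exactly, which the pipeline's
render-and-rethreshold path asserts.

**Neurons.** `generate_neurons()` grows jittered binary trees whose
medio-lateral extent scales with zone width (SC.m 80 µm … SC.l 180 µm) and
projection-target factor (LD 0.7, RE 1.0, PF 1.1), written as valid SWC.

**Realism and limits.** The generator reproduces the *structure* the analysis
consumes — compartment-confined labeling with controlled purity, dispersion,
and passage contamination — not tracer biophysics. Intensity images are
binary-plus-noise rather than graded axonal signal; passage fibers are
straight; laminar targeting uses two layers per zone. These simplifications
are deliberate: they make planted ground truth exact so tests can assert
conservation and recovery rather than plausibility.

## 4. Annotation and quantification (`R/annotation.R`)

`threshold_image()` supports a fixed cutoff or a percentile (type-7 quantile),
keeping strictly-above pixels. `quantify()` assigns each labeled pixel to a
zone × layer compartment after `exclude_passage()` removes passage pixels by
key set-difference; a full accounting attribute guarantees
`input = assigned + passage_excluded + outside_sc` exactly.
`proportions_table()` normalizes per case at zone or zone × layer granularity,
pooling levels by default; all-zero cases are excluded and flagged rather than
producing NaN rows.

## 5. Polar analysis (`R/polar.R`)

Angular densities use a Gaussian kernel density estimate with **boundary
reflection**: each observation t contributes kernels at t, −t, and 180° − t,
so mass is not lost at 0° or 90°; the curve on the grid (0°–90°, step 0.5°) is
then renormalized to unit trapezoid area. The default bandwidth is Scott's
rule, sd · n^(−1/5), floored at half the grid step. Peaks are local maxima
ranked by topographic prominence, kept if prominence ≥ 10% of the global
maximum, greedily separated by ≥ 5°, and reported medial-to-lateral.
`boundary_report()` scores each zone group's dominant peak as aligned
(inside the zone's angular interval) or misaligned, with the distance to the
nearest boundary.

## 6. Overlap network and communities (`R/network.R`)

The overlap between two injections is the pixel-level common-labeling ratio
|A ∩ B| / |A| on level-keyed unique terminal pixel sets (passage excluded),
symmetrized by averaging the two directions. On the resulting weighted graph
(diagonal zeroed) the package implements:

- **Modularity** Q = (1/2m) Σᵢⱼ (wᵢⱼ − γ kᵢkⱼ/2m) δ(cᵢ, cⱼ) with resolution
  γ, accumulated *per community* so closed forms (e.g. two disconnected
  triangles, Q = 0.5) evaluate exactly in floating point.
- **Louvain**: seeded random node order, strict-improvement local moving
  (tolerance 10⁻¹², ties to the lowest community index), then aggregation with
  the diagonal carrying intra-supernode mass, with 2m fixed from the original
  graph. Tests verify it never exceeds, and almost always attains, the
  exhaustive-search optimum on ≤ 8-node graphs, and agrees with an independent
  implementation when available.
- **Consensus**: runs i = 1…n use seed master + i; memberships are
  canonicalized by first occurrence (labels contiguous from 1) and the modal
  partition is reported with its mode count and the mean/sd of the community
  count. Ties resolve to the lexicographically smallest signature, making the
  result order-invariant.
- **Winner-takes-all maps** tile a level into square cells and color each cell
  by the community contributing the most labeled pixels (ties to the lowest
  index; unlabeled cells NA).

## 7. Morphometry (`R/morphometry.R`)

SWC files are parsed and validated (single root, declared parents, acyclic).
Features: arbor width (extent on a configurable axis, default medio-lateral
x), bifurcation count (non-soma nodes with ≥ 2 children; a multifurcation
counts once), branch count and mean branch path length (paths between
topological points), contraction (mean chord/path ratio), total cable length,
and Sholl profiles (segments straddling each radius, soma-soma segments
excluded). PCA uses `prcomp(scale. = TRUE)` with zero-variance features
dropped under a warning. Group comparisons are pairwise two-sided
`wilcox.test` (exact for small untied samples) with Benjamini–Hochberg
correction across all pair × parameter tests at α = 0.05; groups with fewer
than two neurons are excluded and flagged, and fully tied comparisons report
p = 1.

## 8. Pipeline (`R/pipeline.R`)

`run_all(run_config(...))` chains atlas → cohort generation → optional
render + rethreshold → quantification → polar analysis → overlap network and
consensus communities → winner-takes-all map → neuron morphometry, writing
CSV/JSON/PNG artifacts and a `summary.json`. Configuration is validated with
aggregated error messages; each stage wraps failures with its stage name. The
run is deterministic: identical seeds give byte-identical artifacts. For
reduced cohorts, the confined-subset sizes are capped at availability so every
stage still executes.

## 9. Numerical choices

- Trapezoid rule for all density areas; unit-area tolerance 10⁻⁶.
- Densities average pointwise only on identical grids (enforced).
- Exact integer pixel accounting everywhere; conservation asserted, not
  approximated.
- Seeding via `withr::with_seed` so the global RNG state is never clobbered;
  all substreams below 2³¹.
- Modularity per-community accumulation (see §6) for closed-form exactness.

## 10. Problem sizes and runtime

Defaults: 86 cases × 4 levels × ~660 labeled pixels; consensus over 100–1000
Louvain runs on the 86-node overlap graph; brute-force modularity oracles on
≤ 8 nodes (4140 partitions at n = 8). The full test suite runs in under a
minute and the acceptance script in ~17 s on one CPU.

## 11. Limitations

- The atlas is an idealized quarter disc; real SC contours are not circular
  arcs, so pixel-level results are not comparable to registered histology.
- Layer bands are geometric defaults, not measured laminar boundaries.
- The generator's purity/dispersion model omits injection-site size effects,
  level-to-level correlation of labeling, and graded signal intensity.
- Louvain is a heuristic; optimality is guaranteed only where tests brute
  force it. Consensus reports the modal partition, not a co-classification
  matrix.
- Zones are validated only on the synthetic archive; the package makes no
  claim about recovering zones from new empirical data without recalibration.
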