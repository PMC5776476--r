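---
title: "Methods: single-grain community analysis with sandgrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-grain community analysis with sandgrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sandgrain)
```

`sandgrain` implements the quantitative workflow of a single-sand-grain
microbial community study: per-grain 16S OTU tables are filtered and
rarefied, compared by phylotype and phylogenetic diversity measures, mined
for a shared core community, pooled to ask how many grains recover the bulk
sediment's richness, and complemented by a geometric model of colonization
density and by nearest-neighbour statistics on mapped cells. This vignette
explains each model, its assumptions, the tunable parameters, and the design
choices made where conventions genuinely differ.

## Filtering and rarefaction

Libraries amplified from single grains and from bulk sediment are clustered
into species-level OTUs upstream (outside this package). Two preprocessing
rules are applied before any diversity analysis:

* **Dataset-wide rare-OTU removal.** `remove_rare_otus(tbl, min_total = 3)`
  removes OTUs supported by fewer than three reads summed over *all* samples
  — absolute singletons and doubletons, the reads most likely to be
  sequencing artefacts. We interpret "the whole data set" as grains and bulk
  analysed together, since they come from one sequencing run; a per-sample
  variant is available behind the `per_sample` flag for datasets where runs
  were processed separately. The filter never alters retained counts and is
  idempotent.

* **Rarefaction to equal depth.** `subsample_counts()` draws, without
  replacement, the same number of reads from every sample (by default the
  lowest sample depth), so that richness comparisons are not confounded by
  sequencing effort. Each OTU's subsampled count is hypergeometric given the
  sample's composition; the draw is delegated to `vegan::rrarefy()` under a
  locally scoped seed, so a pipeline run is reproducible without disturbing
  the caller's RNG stream.

Rare-biosphere thresholds (`abundance_threshold()`) use a strict ">" on
within-sample relative abundance (0.1‰ and 1‰ are the conventional
cut-offs) and are intended to be applied *after* rarefaction, so that a
given threshold corresponds to the same absolute read count in every sample.

## Diversity measures

All four measures are implemented directly from their definitions, and the
test suite cross-checks each against an established implementation (vegan,
picante, phyloseq) to 1e-9 on randomized fixtures.

* **Chao1** uses the bias-corrected form
  $S_{obs} + f_1(f_1-1)/(2(f_2+1))$, the default in mothur-based workflows;
  the classical $f_1^2/(2f_2)$ form is behind a flag (and undefined without
  doubletons, where the bias-corrected value is substituted with a warning).
* **Inverse Simpson** is the plug-in form $1/\sum p_i^2$ (vegan's
  `invsimpson`); the finite-sample, without-replacement variant is behind a
  flag.
* **Faith's PD** is root-inclusive (picante's `include.root = TRUE`
  convention): the branch length summed over every edge with at least one
  observed descendant, down from the tree's root. Root-inclusive PD makes
  single-taxon samples comparable across clades.
* **UniFrac.** Both variants are computed from one post-order traversal that
  accumulates, per branch, the read mass of each sample below it — O(edges)
  per sample pair. Unweighted UniFrac is unique-branch length over observed
  branch length (presence only, hence invariant to count magnitudes).
  Weighted UniFrac defaults to the normalized form
  $\sum_b L_b\,|p_A(b)-p_B(b)| \,/\, \sum_b L_b\,(p_A(b)+p_B(b))$
  (the GUniFrac α = 1 metric, bounded in [0, 1]); the raw numerator is
  available with `normalized = FALSE`. Because communities are also
  described by their similarity, every pairwise table carries
  `similarity = 1 - distance`. Multifurcating and zero-length branches are
  handled naturally by the traversal; collapsing a zero-length branch
  provably changes neither metric.

## Core community

`find_core()` defines the core as the OTUs detected (count ≥ 1 by default)
in **all** grain samples; `min_prevalence` relaxes that, and the core can
only grow as prevalence is lowered. Presence is evaluated on rarefied
tables — a presence call at unequal depths would mean different detection
effort per grain, so the function warns when sample depths differ. Bulk
samples are excluded from the prevalence rule but kept for comparative
reporting. `core_family_breakdown()` expresses the core's contribution per
family as a fraction of *total* sample reads, pools families contributing on
average < 0.5% into "other core community", and closes the budget with a
"non-core" row so shares sum to one exactly.

## Grain pooling against bulk richness

The pooling procedure asks: sequencing one grain at a time, how quickly is
the OTU richness of the bulk sediment covered? Identical numbers of
sequences must be compared throughout, so:

1. every grain is rarefied once to a common depth $n$;
2. grains are ranked by their individual observed richness on those rarefied
   counts (ties broken by sample id for determinism) and pooled consecutively
   in decreasing or increasing order;
3. for pool size $k$ the pooled bulk counts (`bulk_pooled`, the concatenated
   bulk replicates) are rarefied to $k \cdot n$ reads and coverage is the
   fraction of the bulk subsample's OTUs found in the pool.

The bulk subsample is replicated (`n_replicates = 10` by default) and the
mean and sd reported; the grain subsamples stay fixed across $k$, so the
pool's read count is exactly $k \cdot n$ and the curve's randomness comes
only from the bulk side. When $k \cdot n$ exceeds the pooled bulk depth the
comparison truncates to the full bulk with a warning, and the depth actually
compared is recorded per point. `grains_to_reach(curve, 0.5)` scans for the
smallest pool covering half the bulk richness; a target of 0 is trivially
reached by the first pool, and unreachable targets return `NA` rather than
an error so curves can be compared programmatically.

## Colonization geometry

The geometric model converts bulk measurements into per-grain quantities.
Inputs (`geometry_params()`), with the measured North Sea subtidal defaults:
total cell count $C = 1.1\times10^9$ cells cm⁻³; grain surface area
$A = 1.2\times10^{10}$ µm² cm⁻³ (micro-CT); mean cell footprint
$a = 0.43$ µm²; grain diameters $d = 202$–$635$ µm; porosity $\varphi$.
Derived quantities:

| quantity | formula | default value (reported) |
|---|---|---|
| colonization density | $\rho = C/A$ | 0.09 cells µm⁻² |
| area per cell | $1/\rho$ | 11.1 µm² |
| lattice spacing | $\sqrt{1/\rho}$ | 3.3 µm |
| colonized fraction | $a\rho$ | 4% |
| cells per grain (surface route) | $\pi d^2 \rho$ | 1.2×10⁴–1.1×10⁵ |
| grains per cm³ | $(1-\varphi)/(\pi d^3/6)$ | — |
| cells per grain (packing route) | $C / \text{grains cm}^{-3}$ | 8.2×10³–2.6×10⁵ |

Three conventions deserve explanation:

* **Density is propagated at its measurement precision.** $C$ and $A$ are
  two-significant-figure measurements, so $\rho$ is only meaningful to two
  decimals; `colonization_report()` rounds $\rho$ to 0.09 before deriving
  the downstream quantities (hence 11.1 µm², not 10.9 from the raw ratio).
  `density_digits = NULL` propagates the raw ratio instead, and the raw
  density is always retained in the report object.
* **Rounding lives at the reporting layer.** `tidy()`/`glance()` apply the
  conventional precisions (density two decimals, area/spacing one decimal,
  colonized fraction whole percent, cells per grain two significant figures)
  only when `rounded = TRUE`; raw values stay available, and identities such
  as `area_per_cell * density == 1` hold exactly pre-rounding.
* **Porosity is a fitted default.** No measured porosity accompanies the
  other inputs, so the default $\varphi = 0.423$ was back-solved once so
  that the packing route reproduces the 8.2×10³–2.6×10⁵ cells-per-grain
  range at two significant figures over 202–635 µm grains (the feasible
  interval is 0.4216–0.4246, comfortably within the 0.4–0.5 typical of
  well-sorted marine sand). It is clearly a calibration, not a measurement,
  and should be replaced when a measured value exists.

The two routes scale as $d^2$ and $d^3$ respectively and agree within a
factor of three across the default grain-size range.

## Spatial nearest-neighbour statistics

Cell coordinates from maximum-intensity projections are analysed in 2-D
Euclidean space with no geodesic correction for surface curvature and no
edge correction at the window boundary — matching how such images are
measured. For each cell the distance to its nearest neighbour *within the
same patch class* is computed (exposed, abrasion-prone convex surfaces vs
protected depressions are reported separately because their densities differ
about tenfold); a cross-class mode is a flag away. Cells flagged as
*touching* are excluded by default: automated detectors cannot separate
touching cells, so measured distances are conditional on separability and
therefore biased upward — the exclusion reproduces that censoring. When no
touching flags are supplied they are derived as "any same-class neighbour
closer than `touching_radius`" (default 1 µm, roughly one cell diameter).
Classes retaining fewer than two cells report their size with `NA`
statistics rather than erroring.

The search is grid-binned (expected O(n) for roughly uniform patterns) and
exact: widening ring searches stop only once no unsearched bin can hold a
closer point, and the implementation is tested for exact equality against an
O(n²) distance-matrix oracle. `theoretical_vs_observed()` reports both
relevant scales for a density $\rho$: the even-spread lattice spacing
$\sqrt{1/\rho}$ and the homogeneous-Poisson expectation $1/(2\sqrt{\rho})$ —
observed means falling between them indicate clustering relative to a
lattice but aggregation relative to randomness.

## The synthetic-data generators

`simulate_community()` emulates the statistical structure the analyses
assume, at the study's own scale by default: 17 grain and 3 bulk samples at
40 000–140 000 reads; 400 core OTUs targeted to carry 60% of each grain's
reads (the "one-half to two-thirds" regime); 4000 rare OTUs each present on
a given grain with probability 0.3; 2000 bulk-only OTUs carrying 10% of bulk
reads, so single grains cover only part of bulk richness. OTU base
abundances are lognormal (σ = 2), giving the long-tailed rank-abundance
curve typical of sediment libraries; per-sample counts are multinomial at a
uniform random depth. One read per core OTU is set aside before the
multinomial draw, so core presence on every grain holds *by construction*
while row sums still equal the drawn depth — this is what makes exact core
recovery a meaningful pipeline test. Bulk samples draw from the average of
the grain mixtures (bulk as the union habitat) blended with the bulk-only
profile. The phylogeny is a random bifurcating topology with exponential
branch lengths (any valid tree exercises the metrics), and the taxonomy
assigns OTUs to nested synthetic lineages with Zipf-like family sizes.

`simulate_point_pattern()` emulates the colonization contrast: protected
patches are non-overlapping disks covering ~30% of a 200 × 200 µm window,
populated at 0.4 cells µm⁻², against 0.012 cells µm⁻² on exposed surface;
`protected_patch_fraction = 1` switches to a single homogeneous habitat for
analytic checks. Patterns are Thomas-type clustered (Poisson parents, mean 8
Gaussian-displaced daughters, scale 2 µm); `cluster_scale = 0` degenerates
to a homogeneous Poisson process whose count and nearest-neighbour laws are
known in closed form and asserted in the tests.

What the generators do **not** emulate: read-level error and chimeras, OTU
clustering artefacts, phylogenetic signal in which taxa share grains,
3-D grain topography, and the sub-resolution censoring of real imaging
beyond the touching-radius rule. Passing tests therefore demonstrate that
the *computations* are correct and that the pipeline recovers planted
structure — not that real grains behave like the generator. A further
consequence of the touching-radius censoring: with the default 1 µm radius
the protected-patch mean nearest-neighbour distance cannot fall below 1 µm,
so the simulated protected/exposed contrast in mean NN distance is milder
than the roughly tenfold contrast in intensities.

## Problem sizes and numerical choices

The test suite runs the estimators against reference implementations on 20
randomized fixtures at 1e-9 relative tolerance; rarefaction moments against
the hypergeometric law at 10⁴ replicates (4σ bands); core recovery on the
full 17-grain, 6400-OTU configuration at 5×10⁴ reads; the pooling oracle on
an exhaustively enumerable 4-grain toy; and the Poisson nearest-neighbour
law at 10⁴ points (3 standard errors, which also absorbs the small upward
edge bias of an uncorrected window). Monte-Carlo monotonicity checks on
coverage curves allow dips of 0.02, the replicate noise at 10 bulk
subsamples. Determinism is enforced throughout by explicit seeds; every
seeded function restores the caller's RNG state.

## Limitations

* The core definition is presence-based; a single stray read after
  rarefaction makes an OTU "present". `presence_min` raises that bar, but
  there is no abundance-weighted core model.
* Coverage curves truncate, rather than extrapolate, when the pooled grains
  out-sequence the bulk reference; richness extrapolation beyond observed
  pools is out of scope.
* The geometry model treats grains as smooth spheres; micro-CT surface areas
  at coarse voxel sizes underestimate true surface area, so densities derived
  from them are upper bounds.
* Nearest-neighbour statistics use projected 2-D distances and no edge
  correction; both choices match the imaging convention but bias distances
  slightly (projection down, edges up).
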