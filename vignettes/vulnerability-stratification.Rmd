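---
title: "Vulnerability-based spatial sampling stratification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vulnerability-based spatial sampling stratification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vulnstrat)
```

## The problem

Large child-cohort studies recruit by probability sampling of geographic
space: the study area is divided into strata that fully cover it, each
stratum is segmented, and one segment per stratum is selected at random.
For the stratification to carry information about environmental health, the
strata should be drawn so that each is relatively homogeneous — and the set
of strata heterogeneous — in the exposures and social conditions thought to
shape child health. At the same time the design must obey hard sampling
rules: a small number of strata (preferably 12–15, never more than 20), full
coverage, contiguity, and comparable measures of size (MOS, expected births
per year; every stratum within ±10% of the mean).

`vulnstrat` implements this as a reproducible pipeline: composite
vulnerability indices from unit-level indicators, natural-breaks
classification into an ordered rating, and contiguity-constrained
aggregation of units into size-balanced, homogeneous strata, with a
rule-by-rule compliance validator.

## The indices

Two descriptive indices are built per spatial unit. The hazard/stressor
exposure index **H** combines population density, average daily traffic
density, and the density of stationary pollution sources. The adaptive
capacity / social character index **A** combines high-school-only education
share, median household income, poverty rate, linguistic isolation, and
minority share.

Each raw indicator is aggregated from block groups to their parent town as a
population-weighted mean, then range-standardized onto a common scale:

$$SV = w_r \cdot \frac{x - x_{\min}}{x_{\max} - x_{\min}},$$

with range width $w_r = 10$ and the extremes taken over the entire dataset
for that indicator (no external reference ranges). Indicators whose raw
direction opposes their index (income is the only positively oriented A
indicator) are reflected as $w_r - SV$ before combination, so every column
raises its index in the named direction. The composite is the weighted sum
$\sum_j w_j \, SV_j$ with weights normalized to sum to one; because the
combination is convex, composites live on the same 0–10 scale.

**Weights.** The source design does not prescribe indicator weights; the
package defaults to equal weights within each index, in the spirit of
equal-weight composite development indices, and exposes them fully through
`indicator_spec()`.

**Minority share.** Adaptive capacity should not be inferred from race or
ethnicity in isolation. `default_indicators(include_minority = FALSE)` drops
the minority indicator from the A composite; `compute_indices()` then emits
an environmental-justice flag for units that combine a top-class minority
share with very low capacity on the remaining indicators.

**Classification.** Composite values at the town scale are cut into five
classes (very low … very high) by exact Fisher–Jenks natural breaks — the
contiguous partition of the sorted values minimizing total within-class
squared deviation, computed by dynamic programming. Values equal to a cut
point fall in the lower class, deterministically. The two class labels are
kept as the ordered pair $V=[H,A]$ — 25 possible ratings from $[1,5]$
(best) to $[5,1]$ (worst) — never collapsed into a ratio, because one unit
of hazard is not one unit of capacity.

**Order of operations.** Aggregation and standardization do not commute,
and the source material does not pin the order down; the package defaults
to *aggregate-then-standardize* (population-weighted town means of raw
values, standardized across towns), which matches the narrative order of
the original workflow. The alternative *standardize-then-aggregate* order
is available via the `order` argument of `compute_indices()`; the
block-group-level composites are identical either way, and at the town
scale the two orders agree closely in rank.

## Stratum construction

Let $M$ be the total MOS and $K$ the number of strata. The mean target is
$M/K$ and the acceptable range is `mos_bounds(M/K, tol)` — half-up-rounded
integers at `tol = 0.10` by default, e.g. a mean of 2,113 gives 1,902–2,324.

A unit whose MOS exceeds the upper bound (a large city) can fit in no
stratum and is pre-split at the block-group scale. The canonical piece
count is `split_count()`, the half-up-rounded MOS ratio (10,385 / 2,113 =
4.91 → 5). `split_oversized_units()` orders the city's block groups by
their block-group-level H composite — exploiting contiguous relative
homogeneity in index space, since abstract block-group adjacency is not
part of the model — and packs them greedily into pieces of comparable MOS.
When no piece count yields pieces that individually sit inside the bounds
(the equal shares straddle a bound, or block-group discreteness overflows
it), the splitter cuts full pieces just under the upper bound plus one
remainder piece that merges with neighbouring units during stratification.
Each piece inherits the city's former adjacency and the pieces are chained
to one another.

The solver `build_strata()` then searches for a partition of the top-scale
units into $K$ connected strata minimizing

$$\text{homogeneity\_weight} \sum_s \left(\mathrm{var}(h_s) +
\mathrm{var}(a_s)\right) + \text{mos\_penalty\_weight} \sum_s
\max\!\left(0, \frac{|MOS_s - M/K|}{M/K} - \text{tol}\right)^2$$

with population variances. Contiguity-constrained regionalization under
size balance is NP-hard, so the original design iterated town combinations
by hand; the solver formalizes that search:

1. **Seeding.** $K$ seeds chosen by farthest-point dispersion in $(h_s,
   a_s)$ space (random seeds on restarts).
2. **Region growing.** The stratum with the smallest MOS grows first,
   absorbing the adjacent unassigned unit closest to its index centroid,
   penalizing additions that overshoot the MOS bound.
3. **Simulated annealing.** Boundary-unit moves and boundary swaps under a
   geometric cooling schedule, with proposals biased toward strata that
   violate the MOS bounds; the best feasible state visited is remembered.
4. **Repair and polish.** Steepest descent on total MOS-bound violation
   (with small random kicks between stalled rounds), then strict descent
   on the objective that never leaves feasibility.

Coverage and contiguity are maintained by construction and never violated.
Several restarts are run (default 5) and the best feasible solution is
returned; if none is found, the best attempt comes back flagged infeasible
with the violated rules named — mirroring the way a manual design must
sometimes trade similarity against the size rule — and
`validate_partition()` reports every rule independently either way. All
solver randomness derives from `config$seed`; identical inputs reproduce
identical partitions.

On graphs small enough for exhaustive enumeration of connected
$K$-partitions (≤ 12 units in the test suite), the solver attains the
enumerated optimum.

## Diagnostics

`homogeneity_report()` gives per-stratum means and SDs of both indices (SD
convention: population, divisor $n$, so single-member strata have SD 0 and
published-table comparisons are direct), plus the between-strata variance
share — the fraction of total index variance explained by the grouping,
defined as 0 when the total variance is 0. `random_contiguous_partition()`
generates size-matched random contiguous partitions as a null reference.

`recruitment_plan()` reproduces the study's recruitment arithmetic with a
fixed rounding sequence: per-stratum `floor`, per-year half-up, inflation
half-up (1,000 across 18 strata over 4 years at 30% loss allowance → 55 →
14 → 18 per segment-year).

## The synthetic-county generator

`generate_county()` exists so every stage is testable without any data
download. It emulates the features the method relies on:

* towns on a jittered lattice with rook adjacency (geometry is abstract —
  the method consumes contiguity, not shape);
* block groups nested in towns, with lognormal populations targeting a
  mean of 1,262 and SD 650 — the dispersion of the motivating county
  frame;
* MOS proportional to population (0.05 expected births per person-year,
  the fixture's MOS-to-population ratio) with multiplicative noise;
* a latent "urbanicity" field, spatially smoothed over the lattice,
  loading positively on all three hazard indicators and negatively on
  capacity via a correlated latent capacity factor — the configured
  hazard–capacity correlation defaults to −0.6, reflecting the empirical
  tendency of the two indices to be inversely correlated (industrial urban
  cores versus rural periphery);
* optionally an oversized city (default one town, 20× the MOS of a mean
  town, matching a dominant central city) to exercise the splitting path.

What it does **not** emulate: real cartographic shape and border effects,
spatial autocorrelation structures beyond simple neighbour smoothing,
within-town segregation patterns, missing data, or intercensal drift. A
passing test suite therefore demonstrates the machinery is correct under
the stated statistical structure, not that any particular real county
meets that structure.

## Numerical choices

* **Rounding:** all integer MOS arithmetic uses half-up rounding
  (`round_half_up()`), matching the published bound and split values; base
  R's banker's rounding would give different bounds.
* **Jenks ties:** equal-cost partitions resolve toward the earliest
  feasible boundary; classification sends boundary values to the lower
  class.
* **Degenerate inputs:** a constant indicator is an error, not silently 0;
  `clamp = TRUE` permits out-of-range values when anchors come from
  another dataset; floating-point spill past the standardization endpoints
  is clamped.
* **Scale anchoring:** MOS bounds anchor to `sum(MOS)/n_strata` of the
  supplied top-scale data. Splitting an oversized unit conserves total
  MOS, so the anchor is invariant to whether it is computed before or
  after splitting.
* **Problem sizes:** the test suite runs exhaustive-oracle comparisons at
  ≤ 12 units and end-to-end solver checks on fifty 60-town synthetic
  counties — the scale of the motivating county — which keeps the full
  suite around two minutes on a single core.

## The packaged county fixture

`load_worcester_fixture()` ships a transcription of a published county
stratification (59 Massachusetts towns plus a city represented by five
pre-split sub-strata; 595 block groups; 18 strata). The published table
prints no town contiguity matrix, so the bundled adjacency is a synthetic,
plausible reconstruction under which every published stratum is connected;
it supports contiguity validation and solver runs but individual town
borders are not authoritative. City rows print no town-scale index values;
the fixture carries their mean block-group values instead. Printed stratum
MOS totals differ by ±1 from their towns' sums (source rounding); the
fixture keeps the printed totals in a separate column.

Two published-table quirks are deliberately out of reproduction scope: the
printed town-level index values depend on unpublished raw census/EPA/
traffic inputs, and the printed A classes are not monotone in the printed
A values, so class-label reproduction cannot be exact and is checked only
by property (e.g. the minimum-H town lands in class 1).

## Worked example

```{r example, eval = FALSE}
library(vulnstrat)

# synthetic county, end to end
cfg <- strat_config(n_strata = 14, seed = 17)
county <- generate_county(synth_config(seed = 17, n_towns = 60))
res <- run_pipeline(county, config = cfg)
res$report          # rule-by-rule compliance
res$partition       # strata with MOS and index summaries

# published fixture, validate-only
fx <- load_worcester_fixture()
validate_partition(fx$area, fx$partition, strat_config(18))
```

## Known limitations

* The solver is a heuristic; on large graphs the returned optimum is local
  (restarts mitigate this, and the validator makes any shortfall visible).
* Rook contiguity from polygons assumes shared borders use coincident
  vertices/collinear segments, as in lattice or topologically clean data;
  sliver mismatches below the coordinate tolerance are not healed.
* Inherited adjacency for city pieces is permissive (every piece keeps all
  of the city's neighbours) because sub-city geography is not modelled.
* Segmentation within strata and segment selection are out of scope — they
  belong to the coordinating stage of a study, not the stratification.
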