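# vulnstrat

Vulnerability-based spatial sampling stratification for population health
studies.

Cohort studies that recruit by probability sampling of geographic space must
divide a study area into sampling strata that (a) capture health-relevant
environmental and sociodemographic heterogeneity and (b) obey hard survey
rules: a small number of strata (at most 20, preferably 12–15), full
coverage, contiguity, and comparable measures of size — MOS, expected births
per year, each stratum within ±10% of the mean. `vulnstrat` is a toolkit for
designing and auditing such stratifications.

## What it computes

**Composite indices.** For each spatial unit, a hazards/stressors exposure
index *H* (population density, traffic density, stationary-pollution-source
density) and an adaptive capacity / social character index *A* (education,
income, poverty, linguistic isolation, minority share). Block-group values
are aggregated to towns by population weighting, range-standardized,

    SV = range_width × (x − min) / (max − min),    range_width = 10,

oriented so larger always means more of the index, and combined as a
normalized weighted sum (equal weights by default, fully configurable).

**Rating.** Town-scale composites are classified into five classes by exact
Fisher–Jenks natural breaks and kept as the ordered pair **V = [H, A]** —
25 combinations from [1,5] (best) to [5,1] (worst), never collapsed to a
ratio.

**Strata.** Contiguous groups of units with each stratum's MOS inside
`round(mean ± 10%)`, built by seeded region growing plus simulated-annealing
local search minimizing within-stratum variance of the two indices. Units
too large for any stratum (a big city) are pre-split at the block-group
scale into `round(MOS_city / mean MOS)` pieces. A validator checks every
rule independently; homogeneity diagnostics and recruitment arithmetic round
out the pipeline. A synthetic-county generator with the method's assumed
statistical structure (nested block groups, lognormal populations,
inversely correlated hazard/capacity fields, an oversized city) makes every
stage testable offline.

A transcription of a published 18-stratum county design (59 towns + 5 city
sub-strata, 595 block groups) ships as a fixture; its town adjacency is a
synthetic plausible reconstruction (the source prints none).

## Worked example

```r
library(vulnstrat)

cfg    <- strat_config(n_strata = 14, seed = 17)
county <- generate_county(synth_config(seed = 17, n_towns = 60))
res    <- run_pipeline(county, config = cfg)
res$report
#> compliance report
#>   [ok] no_overlap    each unit in exactly one stratum
#>   [ok] coverage      all top-scale units assigned
#>   [ok] contiguity    every stratum induces a connected subgraph
#>   [ok] strata_count  14 strata (configured 14, hard maximum 20)
#>   [ok] mos_bounds    14/14 strata within [2275, 2781]
#>   overall: PASS
res$partition
#> partition: 63 units in 14 strata
#>   feasible: TRUE
#>   stratum MOS: 2,316.015 - 2,769.312
attr(res$homogeneity, "between_share")
#> [1] 0.754
```

The 60-town county (its city split into 4 pieces, giving 63 top-scale
units) is partitioned into 14 contiguous strata, every stratum's expected
births/year inside the acceptable range 2,275–2,781, with three quarters of
the index variance between strata rather than within them.

The packaged fixture validates against the same rules:

```r
fx <- load_worcester_fixture()
validate_partition(fx$area, fx$partition, strat_config(18))
#>   [ok] mos_bounds    18/18 strata within [1902, 2325]
#>   overall: PASS
mos_bounds(2113, 0.10)   # lo 1902, hi 2324
split_count(10385, 2113) # 5 city strata (ratio 4.91)
recruitment_plan(1000, 18, 4, 0.30)$per_year_inflated # 18 per segment-year
```

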