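---
title: "Facility-to-need ratios for PrEP access: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facility-to-need ratios for PrEP access: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfnr)
```

## The measure and its assumptions

The PrEP facility-to-need ratio (PFNR) of a spatial unit is its count of
service locations of one class — PrEP-prescribing locations or pharmacies —
divided by the unit's 5-year HIV incidence per 100 000 persons. It is a
presence measure: it captures whether locations exist where need is high,
not whether they have the clinical capacity to serve that need. Three
assumptions follow. First, a facility counts toward the unit that
geographically contains its coordinates, not the unit of its mailing
address. Second, all facilities of a class are exchangeable — one pharmacy
equals another regardless of staffing. Third, incidence per 100 000 is an
adequate proxy for prevention need; no population denominator or demand
model enters the ratio.

A unit's PFNR is undefined when its incidence is suppressed (small-count
privacy suppression by the data provider) or zero. Both exclusions are
deliberate: treating suppression as zero would fabricate certainty about
need, and a ratio "to need" at zero measured need is meaningless. Excluded
units are counted and reported (`n_units_excluded`), never imputed. This
matters in practice — state-level county analyses can have a majority of
counties suppressed — and the choice to exclude rather than zero-fill is
this package's documented convention.

## Per-unit distributions, not regional totals

Two formulations of a regional PFNR are defensible: a single aggregate
ratio (total facilities over summed incidence) or the distribution of
per-unit ratios. The package's primary surface is the per-unit
distribution, summarized by mean, median and quartiles, because medians and
IQRs only exist for a distribution and because the distribution exposes
inequality that a regional total hides (a region can look well served in
aggregate while most of its units are deserts). The aggregate formulation
remains available as `aggregate_pfnr()` for sensitivity analysis.

The fold increase from pharmacy expansion is the ratio of the
full-precision class means, `mean(PFNR_pharm) / mean(PFNR_prep)`. Means
rather than medians: the median prescriber PFNR is typically exactly zero
(most units have no prescribing location), which would make a median-based
fold undefined everywhere interesting. The means are never rounded before
division; the report CSV carries both the full-precision value and a
one-decimal display column. When the mean prescriber PFNR is zero the fold
is reported as undefined ("no current access") rather than infinite.

Pooling across regions applies the identical summary algorithm to the
union of all defined unit PFNRs. It is not the mean of region means; the
two agree only under equal region sizes, and the count-weighted identity is
asserted in the test suite.

## Quantiles and other numerical conventions

Quantile conventions differ across software, so the package pins one:
linear interpolation between order statistics at positions `p * (n - 1)`
(zero-based), i.e. R's `quantile(type = 7)` default. The test suite checks
it against an independently written sort-and-interpolate oracle to 12
significant digits on 200 lognormal values.

Containment uses the even-odd (ray casting) rule on planar lon/lat
coordinates. No projection is applied: containment is a topological
question and map projections preserve topology at these scales, so
projecting would add code without changing any count. Ring orientation is
ignored; any ring after the first in a polygon toggles containment and thus
acts as a hole automatically. A point exactly on a shared boundary is
assigned to the candidate unit with the lexicographically smallest
`unit_id` — an arbitrary but deterministic and input-order-independent
tie-break, implemented by testing units in sorted order and letting the
first containing unit win. The same rule silently resolves sliver overlaps
between units; overlapping inputs additionally trigger a data-quality
warning from a heuristic check (each unit's centroid tested against other
units with intersecting bounding boxes — cheap, catches duplicated or
grossly overlapping polygons, and deliberately not a full geometric overlay).
The on-boundary test uses a cross-product tolerance of `1e-12` relative to
coordinate magnitude, enough to absorb double rounding without misclassifying
distinct points at ZCTA scales.

Facilities contained by no unit — for example chain pharmacies registered
at an out-of-region headquarters address — are not errors. They accumulate
in a per-class unassigned tally that the run log reports, which makes the
resulting undercount visible instead of silent. Similarly, address keys
that the offline gazetteer cannot resolve are tallied and excluded, with
`misses + resolved = input rows` enforced by test. The gazetteer is a
deterministic key-to-coordinate table; the package deliberately ships no
live geocoding client, so analyses are reproducible offline and the
geocoding backend is pluggable at the interface.

## What the synthetic generator emulates

`scenario_config()` describes a complete scenario with known ground truth:

- **Units**: a `grid_rows x grid_cols` tiling of square cells
  (`cell_size_deg` degrees, default 0.1, roughly the footprint of an urban
  ZCTA). Real ZCTAs are irregular and multipart; the grid keeps every
  geometric property checkable in closed form, and the containment code is
  exercised on multipolygons and holes separately in the unit tests.
- **Incidence**: independent lognormal draws per unit
  (`incidence_log_mean = log(150)`, `incidence_log_sd = 0.7` by default),
  giving a strictly positive, right-skewed surface with median near 150 and
  a tail beyond 400 cases per 100 000 over 5 years — the shape of mapped
  metropolitan ZCTA risk. Any positive distribution would serve; lognormal
  is the documented, swappable choice. Suppression is independent
  Bernoulli(`suppression_prob`), default 0, set near 0.7 to emulate a
  state where most counties release no estimate.
- **Pharmacies**: homogeneous Poisson counts per unit
  (`pharmacy_intensity = 8` by default, matching the dense, evenly spread
  pattern of licensed pharmacies in metropolitan counties), placed
  uniformly within the unit.
- **Prescribers**: Poisson counts with intensity
  `prescriber_intensity * sum_j w_j exp(-d_j^2 / (2 bw_j^2))` evaluated at
  the unit centroid, a Gaussian-kernel mixture over cluster centers that
  reproduces the urban-core clustering of PrEP-prescribing locations. The
  default places one cluster at the domain center with bandwidth 0.15
  degrees and scale 3, yielding a sparse process (under one prescriber per
  unit on average) in which most units are prescriber deserts while almost
  none are pharmacy deserts — the qualitative contrast the measure exists
  to quantify. With `prescriber_clusters = list()` the process is
  homogeneous at `prescriber_intensity`, the regime used for closed-form
  validation.

Draws come from named substreams derived from the single scenario seed, so
adding a generator never perturbs existing draws, and identical configs
write byte-identical files. Ground truth (per-unit intensities and, for
homogeneous placement, the expected fold increase) is written beside the
generated inputs.

The generator does **not** emulate: irregular unit geometry, spatial
autocorrelation of incidence, correlation between facility placement and
incidence, population density, or street-level address realism. Passing
tests therefore demonstrate correctness of the computation and calibrated
behaviour under known processes — not that real ZCTA data are free of the
geometry and registration pathologies the ingest layer guards against.

## Validation design

Three quantitative checks anchor the suite, at sizes chosen to keep the
full run under a few minutes on one core:

- **Containment**: per-unit counts from 1 000 seeded uniform points over a
  3x3 grid must equal an independent brute-force ray-casting oracle's
  counts exactly.
- **Desert closed forms**: with homogeneous Poisson intensity λ per unit,
  the desert fraction is Binomial(n, e^(−λ))/n; observed fractions over 500
  units at λ = 9 (pharmacies) and λ = 0.3 (prescribers) must fall within
  the central 99% binomial bounds of e^(−9) and e^(−0.3).
- **Fold recovery**: with homogeneous placement for both classes, an
  intensity ratio of 30, and incidence independent of facilities, the
  estimated fold increase is consistent for the true ratio; over 100
  replicates of a 400-unit scenario the replicate mean must lie within the
  Monte-Carlo 95% half-width of 30, and multiplying every incidence by 10
  must leave each replicate's fold unchanged to full precision (the
  scale-invariance property: PFNRs scale as 1/c, the fold is a ratio of
  same-scale means).

## Rendering conventions

Choropleths bin incidence at 0/100/200/300/400+ cases per 100 000 by
default — fixed, interpretable steps that match how metropolitan ZCTA risk
is commonly scaled — with quartile-based binning available. Suppressed and
unreported units get a hatched "no data" fill, never the lowest incidence
color: conflating "no estimate released" with "low need" misstates need
precisely where privacy suppression is heaviest. Dense pharmacy layers can
be decimated for legibility: with factor k, each unit draws
`ceiling(n/k)` markers (every k-th facility after sorting by id — a uniform
per-unit rule, since any grouping convention for "one marker per k
facilities" is equally arbitrary). Decimation is display-only; the test
suite asserts the report CSV is identical under k = 1 and k = 3.

## Limitations

PFNR measures presence, not capacity, travel time or uptake; two regions
with equal PFNRs can differ greatly in realized access. Units differ in
area and population, and a per-unit distribution weights a small urban ZCTA
equally with a large rural county; comparisons across unit levels (ZCTA vs
county analyses) should be interpreted cautiously. Planar degree geometry
is appropriate for containment but the package computes no distances, so
nearest-facility and catchment (e.g. two-step floating catchment area)
extensions are out of scope. Suppression is modelled as independent
Bernoulli, while real suppression correlates with low population — a
conservative mismatch, since correlated suppression would bias summaries in
ways no synthetic check here measures.
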