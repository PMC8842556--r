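---
title: "Regional health care profiles: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional health care profiles: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phcprofile)
```

## What a profile is

A regional health care profile describes the population a planned primary
health care unit (PHCU) would serve. The serving population is defined
geographically: the **catchment area** of the location municipality is the
set of municipalities reachable within a maximum car-travel time, computed
as exact shortest paths on a weighted road network whose edge weights are
minutes. Catchments deliberately cross district borders — a PHCU near a
district boundary draws patients from both sides — while the 116 political
districts serve as the *comparator population*: their populations are of a
similar order of magnitude to typical catchments, which makes the district
distribution of an indicator a meaningful reference for "is this catchment
unusual?".

For each of 35 indicators the profile reports: the catchment value, the
district distribution (total range, quartiles, median, after outlier
cleaning), the national value, the catchment's rank among the districts,
and optionally one comparator district's value for a head-to-head
comparison.

## The travel-time model

The original reporting system computes isochrones in a geographical
information system with real road geometry. This package models travel
time as shortest paths on a supplied inter-municipality weighted graph
(centroid to centroid). That reproduces the isochrone *semantics* — "all
municipalities within a 10-, 15- or 20-minute drive" — without proprietary
road data, and it makes the computation exactly testable against a
brute-force all-pairs oracle. Consequences of this choice:

* a municipality is in or out as a whole; there are no partial
  municipalities along the isochrone boundary;
* travel time exactly equal to the cutoff is **inside** (closed boundary,
  `<=`), so nested cutoffs give nested catchments by construction;
* unreachable municipalities are simply absent from a catchment; a
  disconnected network is legal input;
* "distance to the nearest facility" is measured from the location
  municipality itself, not averaged over catchment members, matching how a
  site-specific distance is read.

## Aggregation kinds

Indicator semantics, not a single rule, decide the regional aggregate:

| kind | rule | used for |
|---|---|---|
| `mean` | unweighted mean of municipal values | percentages, prevalences, rates, life expectancy |
| `sum` | total over members | population, pharmacy counts |
| `ratio_of_sums` | (Σ numerator / Σ denominator) × scale | "inhabitants per GP", "FTE per 100 000" |
| `nearest_facility_time` | travel time from the location | "minutes to the nearest hospital / nursing home" |

The unweighted mean follows the source system's described "averages of all
municipalities"; a population-weighted variant was considered and left out
of the default because it changes the published semantics (the
configuration reserves a switch for it, and it is intentionally not yet
wired into the aggregation path). `ratio_of_sums` recomputes regional
ratios from regional totals rather than averaging municipal ratios: this
is the only well-defined choice when some municipalities have zero
providers, and it makes the singleton region reduce exactly to the
municipal ratio. District values use the *same* kind over the district's
member municipalities; for nearest-facility indicators, where a district
has no single location, the district value is the mean of its member
municipalities' own nearest-facility times. National values mirror the
per-region rules (unweighted mean over all municipalities for `mean`
kinds, national totals for `sum`/`ratio_of_sums`, mean municipal nearest
time otherwise). National totals are deliberately kept for count
indicators even though they dominate the boxplot axis — the table reports
them as the natural national reference for a count.

## Outlier cleaning

The district value set of each indicator is winsorised at Tukey fences
before the distribution summary and ranking: with Q1, Q3 the type-7
quartiles and IQR = Q3 − Q1, values outside
[Q1 − k·IQR, Q3 + k·IQR] are set to the fence, with k = 3 ("far out"
fences) by default and configurable. Capping rather than deleting keeps
every district present in the distribution and the ranking; the flags and
an audit table record every altered value. The operation is idempotent
(the quartiles are unchanged by capping values that lie beyond them, so a
second application finds nothing to do) and never moves a value across the
median. The catchment's own value is **never** winsorised: the local value
the report is about must stay authentic. For constant inputs the IQR is 0,
both fences coincide with the common value, and nothing changes; a single
value is likewise returned unchanged.

Quantiles everywhere use linear interpolation between closest order
statistics (R's default type 7), fixed and documented because quantile
conventions differ across ecosystems; an independent sort-and-interpolate
oracle checks this in the tests.

## Ranking

The catchment value is inserted among the district values, so ranks run
from 1 to 117 at full scale. Rank 1 is the most favourable position under
the indicator's polarity: highest value for `higher_better`, lowest for
`lower_better`; `neutral` indicators (e.g. population) rank by descending
value purely for display. Ties take the best rank — the rank equals one
plus the number of strictly better district values, which is also exactly
how the brute-force test oracle computes it. Polarity is editorial
metadata: it only orients the rank and never alters a value. A missing
catchment value yields a missing rank, rendered "n/a".

## The indicator catalogue

The built-in catalogue holds the 35 indicators in their five domains with
per-indicator metadata: aggregation kind, input fields, units, polarity,
reporting scale, source granularity and a record-linkage flag. Two
metadata decisions required judgement:

* **Which 8 indicators are supra-municipal.** The source system describes
  eight indicators as interpolated from higher regional levels, mostly
  survey data, without listing them. The catalogue flags the four
  prevention/risk-factor survey items and the four survey-derived
  prevalences (diabetes type 2, mental disorders, musculoskeletal
  disorders, chronic head/neck/back pain) — exactly the health-survey
  items in the set. The flag records the data-source limitation; the
  interpolation method itself is out of scope.
* **Record linkage.** The four "rate of inpatients … within 2 years"
  indicators carry `linkage_flag = TRUE`, documenting that the original
  values require person-level linkage of hospital episodes. The flag is
  metadata only — computing such values from claims data is out of scope.

Indicator ids are invented stable snake-case tokens (the source publishes
labels only). A catalogue is serialisable to YAML/JSON and round-trips
exactly; validation rejects duplicate ids, unknown kinds, ratio indicators
without denominators and nearest-facility indicators without a facility
type.

## The synthetic country generator

The generator's defaults are the study conditions: 2122 municipalities in
116 districts. It emulates the *structure* real data would have:

* **Coordinates** uniform in a 600 × 300 km rectangle (the Austrian
  east-west extent); planar metres.
* **Districts** by farthest-point-seeded Lloyd clustering of the
  coordinates — contiguous, non-empty, and of comparable size; on default
  settings the largest/smallest district population ratio stays well
  within the documented bound of 100 ("comparable order of magnitude").
* **Road network**: symmetric 4-nearest-neighbour graph augmented with
  shortest bridging edges until connected; minutes = distance / 60 km/h ×
  log-normal noise (σ = 0.15) for road-quality variation. At default
  density this yields median 15-minute catchments of ~5–10 municipalities.
* **Populations** log-normal (median ≈ 1700, σ_log = 0.9, floor 50):
  many small villages, few towns. Age bands (<15, 15–64, 65–74, 75+) come
  from spatially smooth perturbations of national base shares and sum
  exactly to the total (largest-remainder apportionment).
* **Facilities** per type are Poisson with intensity proportional to
  population — placement probability increases with population, and the
  provider-count raw fields are derived from the same facility table, so
  counts and table agree.
* **Indicator raw values** are Gaussian fields with exponential-decay
  spatial correlation (range 60 km) shifted to each field's plausible
  scale (e.g. male life expectancy ≈ 79 ± 1 years, daily smoking ≈ 21 ±
  3 %), percentages clipped to [0, 100]. Nearby municipalities therefore
  resemble each other, which the tests verify by comparing
  network-adjacent against random-pair correlations. Supra-municipal
  fields are drawn at district level and copied to member municipalities,
  emulating the blurring that interpolation from higher regional levels
  causes in real outputs.
* **Determinism**: one root seed; every component (coordinates, districts,
  network, population, facilities, fields) derives its own child stream,
  so reordering generation steps cannot silently change other components'
  draws.

What the generator does **not** emulate: real Austrian geography and
names, calibrated indicator levels, correlations *between* indicators
(income and life expectancy are independent fields here), urban/rural road
speed differences, and partial-municipality isochrones. Passing tests
therefore demonstrate the pipeline's correctness and its behaviour at
realistic scale — not epidemiological validity of any particular value.

## Report rendering

The report is drawn with base graphics into a multi-page PDF: map page
(municipality points, catchment in ochre, location as a black dot,
comparator district in green), the 35-row boxplot panel grouped under the
five domain headings (box = quartiles, whiskers = total range, red line =
national value, circle = catchment, square = comparator), the results
table, and two definition pages. Municipalities are drawn as points: the
fixture has no real boundary polygons, and stand-in polygons (e.g. Voronoi
cells) would suggest a precision the synthetic geometry does not have.
Display rounding (times to whole minutes, counts to integers, the rest to
one decimal) happens only at the drawing layer; the sidecar CSV carries
the exact values, and the tests assert sidecar/profile equality and
glyph-position/value equality. Rendering never mutates the profile, and a
frozen metadata timestamp makes repeated renders byte-identical, which is
how rendering determinism is tested. Missing values render as "n/a" and
never abort a report.

## Problem sizes and runtime choices

The test suite exercises three fixture scales, with the rectangle extent
shrunk in proportion so settlement density — and hence catchment sizes at
the 10/15/20-minute levels — matches the full-scale fixture: 30
municipalities / 5 districts for unit tests, 300 / 20 for nesting and
autocorrelation properties, and the full 2122 / 116 for the end-to-end
checks, including the complete 2122 × 3 × 35 = 222 810-row batch table,
which is verified against independently built single-shot profiles on 50
random (municipality, cutoff, indicator) triples. Property suites run
1000 randomised cases each for the quantile, winsorisation and rank
primitives against brute-force oracles.

## Known limitations

* Travel times are symmetric and static; no one-way roads, congestion or
  public-transport accessibility.
* The unweighted municipal mean can let a hamlet influence a catchment
  average as much as a town; the weighting switch exists in the
  configuration but is not the published default.
* Ranks treat the catchment as if it were a 117th district; overlapping
  catchment/district populations are not deduplicated.
* Confidence intervals and small-area estimation for survey indicators
  are out of scope; the supra-municipal flag only records the issue.
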