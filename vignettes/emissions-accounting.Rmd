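---
title: "Methods: telemedicine travel-avoidance carbon accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: telemedicine travel-avoidance carbon accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teleco2)
```

## The accounting model

Every telemedicine session between a patient and a provider replaces, under
the model's central assumption, one round-trip car journey between their
locations. The net CO₂ effect of a session is therefore

```
net_g = round_trip_miles × 404 g/mile
        − duration_min × 0.036 GB/min × 0.015 kWh/GB × 4.33×10⁻⁴ t/kWh × 10⁶ g/t
```

The first term is the avoided tailpipe emission: round-trip car miles times
the US EPA 2022 fleet-average emission factor for a passenger vehicle
(404 g CO₂ per mile at 22.0 mpg). The second is the energy cost of holding
the session by video instead: minutes of two-participant 720p video are
converted to data volume (0.036 GB/min), data volume to fixed-line
transmission energy (0.015 kWh/GB), energy to CO₂ via the US grid factor
(4.33×10⁻⁴ metric tons per kWh), and tons to grams. With the default
factors one video-minute costs 0.23382 g CO₂, so the expenditure term is
three to four orders of magnitude below the savings term for any session
with non-trivial travel; net savings go negative essentially only for
zero-travel sessions. All constants live in one `emission_factors()`
record, so a sensitivity analysis is a configuration sweep.

Aggregation multiplies a central per-session net value by a session count
and divides by 10⁶ g/ton. The national session count is extrapolated from
payer share: CMS reimbursed 27,691,878 telemedicine sessions in a year and
accounted for 38% of National Health Expenditures, giving
27,691,878 / 0.38 ≈ 72,873,363 national sessions. The median is the default
central estimate (the per-session distribution is strongly right-skewed;
the mean is available via `central = "mean"` and always yields a larger
total). National headlines are rounded to the nearest hundred tons, with
the raw value always carried alongside.

## Session eligibility and the filter

A session is an eligible clinical encounter when all of the following hold,
evaluated in this fixed order with each excluded record attributed to the
*first* failing rule: exactly two participants (dyad); duration ≥ 5 minutes
(shorter calls are treated as connection tests); duration ≤ 120 minutes
(longer sessions resemble remote monitoring); start within the study window
(2022-01-01 through 2023-02-21, inclusive); one-way geodesic distance
≤ 400 miles (beyond that, in-person travel would not plausibly have
substituted); and a known region. Both duration endpoints are inclusive:
the exclusion rule is strictly "less than 5 minutes", and symmetry is
applied at 120 (the observed analytic extremes, 5.00 and 119.83 minutes,
are consistent with inclusive endpoints). The geodesic cutoff uses
great-circle distance, not road distance, and ≤ semantics — a session at
exactly 400 miles is retained; a 10⁻⁹-mile slack absorbs floating-point
noise at the boundary. The filter never errors on a rule violation: it
counts it, and the report's exclusion counts sum exactly to
`n_input − n_retained`.

## Stratified proportional sampling

Retained sessions fall into 40 strata: region (Midwest, Northeast,
Southeast, Southwest, West) × duration class (short = 5–30 minutes
inclusive, long = over 30 to 120) × day class (weekday vs weekend, in UTC
calendar terms, since timestamps are UTC and no timezone conversion rule is
defined) × hour class (peak = 13:00–23:59 UTC, off-peak otherwise). A
session of exactly 30 minutes is short — the class definition is
"5–30 minutes, or greater than 30" — and a start at exactly 13:00 UTC is
peak.

Sample counts are apportioned by the largest-remainder (Hamilton) method:
each stratum gets the floor of its exact quota, and leftover units go to
the largest fractional remainders, ties broken by a documented total
ordering of the keys (region alphabetical, then short < long,
weekday < weekend, peak < off-peak). Hamilton apportionment is exact (the
counts always sum to the requested size), never exceeds any stratum's
population, and distorts no stratum's share by a full 1/n. Within strata
the draw is simple random sampling without replacement; rows are ordered by
session id within each stratum before drawing, so the sample depends only
on the record set and the seed, not on input row order.

## Travel distance

Geodesic distance is the haversine formula on a sphere of radius
3958.8 miles. The spherical model errs by under 0.5% against an ellipsoid,
irrelevant at this analysis's precision; the tests check the closed form
against a brute-force great-circle integration to 10⁻⁶ relative error.

Road distance comes through a pluggable routing contract:
`route(router, origin, destination)` returns one-way road miles and hours,
with road ≥ geodesic guaranteed. The live distance-matrix service the
estimates conceptually correspond to is out of scope; the default
implementation is a synthetic router that multiplies the geodesic distance
by a circuity (detour) factor drawn from a normal distribution truncated at
1.0 (default mean 1.3, SD 0.1 — typical US road-network circuity) and
divides by a fixed average speed (default 45 mph) for travel time. The
factor is a pure hash of the seed and the coordinate pair, so identical
queries return identical answers in any call order. The round trip is
exactly twice the one-way route — a distance-matrix query is one-way, and
doubling is the only reconstruction consistent with paired round-trip
time/distance reporting.

The car-mode-share adjustment (×0.848, the adult car-commuting share in
American Community Survey data) is deliberately exposed as a switch rather
than hard-wired. The source material is internally inconsistent about where
it applies: the prose adjusts travel distance before emissions, yet the
published per-session savings column equals 404 g times the *unadjusted*
round-trip distance, and the national chain uses the unadjusted median net.
The package therefore stores `adjusted_round_trip_miles` on every session
but defaults to the unadjusted basis for per-session savings
(`miles_basis = "round_trip"`); setting `miles_basis = "adjusted"` applies
the factor per session, and the factor can equally be applied once at the
aggregate level.

## What the synthetic generator emulates

The proprietary platform data behind the original observations has no
public accession, so `generate_sessions()` provides a population with the
same statistical structure:

* **Regional shares** — Northeast 34.18%, Southeast 20.42%, West 18.99%,
  Midwest 17.26%, Southwest 9.15%.
* **Bimodal duration** — a two-component mixture of truncated normals,
  short on [5, 30] (mean 19, SD 7) and long on (30, 120] (mean 45, SD 16),
  with a 44.06% short share. The component means/SDs are the package's own
  choice: only bimodality, the class shares and the support are observed;
  the defaults land the overall mean and median near their observed values
  (≈34.5 and ≈36.7 minutes).
* **Travel distance** — per-region log-normal one-way geodesic miles, the
  simplest two-parameter right-skewed family. The log-location is set so
  the median equals half the observed round-trip road median per region
  (Midwest 24, Northeast 23, Southeast 31.5, Southwest 24.5, West 22
  miles); the log-scale is set from each region's observed mean/median
  ratio, `sdlog = sqrt(2 log(mean/median))`, which is exact for a
  log-normal. Patients are placed at a uniformly random bearing and the
  sampled geodesic distance from their provider (scattered uniformly in a
  per-region bounding box), so the configured distance law holds exactly by
  construction.
* **Timing** — weekday shares proportional to the observed day-of-week
  counts (Tuesday–Thursday heaviest, ≈3.1% on weekends) and an 85% share of
  sessions in the 13:00–23:59 UTC window. The peak share itself is not
  directly observed; 85% reflects that the window covers US business hours
  (8 a.m.–6 p.m. Eastern) where clinical scheduling concentrates.
* **Planted violations** — 2% of records violate an inclusion rule
  (sub-5-minute or over-120-minute durations, more than two participants,
  missing region, in equal parts) so the filter stage is genuinely
  exercised; geodesic distances above 400 miles arise naturally from the
  log-normal tail (≈2–3% of draws).

One master seed drives everything; each component (region, duration,
provider location, distance, bearing, timestamp, violations) draws from its
own derived stream, so adding a component never perturbs existing draws and
two runs with the same configuration are byte-identical.

What the generator does **not** emulate: street-level geography or
population-density-weighted placement (the analysis consumes only pairwise
distances), IP-geolocation error, within-provider session clustering, or
correlation between duration and distance. Consequently, passing tests
demonstrate that the pipeline's *mechanics* — filtering, apportionment,
routing contracts, conversion chains — are correct and that configured
distributions are recovered; they do not re-establish the observed
sample-level medians. In particular, the synthetic round-trip road median
(≈60 miles at the default calibration) exceeds the observed 49 miles by
construction, because the geodesic medians are calibrated to half the road
medians and the detour factor then multiplies by ≈1.3; the calibrated
quantity, the one-way geodesic median, is what the recovery tests check
(within 10% at n = 100,000).

## Numerical choices

* Truncated-normal and truncated log-normal draws use inverse-CDF sampling
  (one uniform per value), keeping streams stable under vectorisation.
* Quartiles use linear interpolation between order statistics
  (`quantile()` type 7, the mainstream default); the quartile rule is
  documented because interquartile endpoints are reported quantities. The
  SD is the sample SD (n−1), reported as 0 for a singleton.
* Per-minute net savings for a zero-duration session is defined as 0; the
  filter guarantees duration ≥ 5, so this is a guard, not a semantics
  choice.
* Ties in largest-remainder apportionment break by the canonical stratum
  ordering, making allocations fully deterministic.
* The synthetic router's per-pair determinism comes from a sine-based
  coordinate hash mapped through the truncated-normal quantile function;
  with SD = 0 the factor degenerates exactly to its mean.

## Problem sizes

The shipped analysis scripts simulate 1,000,000 sessions and draw a
79,904-session proportional sample, matching the scale of the original
design (the package runs this end to end in well under a minute).
Distributional tests use n = 100,000, where binomial noise on a share is
about ±0.15 percentage points, comfortably inside the ±0.5-point and ±1-point
recovery tolerances; unit tests use populations of a few thousand.

## Known limitations

The accounting attributes one full avoided round trip to every session,
with no no-show, trip-chaining or multi-purpose-travel correction beyond
the optional mode-share factor. The expenditure side covers transmission
energy only — no device embodied emissions or data-centre overheads. The
national extrapolation rests on a single payer-share point estimate with no
uncertainty interval; it scales reimbursement share to session share
linearly. A published discussion figure of 1,462,932 tons is not derivable
from any printed combination of the central estimates and session counts;
the package reproduces only the 1,443,800-ton chain
(19,812.45 g × 72,873,363 sessions).
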