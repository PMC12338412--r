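---
title: "Methods: service bands, red-criteria triage, and access metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: service bands, red-criteria triage, and access metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traumaccess)
```

## The problem

Severely injured patients benefit from reaching a level 1 or 2 trauma
center within the "golden hour". Two distinct failures stand between a
prehospital system and that goal:

* **delay** — the ambulance heads to the right kind of facility, but the
  observed transport takes longer than 60 minutes; and
* **undertriage** — a high-acuity patient is taken to a facility below
  definitive trauma care although an appropriate center was reachable in
  time.

`traumaccess` quantifies both from three ingredients: a road network
with speed limits, rosters of facilities and emergency dispatch
centers, and an incident registry. Dispatch centers act as proxies for
incident sites, which is the convention of prehospital registries that
log the dispatching station rather than exact scene coordinates.

## Service-zone model

The road network is a weighted directed graph. An edge of length $\ell$
meters with speed limit $v$ km/h costs

$$t = \frac{\ell/1000}{v} \times 60 \text{ minutes,}$$

i.e. free-flow driving time; congestion never enters the theoretical
zone analysis. For each dispatch center $d$ the pipeline computes the
Dijkstra shortest travel time $T(d)$ to the *nearest* level 1/2 trauma
center, then assigns the service band as the smallest threshold in
$\{15, 30, 45, 60\}$ minutes that is $\ge T(d)$, with `BEYOND` past 60
minutes or when no trauma center is reachable.

Numerical conventions, each of which was a genuine design choice:

* **Band edges are upper-inclusive**: a center at exactly 30.0 minutes
  belongs to the 30-minute band. "Reachable within 30 minutes" reads
  naturally as $T \le 30$, and the same convention puts a 60.0-minute
  center inside the covered city rather than beyond it.
* **Edges are bidirectional by default**; one-way streets are supported
  through an `oneway` flag. Road datasets that do not annotate
  directionality are treated as two-way.
* **Snapping** of facilities and dispatch centers to the network uses
  great-circle (haversine) distance to the nearest node, at load time
  only. Haversine distance never contributes to travel time.
* Shortest-path **tie-breaking needs no rule**: only the cost is
  consumed downstream, and equal-cost paths have equal cost.

`shortest_travel_time()` returns `Inf` for unreachable origins, which
`service_band()` maps to `BEYOND`; no special sentinel value leaks into
user code.

## Red-criteria triage

The field-triage red criteria are a pure disjunction:

* penetrating mechanism — always red, regardless of vitals and age;
* age 14–64: systolic blood pressure (SBP) $< 90$ mmHg **or**
  heart rate $>$ SBP (a shock-index surrogate);
* age $\ge 65$: SBP $< 110$ mmHg **or** heart rate $>$ SBP.

Boundary behavior is exact and tested exhaustively: SBP 90 at age 64 is
not red, 89 is; SBP 110 at 65 is not red, 109 is; heart rate *equal* to
SBP never triggers the shock rule (the inequality is strict). Age 65
itself uses the elderly thresholds.

Two missing-data policies had to be decided:

* **Missing age**: the record stays in the cohort (only ages *known* to
  be below 14 are pediatric exclusions) and is triaged with the adult
  thresholds.
* **Missing vitals**: a non-penetrating record with missing SBP or HR
  cannot satisfy a vitals criterion, so the default classifies it
  `NOT_RED`. `missing_vitals = "red"` escalates such records instead,
  as an upper-bound sensitivity analysis; the truth is unknowable from
  the record.

Cohort selection applies four tests in a fixed order — outcome
recorded, inside the region of interest, age $\ge 14$, trauma-related —
and tallies each excluded record under the *first* failing reason.
Because real exclusion categories overlap, the flow report also carries
overlap-tolerant counts (each record counted under every reason it
fails); the two views bracket any sequential accounting a registry
custodian might have used.

## Delay and undertriage

**Delay** uses the *observed* travel time recorded on the incident
(assignment to hospital arrival), not the theoretical network time: a
transfer to a level 1/2 center is delayed when that observed time
strictly exceeds 60 minutes. This is the only reading under which
nominally well-covered 15-minute areas can still show double-digit
delay rates — the zones are free-flow, the trips are not. Delay is
undefined (`NA`) for other destinations and for missing times.

**Undertriage** conversely uses the *theoretical* band: a red-criteria
case is undertriaged when it went to a lower-level facility although
its dispatch center's band shows a level 1/2 center reachable within 60
minutes. The destination set counted as undertriage is configurable:

* default `{NTC}` — non-trauma centers only, matching the headline
  accounting in which level 3 transfers are not counted against the
  system;
* `strict = TRUE` adds `{LEVEL3}`, implementing the wider definition in
  which anything below definitive care counts.

The strict count is provably $\ge$ the default count on the same data,
and both are reported.

The tristate outcomes (applicable-true / applicable-false /
not-applicable) are represented as R logicals with `NA` meaning *not
applicable*; records that cannot contribute to a denominator simply
drop out of it.

**Percentages** are formatted to one decimal with half-up rounding
(base R's `round()` is half-even, which disagrees with conventional
table formatting on ties). Table conventions: band rows are shares of
their region's totals; region totals are shares of the citywide totals;
the overall row reports transfers as a share of all red-criteria cases
and delays as a share of transfers. Zero denominators yield `NA`, never
an error.

## The synthetic city generator

No public incident registry exists for this setting, so the package
ships a generator whose defaults *are* the study conditions it
emulates: a metropolitan EMS system with 53 hospitals (8 of them level
1/2, 4 level 3), 50 dispatch centers split 20/13/7/6/4 across the
East/North/West/South/Middle regions, and an incident mix calibrated to
the published cohort marginals — mechanism 68.3% blunt (70.1% motor
vehicle collisions, 29.9% falls within blunt), 21.1% penetrating, 1.9%
thermal, 8.7% other; sex 73.8/25.4/0.8% male/female/missing; age 87.9%
adult, 10.8% elderly, 1.2% missing; regional burden
41.5/24.9/12.7/12.1/8.9%.

The geometry is a 10×10 grid at 6 km spacing (roughly the 54 km extent
of the metropolitan area emulated), with speed limits drawn from
\{40, 60, 80, 100\} km/h at weights 0.2/0.4/0.3/0.1 — an urban mix of
arterials and highways. Regions partition the grid by quadrant around a
central `MIDDLE` box. Facilities land on distinct random nodes;
dispatch centers on random nodes of their region.

Where the emulated system publishes only categorical marginals, the
distributional forms are this package's own choices and are documented
as such:

* **Vitals**: SBP $\sim N(125, 15^2)$ truncated at 60 mmHg, HR
  $\sim N(85, 12^2)$ truncated at 30 bpm — plausible prehospital
  vitals, not validated against any source. Under these defaults about
  4% of non-penetrating cases are spontaneously red; an additional
  planted fraction `p_force_red = 0.07` of non-penetrating cases gets
  SBP forced below the age-appropriate threshold, which puts total
  red-criteria prevalence at
  $0.211 + 0.789 \times (0.07 + 0.93 \times 0.04) \approx 0.30$, the
  prevalence the generator is meant to reproduce.
* **Destination**: with probability `p_tc = 0.668` the case goes to the
  *nearest* level 1/2 center, otherwise to the nearest lower-level
  facility. The level 3 vs NTC split among diversions is therefore
  geometric (41 NTCs vs 4 level 3 centers makes the nearest
  alternative an NTC for most nodes), landing near the observed
  4.5%/28.7% split without a dedicated parameter.
* **Congestion**: observed time = network time × LogNormal(0, σ) with
  σ = 0.35; with probability `p_slow = 0.21` the trip is further
  inflated uniformly into 61–120 minutes. Free-flow times on a 54 km
  grid rarely exceed 60 minutes, so `p_slow` is what drives the delay
  rate, and its default equals the delay share the generator emulates.

Every draw flows from one integer seed; identical seeds give
byte-identical registries. `planted_truth()` computes the expected red
fraction, undertriage probability and delay probability from a 10×
oversize reference registry drawn with an independent seed offset, plus
the exact (deterministic) band of every dispatch center.

### What passing tests do and do not show

The end-to-end recovery test generates 20,000 incidents, runs the full
pipeline, and requires each estimated rate to sit inside a 99% binomial
confidence interval around the planted value (reference simulation
n = 200,000); the shortest-path engine is checked against exhaustive
simple-path enumeration on 200 random graphs of up to 8 nodes; the
triage classifier is checked on the exhaustive boundary grid; and the
aggregation layer reproduces, to one decimal, every internally
consistent percentage of a fixture instantiating the published cohort
counts. These problem sizes keep the whole suite under a minute on one
CPU while leaving the binomial tolerances tight.

What this does **not** show: the generator's grid geometry has none of
the escarpments, ring roads or density gradients of a real city; the
congestion model is spatially unstructured, whereas real delays
concentrate where traffic does; vitals are independent of mechanism and
age beyond the planted forcing; and destination choice ignores bed
availability, bypass protocols and crew judgment. Passing recovery
tests demonstrates that the *pipeline arithmetic* is right, not that
the synthetic city is a faithful model of any real one.

### A note on the replica fixtures

The published cohort table that the fixtures instantiate is internally
inconsistent in one place: the red-criteria column's mechanism counts
sum to 25,425 against a stated red-criteria total of 31,072 (its other
breakdowns — sex, age, region, destination — do sum correctly). A
fixture cannot satisfy both, so the replica preserves the red-criteria
total, all consistent marginals, and the blunt/penetrating/thermal
counts exactly, carrying the 5,647 unaccounted vitals-positive cases
under the "other" mechanism. Tests assert the internally consistent
cells only. Similarly, the upstream exclusion-flow counts do not sum to
the included total, which is why the flow report exposes both
sequential and overlap-tolerant tallies rather than forcing a match.

## Known limitations

* GeoJSON I/O handles flat Point and two-point LineString
  FeatureCollections — exactly the layers this pipeline produces and
  consumes — not arbitrary geometry collections.
* The band map keys on dispatch centers, not incidents; systems that
  geocode true scene locations would need a per-incident snapping step
  before the same machinery applies.
* Travel-time weights are static; time-of-day speed profiles would
  require edge weights per period and are out of scope.
* Percentages are recomputed from counts at one decimal; consumers who
  need more precision should use the count columns.
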