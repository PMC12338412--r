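# traumaccess

Road-network trauma-center accessibility and field-triage analytics for
prehospital (EMS) incident registries.

Trauma systems fail severely injured patients in two ways: **delays**
(transport to a level 1/2 trauma center taking longer than the
60-minute golden hour) and **undertriage** (high-acuity patients taken
to a lower-level facility although definitive care was reachable in
time). `traumaccess` measures both for a city, given a road network, a
facility roster, a dispatch-center roster and an incident registry. It
is written for trauma-system researchers and EMS quality-improvement
teams working with registry extracts.

## What it computes

* **Service bands** — for each dispatch center $d$, the free-flow
  Dijkstra travel time $T(d) = \min_{f \in \text{L1/L2}} t(d, f)$ to
  the nearest level 1/2 trauma center, with edge weights
  $t = (\ell/1000)/v \times 60$ minutes from edge length $\ell$ (m) and
  speed limit $v$ (km/h), banded into {≤15, ≤30, ≤45, ≤60, beyond}
  minutes.
* **Red-criteria (RC) triage** — a case is RC iff it is penetrating
  trauma, or SBP < 90 mmHg or HR > SBP at age 14–64, or SBP < 110 mmHg
  or HR > SBP at age ≥ 65.
* **Delay** — observed travel time to a level 1/2 destination > 60 min.
* **Undertriage** — an RC case sent to a non-trauma center (optionally
  also level 3, `strict` mode) while its dispatch center's band shows a
  level 1/2 center reachable within 60 min.
* **Reports** — cohort composition, region × band transfer/delay
  tables, per-dispatch-center delay and diversion rates, exclusion-flow
  report, plus GeoJSON layers of bands and rates.

A seeded synthetic-city generator (grid road network, facility and
dispatch rosters, incident registry with planted red/delay/undertriage
rates) stands in for the non-public registries this kind of analysis
runs on, and doubles as the validation harness.

## Worked example

```r
library(traumaccess)

city     <- generate_city(city_params(seed = 11))
records  <- generate_incidents(city, incident_params(n = 20000, seed = 11))
band_map <- assign_dispatch_bands(city$network, city$dispatch, city$facilities)
table(band_map$band)
#>    B15    B30    B45    B60 BEYOND
#>     34     15      1      0      0

flt      <- apply_inclusion_filters(records)
assessed <- assess_records(flt$included, band_map, city$facilities)
str(summarise_access(assessed))
#> List of 9
#>  $ n                  : int 20000
#>  $ rc_n               : int 5884
#>  $ rc_pct             : num 29.4
#>  $ rc_l12_n           : int 3905
#>  $ rc_l12_pct         : num 66.4
#>  $ rc_delayed_n       : int 790
#>  $ rc_delayed_pct     : num 20.2
#>  $ rc_undertriaged_n  : int 1895
#>  $ rc_undertriaged_pct: num 32.2
```

Of 20,000 included incidents, 29.4% meet the red criteria; 66.4% of
those reached a level 1/2 trauma center, 20.2% of these transfers took
longer than 60 minutes, and 32.2% of all RC cases were diverted to a
non-trauma center despite a reachable trauma center. The region × band
breakdown shows where:

```r
head(build_access_table(assessed), 5)
#> # A tibble: 5 × 6
#>   region  band      n n_pct delayed_n delayed_pct
#> 1 OVERALL TOTAL  3905  66.4       790        20.2
#> 2 NORTH   TOTAL   957  24.5       198        25.1
#> 3 NORTH   B15     596  62.3       112        56.6
#> 4 NORTH   B30     286  29.9        71        35.9
#> 5 NORTH   B45      75   7.8        15         7.6
```

Band rows are shares of their region's totals; region totals are shares
of the citywide totals. `build_dispatch_table()` gives per-station
delay and diversion percentages, and `build_cohort_table()` the
demographic breakdown.

The same pipeline runs from the shell over files
(GeoJSON network/rosters + registry CSV):

```sh
Rscript inst/cli/traumaccess.R run --seed 11 --out results/
Rscript inst/cli/traumaccess.R metrics --registry registry.csv \
    --network network.geojson --facilities facilities.geojson \
    --dispatch dispatch.geojson --out results/
```

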