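Package: traumaccess
Title: Road-Network Trauma-Center Accessibility and Field Triage Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying prehospital access to definitive trauma
    care on a road network. Computes free-flow travel-time service bands
    (15/30/45/60 minutes) from emergency dispatch centers to level 1/2
    trauma centers with Dijkstra shortest paths, classifies incident
    records against field trauma triage "red criteria" (penetrating
    mechanism or age-stratified hypotension / shock-index rules), and
    aggregates transport delays (observed travel time beyond the golden
    hour) and undertriage (high-acuity patients diverted to non-trauma
    centers despite a reachable trauma center) by region, service band and
    dispatch center. Includes a seeded synthetic-city generator that
    emulates a prehospital incident registry with planted ground-truth
    rates for end-to-end validation, and GeoJSON/CSV readers and writers
    so simulation and analysis round-trip through disk.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    igraph,
    jsonlite,
    geosphere,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
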