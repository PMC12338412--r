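# Fixture builders. The published-table replicas instantiate the printed
# numerator/denominator counts of the study cohort so the aggregation
# pipeline's percentages can be checked against the printed values.

# Roster of destination facilities shared by the table fixtures.
fixture_facilities <- function() {
  tibble::tibble(
    id = c("FL1", "FL2", "FL3", "FNTC"),
    name = c("TC one", "TC two", "Level three", "General hospital"),
    lon = c(46.7, 46.75, 46.8, 46.85),
    lat = c(24.7, 24.72, 24.74, 24.76),
    level = c("LEVEL1", "LEVEL2", "LEVEL3", "NTC"),
    node_id = NA_character_
  )
}

# Interleave-free block assignment of a categorical attribute: exact
# counts, deterministic order.
rep_levels <- function(counts) rep(names(counts), times = counts)

# Cohort-table replica: 102,895 records, 31,072 of them red criteria,
# with the published sex/age/region/destination marginals in both
# strata and the published mechanism counts for the all-cases column.
# The red-criteria column's printed mechanism counts do not sum to the
# red-criteria total; the unaccounted 5,647 vitals-positive cases are
# carried under OTHER mechanism (see the methods vignette).
make_cohort_fixture <- function() {
  red_n <- 31072
  not_n <- 102895 - red_n

  red <- tibble::tibble(.rows = red_n)
  red$sex <- c(rep_levels(c(MALE = 20601, FEMALE = 10286)), rep(NA, 185))
  red$age <- c(rep(40, 22075), rep(70, 8749), rep(NA, 248))
  red$mechanism_code <- c(rep("MVC", 1979), rep("FALL", 1503),
                          rep("STAB", 21666), rep("FLAME_BURN", 112),
                          rep("OTHER", 165 + 5647))
  red$region <- rep_levels(c(EAST = 13267, NORTH = 6680, WEST = 4205,
                             SOUTH = 4133, MIDDLE = 2787))
  red$destination_facility_id <- rep_levels(c(FL1 = 20747, FL3 = 1413,
                                              FNTC = 8912))
  # force the vitals criterion for every non-penetrating row, at the
  # age-appropriate threshold; penetrating rows are red by mechanism
  pen <- red$mechanism_code %in% c("STAB", "GUNSHOT")
  elderly <- !is.na(red$age) & red$age >= 65
  red$sbp <- ifelse(pen, 120, ifelse(elderly, 100, 80))
  red$hr <- 70

  not <- tibble::tibble(.rows = not_n)
  not$sex <- c(rep_levels(c(MALE = 75973 - 20601, FEMALE = 26109 - 10286)),
               rep(NA, 813 - 185))
  not$age <- c(rep(40, 90478 - 22075), rep(70, 11140 - 8749),
               rep(NA, 1277 - 248))
  not$mechanism_code <- rep_levels(c(MVC = 49294 - 1979, FALL = 21010 - 1503,
                                     FLAME_BURN = 1949 - 112,
                                     OTHER = 8976 - 165 - 5647))
  not$region <- rep_levels(c(EAST = 42665 - 13267, NORTH = 25576 - 6680,
                             WEST = 13053 - 4205, SOUTH = 12475 - 4133,
                             MIDDLE = 9126 - 2787))
  not$destination_facility_id <- rep_levels(c(FL1 = 64300 - 20747,
                                              FL3 = 5451 - 1413,
                                              FNTC = 33144 - 8912))
  not$sbp <- 120
  not$hr <- 70

  records <- dplyr::bind_rows(red, not)
  records$id <- sprintf("C%06d", seq_len(nrow(records)))
  records$timestamp <- "2022-01-01T00:00:00Z"
  records$dispatch_center_id <- paste0("D_", records$region)
  records$trauma_flag <- TRUE
  records$outcome_recorded <- TRUE
  records$observed_travel_time <- NA_real_

  band_map <- tibble::tibble(
    dispatch_id = paste0("D_", c("EAST", "NORTH", "WEST", "SOUTH", "MIDDLE")),
    minutes = 10,
    band = factor("B15", levels = c("B15", "B30", "B45", "B60", "BEYOND"))
  )
  list(records = records, band_map = band_map,
       facilities = fixture_facilities())
}

# Region x band replica of the red-criteria level 1/2 transfer table:
# per-cell transfer and delayed counts, plus the 1,413 level-3 and 8,912
# NTC red-criteria cases needed for the citywide denominators.
make_access_fixture <- function() {
  cells <- tibble::tribble(
    ~region, ~band, ~n, ~delayed,
    "EAST", "B15", 316, 78,
    "EAST", "B30", 6247, 1149,
    "EAST", "B45", 2715, 597,
    "NORTH", "B30", 3034, 674,
    "NORTH", "B45", 671, 249,
    "NORTH", "B60", 26, 15,
    "WEST", "B15", 1663, 293,
    "WEST", "B30", 1832, 419,
    "SOUTH", "B15", 2156, 379,
    "SOUTH", "B30", 532, 184,
    "MIDDLE", "B15", 1103, 242,
    "MIDDLE", "B30", 452, 100
  )
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    with(cells[i, ], tibble::tibble(
      region = region,
      dispatch_center_id = paste0("D_", region, "_", band),
      destination_facility_id = "FL1",
      observed_travel_time = c(rep(90, delayed), rep(30, n - delayed))
    ))
  })
  transfers <- dplyr::bind_rows(rows)
  diverted <- tibble::tibble(
    region = "EAST",
    dispatch_center_id = "D_EAST_B15",
    destination_facility_id = rep_levels(c(FL3 = 1413, FNTC = 8912)),
    observed_travel_time = NA_real_
  )
  records <- dplyr::bind_rows(transfers, diverted)
  records$id <- sprintf("A%06d", seq_len(nrow(records)))
  records$timestamp <- "2022-01-01T00:00:00Z"
  records$age <- 40
  records$sex <- "MALE"
  records$sbp <- 120
  records$hr <- 80
  records$mechanism_code <- "STAB"  # red criteria by mechanism
  records$trauma_flag <- TRUE
  records$outcome_recorded <- TRUE

  bands <- unique(records$dispatch_center_id)
  band_map <- tibble::tibble(
    dispatch_id = bands,
    minutes = 10,
    band = factor(sub(".*_", "", bands),
                  levels = c("B15", "B30", "B45", "B60", "BEYOND"))
  )
  list(records = records, band_map = band_map,
       facilities = fixture_facilities())
}

# Small assessed cohort from the synthetic generator, for group-by
# oracle comparisons.
make_random_assessed <- function(n = 800, seed = 404) {
  city <- generate_city(city_params(
    rows = 6, cols = 6, spacing_m = 4000,
    facility_counts = c(LEVEL1 = 1, LEVEL2 = 1, LEVEL3 = 1, NTC = 6),
    dispatch_counts = c(EAST = 2, NORTH = 2, WEST = 2, SOUTH = 2, MIDDLE = 1),
    seed = seed))
  records <- generate_incidents(city, incident_params(n = n, seed = seed))
  band_map <- assign_dispatch_bands(city$network, city$dispatch,
                                    city$facilities)
  assess_records(records, band_map, city$facilities)
}
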