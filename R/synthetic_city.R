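#' Parameters for the synthetic city generator
#'
#' A rectangular grid road network with sampled speed limits, a facility
#' roster and a dispatch-center roster. Defaults emulate the study
#' setting: 53 hospitals of which 8 are level 1/2 trauma centers and 4
#' level 3, and 50 dispatch centers distributed 20/13/7/6/4 over the
#' East/North/West/South/Middle regions.
#'
#' @param rows,cols Grid dimensions (each >= 2). The default 10x10 grid at
#'   6 km spacing spans roughly 54 km, comparable to the metropolitan
#'   extent it emulates.
#' @param spacing_m Distance between adjacent grid nodes in meters.
#' @param speeds,speed_weights Speed-limit palette (km/h) and sampling
#'   weights for grid edges.
#' @param facility_counts Named vector of facility counts per level.
#' @param dispatch_counts Named vector of dispatch-center counts per
#'   region.
#' @param origin_lon,origin_lat Southwest corner of the grid (WGS84).
#' @param seed Integer seed; fully determines the city.
#' @return List of class `city_params`.
#' @export
city_params <- function(rows = 10, cols = 10, spacing_m = 6000,
                        speeds = c(40, 60, 80, 100),
                        speed_weights = c(0.2, 0.4, 0.3, 0.1),
                        facility_counts = c(LEVEL1 = 2, LEVEL2 = 6,
                                            LEVEL3 = 4, NTC = 41),
                        dispatch_counts = c(EAST = 20, NORTH = 13, WEST = 7,
                                            SOUTH = 6, MIDDLE = 4),
                        origin_lon = 46.5, origin_lat = 24.5,
                        seed = 1L) {
  if (rows < 2 || cols < 2) {
    stop("grid must be at least 2x2 (a 1x1 grid has no edges)", call. = FALSE)
  }
  stopifnot(spacing_m > 0, length(speeds) == length(speed_weights),
            all(speeds > 0), all(speed_weights >= 0), sum(speed_weights) > 0)
  if (!any(names(facility_counts) %in% c("LEVEL1", "LEVEL2")) ||
      sum(facility_counts[c("LEVEL1", "LEVEL2")], na.rm = TRUE) < 1) {
    stop("at least one LEVEL1 or LEVEL2 facility is required", call. = FALSE)
  }
  if (any(dispatch_counts < 1)) {
    stop("each region needs at least one dispatch center", call. = FALSE)
  }
  structure(list(rows = rows, cols = cols, spacing_m = spacing_m,
                 speeds = speeds, speed_weights = speed_weights,
                 facility_counts = facility_counts,
                 dispatch_counts = dispatch_counts,
                 origin_lon = origin_lon, origin_lat = origin_lat,
                 seed = as.integer(seed)),
            class = "city_params")
}

# Region partition: a central box is MIDDLE; the rest split into four
# quadrants by the dominant offset from the grid center (ties go
# east/west).
grid_regions <- function(rows, cols) {
  r <- rep(seq_len(rows), each = cols)
  c_ <- rep(seq_len(cols), times = rows)
  dr <- r - (rows + 1) / 2
  dc <- c_ - (cols + 1) / 2
  mid <- abs(dr) <= rows / 6 & abs(dc) <= cols / 6
  region <- ifelse(mid, "MIDDLE",
                   ifelse(abs(dr) > abs(dc),
                          ifelse(dr > 0, "NORTH", "SOUTH"),
                          ifelse(dc > 0, "EAST", "WEST")))
  region
}

#' Generate a synthetic city
#'
#' Builds a connected grid road network with speed limits sampled from
#' the palette, places facilities on distinct random nodes and dispatch
#' centers on random nodes within their assigned region, and snaps both
#' rosters to the network. Reproducible: the seed fully determines the
#' output.
#'
#' @param params A [city_params()] object.
#' @return List of class `synthetic_city` with elements `network`
#'   ([road_network()]), `facilities`, `dispatch` and `params`.
#' @export
generate_city <- function(params = city_params()) {
  stopifnot(inherits(params, "city_params"))
  set.seed(params$seed)
  rows <- params$rows; cols <- params$cols
  n_nodes <- rows * cols
  if (sum(params$facility_counts) > n_nodes) {
    stop("more facilities than network nodes", call. = FALSE)
  }

  r <- rep(seq_len(rows), each = cols)
  c_ <- rep(seq_len(cols), times = rows)
  # approximate meters -> degrees at the origin latitude
  dlat <- params$spacing_m / 111320
  dlon <- params$spacing_m / (111320 * cos(params$origin_lat * pi / 180))
  nodes <- tibble(id = paste0("n", r, "_", c_),
                  lon = params$origin_lon + (c_ - 1) * dlon,
                  lat = params$origin_lat + (r - 1) * dlat)
  region <- grid_regions(rows, cols)

  node_id <- function(ri, ci) paste0("n", ri, "_", ci)
  horiz <- expand.grid(ri = seq_len(rows), ci = seq_len(cols - 1))
  vert <- expand.grid(ri = seq_len(rows - 1), ci = seq_len(cols))
  edges <- tibble(
    node_a = c(node_id(horiz$ri, horiz$ci), node_id(vert$ri, vert$ci)),
    node_b = c(node_id(horiz$ri, horiz$ci + 1), node_id(vert$ri + 1, vert$ci)),
    length_m = params$spacing_m,
    speed_kmh = sample(params$speeds, nrow(horiz) + nrow(vert),
                       replace = TRUE, prob = params$speed_weights),
    oneway = FALSE
  )
  network <- road_network(nodes, edges)

  fc <- params$facility_counts[params$facility_counts > 0]
  fac_nodes <- sample(nodes$id, sum(fc), replace = FALSE)
  facilities <- tibble(
    id = paste0("F", seq_len(sum(fc))),
    name = paste0("Facility ", seq_len(sum(fc))),
    level = rep(names(fc), times = fc),
    node_id = fac_nodes
  )
  facilities$lon <- nodes$lon[match(facilities$node_id, nodes$id)]
  facilities$lat <- nodes$lat[match(facilities$node_id, nodes$id)]

  dc <- params$dispatch_counts
  disp_nodes <- unlist(lapply(names(dc), function(rg) {
    pool <- nodes$id[region == rg]
    if (length(pool) == 0) stop("region ", rg, " has no grid nodes", call. = FALSE)
    sample(pool, dc[[rg]], replace = dc[[rg]] > length(pool))
  }))
  dispatch <- tibble(
    id = paste0("D", seq_along(disp_nodes)),
    name = paste0("Dispatch ", seq_along(disp_nodes)),
    region = rep(names(dc), times = dc),
    node_id = disp_nodes
  )
  dispatch$lon <- nodes$lon[match(dispatch$node_id, nodes$id)]
  dispatch$lat <- nodes$lat[match(dispatch$node_id, nodes$id)]

  structure(list(network = network,
                 facilities = facilities[, c("id", "name", "lon", "lat",
                                             "level", "node_id")],
                 dispatch = dispatch[, c("id", "name", "lon", "lat",
                                         "region", "node_id")],
                 params = params),
            class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat("<synthetic_city> ", x$params$rows, "x", x$params$cols, " grid, ",
      nrow(x$facilities), " facilities, ", nrow(x$dispatch),
      " dispatch centers\n", sep = "")
  invisible(x)
}

#' Parameters for the synthetic incident registry
#'
#' Mixture and noise parameters for generating prehospital incident
#' records. Category mixes default to the published cohort marginals:
#' mechanism 68.3% blunt (70.1% MVC / 29.9% falls within blunt), 21.1%
#' penetrating, 1.9% thermal, 8.7% other; sex 73.8/25.4/0.8; age
#' 87.9% 14-64, 10.8% >= 65, 1.2% missing; regional burden
#' 41.5/24.9/12.7/12.1/8.9 (E/N/W/S/M). Vitals are truncated normals;
#' `p_force_red` plants an extra fraction of non-penetrating cases with
#' hypotensive SBP so total red-criteria prevalence lands near 30%.
#' `p_tc` is the probability of transport to the nearest level 1/2
#' trauma center (default 0.668); otherwise the nearest lower-level
#' facility receives the case. Observed travel time is the network time
#' times a LogNormal(0, sigma) congestion multiplier; with probability
#' `p_slow` the trip is additionally inflated past 60 minutes (default
#' 0.21, the headline delay share).
#'
#' @param n Number of incidents.
#' @param mechanism_mix,blunt_split,pen_split,sex_mix,age_mix,region_mix
#'   Named probability vectors (normalized internally).
#' @param sbp_mean,sbp_sd,hr_mean,hr_sd Vitals model (mmHg, bpm); SBP is
#'   truncated at 60, HR at 30.
#' @param p_force_red Fraction of non-penetrating cases with SBP forced
#'   below the age-appropriate red threshold.
#' @param p_tc Probability of transport to the nearest level 1/2 center.
#' @param sigma Log-scale SD of the congestion multiplier.
#' @param p_slow Probability that the observed time is inflated beyond
#'   60 minutes.
#' @param seed Integer seed; fully determines the registry.
#' @return List of class `incident_params`.
#' @export
incident_params <- function(n = 20000,
                            mechanism_mix = c(BLUNT = 0.683, PENETRATING = 0.211,
                                              THERMAL = 0.019, OTHER = 0.087),
                            blunt_split = c(MVC = 0.701, FALL = 0.299),
                            pen_split = c(STAB = 0.5, GUNSHOT = 0.5),
                            sex_mix = c(MALE = 0.738, FEMALE = 0.254,
                                        MISSING = 0.008),
                            age_mix = c(ADULT = 0.879, ELDERLY = 0.108,
                                        MISSING = 0.012),
                            region_mix = c(EAST = 0.415, NORTH = 0.249,
                                           WEST = 0.127, SOUTH = 0.121,
                                           MIDDLE = 0.089),
                            sbp_mean = 125, sbp_sd = 15,
                            hr_mean = 85, hr_sd = 12,
                            p_force_red = 0.07,
                            p_tc = 0.668,
                            sigma = 0.35,
                            p_slow = 0.21,
                            seed = 1L) {
  norm1 <- function(p) p / sum(p)
  for (p in list(mechanism_mix, blunt_split, pen_split, sex_mix, age_mix,
                 region_mix)) {
    stopifnot(all(p >= 0), sum(p) > 0)
  }
  stopifnot(n >= 1, sbp_sd >= 0, hr_sd >= 0,
            p_force_red >= 0, p_force_red <= 1,
            p_tc >= 0, p_tc <= 1, sigma >= 0, p_slow >= 0, p_slow <= 1)
  structure(list(n = as.integer(n),
                 mechanism_mix = norm1(mechanism_mix),
                 blunt_split = norm1(blunt_split),
                 pen_split = norm1(pen_split),
                 sex_mix = norm1(sex_mix),
                 age_mix = norm1(age_mix),
                 region_mix = norm1(region_mix),
                 sbp_mean = sbp_mean, sbp_sd = sbp_sd,
                 hr_mean = hr_mean, hr_sd = hr_sd,
                 p_force_red = p_force_red, p_tc = p_tc,
                 sigma = sigma, p_slow = p_slow,
                 seed = as.integer(seed)),
            class = "incident_params")
}

# Truncated-normal draws via inverse CDF; sd = 0 degenerates to the mean.
rtruncnorm_low <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  p0 <- pnorm(lower, mean, sd)
  qnorm(runif(n, p0, 1), mean, sd)
}

sample_mix <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

#' Generate a synthetic incident registry
#'
#' Draws `n` prehospital incident records from the mixtures in `params`,
#' located at dispatch-center nodes (dispatch centers proxy incident
#' sites). Destinations follow the nearest-facility rule with
#' probability `p_tc` of reaching a level 1/2 center; observed travel
#' time is the free-flow network time from dispatch node to destination
#' node times a congestion multiplier, with a planted probability of
#' inflation past 60 minutes. Identical seeds yield identical
#' registries.
#'
#' @param city A [generate_city()] result.
#' @param params An [incident_params()] object.
#' @return Tibble of incident records (one row per case) with the
#'   registry schema plus a `network_travel_time` column.
#' @export
generate_incidents <- function(city, params = incident_params()) {
  stopifnot(inherits(city, "synthetic_city"), inherits(params, "incident_params"))
  set.seed(params$seed)
  n <- params$n
  disp <- city$dispatch
  fac <- city$facilities

  # free-flow minutes from every dispatch node to every facility node
  dmat <- igraph::distances(city$network$graph,
                            v = disp$node_id, to = fac$node_id, mode = "out")
  is_tc <- fac$level %in% c("LEVEL1", "LEVEL2")
  if (!any(is_tc)) stop("city has no LEVEL1/LEVEL2 facility", call. = FALSE)

  region <- sample_mix(n, params$region_mix)
  disp_idx <- integer(n)
  for (rg in names(params$region_mix)) {
    sel <- region == rg
    if (!any(sel)) next
    pool <- which(disp$region == rg)
    if (length(pool) == 0) pool <- seq_len(nrow(disp))
    disp_idx[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
  }

  category <- sample_mix(n, params$mechanism_mix)
  code <- character(n)
  code[category == "BLUNT"] <- sample_mix(sum(category == "BLUNT"),
                                          params$blunt_split)
  code[category == "PENETRATING"] <- sample_mix(sum(category == "PENETRATING"),
                                                params$pen_split)
  code[category == "THERMAL"] <- sample(c("FLAME_BURN", "SCALD", "FROSTBITE"),
                                        sum(category == "THERMAL"), replace = TRUE)
  code[category == "OTHER"] <- sample(c("DOMESTIC_VIOLENCE", "OTHER"),
                                      sum(category == "OTHER"),
                                      replace = TRUE, prob = c(0.3, 0.7))

  sex <- sample_mix(n, params$sex_mix)
  sex[sex == "MISSING"] <- NA
  age_grp <- sample_mix(n, params$age_mix)
  age <- rep(NA_real_, n)
  age[age_grp == "ADULT"] <- floor(runif(sum(age_grp == "ADULT"), 14, 65))
  age[age_grp == "ELDERLY"] <- floor(runif(sum(age_grp == "ELDERLY"), 65, 96))

  sbp <- rtruncnorm_low(n, params$sbp_mean, params$sbp_sd, 60)
  hr <- rtruncnorm_low(n, params$hr_mean, params$hr_sd, 30)
  force_red <- runif(n) < params$p_force_red & category != "PENETRATING"
  thr <- ifelse(!is.na(age) & age >= 65, 110, 90)
  sbp[force_red] <- runif(sum(force_red), 60, thr[force_red] - 1)

  to_tc <- runif(n) < params$p_tc
  tc_cols <- which(is_tc)
  other_cols <- which(!is_tc)
  nearest <- function(rows, cols) {
    if (length(cols) == 0) stop("no eligible destination facility", call. = FALSE)
    sub <- dmat[rows, cols, drop = FALSE]
    cols[max.col(-sub, ties.method = "first")]
  }
  dest_idx <- integer(n)
  dest_idx[to_tc] <- nearest(disp_idx[to_tc], tc_cols)
  if (any(!to_tc)) dest_idx[!to_tc] <- nearest(disp_idx[!to_tc], other_cols)
  net_min <- dmat[cbind(disp_idx, dest_idx)]

  observed <- net_min * exp(rnorm(n, 0, params$sigma))
  slow <- runif(n) < params$p_slow
  observed[slow] <- pmax(observed[slow], runif(sum(slow), 61, 120))

  t0 <- as.POSIXct("2021-01-01", tz = "UTC")
  t1 <- as.POSIXct("2023-03-31", tz = "UTC")
  ts <- t0 + runif(n) * as.numeric(difftime(t1, t0, units = "secs"))

  tibble(
    id = sprintf("I%06d", seq_len(n)),
    timestamp = format(ts, "%Y-%m-%dT%H:%M:%SZ"),
    dispatch_center_id = disp$id[disp_idx],
    region = disp$region[disp_idx],
    age = age,
    sex = sex,
    sbp = round(sbp),
    hr = round(hr),
    mechanism_code = code,
    trauma_flag = TRUE,
    outcome_recorded = TRUE,
    destination_facility_id = fac$id[dest_idx],
    observed_travel_time = round(observed, 2),
    network_travel_time = round(net_min, 2)
  )
}

#' Planted ground-truth rates for a synthetic city
#'
#' The expected red-criteria fraction, undertriage probability (among
#' red cases, default destination set) and delay probability (among red
#' cases transported to a level 1/2 center), estimated from an oversize
#' reference registry drawn with an independent seed and pushed through
#' the classification rules; plus the exact service band of every
#' dispatch center (deterministic, from the network). Used as the
#' recovery-test oracle.
#'
#' @param city A [generate_city()] result.
#' @param params An [incident_params()] object.
#' @param n_ref Reference-simulation size (default ten times `params$n`,
#'   capped at 200,000).
#' @return List of class `planted_truth` with `red_fraction`,
#'   `undertriage_prob`, `delay_prob`, `bands` and `n_ref`.
#' @export
planted_truth <- function(city, params, n_ref = NULL) {
  if (is.null(n_ref)) n_ref <- min(10L * params$n, 200000L)
  ref_params <- params
  ref_params$n <- as.integer(n_ref)
  ref_params$seed <- (params$seed + 999983L) %% .Machine$integer.max
  ref <- generate_incidents(city, ref_params)
  band_map <- assign_dispatch_bands(city$network, city$dispatch, city$facilities)
  assessed <- assess_records(ref, band_map, city$facilities)
  red <- assessed$triage_class == "RED"
  tr <- red & assessed$destination_level %in% c("LEVEL1", "LEVEL2")
  structure(list(
    red_fraction = mean(red),
    undertriage_prob = mean(assessed$undertriaged[red], na.rm = TRUE),
    delay_prob = mean(assessed$delayed[tr], na.rm = TRUE),
    bands = band_map,
    n_ref = n_ref
  ), class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf(paste0("<planted_truth> red fraction %.3f | undertriage %.3f | ",
                     "delay %.3f (reference n = %d)\n"),
              x$red_fraction, x$undertriage_prob, x$delay_prob, x$n_ref))
  invisible(x)
}
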