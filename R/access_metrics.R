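#' Delayed-transfer determination
#'
#' A transfer is delayed when the OBSERVED travel time (assignment to
#' hospital arrival, as recorded on the incident) to a level 1/2 trauma
#' center strictly exceeds the threshold (default 60 minutes, the golden
#' hour). Delay is defined only for transfers to level 1/2 centers;
#' everything else — including level 1/2 transfers with a missing
#' travel time — is not applicable and returns `NA`.
#'
#' @param destination_level Destination designation per record
#'   (`LEVEL1`, `LEVEL2`, `LEVEL3`, `NTC`, `MISSING`).
#' @param observed_minutes Observed travel time in minutes (`NA` allowed).
#' @param threshold Delay threshold in minutes (default 60).
#' @return Logical vector: `TRUE` delayed, `FALSE` on time, `NA` not
#'   applicable.
#' @export
is_delayed <- function(destination_level, observed_minutes,
                       threshold = DEFAULT_DELAY_THRESHOLD) {
  lvl12 <- as.character(destination_level) %in% c("LEVEL1", "LEVEL2")
  out <- rep(NA, length(lvl12))
  ok <- lvl12 & !is.na(observed_minutes)
  out[ok] <- observed_minutes[ok] > threshold
  out
}

#' Undertriage determination
#'
#' A red-criteria case is undertriaged when it was transported to a
#' facility below definitive trauma care although a level 1/2 trauma
#' center was theoretically reachable within 60 minutes (i.e. its
#' dispatch center's service band is not `BEYOND`). The destination set
#' counted as undertriage defaults to non-trauma centers only
#' (`{NTC}`, matching the headline accounting); `strict = TRUE` also
#' counts level 3 centers, implementing the wider written definition.
#' Undertriage is not applicable (`NA`) for non-red cases.
#'
#' @param triage_class `"RED"` / `"NOT_RED"` per record.
#' @param destination_level Destination designation per record.
#' @param band Service band of the record's dispatch center (from
#'   [assign_dispatch_bands()]); must be known for every RED record.
#' @param strict If `TRUE`, count level 3 destinations as undertriage too.
#' @return Logical vector: `TRUE` undertriaged, `FALSE` not, `NA` not
#'   applicable.
#' @export
is_undertriaged <- function(triage_class, destination_level, band,
                            strict = FALSE) {
  red <- as.character(triage_class) == "RED"
  if (any(red & is.na(band))) {
    stop("dispatch center of a RED record is missing from the service-band map",
         call. = FALSE)
  }
  dest_set <- if (strict) c("LEVEL3", "NTC") else "NTC"
  out <- rep(NA, length(red))
  reachable <- !is.na(band) & as.character(band) != "BEYOND"
  out[red] <- (as.character(destination_level) %in% dest_set & reachable)[red]
  out
}

#' Assess incident records against triage, delay and undertriage rules
#'
#' The per-record core of the pipeline: categorizes the mechanism,
#' applies the red-criteria classifier, resolves the destination
#' facility's designation and the dispatch center's service band, and
#' derives the delayed / undertriaged indicators.
#'
#' @param records Included incident registry tibble.
#' @param band_map Service-band map from [assign_dispatch_bands()].
#' @param facilities Facility roster tibble (`id`, `level`).
#' @param strict_undertriage Passed to [is_undertriaged()].
#' @param delay_threshold Passed to [is_delayed()].
#' @param missing_vitals Passed to [is_red_criteria()].
#' @return `records` with columns `category`, `subtype`, `triage_class`,
#'   `destination_level`, `band`, `delayed`, `undertriaged` appended.
#' @export
assess_records <- function(records, band_map, facilities,
                           strict_undertriage = FALSE,
                           delay_threshold = DEFAULT_DELAY_THRESHOLD,
                           missing_vitals = "not_red") {
  records <- as_tibble(records)
  mech <- classify_mechanism(records$mechanism_code)
  records$category <- mech$category
  records$subtype <- mech$subtype
  records$triage_class <- is_red_criteria(records$age, records$sbp, records$hr,
                                          mech$category,
                                          missing_vitals = missing_vitals)
  lvl <- facilities$level[match(records$destination_facility_id, facilities$id)]
  lvl[is.na(records$destination_facility_id) | is.na(lvl)] <- "MISSING"
  records$destination_level <- factor(as.character(lvl),
                                      levels = c(FACILITY_LEVELS, "MISSING"))
  records$band <- band_map$band[match(records$dispatch_center_id,
                                      band_map$dispatch_id)]
  records$delayed <- is_delayed(records$destination_level,
                                records$observed_travel_time,
                                threshold = delay_threshold)
  records$undertriaged <- is_undertriaged(records$triage_class,
                                          records$destination_level,
                                          records$band,
                                          strict = strict_undertriage)
  records
}

count_levels <- function(x, levels) {
  vapply(levels, function(l) sum(!is.na(x) & x == l), numeric(1))
}

#' Cohort composition table
#'
#' Counts and one-decimal percentages by sex, age group (14-64, >= 65,
#' missing), trauma category (with MVC and falls reported as shares of
#' blunt trauma), region and destination designation — for all included
#' cases and for the red-criteria subset.
#'
#' @param assessed Output of [assess_records()].
#' @return Tibble `section`, `level`, `n_all`, `pct_all`, `n_red`,
#'   `pct_red`. Percentages are of the column totals, except the MVC and
#'   fall rows, which are shares of blunt trauma.
#' @export
build_cohort_table <- function(assessed) {
  red <- assessed$triage_class == "RED"
  n_all <- nrow(assessed)
  n_red <- sum(red)

  age_group <- ifelse(is.na(assessed$age), "MISSING",
                      ifelse(assessed$age >= 65, "GE65", "14-64"))
  sex <- ifelse(is.na(assessed$sex), "MISSING", as.character(assessed$sex))

  section_rows <- function(section, values, levels, denom_all = n_all,
                           denom_red = n_red) {
    ca <- count_levels(values, levels)
    cr <- count_levels(values[red], levels)
    tibble(section = section, level = levels,
           n_all = unname(ca), pct_all = pct(ca, denom_all),
           n_red = unname(cr), pct_red = pct(cr, denom_red))
  }

  out <- bind_rows(
    tibble(section = "total", level = "N",
           n_all = n_all, pct_all = pct(n_all, n_all),
           n_red = n_red, pct_red = pct(n_red, n_all)),
    section_rows("sex", sex, SEX_LEVELS),
    section_rows("age_group", age_group, c("14-64", "GE65", "MISSING")),
    section_rows("mechanism", assessed$category, TRAUMA_CATEGORIES),
    # MVC / fall shares are of blunt-trauma counts, not of the cohort
    {
      blunt_all <- sum(assessed$category == "BLUNT")
      blunt_red <- sum(assessed$category[red] == "BLUNT")
      ca <- count_levels(assessed$subtype, c("MVC", "FALL"))
      cr <- count_levels(assessed$subtype[red], c("MVC", "FALL"))
      tibble(section = "mechanism_blunt", level = c("MVC", "FALL"),
             n_all = unname(ca), pct_all = pct(ca, blunt_all),
             n_red = unname(cr), pct_red = pct(cr, blunt_red))
    },
    section_rows("region", assessed$region, REGIONS),
    section_rows("destination", assessed$destination_level,
                 c(FACILITY_LEVELS, "MISSING"))
  )
  out
}

#' Region-by-band access table for red-criteria transfers
#'
#' Cross-tabulates red-criteria transfers to level 1/2 trauma centers by
#' region and service band, with delayed counts. Percentage conventions
#' follow the published-table layout: band rows are shares of the region
#' totals (transfers of region transfers, delayed of region delayed);
#' region total rows are shares of the citywide totals; the overall row
#' reports transfers as a share of all red-criteria cases and delays as a
#' share of transfers.
#'
#' @param assessed Output of [assess_records()].
#' @return Tibble `region`, `band`, `n`, `n_pct`, `delayed_n`,
#'   `delayed_pct`; `region = "OVERALL"` and `band = "TOTAL"` mark the
#'   margin rows.
#' @export
build_access_table <- function(assessed) {
  rc <- assessed[assessed$triage_class == "RED", , drop = FALSE]
  tr <- rc[rc$destination_level %in% c("LEVEL1", "LEVEL2"), , drop = FALSE]
  n_rc <- nrow(rc)
  n_tr <- nrow(tr)
  n_del <- sum(tr$delayed, na.rm = TRUE)

  overall <- tibble(region = "OVERALL", band = "TOTAL",
                    n = n_tr, n_pct = pct(n_tr, n_rc),
                    delayed_n = n_del, delayed_pct = pct(n_del, n_tr))

  regions_present <- REGIONS[REGIONS %in% unique(as.character(tr$region))]
  per_region <- lapply(regions_present, function(rg) {
    sub <- tr[tr$region == rg, , drop = FALSE]
    r_n <- nrow(sub)
    r_del <- sum(sub$delayed, na.rm = TRUE)
    total_row <- tibble(region = rg, band = "TOTAL",
                        n = r_n, n_pct = pct(r_n, n_tr),
                        delayed_n = r_del, delayed_pct = pct(r_del, n_del))
    bands <- levels(sub$band)
    bands <- bands[bands %in% unique(as.character(sub$band))]
    band_rows <- lapply(bands, function(b) {
      bb <- sub[as.character(sub$band) == b, , drop = FALSE]
      b_del <- sum(bb$delayed, na.rm = TRUE)
      tibble(region = rg, band = b,
             n = nrow(bb), n_pct = pct(nrow(bb), r_n),
             delayed_n = b_del, delayed_pct = pct(b_del, r_del))
    })
    bind_rows(total_row, bind_rows(band_rows))
  })
  bind_rows(overall, bind_rows(per_region))
}

#' Per-dispatch-center delay and undertriage table
#'
#' For every dispatch center: its region and service band, red-criteria
#' case count, the percentage of its red-criteria level 1/2 transfers
#' that were delayed, and the percentage of its red-criteria cases
#' diverted to a non-trauma center.
#'
#' @param assessed Output of [assess_records()].
#' @return Tibble `dispatch_id`, `region`, `band`, `rc_n`, `l12_n`,
#'   `delayed_n`, `delayed_pct`, `ntc_n`, `ntc_pct`, one row per dispatch
#'   center present in the data.
#' @export
build_dispatch_table <- function(assessed) {
  rc <- assessed[assessed$triage_class == "RED", , drop = FALSE]
  rc %>%
    group_by(dispatch_id = as.character(.data$dispatch_center_id)) %>%
    summarise(
      region = as.character(.data$region[1]),
      band = as.character(.data$band[1]),
      rc_n = n(),
      l12_n = sum(.data$destination_level %in% c("LEVEL1", "LEVEL2")),
      delayed_n = sum(.data$delayed, na.rm = TRUE),
      ntc_n = sum(.data$destination_level == "NTC"),
      .groups = "drop"
    ) %>%
    mutate(delayed_pct = pct(.data$delayed_n, .data$l12_n),
           ntc_pct = pct(.data$ntc_n, .data$rc_n)) %>%
    select("dispatch_id", "region", "band", "rc_n", "l12_n",
           "delayed_n", "delayed_pct", "ntc_n", "ntc_pct") %>%
    arrange(.data$dispatch_id)
}

#' Range of dispatch-center rates within each service band
#'
#' Minimum and maximum delayed and NTC-transfer percentages across the
#' dispatch centers of each band.
#'
#' @param dispatch_table Output of [build_dispatch_table()].
#' @return Tibble `band`, `delayed_min`, `delayed_max`, `ntc_min`,
#'   `ntc_max`.
#' @export
dispatch_band_range <- function(dispatch_table) {
  dispatch_table %>%
    filter(!is.na(.data$band)) %>%
    group_by(band = .data$band) %>%
    summarise(delayed_min = suppressWarnings(min(.data$delayed_pct, na.rm = TRUE)),
              delayed_max = suppressWarnings(max(.data$delayed_pct, na.rm = TRUE)),
              ntc_min = suppressWarnings(min(.data$ntc_pct, na.rm = TRUE)),
              ntc_max = suppressWarnings(max(.data$ntc_pct, na.rm = TRUE)),
              .groups = "drop") %>%
    mutate(across(c("delayed_min", "delayed_max", "ntc_min", "ntc_max"),
                  ~ ifelse(is.finite(.x), .x, NA_real_)))
}

#' Summary metrics for an assessed cohort
#'
#' Headline rates computed from an assessed registry: red-criteria
#' prevalence, share of red-criteria cases reaching a level 1/2 trauma
#' center, delay percentage among those transfers, and undertriage
#' percentage among red-criteria cases.
#'
#' @param assessed Output of [assess_records()].
#' @return Named list of counts and percentages.
#' @export
summarise_access <- function(assessed) {
  red <- assessed$triage_class == "RED"
  rc <- assessed[red, , drop = FALSE]
  tr <- rc$destination_level %in% c("LEVEL1", "LEVEL2")
  list(
    n = nrow(assessed),
    rc_n = nrow(rc),
    rc_pct = pct(nrow(rc), nrow(assessed)),
    rc_l12_n = sum(tr),
    rc_l12_pct = pct(sum(tr), nrow(rc)),
    rc_delayed_n = sum(rc$delayed[tr], na.rm = TRUE),
    rc_delayed_pct = pct(sum(rc$delayed[tr], na.rm = TRUE), sum(tr)),
    rc_undertriaged_n = sum(rc$undertriaged, na.rm = TRUE),
    rc_undertriaged_pct = pct(sum(rc$undertriaged, na.rm = TRUE), nrow(rc))
  )
}
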