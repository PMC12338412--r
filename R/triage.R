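# Mechanism-code vocabulary -> (category, subtype). Blunt covers motor
# vehicle collisions and falls; penetrating covers stab and gunshot
# wounds; thermal covers flame burns, scalds, frostbite and other heat or
# cold exposure; everything else (domestic violence, sexual offenses,
# miscellaneous) is OTHER.
MECHANISM_MAP <- data.frame(
  code = c("MVC", "FALL",
           "STAB", "GUNSHOT",
           "FLAME_BURN", "SCALD", "FROSTBITE", "HEAT_EXPOSURE", "COLD_EXPOSURE",
           "DOMESTIC_VIOLENCE", "SEXUAL_OFFENSE", "OTHER"),
  category = c("BLUNT", "BLUNT",
               "PENETRATING", "PENETRATING",
               "THERMAL", "THERMAL", "THERMAL", "THERMAL", "THERMAL",
               "OTHER", "OTHER", "OTHER"),
  subtype = c("MVC", "FALL",
              "STAB", "GUNSHOT",
              "BURN_OTHER", "BURN_OTHER", "BURN_OTHER", "BURN_OTHER", "BURN_OTHER",
              "MISC", "MISC", "MISC"),
  stringsAsFactors = FALSE
)

#' Classify a raw mechanism code into a trauma category
#'
#' Total, deterministic mapping from coded cause of injury into the four
#' major trauma categories (blunt, penetrating, thermal, other) and a
#' subtype. Codes outside the recognized vocabulary are absorbed into
#' `OTHER`/`MISC` with a warning.
#'
#' @param mechanism_code Character vector of raw mechanism codes.
#' @return Tibble with factor columns `category` and `subtype`, one row
#'   per input code.
#' @examples
#' classify_mechanism(c("MVC", "STAB", "SCALD"))
#' @export
classify_mechanism <- function(mechanism_code) {
  idx <- match(as.character(mechanism_code), MECHANISM_MAP$code)
  unknown <- unique(mechanism_code[is.na(idx) & !is.na(mechanism_code)])
  if (length(unknown) > 0) {
    warning("unrecognized mechanism code(s) mapped to OTHER/MISC: ",
            paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  cat_ <- ifelse(is.na(idx), "OTHER", MECHANISM_MAP$category[idx])
  sub_ <- ifelse(is.na(idx), "MISC", MECHANISM_MAP$subtype[idx])
  tibble(category = factor(cat_, levels = TRAUMA_CATEGORIES),
         subtype = factor(sub_, levels = TRAUMA_SUBTYPES))
}

#' Apply registry inclusion/exclusion filters
#'
#' Reproduces the cohort-selection flow for a prehospital registry:
#' records are kept when they have recorded outcome data, originate from
#' a dispatch region of interest, involve a patient aged 14 or older
#' (records with missing age are retained), and are trauma-related.
#' Excluded records are tallied under the FIRST failing reason in the
#' fixed order `missing_outcome -> outside_region -> pediatric ->
#' nontrauma`. Malformed rows (impossible vitals or negative ages/times)
#' are tallied separately and never enter the cohort.
#'
#' Because real-world exclusion categories can overlap, the tally also
#' carries overlap-tolerant counts (each record counted under every
#' reason it fails) in its `overlap` field.
#'
#' @param records Incident registry tibble (see [read_registry()] for the
#'   column schema).
#' @param regions Character vector of region labels considered inside the
#'   area of interest (default: the five city regions).
#' @return List with `included` (the filtered tibble) and `tally`
#'   (class `exclusion_tally`): counts `total`, `malformed`,
#'   `missing_outcome`, `outside_region`, `pediatric`, `nontrauma`,
#'   `included` and the `overlap` vector.
#' @export
apply_inclusion_filters <- function(records, regions = REGIONS) {
  records <- as_tibble(records)
  n <- nrow(records)
  num_or_na <- function(x) if (is.null(x)) rep(NA_real_, n) else as.numeric(x)
  age <- num_or_na(records$age)
  sbp <- num_or_na(records$sbp)
  hr <- num_or_na(records$hr)
  ott <- num_or_na(records$observed_travel_time)

  malformed <- (!is.na(age) & age < 0) | (!is.na(sbp) & sbp <= 0) |
    (!is.na(hr) & hr <= 0) | (!is.na(ott) & ott < 0)

  fail_outcome <- !isTRUE_vec(records$outcome_recorded)
  fail_region <- !(as.character(records$region) %in% regions)
  fail_pediatric <- !is.na(age) & age < 14
  fail_nontrauma <- !isTRUE_vec(records$trauma_flag)

  disposition <- rep("included", n)
  disposition[fail_nontrauma] <- "nontrauma"
  disposition[fail_pediatric] <- "pediatric"
  disposition[fail_region] <- "outside_region"
  disposition[fail_outcome] <- "missing_outcome"
  disposition[malformed] <- "malformed"

  tally <- structure(list(
    total = n,
    malformed = sum(disposition == "malformed"),
    missing_outcome = sum(disposition == "missing_outcome"),
    outside_region = sum(disposition == "outside_region"),
    pediatric = sum(disposition == "pediatric"),
    nontrauma = sum(disposition == "nontrauma"),
    included = sum(disposition == "included"),
    overlap = c(missing_outcome = sum(fail_outcome & !malformed),
                outside_region = sum(fail_region & !malformed),
                pediatric = sum(fail_pediatric & !malformed),
                nontrauma = sum(fail_nontrauma & !malformed))
  ), class = "exclusion_tally")

  list(included = records[disposition == "included", , drop = FALSE],
       tally = tally)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.exclusion_tally <- function(x, ...) {
  cat("<exclusion_tally> total:", x$total,
      "| included:", x$included,
      "| missing_outcome:", x$missing_outcome,
      "| outside_region:", x$outside_region,
      "| pediatric:", x$pediatric,
      "| nontrauma:", x$nontrauma,
      "| malformed:", x$malformed, "\n")
  invisible(x)
}

#' Field-triage red-criteria classifier
#'
#' The highest-acuity field triage class. A case is RED when any of the
#' following holds:
#' * penetrating mechanism, regardless of age and vitals;
#' * age 14-64 with systolic blood pressure below 90 mmHg, or heart rate
#'   strictly exceeding systolic blood pressure;
#' * age 65 and above with systolic blood pressure below 110 mmHg, or
#'   heart rate strictly exceeding systolic blood pressure.
#'
#' Records with missing age use the adult (14-64) thresholds. A
#' non-penetrating record with a missing vital cannot satisfy the
#' corresponding vitals criterion under the default policy
#' (`missing_vitals = "not_red"`); `missing_vitals = "red"` instead
#' escalates such records, as an upper-bound sensitivity analysis.
#'
#' @param age Age in years (`NA` allowed; values below 14 are rejected —
#'   pediatric cases must be excluded upstream).
#' @param sbp Systolic blood pressure in mmHg (`NA` allowed).
#' @param hr Heart rate in beats/min (`NA` allowed).
#' @param category Trauma category (from [classify_mechanism()]).
#' @param missing_vitals Policy for non-penetrating records with missing
#'   SBP or HR: `"not_red"` (default) or `"red"`.
#' @return Character vector of `"RED"` / `"NOT_RED"`.
#' @export
is_red_criteria <- function(age, sbp, hr, category,
                            missing_vitals = c("not_red", "red")) {
  missing_vitals <- match.arg(missing_vitals)
  if (any(!is.na(age) & age < 14)) {
    stop("age < 14: pediatric records must be excluded before triage",
         call. = FALSE)
  }
  category <- as.character(category)
  pen <- category == "PENETRATING"
  elderly <- !is.na(age) & age >= 65
  sbp_thr <- ifelse(elderly, 110, 90)
  sbp_red <- !is.na(sbp) & sbp < sbp_thr
  shock_red <- !is.na(sbp) & !is.na(hr) & hr > sbp
  red <- pen | sbp_red | shock_red
  if (missing_vitals == "red") {
    red <- red | (!pen & (is.na(sbp) | is.na(hr)))
  }
  ifelse(red, "RED", "NOT_RED")
}
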