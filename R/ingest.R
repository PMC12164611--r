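#' Cardiometabolic outcome panel
#'
#' The ten outcomes the pipeline models, in canonical reporting order,
#' with the transform applied before regression (natural log for
#' right-skewed markers, identity for z-scores and blood pressures).
#'
#' @return Tibble with columns `name` (column name in the participant
#'   table), `transform` (`"log"` or `"identity"`), `label` and `units`.
#' @export
outcome_specs <- function() {
  tibble::tribble(
    ~name,      ~transform,  ~label,                        ~units,
    "bmi",      "log",       "Log BMI",                     "kg/m2",
    "bmi_z",    "identity",  "BMI z-score",                 "z",
    "glucose",  "log",       "Log fasting glucose",         "mmol/l",
    "insulin",  "log",       "Log insulin",                 "pmol/l",
    "hdl",      "log",       "Log HDL-C",                   "mmol/l",
    "ldl",      "log",       "Log LDL-C",                   "mmol/l",
    "trig",     "log",       "Log fasting triglycerides",   "mmol/l",
    "sbp",      "identity",  "Systolic blood pressure",     "mmHg",
    "dbp",      "identity",  "Diastolic blood pressure",    "mmHg",
    "waist",    "log",       "Log waist circumference",     "cm"
  )
}

#' Valid-day and cohort filter settings
#'
#' @param min_wear_minutes Minimum accelerometer wear per day for a day to
#'   count as valid (default 600 min = 10 h).
#' @param min_valid_days Minimum number of valid days per participant
#'   (default 3).
#' @param sleep_bounds Plausibility bounds on self-reported sleep, minutes
#'   (default 240-960).
#' @param require_outcomes Character vector of outcome columns that must be
#'   non-missing for a participant to enter the cohort (default none;
#'   individual models always use complete cases for their own outcome).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_wear_minutes = 600, min_valid_days = 3,
                          sleep_bounds = c(240, 960),
                          require_outcomes = character()) {
  stopifnot(min_valid_days >= 1, length(sleep_bounds) == 2L,
            sleep_bounds[1] <= sleep_bounds[2])
  structure(list(min_wear_minutes = min_wear_minutes,
                 min_valid_days = as.integer(min_valid_days),
                 sleep_bounds = sleep_bounds,
                 require_outcomes = require_outcomes),
            class = "filter_config")
}

daily_cols <- function() {
  c("participant_id", "day_index", "wear_minutes",
    "sed", "lpa", "mpa", "vpa", "sleep", "month")
}

#' Read per-day movement records
#'
#' Expects a CSV with columns `participant_id`, `day_index`,
#' `wear_minutes`, `sed`, `lpa`, `mpa`, `vpa`, `sleep`, `month` (all
#' minutes except the id, day index and month).
#'
#' @param path CSV file path.
#' @return Tibble of daily records.
#' @export
read_daily_records <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(daily_cols(), names(x))
  if (length(missing)) {
    stop("daily records file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Read per-participant demographics and outcomes
#'
#' Expects a CSV with `participant_id`, `sex` (`male`/`female`), `age`
#' (years), `ethnicity`, and one column per outcome in [outcome_specs()]
#' (missing values allowed).
#'
#' @param path CSV file path.
#' @return Tibble of participant information.
#' @export
read_participant_info <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("participant_id", "sex", "age", "ethnicity"), names(x))
  if (length(missing)) {
    stop("participant file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Filter daily records to valid days
#'
#' A day is retained when its wear time meets the threshold, its sleep
#' lies within the plausibility bounds, and all minute fields are present
#' and non-negative. Malformed rows are logged, never fatal.
#'
#' @param days Tibble of daily records (see [read_daily_records()]).
#' @param cfg A [filter_config()].
#' @return List with `days` (retained rows) and `exclusions` (tibble of
#'   `participant_id`, `day_index`, `reason` with reasons `"malformed"`,
#'   `"wear_time"`, `"sleep_bounds"`).
#' @export
filter_valid_days <- function(days, cfg = filter_config()) {
  num <- c("wear_minutes", "sed", "lpa", "mpa", "vpa", "sleep")
  vals <- as.matrix(days[, num])
  malformed <- rowSums(!is.finite(vals) | vals < 0) > 0 |
    rowSums(vals[, c("sed", "lpa", "mpa", "vpa"), drop = FALSE],
            na.rm = TRUE) <= 0
  wear_fail <- !malformed & vals[, "wear_minutes"] < cfg$min_wear_minutes
  sleep_fail <- !malformed & !wear_fail &
    (vals[, "sleep"] < cfg$sleep_bounds[1] | vals[, "sleep"] > cfg$sleep_bounds[2])
  reason <- rep(NA_character_, nrow(days))
  reason[malformed] <- "malformed"
  reason[wear_fail] <- "wear_time"
  reason[sleep_fail] <- "sleep_bounds"
  keep <- is.na(reason)
  exclusions <- tibble::tibble(
    participant_id = days$participant_id[!keep],
    day_index = days$day_index[!keep],
    reason = reason[!keep]
  )
  list(days = days[keep, , drop = FALSE], exclusions = exclusions)
}

# Per-participant means of the behaviour columns plus valid-day count and
# modal monitoring month (ties broken by the earliest month). rowsum() keeps
# this linear in the number of day rows.
aggregate_days <- function(days) {
  ids <- factor(days$participant_id)
  cols <- c("sed", "lpa", "mpa", "vpa", "sleep")
  sums <- rowsum(as.matrix(days[, cols]), ids)
  nvd <- as.integer(table(ids))
  means <- sums / nvd
  mtab <- table(ids, factor(days$month, levels = sort(unique(days$month))))
  month <- as.integer(colnames(mtab))[max.col(mtab, ties.method = "first")]
  tibble::tibble(participant_id = levels(ids), n_valid_days = nvd,
                 sed = means[, "sed"], lpa = means[, "lpa"],
                 mpa = means[, "mpa"], vpa = means[, "vpa"],
                 sleep = means[, "sleep"], month = month)
}

#' Assemble analysis-ready participant records
#'
#' Averages each participant's behaviour minutes over their valid days,
#' proportionally rescales the four waking behaviours to fill
#' `1440 - mean sleep` (wear time rarely tiles the full day), replaces
#' zeros, and closes to 1440 minutes. Participants with too few valid days
#' or missing required outcomes are excluded with a reason.
#'
#' @param days Tibble of daily records, already filtered by
#'   [filter_valid_days()].
#' @param info Tibble of participant demographics and outcomes.
#' @param cfg A [filter_config()].
#' @param zero_floor Minutes used by [zero_replace()] before closure.
#' @return List with `records` (one row per retained participant: id,
#'   demographics, `n_valid_days`, `month`, closed `SED`/`LPA`/`MPA`/
#'   `VPA`/`Sleep` minutes, outcomes), `excluded` (id + reason), and
#'   `flow` (named counts: input, retained, and per-reason exclusions).
#' @export
assemble_participants <- function(days, info, cfg = filter_config(),
                                  zero_floor = 0.5) {
  agg <- aggregate_days(days)
  merged <- dplyr::left_join(info, agg, by = "participant_id")

  too_few <- is.na(merged$n_valid_days) | merged$n_valid_days < cfg$min_valid_days
  missing_outcome <- rep(FALSE, nrow(merged))
  for (oc in cfg$require_outcomes) {
    if (!oc %in% names(merged)) {
      stop("required outcome column not present: ", oc, call. = FALSE)
    }
    missing_outcome <- missing_outcome | is.na(merged[[oc]])
  }
  reason <- dplyr::case_when(too_few ~ "too_few_days",
                             missing_outcome ~ "missing_outcome",
                             TRUE ~ NA_character_)
  keep <- is.na(reason)
  excluded <- tibble::tibble(participant_id = merged$participant_id[!keep],
                             reason = reason[!keep])
  kept <- merged[keep, , drop = FALSE]

  if (nrow(kept) > 0L) {
    waking <- as.matrix(kept[, c("sed", "lpa", "mpa", "vpa")])
    scale <- (1440 - kept$sleep) / rowSums(waking)
    comp <- cbind(waking * scale, Sleep = kept$sleep)
    colnames(comp) <- movement_parts()
    comp <- zero_replace(comp, strategy = "fixed_floor", floor = zero_floor)
    comp <- close_composition(comp, total = 1440)
  } else {
    comp <- matrix(numeric(0), ncol = 5L,
                   dimnames = list(NULL, movement_parts()))
  }

  records <- dplyr::bind_cols(
    kept[, setdiff(names(kept), c("sed", "lpa", "mpa", "vpa", "sleep"))],
    tibble::as_tibble(comp)
  )
  reasons <- table(factor(reason, levels = c("too_few_days", "missing_outcome")))
  flow <- c(list(input = nrow(merged), retained = nrow(records)),
            as.list(reasons))
  list(records = records, excluded = excluded, flow = flow)
}

#' Run the full ingestion stage
#'
#' Convenience wrapper: valid-day filtering followed by participant
#' assembly, returning records plus a combined flow summary.
#'
#' @param days,info,cfg,zero_floor As in [filter_valid_days()] and
#'   [assemble_participants()].
#' @return List with `records`, `day_exclusions`, `excluded` and `flow`.
#' @export
ingest_cohort <- function(days, info, cfg = filter_config(), zero_floor = 0.5) {
  fd <- filter_valid_days(days, cfg)
  asm <- assemble_participants(fd$days, info, cfg, zero_floor = zero_floor)
  day_reasons <- table(factor(fd$exclusions$reason,
                              levels = c("malformed", "wear_time", "sleep_bounds")))
  flow <- c(asm$flow,
            stats::setNames(as.list(day_reasons),
                            paste0("days_", names(day_reasons))))
  list(records = asm$records, day_exclusions = fd$exclusions,
       excluded = asm$excluded, flow = flow)
}
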