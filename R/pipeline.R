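default_pipeline_config <- function() {
  list(
    daily_csv = NULL,
    participants_csv = NULL,
    output_dir = "movecoda-output",
    filter = list(min_wear_minutes = 600, min_valid_days = 3,
                  sleep_bounds = c(240, 960), require_outcomes = character()),
    outcomes = outcome_specs()$name,
    covariates = default_covariates(),
    delta = 10,
    stratify = "by_sex",
    d_method = "raw",
    r_squared = "increment",
    pct_method = "exact",
    seed = 1
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (is.null(cfg$daily_csv) || is.null(cfg$participants_csv)) {
    stop("config must name daily_csv and participants_csv", call. = FALSE)
  }
  cfg
}

write_table <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_csv(tibble::as_tibble(x), path)
  path
}

matrix_to_tibble <- function(m, rowlab = "part") {
  out <- tibble::as_tibble(m)
  dplyr::mutate(out, !!rowlab := rownames(m), .before = 1)
}

#' Run the full analysis pipeline
#'
#' Reads daily-movement and participant CSVs, filters and assembles the
#' cohort, and emits the standard report set into `output_dir`:
#' `table1.csv` (covariate-adjusted sex comparisons with Cohen's d),
#' `table2.csv` (movement summary), `table3.csv` (log-ratio variation
#' matrix), `table4.csv` (compositional ILR models),
#' `table5_<outcome>_<sex>.csv` plus `_flags` companions (isotemporal
#' change matrices flagged against the smallest worthwhile change),
#' `flow.json` (participant flow) and `models.json` (full model detail
#' with CIs). Identical inputs, config and seed give identical outputs.
#'
#' @param config Path to a YAML config or an equivalent named list.
#'   Required keys `daily_csv`, `participants_csv`; everything else has
#'   documented defaults (wear/valid-day filter, outcome list, covariates,
#'   reallocation delta, sex stratification).
#' @return Invisibly, a list with `records`, `flow`, `tables` (paths),
#'   `fits`, and `change_matrices`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  days <- read_daily_records(cfg$daily_csv)
  info <- read_participant_info(cfg$participants_csv)
  fcfg <- filter_config(cfg$filter$min_wear_minutes, cfg$filter$min_valid_days,
                        cfg$filter$sleep_bounds,
                        cfg$filter$require_outcomes %||% character())
  ing <- ingest_cohort(days, info, fcfg)
  rec <- ing$records
  if (nrow(rec) == 0L) stop("no_valid_participants", call. = FALSE)
  outcomes <- intersect(cfg$outcomes, names(rec))

  paths <- list()
  jsonlite::write_json(ing$flow, file.path(cfg$output_dir, "flow.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$flow <- file.path(cfg$output_dir, "flow.json")
  write_table(ing$excluded, cfg$output_dir, "excluded_participants.csv")
  write_table(ing$day_exclusions, cfg$output_dir, "excluded_days.csv")

  tab1 <- dplyr::bind_rows(lapply(outcomes, function(oc) {
    ancova_sex_comparison(rec, oc, covariates = intersect(
      c("age", "ethnicity"), cfg$covariates), d_method = cfg$d_method)
  }))
  paths$table1 <- write_table(tab1, cfg$output_dir, "table1.csv")
  paths$table2 <- write_table(movement_summary(rec), cfg$output_dir, "table2.csv")
  vm <- variation_matrix(as.matrix(rec[, movement_parts()]))
  paths$table3 <- write_table(matrix_to_tibble(vm), cfg$output_dir, "table3.csv")

  fits <- lapply(outcomes, function(oc) {
    fit_compositional_model(rec, oc, covariates = cfg$covariates,
                            r_squared = cfg$r_squared)
  })
  names(fits) <- outcomes
  summ <- summarize_models(fits)
  paths$table4 <- write_table(summ$table, cfg$output_dir, "table4.csv")

  strata <- if (identical(cfg$stratify, "by_sex")) c("male", "female") else "pooled"
  cms <- list()
  for (s in strata) {
    sub <- if (s == "pooled") rec else rec[rec$sex == s, , drop = FALSE]
    reference <- geometric_mean_composition(as.matrix(sub[, movement_parts()]))
    for (oc in outcomes) {
      fit_s <- if (s == "pooled") fits[[oc]] else
        fit_compositional_model(sub, oc,
                                covariates = setdiff(cfg$covariates, "sex"),
                                r_squared = cfg$r_squared)
      swc <- compute_swc(sub, oc, by_sex = FALSE)
      cm <- change_matrix(fit_s, reference, swc = swc$swc, delta = cfg$delta,
                          method = cfg$pct_method)
      key <- paste0("table5_", oc, "_", s)
      paths[[key]] <- write_table(matrix_to_tibble(cm$pct, "receiver"),
                                  cfg$output_dir, paste0(key, ".csv"))
      write_table(matrix_to_tibble(cm$flags, "receiver"),
                  cfg$output_dir, paste0(key, "_flags.csv"))
      cms[[paste(oc, s, sep = "_")]] <- cm
    }
  }

  models_json <- lapply(fits, function(f) {
    list(outcome = f$outcome, label = f$label, transform = f$transform,
         n = f$n, model_p = f$model_p, r_squared = f$r_squared,
         r_squared_total = f$r_squared_total,
         behaviours = f$behaviours, residual_sd = f$residual_sd)
  })
  jsonlite::write_json(
    list(models = models_json, r_squared_range = summ$r_squared_range),
    file.path(cfg$output_dir, "models.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  paths$models <- file.path(cfg$output_dir, "models.json")

  invisible(list(records = rec, flow = ing$flow, tables = paths,
                 fits = fits, change_matrices = cms))
}

#' Run the synthetic-validation suite
#'
#' Generates cohorts from a [generator_config()], runs the full pipeline
#' through [recovery_report()], and writes `recovery_report.json`
#' (coverage, bias, RMSE per behaviour, change-matrix discrepancy).
#'
#' @param config Path to a YAML config or a named list with optional keys
#'   `n_per_sex`, `outcome`, `n_replicates`, `seed`, `output_dir`, and
#'   failure thresholds `max_abs_bias_pct`, `coverage_bounds`.
#' @return Invisibly, the recovery report; errors if a failure threshold
#'   is breached.
#' @export
run_validation <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(n_per_sex = 2000, outcome = "bmi", n_replicates = 200,
                   seed = 1, output_dir = "movecoda-output",
                   max_abs_bias_pct = 2, coverage_bounds = c(0.93, 0.97))
  cfg <- utils::modifyList(defaults, config)
  gcfg <- generator_config(n_per_sex = c(male = cfg$n_per_sex,
                                         female = cfg$n_per_sex))
  rep <- recovery_report(gcfg, outcome = cfg$outcome,
                         n_replicates = cfg$n_replicates, seed = cfg$seed)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(coefficients = rep$coefficients,
         change_discrepancy_max = max(rep$change_discrepancy),
         change_discrepancy_mean = mean(rep$change_discrepancy),
         n_replicates = rep$n_replicates),
    file.path(cfg$output_dir, "recovery_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  ok_bias <- all(abs(rep$coefficients$bias_pct) <= cfg$max_abs_bias_pct)
  ok_cov <- all(rep$coefficients$coverage >= cfg$coverage_bounds[1] &
                  rep$coefficients$coverage <= cfg$coverage_bounds[2])
  if (!ok_bias || !ok_cov) {
    stop("validation thresholds breached: ",
         if (!ok_bias) "bias " else "", if (!ok_cov) "coverage" else "",
         call. = FALSE)
  }
  invisible(rep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
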