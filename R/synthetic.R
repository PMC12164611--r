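#' Default planted outcome models for the synthetic cohort
#'
#' One entry per outcome in [outcome_specs()]: intercept (model scale, at
#' the reference covariate profile), four planted ILR coefficients in the
#' canonical SED-first pivot basis, additive female and per-year age
#' effects, residual SD on the model scale, and a missing-at-random rate.
#' Mean levels and spreads are set to plausible paediatric cohort values;
#' the ILR coefficients are modest effects with adiposity markers loading
#' negatively on vigorous activity. These are documented defaults, not
#' estimates fitted to any dataset.
#'
#' @return Named list of outcome model definitions.
#' @export
default_outcome_models <- function() {
  om <- function(transform, intercept, beta, sex_female, age, noise_sd,
                 missing_rate) {
    list(transform = transform, intercept = intercept, beta = beta,
         sex_female = sex_female, age = age, noise_sd = noise_sd,
         missing_rate = missing_rate)
  }
  list(
    bmi     = om("log", log(18.6), c(0.05, 0.00, -0.02, -0.05), 0.02, 0.010, 0.16, 0.00),
    bmi_z   = om("identity", 0, c(0.30, 0.05, -0.10, -0.30), 0.10, 0.000, 0.95, 0.00),
    glucose = om("log", log(5.05), c(0.010, 0.010, -0.005, 0.002), -0.02, 0.002, 0.075, 0.73),
    insulin = om("log", log(50), c(0.08, 0.05, -0.05, -0.03), 0.17, 0.050, 0.50, 0.73),
    hdl     = om("log", log(1.45), c(-0.02, -0.01, 0.01, 0.02), -0.05, -0.005, 0.20, 0.41),
    ldl     = om("log", log(2.4), c(-0.03, -0.02, 0.00, -0.01), 0.08, -0.010, 0.24, 0.41),
    trig    = om("log", log(0.9), c(0.08, 0.06, -0.01, 0.00), 0.10, 0.010, 0.45, 0.42),
    sbp     = om("identity", 105, c(2.0, 1.5, -1.5, -0.5), 0.0, 1.2, 11.0, 0.20),
    dbp     = om("identity", 59, c(0.5, -1.0, -1.0, -0.2), 1.0, 0.5, 6.8, 0.20),
    waist   = om("log", log(65.5), c(0.04, 0.01, 0.01, -0.03), -0.02, 0.020, 0.12, 0.00)
  )
}

#' Synthetic cohort generator configuration
#'
#' Defines the generative model: sex-specific compositional centres
#' (defaults are typical boys'/girls' geometric-mean 24-hour compositions
#' for this age group), a logistic-normal spread around them (Gaussian in
#' ILR space, canonical SED-first pivot basis), planted linear outcome
#' models, and day-level parameters controlling how each participant's
#' composition is split into noisy monitored days.
#'
#' @param n_per_sex Named integer vector `c(male =, female =)`.
#' @param mean_composition Named list per sex of 5-part compositions in
#'   minutes (closed to 1440 internally).
#' @param ilr_sd Marginal SDs of the four ILR coordinates (used to build a
#'   diagonal covariance when `ilr_covariance` is NULL).
#' @param ilr_covariance Optional list per sex of 4x4 positive-definite
#'   covariance matrices.
#' @param outcome_models Planted outcome models, see
#'   [default_outcome_models()].
#' @param day List of day-level parameters: `n_days_range` and
#'   `n_days_probs` (distribution of monitored days), `wear_mean` and
#'   `wear_sd` (minutes), `invalid_day_rate` (probability a day is planted
#'   to fail the wear criterion), `jitter_sd` (log-scale day-to-day jitter
#'   of waking behaviours), `sleep_day_sd` (minutes).
#' @param wear_threshold Wear-time validity threshold the generator uses
#'   for its bookkeeping of which days are valid (minutes).
#' @param n_invalid_participants Number of participants planted to fail
#'   entirely (every day below the wear threshold).
#' @param n_missing_outcome Number of additional participants planted
#'   with a missing `missing_outcome` value.
#' @param missing_outcome Outcome column used for planted missingness.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_per_sex = c(male = 4613, female = 5325),
                             mean_composition = list(
                               male = c(SED = 342.1, LPA = 350.7, MPA = 40.5,
                                        VPA = 14.0, Sleep = 692.7),
                               female = c(SED = 365.8, LPA = 348.5, MPA = 30.2,
                                          VPA = 11.5, Sleep = 681.1)),
                             ilr_sd = c(0.18, 0.18, 0.40, 0.55),
                             ilr_covariance = NULL,
                             outcome_models = default_outcome_models(),
                             day = list(),
                             wear_threshold = 600,
                             n_invalid_participants = 0,
                             n_missing_outcome = 0,
                             missing_outcome = "bmi") {
  stopifnot(all(c("male", "female") %in% names(n_per_sex)),
            all(n_per_sex >= 0))
  if (is.null(ilr_covariance)) {
    ilr_covariance <- list(male = diag(ilr_sd^2), female = diag(ilr_sd^2))
  }
  for (s in c("male", "female")) {
    ev <- eigen(ilr_covariance[[s]], symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("ILR covariance for ", s, " is not positive-definite",
                           call. = FALSE)
  }
  day_defaults <- list(n_days_range = 3:8,
                       n_days_probs = c(0.05, 0.15, 0.25, 0.30, 0.15, 0.10),
                       wear_mean = 792, wear_sd = 102,
                       invalid_day_rate = 0.03,
                       jitter_sd = 0.08, sleep_day_sd = 20)
  day <- utils::modifyList(day_defaults, day)
  structure(list(n_per_sex = n_per_sex,
                 mean_composition = lapply(mean_composition, close_composition),
                 ilr_covariance = ilr_covariance,
                 outcome_models = outcome_models,
                 day = day,
                 wear_threshold = wear_threshold,
                 n_invalid_participants = n_invalid_participants,
                 n_missing_outcome = n_missing_outcome,
                 missing_outcome = missing_outcome),
            class = "generator_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw participant-level compositions (logistic-normal around the sex
# centre) and covariates. Returns a tibble plus the canonical basis used.
draw_participants <- function(cfg) {
  basis <- pivot_basis(movement_parts()[1])
  per_sex <- lapply(c("male", "female"), function(s) {
    n <- cfg$n_per_sex[[s]]
    if (n == 0L) return(NULL)
    mu <- ilr_transform(cfg$mean_composition[[s]], basis)
    z <- MASS::mvrnorm(n, mu = mu, Sigma = cfg$ilr_covariance[[s]])
    if (n == 1L) z <- matrix(z, nrow = 1L)
    comp <- ilr_inverse(z, basis, total = 1440)
    tibble::tibble(
      sex = s,
      age = clamp(stats::rnorm(n, 11.4, 1.75), 6, 18),
      ethnicity = sample(c("White", "Black", "Asian", "NotReported"), n,
                         replace = TRUE, prob = c(0.850, 0.003, 0.008, 0.139)),
      month = sample(1:12, n, replace = TRUE),
      !!!tibble::as_tibble(comp)
    )
  })
  out <- dplyr::bind_rows(per_sex)
  out$participant_id <- sprintf("P%06d", seq_len(nrow(out)))
  list(participants = dplyr::relocate(out, "participant_id"), basis = basis)
}

#' Generate a synthetic cohort
#'
#' Draws participant compositions from the sex-specific logistic-normal
#' model, splits each into noisy monitored days (multiplicative jitter of
#' the waking behaviours within drawn wear time, Gaussian jitter of
#' sleep), plants invalid days and participant-level exclusions as
#' configured, and generates outcomes as linear models on the ILR
#' coordinates of the participant's analysis composition (the composition
#' the ingestion stage recovers from the valid days) plus covariate
#' effects and Gaussian noise. Everything planted is recorded in the
#' returned ground truth, which the pipeline under test never reads.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return List with `daily` (day-level records in the ingestion schema),
#'   `participants` (demographics + outcomes), and `ground_truth` (planted
#'   coefficients, basis, per-participant true ILR coordinates, planted
#'   exclusion ids, planted missingness).
#' @export
generate_cohort <- function(cfg = generator_config(), seed = 1) {
  set.seed(seed)
  dp <- draw_participants(cfg)
  pt <- dp$participants
  basis <- dp$basis
  n <- nrow(pt)
  comp_latent <- as.matrix(pt[, movement_parts()])

  # plant participant-level failures
  planted_invalid <- planted_missing <- character()
  n_plant <- cfg$n_invalid_participants + cfg$n_missing_outcome
  if (n_plant > 0L) {
    if (n_plant > n) stop("more planted failures than participants", call. = FALSE)
    picked <- sample(pt$participant_id, n_plant)
    planted_invalid <- utils::head(picked, cfg$n_invalid_participants)
    planted_missing <- utils::tail(picked, cfg$n_missing_outcome)
  }

  # day-level expansion
  d <- cfg$day
  n_days <- sample(d$n_days_range, n, replace = TRUE, prob = d$n_days_probs)
  idx <- rep(seq_len(n), n_days)
  nd_tot <- length(idx)
  day_index <- sequence(n_days)
  invalid_day <- stats::runif(nd_tot) < d$invalid_day_rate
  invalid_day[pt$participant_id[idx] %in% planted_invalid] <- TRUE
  wear <- ifelse(invalid_day,
                 stats::runif(nd_tot, 200, cfg$wear_threshold - 10),
                 clamp(stats::rnorm(nd_tot, d$wear_mean, d$wear_sd),
                       cfg$wear_threshold + 10, 1100))
  sleep_day <- clamp(comp_latent[idx, "Sleep"] +
                       stats::rnorm(nd_tot, 0, d$sleep_day_sd), 250, 950)
  waking <- comp_latent[idx, c("SED", "LPA", "MPA", "VPA"), drop = FALSE] *
    exp(matrix(stats::rnorm(nd_tot * 4L, 0, d$jitter_sd), ncol = 4L))
  waking <- waking / rowSums(waking) * wear
  daily <- tibble::tibble(
    participant_id = pt$participant_id[idx],
    day_index = day_index,
    wear_minutes = wear,
    sed = waking[, 1], lpa = waking[, 2], mpa = waking[, 3], vpa = waking[, 4],
    sleep = sleep_day,
    month = pt$month[idx]
  )

  # analysis composition: what ingestion will recover from the valid days;
  # fall back to the latent composition when no day is valid
  valid <- daily[wear >= cfg$wear_threshold, , drop = FALSE]
  vid <- factor(valid$participant_id)
  sums <- rowsum(as.matrix(valid[, c("sed", "lpa", "mpa", "vpa", "sleep")]), vid)
  vmeans <- sums / as.integer(table(vid))
  comp_obs <- comp_latent
  pos <- match(levels(vid), pt$participant_id)
  wk <- vmeans[, c("sed", "lpa", "mpa", "vpa"), drop = FALSE]
  wk <- wk * (1440 - vmeans[, "sleep"]) / rowSums(wk)
  comp_obs[pos, ] <- close_composition(
    zero_replace(cbind(wk, Sleep = vmeans[, "sleep"])), total = 1440)
  z_obs <- ilr_transform(comp_obs, basis)

  # outcomes: planted linear models on the ILR coordinates
  female <- pt$sex == "female"
  age_c <- pt$age - 11.4
  truth_missing <- list()
  for (oc in names(cfg$outcome_models)) {
    m <- cfg$outcome_models[[oc]]
    eta <- m$intercept + drop(z_obs %*% m$beta) +
      m$sex_female * female + m$age * age_c +
      stats::rnorm(n, 0, m$noise_sd)
    y <- if (m$transform == "log") exp(eta) else eta
    miss <- stats::runif(n) < m$missing_rate
    y[miss] <- NA_real_
    if (oc == cfg$missing_outcome && length(planted_missing)) {
      y[pt$participant_id %in% planted_missing] <- NA_real_
    }
    pt[[oc]] <- y
    truth_missing[[oc]] <- sum(miss)
  }

  participants <- pt[, c("participant_id", "sex", "age", "ethnicity",
                         names(cfg$outcome_models))]
  ground_truth <- list(
    config = cfg,
    basis = basis,
    beta = lapply(cfg$outcome_models, `[[`, "beta"),
    ilr_observed = z_obs,
    composition_observed = comp_obs,
    planted_invalid_participants = planted_invalid,
    planted_missing_participants = planted_missing,
    n_missing_random = truth_missing,
    n_invalid_days = sum(invalid_day)
  )
  list(daily = daily, participants = participants, ground_truth = ground_truth)
}

#' Wrap planted parameters as a model object
#'
#' Builds a minimal `outcome_model_fit` from known coefficients so the
#' analytic change matrix implied by planted parameters can be computed
#' with the same [change_matrix()] code path operating on fitted models.
#'
#' @param beta_ilr Length-4 coefficient vector in `basis` coordinates.
#' @param transform `"identity"` or `"log"`.
#' @param outcome_mean Raw-scale mean outcome for percentage scaling.
#' @param basis ILR basis of `beta_ilr` (default canonical SED-first).
#' @param outcome Label.
#' @return An `outcome_model_fit`-classed list usable by
#'   [predict_change()] and [change_matrix()].
#' @export
manual_model <- function(beta_ilr, transform = "identity", outcome_mean = 1,
                         basis = pivot_basis(movement_parts()[1]),
                         outcome = "manual") {
  clr <- drop(t(basis$contrast) %*% beta_ilr)
  names(clr) <- basis$part_order
  structure(list(outcome = outcome, label = outcome, transform = transform,
                 basis = basis, ilr_coefficients = beta_ilr,
                 clr_coefficients = clr[movement_parts()],
                 outcome_mean = outcome_mean),
            class = "outcome_model_fit")
}

# True pivot coefficient of behaviour b implied by planted beta (given in
# `basis` coordinates): rotate the CLR coefficient vector into the pivot
# basis of b and take the first coordinate.
true_pivot_coefficients <- function(beta, basis) {
  clr <- drop(t(basis$contrast) %*% beta)
  names(clr) <- basis$part_order
  vapply(movement_parts(), function(b) {
    bb <- pivot_basis(b)
    sum(bb$contrast[1, ] * clr[bb$part_order])
  }, numeric(1))
}

#' Monte-Carlo parameter-recovery study
#'
#' Repeatedly generates a cohort, runs the full pipeline (ingestion,
#' compositional model fit, change matrix), and compares the recovered
#' per-behaviour pivot coefficients with the values implied by the
#' planted coefficients: bias (absolute and as % of the true magnitude),
#' RMSE, and empirical coverage of the 95% CIs. Also reports the maximum
#' absolute discrepancy between the pipeline's change matrix and the
#' analytic change matrix implied by the planted coefficients (absolute
#' outcome units), evaluated at the generator's male centre composition.
#'
#' @param cfg A [generator_config()] (use moderate `n_per_sex` — the cost
#'   is `n_replicates` full pipeline runs).
#' @param outcome Outcome to track.
#' @param n_replicates Number of Monte-Carlo replicates.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param covariates Covariates for the fitted model.
#' @return List with `coefficients` (tibble per behaviour: true value,
#'   mean estimate, bias, bias_pct, rmse, coverage),
#'   `change_discrepancy` (per-replicate max |pipeline - analytic|, raw
#'   outcome units), and `n_replicates`.
#' @export
recovery_report <- function(cfg, outcome = "bmi", n_replicates = 200,
                            seed = 1, covariates = c("age", "sex")) {
  basis <- pivot_basis(movement_parts()[1])
  m <- cfg$outcome_models[[outcome]]
  if (is.null(m)) stop("outcome not in generator config: ", outcome, call. = FALSE)
  truth <- true_pivot_coefficients(m$beta, basis)
  reference <- cfg$mean_composition$male
  mean_level <- if (m$transform == "log") exp(m$intercept) else m$intercept
  analytic <- change_matrix(
    manual_model(m$beta, transform = m$transform, outcome_mean = mean_level,
                 basis = basis, outcome = outcome),
    reference)

  est <- cover <- matrix(NA_real_, n_replicates, 5,
                         dimnames = list(NULL, movement_parts()))
  disc <- numeric(n_replicates)
  fcfg <- filter_config(min_wear_minutes = cfg$wear_threshold)
  for (r in seq_len(n_replicates)) {
    cohort <- generate_cohort(cfg, seed = seed + r)
    ing <- ingest_cohort(cohort$daily, cohort$participants, fcfg)
    fit <- fit_compositional_model(ing$records, outcome,
                                   covariates = covariates)
    b <- fit$behaviours
    est[r, b$behaviour] <- b$coefficient
    cover[r, b$behaviour] <- as.numeric(b$ci_lo <= truth[b$behaviour] &
                                          truth[b$behaviour] <= b$ci_hi)
    cm <- change_matrix(fit, reference, outcome_mean = mean_level)
    disc[r] <- max(abs(cm$absolute - analytic$absolute), na.rm = TRUE)
  }
  bias <- colMeans(est) - truth
  list(
    coefficients = tibble::tibble(
      behaviour = movement_parts(),
      true = as.numeric(truth),
      estimate = colMeans(est),
      bias = as.numeric(bias),
      bias_pct = as.numeric(bias / abs(truth) * 100),
      rmse = sqrt(colMeans(sweep(est, 2, truth)^2)),
      coverage = colMeans(cover)
    ),
    change_discrepancy = disc,
    n_replicates = n_replicates
  )
}

#' Consistency of the pipeline change matrix in sample size
#'
#' For each cohort size, generates one cohort, runs the pipeline, and
#' records the maximum absolute discrepancy (percent points) between the
#' pipeline change matrix and the analytic matrix implied by the planted
#' coefficients. Discrepancies shrink as the cohort grows.
#'
#' @param n_grid Vector of per-sex cohort sizes.
#' @param outcome Outcome to track.
#' @param seed Integer seed.
#' @param cfg Base [generator_config()]; its `n_per_sex` is overridden.
#' @param n_replicates Replicates averaged per grid point.
#' @return Tibble with `n_per_sex` and `max_discrepancy`.
#' @export
change_matrix_consistency <- function(n_grid = c(500, 2000, 8000),
                                      outcome = "bmi", seed = 1,
                                      cfg = generator_config(),
                                      n_replicates = 3) {
  rows <- lapply(n_grid, function(n) {
    cfg$n_per_sex <- c(male = n, female = n)
    rep <- recovery_report(cfg, outcome = outcome, n_replicates = n_replicates,
                           seed = seed + n)
    tibble::tibble(n_per_sex = n,
                   max_discrepancy = mean(rep$change_discrepancy))
  })
  dplyr::bind_rows(rows)
}

#' Null calibration of the compositional F test
#'
#' Simulates cohorts in which the outcome is pure noise (no compositional
#' effect) and returns the p values of the joint F test of the four ILR
#' coordinates. Under the null these are uniform, so the rejection rate
#' at any alpha should match alpha to binomial error.
#'
#' @param n_sims Number of simulated cohorts.
#' @param n Participants per simulated cohort.
#' @param seed Integer seed.
#' @param noise_sd Outcome noise SD.
#' @return Numeric vector of `n_sims` p values.
#' @export
simulate_null_pvalues <- function(n_sims = 1000, n = 250, seed = 1,
                                  noise_sd = 1) {
  set.seed(seed)
  cfg <- generator_config(n_per_sex = c(male = ceiling(n / 2),
                                        female = floor(n / 2)))
  vapply(seq_len(n_sims), function(i) {
    dp <- draw_participants(cfg)
    pt <- dp$participants
    pt$y <- stats::rnorm(nrow(pt), 0, noise_sd)
    fit <- fit_compositional_model(pt, "y", covariates = c("age", "sex"),
                                   transform = "identity",
                                   pivot_coefficients = FALSE)
    fit$model_p
  }, numeric(1))
}
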