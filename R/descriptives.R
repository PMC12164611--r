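#' Effect-size band for Cohen's d
#'
#' Bands |d| as trivial, moderate, large or very large using the
#' conventional thresholds 0.20 / 0.60 / 0.80. The printed thresholds
#' leave gaps (0.20 vs 0.21); these are closed with half-open intervals on
#' the midpoints, so any value that rounds to 0.20 is trivial and any that
#' rounds to 0.21 is moderate.
#'
#' @param d Numeric vector of effect sizes (sign ignored).
#' @return Character vector of band labels.
#' @export
effect_band <- function(d) {
  a <- abs(d)
  dplyr::case_when(
    a < 0.205 ~ "trivial",
    a < 0.605 ~ "moderate",
    a < 0.805 ~ "large",
    TRUE ~ "very large"
  )
}

#' Cohen's d with confidence interval and band
#'
#' Standardised mean difference `(mean(x) - mean(y)) / s_pooled` with the
#' pooled SD using n-1 weights, a normal-approximation 95% CI from the
#' usual sampling variance `(n1+n2)/(n1 n2) + d^2 / (2(n1+n2))`, and the
#' [effect_band()] label.
#'
#' @param x,y Numeric vectors for the two groups (NAs dropped).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `d`, `ci_lo`, `ci_hi`, `band`, `n1`, `n2`.
#' @export
cohens_d <- function(x, y, conf_level = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("both groups need n >= 2", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("pooled SD is zero", call. = FALSE)
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(d = d, ci_lo = d - zq * se, ci_hi = d + zq * se,
                 band = effect_band(d), n1 = n1, n2 = n2)
}

#' Covariate-adjusted sex comparison of one outcome
#'
#' Fits `outcome ~ sex + covariates` by ordinary least squares, reports
#' the F test for sex (identical to the one-way ANCOVA F), the
#' least-squares (covariate-adjusted) means per sex, and Cohen's d. The
#' default d is computed from the raw group data; `d_method = "adjusted"`
#' standardises the adjusted mean difference by the pooled SD of the
#' model residuals within sex, which is what covariate-adjusted effect
#' sizes report.
#'
#' @param records Participant records tibble with a `sex` column
#'   (`male`/`female`).
#' @param outcome Name of the outcome column.
#' @param covariates Adjustment covariates (default age and ethnicity).
#' @param d_method `"raw"` or `"adjusted"`.
#' @return One-row tibble: n per sex, adjusted means, adjusted difference
#'   (female minus male), F, p, d with CI and band.
#' @export
ancova_sex_comparison <- function(records, outcome,
                                  covariates = c("age", "ethnicity"),
                                  d_method = c("raw", "adjusted")) {
  d_method <- match.arg(d_method)
  need <- c(outcome, "sex", covariates)
  df <- records[stats::complete.cases(records[, need]), need]
  df$sex <- factor(df$sex, levels = c("male", "female"))
  if (any(table(df$sex) < 2L)) stop("need >= 2 participants per sex", call. = FALSE)
  for (cv in covariates) {
    if (!is.numeric(df[[cv]]) && length(unique(df[[cv]])) < 2L) {
      stop("singular design; collinear term(s): ", cv, call. = FALSE)
    }
  }
  df$.y <- df[[outcome]]

  rhs <- paste(c("sex", covariates), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
  alias <- stats::alias(full)$Complete
  if (!is.null(alias)) {
    stop("singular design; collinear term(s): ",
         paste(rownames(alias), collapse = ", "), call. = FALSE)
  }
  reduced <- stats::update(full, . ~ . - sex)
  ftest <- stats::anova(reduced, full)
  emm <- emmeans::emmeans(full, "sex")
  emm_df <- as.data.frame(emm)
  adj <- stats::setNames(emm_df$emmean, as.character(emm_df$sex))

  if (d_method == "raw") {
    dd <- cohens_d(df$.y[df$sex == "female"], df$.y[df$sex == "male"])
  } else {
    r <- stats::residuals(full)
    n1 <- sum(df$sex == "female"); n2 <- sum(df$sex == "male")
    sp2 <- ((n1 - 1) * stats::var(r[df$sex == "female"]) +
              (n2 - 1) * stats::var(r[df$sex == "male"])) / (n1 + n2 - 2)
    d <- (adj[["female"]] - adj[["male"]]) / sqrt(sp2)
    se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
    dd <- tibble::tibble(d = d, ci_lo = d - 1.959964 * se,
                         ci_hi = d + 1.959964 * se,
                         band = effect_band(d), n1 = n1, n2 = n2)
  }

  tibble::tibble(
    outcome = outcome,
    n_male = sum(df$sex == "male"), n_female = sum(df$sex == "female"),
    mean_male = adj[["male"]], mean_female = adj[["female"]],
    difference = adj[["female"]] - adj[["male"]],
    f_statistic = ftest$F[2], p_value = ftest$`Pr(>F)`[2],
    d = dd$d, d_ci_lo = dd$ci_lo, d_ci_hi = dd$ci_hi, d_band = dd$band,
    d_method = d_method
  )
}

#' Movement behaviour summary table
#'
#' Per behaviour (optionally per sex): the arithmetic mean of the stored
#' minutes, the geometric-mean composition closed to 1440 min, and the
#' geometric value as a percentage of 24 hours. The geometric-mean column
#' always sums to 1440 and the percentage column to 100.
#'
#' @param records Participant records with `SED`/`LPA`/`MPA`/`VPA`/`Sleep`
#'   columns.
#' @param by_sex Stratify by the `sex` column (default TRUE).
#' @return Tibble with columns `sex` (if stratified), `part`,
#'   `overall_mean`, `geometric_mean`, `pct_of_day`.
#' @export
movement_summary <- function(records, by_sex = TRUE) {
  one_group <- function(df, label = NULL) {
    comp <- as.matrix(df[, movement_parts()])
    gm <- geometric_mean_composition(comp, total = 1440)
    out <- tibble::tibble(
      part = movement_parts(),
      overall_mean = unname(colMeans(comp)),
      geometric_mean = as.numeric(gm),
      pct_of_day = as.numeric(gm) / 1440 * 100
    )
    if (!is.null(label)) out <- dplyr::mutate(out, sex = label, .before = 1)
    out
  }
  if (!by_sex) return(one_group(records))
  dplyr::bind_rows(lapply(split(records, records$sex),
                          function(df) one_group(df, df$sex[1])))
}
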