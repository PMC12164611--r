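default_covariates <- function() c("age", "sex", "ethnicity", "month")

# Coerce model covariates to the conventions used throughout: sex with
# male as reference, ethnicity with White as reference, monitoring month
# dummy-coded with January as reference. Errors if a covariate is constant
# (the design would be singular) naming the column.
prepare_covariates <- function(df, covariates) {
  for (cv in covariates) {
    v <- df[[cv]]
    if (cv == "sex") {
      v <- factor(v, levels = c("male", "female"))
    } else if (cv == "ethnicity") {
      lev <- unique(as.character(v))
      lev <- c(intersect("White", lev), setdiff(lev, "White"))
      v <- factor(v, levels = lev)
    } else if (cv == "month") {
      v <- factor(v, levels = sort(unique(v)))
    }
    if (is.factor(v) && nlevels(droplevels(v)) < 2L) {
      stop("covariate has a single level: ", cv, call. = FALSE)
    }
    df[[cv]] <- v
  }
  df
}

#' Fit a compositional outcome model on ILR coordinates
#'
#' Ordinary least squares of a (possibly log-transformed) cardiometabolic
#' outcome on the four ILR coordinates of the 24-hour movement
#' composition plus covariates. The joint contribution of the composition
#' is tested with an F test against the covariate-only model, and the
#' variance explained by the composition is reported as the R-squared
#' increment over that covariate-only model (set
#' `r_squared = "total"` for the full-model R-squared instead). For each
#' behaviour the model is refit in the pivot basis that places that
#' behaviour first, and the first coordinate's coefficient — the
#' behaviour against the geometric mean of the other four — is reported
#' with its two-sided t-test p value and 95% CI. All five rotations are
#' reparameterisations of the same model: fitted values, residuals, model
#' p and R-squared are identical across them.
#'
#' @param records Participant records with composition columns
#'   `SED`/`LPA`/`MPA`/`VPA`/`Sleep`, covariates and outcome columns.
#' @param outcome Outcome column name; its transform is looked up in
#'   [outcome_specs()] unless `transform` is given.
#' @param covariates Covariate columns (default age, sex, ethnicity,
#'   month of monitoring).
#' @param transform `"identity"` or `"log"` (natural log); overrides the
#'   [outcome_specs()] lookup.
#' @param pivot_coefficients Compute the five per-behaviour rotations
#'   (default TRUE; skip for speed in simulation studies that only need
#'   the joint test).
#' @param r_squared `"increment"` (default) or `"total"`.
#' @return An `outcome_model_fit` object; see Details for fields.
#' @export
fit_compositional_model <- function(records, outcome,
                                    covariates = default_covariates(),
                                    transform = NULL,
                                    pivot_coefficients = TRUE,
                                    r_squared = c("increment", "total")) {
  r_squared <- match.arg(r_squared)
  specs <- outcome_specs()
  if (is.null(transform)) {
    transform <- if (outcome %in% specs$name) {
      specs$transform[specs$name == outcome]
    } else "identity"
  }
  need <- c(outcome, covariates, movement_parts())
  df <- records[stats::complete.cases(records[, need]), need, drop = FALSE]
  df <- prepare_covariates(df, covariates)
  n <- nrow(df)

  comp <- as.matrix(df[, movement_parts()])
  basis <- pivot_basis(movement_parts()[1])
  z <- ilr_transform(comp, basis)
  colnames(z) <- paste0("ilr", seq_len(ncol(z)))
  y <- if (transform == "log") log(df[[outcome]]) else df[[outcome]]
  mdf <- cbind(data.frame(.y = y, z), df[, covariates, drop = FALSE])

  rhs_cov <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f_full <- stats::as.formula(paste(".y ~", paste(colnames(z), collapse = " + "),
                                    "+", rhs_cov))
  full <- stats::lm(f_full, data = mdf)
  if (n <= length(stats::coef(full))) {
    stop("more parameters than observations (n = ", n, ")", call. = FALSE)
  }
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("rank-deficient design; aliased term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  reduced <- stats::lm(stats::as.formula(paste(".y ~", rhs_cov)), data = mdf)
  cmp <- stats::anova(reduced, full)
  r2_full <- summary(full)$r.squared
  r2_cov <- summary(reduced)$r.squared

  beta_ilr <- stats::coef(full)[colnames(z)]
  beta_clr <- drop(t(basis$contrast) %*% beta_ilr)
  names(beta_clr) <- basis$part_order
  beta_clr <- beta_clr[movement_parts()]

  behaviours <- NULL
  if (pivot_coefficients) {
    rows <- lapply(movement_parts(), function(b) {
      bb <- pivot_basis(b)
      zb <- ilr_transform(comp, bb)
      colnames(zb) <- paste0("ilr", seq_len(ncol(zb)))
      mb <- cbind(data.frame(.y = y, zb), df[, covariates, drop = FALSE])
      fb <- stats::lm(f_full, data = mb)
      sm <- summary(fb)$coefficients
      ci <- stats::confint(fb, "ilr1", level = 0.95)
      tibble::tibble(behaviour = b, coefficient = sm["ilr1", "Estimate"],
                     p_value = sm["ilr1", "Pr(>|t|)"],
                     ci_lo = ci[1], ci_hi = ci[2])
    })
    behaviours <- dplyr::bind_rows(rows)
  }

  structure(list(
    outcome = outcome,
    label = if (outcome %in% specs$name) specs$label[specs$name == outcome] else outcome,
    transform = transform,
    n = n,
    model_p = cmp$`Pr(>F)`[2],
    model_f = cmp$F[2],
    r_squared = if (r_squared == "increment") r2_full - r2_cov else r2_full,
    r_squared_definition = r_squared,
    r_squared_total = r2_full,
    r_squared_covariates = r2_cov,
    behaviours = behaviours,
    basis = basis,
    ilr_coefficients = beta_ilr,
    clr_coefficients = beta_clr,
    covariate_coefficients = stats::coef(full)[setdiff(names(stats::coef(full)),
                                                       colnames(z))],
    residual_sd = summary(full)$sigma,
    outcome_mean = mean(df[[outcome]])
  ), class = "outcome_model_fit")
}

#' @export
print.outcome_model_fit <- function(x, ...) {
  cat("Compositional ILR model:", x$label, "\n")
  cat(sprintf("  n = %d, model p = %.3g, R2 (%s) = %.3f\n",
              x$n, x$model_p, x$r_squared_definition, x$r_squared))
  if (!is.null(x$behaviours)) {
    b <- x$behaviours
    cat("  pivot coefficients:\n")
    for (i in seq_len(nrow(b))) {
      cat(sprintf("    %-6s %8.4f  (p = %.3g)\n",
                  b$behaviour[i], b$coefficient[i], b$p_value[i]))
    }
  }
  invisible(x)
}

#' Summarise a set of compositional model fits
#'
#' Builds the wide one-row-per-outcome report (model p, R-squared, pivot
#' coefficient and p per behaviour) in the canonical outcome order, plus
#' the headline variance-explained range across outcomes.
#'
#' @param fits List of [fit_compositional_model()] results.
#' @return List with `table` (tibble) and `r_squared_range`
#'   (`c(min, max)`).
#' @export
summarize_models <- function(fits) {
  if (!length(fits)) stop("no fits supplied", call. = FALSE)
  rows <- lapply(fits, function(f) {
    row <- tibble::tibble(outcome = f$outcome, label = f$label, n = f$n,
                          model_p = f$model_p, r_squared = f$r_squared)
    if (!is.null(f$behaviours)) {
      for (i in seq_len(nrow(f$behaviours))) {
        b <- f$behaviours$behaviour[i]
        row[[paste0("Y_", b)]] <- f$behaviours$coefficient[i]
        row[[paste0("p_", b)]] <- f$behaviours$p_value[i]
      }
    }
    row
  })
  tab <- dplyr::bind_rows(rows)
  ord <- match(outcome_specs()$name, tab$outcome)
  tab <- dplyr::bind_rows(tab[ord[!is.na(ord)], ],
                          tab[!tab$outcome %in% outcome_specs()$name, ])
  r2 <- range(tab$r_squared)
  list(table = tab, r_squared_range = r2)
}
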