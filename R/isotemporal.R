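#' Reallocate time between two behaviours
#'
#' Moves `delta` minutes from the donor behaviour to the receiver, leaving
#' the other parts (and the 1440-minute total) unchanged. Errors with an
#' `infeasible_reallocation` condition when the donor does not hold more
#' than `delta` minutes — a real constraint, not an edge case: a 10-minute
#' donation can exceed a group's entire mean vigorous-activity time.
#'
#' @param reference Named composition vector (minutes, summing to the day).
#' @param donor,receiver Part labels; must differ.
#' @param delta Minutes to move (default 10).
#' @return Composition vector with the same names and total.
#' @export
#' @examples
#' ref <- close_composition(c(SED = 342.1, LPA = 350.7, MPA = 40.5,
#'                            VPA = 14.0, Sleep = 692.7))
#' reallocate(ref, donor = "VPA", receiver = "SED", delta = 10)
reallocate <- function(reference, donor, receiver, delta = 10) {
  stopifnot(delta >= 0)
  if (donor == receiver) stop("donor and receiver must differ", call. = FALSE)
  if (!all(c(donor, receiver) %in% names(reference))) {
    stop("donor/receiver not among composition parts", call. = FALSE)
  }
  if (reference[[donor]] - delta <= 0) {
    stop(errorCondition(
      sprintf("cannot move %.4g min out of %s (only %.4g min available)",
              delta, donor, reference[[donor]]),
      class = c("infeasible_reallocation", "error", "condition")))
  }
  out <- reference
  out[[donor]] <- out[[donor]] - delta
  out[[receiver]] <- out[[receiver]] + delta
  out
}

#' Predicted outcome change for one reallocation
#'
#' Evaluates the fitted compositional model at the reference composition
#' and at the reallocated composition; the covariate terms cancel in the
#' difference, so the predicted change in model space is
#' `beta' (ilr(reallocated) - ilr(reference))`. For identity outcomes this
#' is converted to a percentage of the group mean; for log outcomes the
#' exact back-transform `(exp(delta_yhat) - 1) * 100` is used by default
#' (`method = "linear"` gives the first-order `delta_yhat * 100`
#' approximation).
#'
#' @param fit An [fit_compositional_model()] result.
#' @param reference Named composition vector (typically the group
#'   geometric-mean composition).
#' @param donor,receiver,delta Reallocation, as in [reallocate()].
#' @param outcome_mean Group mean of the raw outcome used to express the
#'   change as a percentage (default the fit's estimation-sample mean).
#' @param method Back-transform for log outcomes: `"exact"` or
#'   `"linear"`.
#' @return One-row tibble: `donor`, `receiver`, `delta_yhat` (model
#'   space), `pct_change`, `absolute_change` (raw outcome units).
#' @export
predict_change <- function(fit, reference, donor, receiver, delta = 10,
                           outcome_mean = fit$outcome_mean,
                           method = c("exact", "linear")) {
  method <- match.arg(method)
  new <- reallocate(reference, donor, receiver, delta)
  dz <- ilr_transform(new, fit$basis) - ilr_transform(reference, fit$basis)
  dy <- sum(fit$ilr_coefficients * dz)
  if (fit$transform == "log") {
    pct <- if (method == "exact") (exp(dy) - 1) * 100 else dy * 100
    absolute <- (exp(dy) - 1) * outcome_mean
  } else {
    pct <- dy / outcome_mean * 100
    absolute <- dy
  }
  tibble::tibble(donor = donor, receiver = receiver, delta_yhat = dy,
                 pct_change = pct, absolute_change = absolute)
}

#' Smallest worthwhile change per outcome
#'
#' `0.2 x group SD` of the raw outcome, the conventional distribution-based
#' minimum practically meaningful difference, also expressed as a
#' percentage of the group mean.
#'
#' @param records Participant records.
#' @param outcome Outcome column name.
#' @param by_sex Stratify by sex (default TRUE).
#' @return Tibble with `sex` (if stratified), `n`, `mean`, `sd`, `swc`,
#'   `swc_pct_of_mean`.
#' @export
compute_swc <- function(records, outcome, by_sex = TRUE) {
  one <- function(df, label = NULL) {
    v <- df[[outcome]]
    v <- v[!is.na(v)]
    if (length(v) < 2L) stop("group needs n >= 2", call. = FALSE)
    s <- stats::sd(v)
    if (s == 0) stop("zero SD; smallest worthwhile change undefined", call. = FALSE)
    out <- tibble::tibble(outcome = outcome, n = length(v), mean = mean(v),
                          sd = s, swc = 0.2 * s,
                          swc_pct_of_mean = 0.2 * s / mean(v) * 100)
    if (!is.null(label)) out <- dplyr::mutate(out, sex = label, .after = 1)
    out
  }
  if (!by_sex) return(one(records))
  dplyr::bind_rows(lapply(split(records, records$sex),
                          function(df) one(df, df$sex[1])))
}

#' Isotemporal-substitution change matrix
#'
#' Evaluates [predict_change()] for all 20 ordered behaviour pairs around
#' a reference composition, laid out with the receiving behaviour in rows
#' and the donating behaviour in columns. Cells where the donor holds
#' fewer minutes than `delta` are left missing rather than extrapolated.
#' When a smallest worthwhile change is supplied, cells whose absolute
#' predicted change exceeds it are flagged. Percentage changes blow up
#' when the group mean outcome is near zero (z-scores); the matrix
#' carries a `near_zero_mean` warning flag and the absolute-units matrix
#' so the pathology stays visible.
#'
#' @param fit An [fit_compositional_model()] result.
#' @param reference Named reference composition (group geometric mean).
#' @param swc Smallest worthwhile change in raw outcome units (a single
#'   number, e.g. the `swc` column of [compute_swc()]), or NULL for no
#'   flags.
#' @param delta Minutes reallocated (default 10).
#' @param outcome_mean,method Passed to [predict_change()].
#' @return A `change_matrix` object: list with `pct` and `absolute`
#'   (5 x 5 matrices, rows = receiver, columns = donor, diagonal NA),
#'   `flags` (logical matrix or NULL), `outcome`, `delta`, `swc`,
#'   `reference`, `infeasible` (logical matrix), `near_zero_mean`.
#' @export
change_matrix <- function(fit, reference, swc = NULL, delta = 10,
                          outcome_mean = fit$outcome_mean,
                          method = c("exact", "linear")) {
  method <- match.arg(method)
  parts <- movement_parts()
  pct <- absolute <- matrix(NA_real_, 5, 5, dimnames = list(receiver = parts,
                                                            donor = parts))
  infeasible <- matrix(FALSE, 5, 5, dimnames = dimnames(pct))
  for (dn in parts) {
    for (rc in setdiff(parts, dn)) {
      res <- tryCatch(
        predict_change(fit, reference, donor = dn, receiver = rc,
                       delta = delta, outcome_mean = outcome_mean,
                       method = method),
        infeasible_reallocation = function(e) NULL)
      if (is.null(res)) {
        infeasible[rc, dn] <- TRUE
      } else {
        pct[rc, dn] <- res$pct_change
        absolute[rc, dn] <- res$absolute_change
      }
    }
  }
  flags <- if (!is.null(swc)) {
    stopifnot(is.numeric(swc), length(swc) == 1L, swc > 0)
    abs(absolute) > swc
  } else NULL
  structure(list(pct = pct, absolute = absolute, flags = flags,
                 outcome = fit$outcome, delta = delta, swc = swc,
                 reference = reference, infeasible = infeasible,
                 near_zero_mean = abs(outcome_mean) < 1),
            class = "change_matrix")
}

#' @export
print.change_matrix <- function(x, ...) {
  cat(sprintf("Change matrix (%s, %g-min reallocation, %% change; rows = to, cols = from)\n",
              x$outcome, x$delta))
  m <- round(x$pct, 2)
  if (!is.null(x$flags)) {
    disp <- matrix(ifelse(is.na(m), "", paste0(format(m), ifelse(x$flags, "*", " "))),
                   5, 5, dimnames = dimnames(m))
    print(disp, quote = FALSE)
    cat(sprintf("* |change| above smallest worthwhile change (%.4g units)\n", x$swc))
  } else {
    print(m)
  }
  if (x$near_zero_mean) {
    cat("note: group mean outcome is near zero; percentage changes are unstable,",
        "use the absolute-units matrix\n")
  }
  invisible(x)
}
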