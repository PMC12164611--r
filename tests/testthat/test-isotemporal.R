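boys_reference <- function() {
  close_composition(c(SED = 342.1, LPA = 350.7, MPA = 40.5, VPA = 14.0,
                      Sleep = 692.7))
}

test_that("reallocation moves minutes between exactly two behaviours", {
  ref <- boys_reference()
  expect_equal(reallocate(ref, "VPA", "SED", delta = 0), ref)
  out <- reallocate(ref, donor = "VPA", receiver = "SED", delta = 10)
  expect_equal(unname(out[movement_parts()]),
               c(352.1, 350.7, 40.5, 4.0, 692.7), tolerance = 1e-10)
  expect_equal(sum(out), 1440)
  expect_error(reallocate(ref, "VPA", "VPA"), "differ")
})

test_that("reallocation exceeding the donor's minutes is infeasible, not extrapolated", {
  girls <- close_composition(c(SED = 365.8, LPA = 348.5, MPA = 30.2,
                               VPA = 11.5, Sleep = 681.1))
  expect_equal(reallocate(girls, "VPA", "SED", 10)[["VPA"]],
               girls[["VPA"]] - 10)
  err <- tryCatch(reallocate(girls, "VPA", "SED", 12), condition = identity)
  expect_s3_class(err, "infeasible_reallocation")
})

test_that("chained reallocations compose exactly in composition space", {
  ref <- boys_reference()
  ab <- reallocate(ref, "SED", "LPA", 10)
  abc <- reallocate(ab, "LPA", "MPA", 10)
  expect_equal(abc, reallocate(ref, "SED", "MPA", 10))
})

test_that("predicted change matches hand-computed and CLR-space oracles", {
  ref <- boys_reference()
  basis <- pivot_basis("SED")
  fit0 <- manual_model(rep(0, 4), "identity", outcome_mean = 20)
  expect_equal(predict_change(fit0, ref, "VPA", "SED")$pct_change, 0)

  fit1 <- manual_model(c(1, 0, 0, 0), "identity", outcome_mean = 1)
  new <- reallocate(ref, "VPA", "SED", 10)
  dz1 <- ilr_transform(new, basis)[1] - ilr_transform(ref, basis)[1]
  expect_equal(predict_change(fit1, ref, "VPA", "SED")$delta_yhat,
               unname(dz1), tolerance = 1e-9)

  set.seed(6)
  for (i in 1:5) {
    beta <- rnorm(4)
    fit <- manual_model(beta, "identity", outcome_mean = 50)
    res <- predict_change(fit, ref, "MPA", "Sleep")
    dclr <- clr_transform(reallocate(ref, "MPA", "Sleep", 10)) - clr_transform(ref)
    expect_equal(res$delta_yhat,
                 sum(fit$clr_coefficients * dclr[movement_parts()]),
                 tolerance = 1e-9)
  }
})

test_that("predicted change is unchanged by the covariate profile", {
  rec <- make_records(n = 300, noise_sd = 0.3, seed = 14)
  fit <- fit_compositional_model(rec, "y", covariates = c("age", "sex"),
                                 transform = "identity")
  ref <- boys_reference()
  new <- reallocate(ref, "SED", "VPA", 10)
  basis <- fit$basis
  # full-model predictions at two covariate profiles
  predict_full <- function(comp, age, female) {
    sum(fit$ilr_coefficients * ilr_transform(comp, basis)) +
      fit$covariate_coefficients[["(Intercept)"]] +
      fit$covariate_coefficients[["age"]] * age +
      fit$covariate_coefficients[["sexfemale"]] * female
  }
  d1 <- predict_full(new, age = 9, female = 0) - predict_full(ref, 9, 0)
  d2 <- predict_full(new, age = 14, female = 1) - predict_full(ref, 14, 1)
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_equal(predict_change(fit, ref, "SED", "VPA")$delta_yhat, d1,
               tolerance = 1e-12)
})

test_that("model-space changes flip sign when donor and receiver swap", {
  ref <- boys_reference()
  set.seed(9)
  fit <- manual_model(rnorm(4), "log", outcome_mean = 18)
  pairs <- utils::combn(movement_parts(), 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    dy_ab <- predict_change(fit, ref, a, b)$delta_yhat
    dy_ba <- predict_change(fit, ref, b, a)$delta_yhat
    expect_true(sign(dy_ab) == -sign(dy_ba))
    # percent changes of log outcomes are NOT exactly antisymmetric
    pct_ab <- predict_change(fit, ref, a, b)$pct_change
    pct_ba <- predict_change(fit, ref, b, a)$pct_change
    if (a == "SED" && b == "VPA") expect_gt(abs(pct_ab + pct_ba), 1e-6)
  }
})

test_that("smallest worthwhile change is 0.2 SD and scale-equivariant", {
  rec <- tibble::tibble(sex = rep(c("male", "female"), each = 40),
                        bmi = c(vector_with_stats(40, 20, 5),
                                vector_with_stats(40, 18.8, 3.4)))
  swc <- compute_swc(rec, "bmi")
  expect_equal(swc$swc[swc$sex == "male"], 1.0)
  expect_equal(swc$swc[swc$sex == "female"], 0.68)
  expect_equal(swc$swc_pct_of_mean[swc$sex == "female"], 0.68 / 18.8 * 100,
               tolerance = 1e-9)
  rec2 <- dplyr::mutate(rec, bmi = bmi * 2)
  expect_equal(compute_swc(rec2, "bmi")$swc, swc$swc * 2)
  expect_error(compute_swc(tibble::tibble(bmi = rep(1, 5)), "bmi",
                           by_sex = FALSE), "zero SD")
})

test_that("change matrices flag only effects larger than the SWC", {
  ref <- boys_reference()
  zero <- change_matrix(manual_model(rep(0, 4), "identity", 20), ref, swc = 1)
  expect_true(all(zero$pct[!is.na(zero$pct)] == 0))
  expect_false(any(zero$flags, na.rm = TRUE))

  # a strong VPA-vs-rest effect flags every VPA reallocation but leaves
  # exchanges among the large, slowly-varying behaviours unflagged
  vpa_fit <- manual_model(c(1.2, 0, 0, 0), "log", outcome_mean = 18.8,
                          basis = pivot_basis("VPA"))
  cm <- change_matrix(vpa_fit, ref, swc = 0.2 * 3.4)
  expect_true(all(cm$flags["VPA", -4]))
  expect_true(all(cm$flags[-4, "VPA"]))
  big3 <- c("SED", "LPA", "Sleep")
  off <- cm$flags[big3, big3]
  expect_false(any(off[!is.na(off)]))
})

test_that("scaling coefficients up never removes a flag", {
  ref <- boys_reference()
  set.seed(2)
  beta <- rnorm(4, sd = 0.1)
  small <- change_matrix(manual_model(beta, "log", 18.8), ref, swc = 0.5)
  big <- change_matrix(manual_model(beta * 3, "log", 18.8), ref, swc = 0.5)
  idx <- !is.na(small$flags)
  expect_true(all(big$flags[idx] >= small$flags[idx]))
})

test_that("infeasible cells stay missing and near-zero means raise the warning flag", {
  tight <- close_composition(c(SED = 400, LPA = 400, MPA = 100, VPA = 8,
                               Sleep = 532))
  fit <- manual_model(c(0.3, 0.1, -0.1, 0.2), "identity", outcome_mean = 0.05)
  cm <- change_matrix(fit, tight, delta = 10)
  expect_true(all(cm$infeasible[, "VPA"][-4]))  # VPA cannot donate 10 min
  expect_true(all(is.na(cm$pct[, "VPA"][-4])))
  expect_false(any(cm$infeasible[, "SED"]))
  expect_true(cm$near_zero_mean)
})
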