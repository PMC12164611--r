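make_days <- function(...) {
  tibble::tibble(...)
}

base_day <- function(id, day = 1L, wear = 800, sed = 320, lpa = 330, mpa = 40,
                     vpa = 15, sleep = 620, month = 5L) {
  tibble::tibble(participant_id = id, day_index = day, wear_minutes = wear,
                 sed = sed, lpa = lpa, mpa = mpa, vpa = vpa, sleep = sleep,
                 month = month)
}

test_that("valid-day filter excludes by wear, sleep and malformedness with reasons", {
  days <- dplyr::bind_rows(
    base_day("a"),
    base_day("b", wear = 400),
    base_day("c", sleep = 100),
    base_day("d", sed = NA_real_),
    base_day("e", vpa = -3)
  )
  res <- filter_valid_days(days, filter_config())
  expect_equal(res$days$participant_id, "a")
  expect_equal(sort(res$exclusions$participant_id), c("b", "c", "d", "e"))
  got <- setNames(res$exclusions$reason, res$exclusions$participant_id)
  expect_equal(got[["b"]], "wear_time")
  expect_equal(got[["c"]], "sleep_bounds")
  expect_equal(got[["d"]], "malformed")
  expect_equal(got[["e"]], "malformed")
})

test_that("filter is the identity on fully valid data and order-independent", {
  days <- dplyr::bind_rows(lapply(1:6, function(i) base_day(paste0("p", i))))
  res <- filter_valid_days(days, filter_config())
  expect_equal(res$days, days)
  expect_equal(nrow(res$exclusions), 0L)

  mixed <- dplyr::bind_rows(
    days, base_day("w", wear = 500), base_day("s", sleep = 1000),
    base_day("ws", wear = 500, sleep = 1000)
  )
  wear_only <- filter_config(min_wear_minutes = 600, sleep_bounds = c(0, 1e6))
  sleep_only <- filter_config(min_wear_minutes = 0, sleep_bounds = c(240, 960))
  both <- filter_config()
  ab <- filter_valid_days(filter_valid_days(mixed, wear_only)$days, sleep_only)$days
  ba <- filter_valid_days(filter_valid_days(mixed, sleep_only)$days, wear_only)$days
  expect_equal(ab, ba)
  expect_equal(ab, filter_valid_days(mixed, both)$days)
})

demo_info <- function(ids) {
  tibble::tibble(participant_id = ids, sex = "male", age = 11,
                 ethnicity = "White", bmi = 18)
}

test_that("assembly keeps a day whose waking parts already tile the non-sleep time", {
  cfg <- filter_config(min_valid_days = 1)
  day <- base_day("a", wear = 840, sed = 400, lpa = 350, mpa = 60, vpa = 30,
                  sleep = 600)
  res <- assemble_participants(day, demo_info("a"), cfg)
  rec <- res$records
  expect_equal(rec$SED, 400)
  expect_equal(rec$VPA, 30)
  expect_equal(rec$Sleep, 600)
  expect_equal(rec$n_valid_days, 1L)
  expect_equal(sum(unlist(rec[, movement_parts()])), 1440)
})

test_that("waking behaviours are rescaled proportionally to fill 1440 minus sleep", {
  cfg <- filter_config(min_valid_days = 1)
  day <- base_day("a", wear = 700, sed = 350, lpa = 250, mpa = 70, vpa = 30,
                  sleep = 600)
  rec <- assemble_participants(day, demo_info("a"), cfg)$records
  # waking sum 700, target 840: scale 1.2
  expect_equal(rec$SED, 350 * 1.2)
  expect_equal(rec$LPA, 250 * 1.2)
  expect_equal(rec$MPA, 70 * 1.2)
  expect_equal(rec$VPA, 30 * 1.2)
  expect_equal(rec$Sleep, 600)
})

test_that("participants are excluded with reasons and counts are conserved", {
  cfg <- filter_config(min_valid_days = 3, require_outcomes = "bmi")
  days <- dplyr::bind_rows(
    lapply(1:3, function(i) base_day("full", day = i)),
    lapply(1:2, function(i) base_day("short", day = i)),
    lapply(1:3, function(i) base_day("nobmi", day = i))
  )
  info <- demo_info(c("full", "short", "nobmi", "nodays"))
  info$bmi[info$participant_id == "nobmi"] <- NA
  res <- assemble_participants(days, info, cfg)
  expect_equal(res$records$participant_id, "full")
  got <- setNames(res$excluded$reason, res$excluded$participant_id)
  expect_equal(got[["short"]], "too_few_days")
  expect_equal(got[["nodays"]], "too_few_days")
  expect_equal(got[["nobmi"]], "missing_outcome")
  expect_equal(nrow(res$records) + nrow(res$excluded), nrow(info))
  expect_equal(res$flow$input, 4L)
  expect_equal(res$flow$retained, 1L)
})

test_that("modal monitoring month breaks ties toward the earliest month", {
  cfg <- filter_config(min_valid_days = 1)
  days <- dplyr::bind_rows(
    base_day("a", day = 1, month = 9L), base_day("a", day = 2, month = 9L),
    base_day("a", day = 3, month = 2L),
    base_day("b", day = 1, month = 11L), base_day("b", day = 2, month = 4L)
  )
  rec <- assemble_participants(days, demo_info(c("a", "b")), cfg)$records
  expect_equal(rec$month[rec$participant_id == "a"], 9L)
  expect_equal(rec$month[rec$participant_id == "b"], 4L)
})

test_that("planted exclusions in a synthetic cohort are recovered exactly", {
  cfg <- generator_config(n_per_sex = c(male = 150, female = 150),
                          day = list(invalid_day_rate = 0),
                          n_invalid_participants = 40, n_missing_outcome = 25,
                          missing_outcome = "bmi")
  cohort <- generate_cohort(cfg, seed = 21)
  ing <- ingest_cohort(cohort$daily, cohort$participants,
                       filter_config(require_outcomes = "bmi"))
  expect_equal(nrow(ing$records), 300 - 40 - 25)
  expect_equal(sum(ing$excluded$reason == "too_few_days"), 40)
  expect_equal(sum(ing$excluded$reason == "missing_outcome"), 25)
  expect_setequal(
    ing$excluded$participant_id[ing$excluded$reason == "too_few_days"],
    cohort$ground_truth$planted_invalid_participants)
  expect_setequal(
    ing$excluded$participant_id[ing$excluded$reason == "missing_outcome"],
    cohort$ground_truth$planted_missing_participants)
  # retained + excluded = input, and day-level bookkeeping matches
  expect_equal(nrow(ing$records) + nrow(ing$excluded),
               nrow(cohort$participants))
  expect_equal(nrow(ing$day_exclusions), cohort$ground_truth$n_invalid_days)
})
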