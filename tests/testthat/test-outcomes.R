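std <- reference_standards()

baseline <- function(id = "p1", ...) new_patient(patient_id = id, ...)

test_that("clinical failure fires on the tabulated criteria at the right windows", {
  p <- baseline()

  # day-7 fever alone is a failure
  f <- dplyr::bind_rows(sim_followup_row("p1", 3),
                        sim_followup_row("p1", 7, temperature_c = 38.4))
  out <- assess_failure(f, p, std)
  expect_true(out$clinical_failure)
  expect_equal(out$failure_day, 7)
  expect_match(out$failure_criteria, "fever_day7")

  # temperature 37.9 at day 7 is below the 38.0 follow-up threshold
  f <- dplyr::bind_rows(sim_followup_row("p1", 3),
                        sim_followup_row("p1", 7, temperature_c = 37.9))
  expect_false(assess_failure(f, p, std)$clinical_failure)

  # day-3 cough history with lower chest indrawing fails at day 3
  f <- dplyr::bind_rows(
    sim_followup_row("p1", 3, cough_history = TRUE, lower_chest_indrawing = TRUE),
    sim_followup_row("p1", 7))
  out <- assess_failure(f, p, std)
  expect_true(out$clinical_failure)
  expect_equal(out$failure_day, 3)
  expect_match(out$failure_criteria, "pneumonia_day3")

  # age-banded tachypnea rule: 55/min with cough fails at 18 months (cutoff
  # 50) but not under 12 months (cutoff 60)
  f10 <- dplyr::bind_rows(
    sim_followup_row("p10", 3, cough_history = TRUE, respiratory_rate_per_min = 55),
    sim_followup_row("p10", 7))
  expect_false(assess_failure(f10, baseline("p10", age_months = 10, weight_kg = 8),
                              std)$clinical_failure)
  f18 <- dplyr::bind_rows(
    sim_followup_row("p1", 3, cough_history = TRUE, respiratory_rate_per_min = 55),
    sim_followup_row("p1", 7))
  expect_true(assess_failure(f18, p, std)$clinical_failure)

  # hypoxemia at an unscheduled day-5 contact is a severe-disease failure
  f <- dplyr::bind_rows(sim_followup_row("p1", 3),
                        sim_followup_row("p1", 5, sao2_percent = 88),
                        sim_followup_row("p1", 7))
  out <- assess_failure(f, p, std)
  expect_true(out$clinical_failure)
  expect_equal(out$failure_day, 5)
  expect_match(out$failure_criteria, "hypoxemia")

  # all contacts unremarkable -> no failure
  f <- dplyr::bind_rows(sim_followup_row("p1", 3), sim_followup_row("p1", 7))
  out <- assess_failure(f, p, std)
  expect_false(out$clinical_failure)
  expect_false(out$lost_to_followup)

  # no day-7-window contact and not dead -> lost, failure undefined
  f <- sim_followup_row("p1", 3)
  out <- assess_failure(f, p, std)
  expect_true(out$lost_to_followup)
  expect_true(is.na(out$clinical_failure))
})

test_that("failure is monotone: adding a qualifying observation never rescues a failure", {
  p <- baseline()
  base_obs <- dplyr::bind_rows(
    sim_followup_row("p1", 3, cough_history = TRUE, lower_chest_indrawing = TRUE),
    sim_followup_row("p1", 7))
  expect_true(assess_failure(base_obs, p, std)$clinical_failure)
  extra <- dplyr::bind_rows(base_obs,
                            sim_followup_row("p1", 6, convulsions_24h = 3))
  out <- assess_failure(extra, p, std)
  expect_true(out$clinical_failure)
  expect_equal(out$failure_day, 3)  # earliest qualifying day is kept
})

test_that("failure thresholds reuse the same percentile registry as the engines", {
  age <- 9; temp <- 38.6
  thr <- rr_percentile(age, temp, 97, std)
  just_below <- sim_followup_row("p9", 4, temperature_c = temp,
                                 respiratory_rate_per_min = thr - 1)
  at_thr <- sim_followup_row("p9", 4, temperature_c = temp,
                             respiratory_rate_per_min = thr)
  pat <- baseline("p9", age_months = age, weight_kg = 8)
  d7 <- sim_followup_row("p9", 7)
  expect_false(assess_failure(dplyr::bind_rows(just_below, d7), pat, std)$clinical_failure)
  out <- assess_failure(dplyr::bind_rows(at_thr, d7), pat, std)
  expect_true(out$clinical_failure)
  expect_match(out$failure_criteria, "severe_tachypnea")
})

test_that("not-cured rule: caregiver concern or any fever triggers re-treatment", {
  f <- dplyr::bind_rows(
    sim_followup_row("a", 3, caregiver_considers_ill = TRUE, temperature_c = 36.8),
    sim_followup_row("b", 3, temperature_c = 38.1),
    sim_followup_row("c", 3, temperature_c = 36.8))
  out <- not_cured(f, std)
  expect_identical(out$not_cured, c(TRUE, TRUE, FALSE))
})

test_that("severe adverse events: deaths and secondary admissions by day 30", {
  f <- dplyr::bind_rows(sim_followup_row("p1", 3), sim_followup_row("p1", 7),
                        sim_followup_row("p1", 20, died = TRUE, hospitalized = TRUE))
  out <- assess_sae(f)
  expect_true(out$severe_adverse_event)
  expect_equal(out$sae_kind, "death")

  f <- dplyr::bind_rows(sim_followup_row("p2", 3),
                        sim_followup_row("p2", 4, hospitalized = TRUE),
                        sim_followup_row("p2", 7))
  out <- assess_sae(f)
  expect_true(out$severe_adverse_event)
  expect_equal(out$sae_kind, "secondary_admission")

  # a day-0 primary-referral admission is not a secondary admission
  f <- dplyr::bind_rows(sim_followup_row("p3", 0, hospitalized = TRUE),
                        sim_followup_row("p3", 3), sim_followup_row("p3", 7))
  out <- assess_sae(f)
  expect_false(out$severe_adverse_event)
  expect_true(is.na(out$sae_kind))
})
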