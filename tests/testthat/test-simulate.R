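test_that("cohort generation is deterministic and extensible under the root seed", {
  cfg <- cohort_config(n = 120, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  # hierarchical substreams: growing n extends the cohort without reshuffling
  big <- generate_cohort(cohort_config(n = 240, seed = 5))
  expect_identical(a, big[seq_len(120), ])

  # a different seed changes realizations
  expect_false(identical(a$temperature_c,
                         generate_cohort(cohort_config(n = 120, seed = 6))$temperature_c))
})

test_that("generated records always satisfy the enrollment invariants (round trip)", {
  coh <- generate_cohort(cohort_config(n = 300, seed = 11))
  expect_silent(validate_patients(cohort_patients(coh)))
  expect_true(all(coh$temperature_c >= 37.5))
  expect_true(all(coh$age_months >= 2 & coh$age_months <= 59))
  expect_true(all(coh$weight_kg >= 2.5))
})

test_that("configured marginals are recovered at scale", {
  cfg <- cohort_config(n = 2000, seed = 3)
  coh <- generate_cohort(cfg)

  # age-band shares within +-3 pp of the configured weights
  shares <- c(mean(coh$age_months <= 11),
              mean(coh$age_months >= 12 & coh$age_months <= 23),
              mean(coh$age_months >= 24))
  expect_true(all(abs(shares - cfg$age_weights) < 0.03))

  # degenerate mix: all-malaria cohort is mRDT-positive at the test sensitivity
  mal <- generate_cohort(cohort_config(n = 1000, seed = 3,
                                       etiology_mix = c(malaria = 1)))
  expect_true(all(mal$latent_condition == "malaria"))
  expect_equal(mean(mal$mrdt_positive), 0.97, tolerance = 0.02)
})

test_that("follow-up simulation responds to management: untreated bacterial disease fails more", {
  cfg <- cohort_config(n = 600, seed = 9,
                       etiology_mix = c(bacterial_pneumonia = 1))
  coh <- generate_cohort(cfg)
  patients <- cohort_patients(coh)

  treat_all <- routine_care_policy(patients, antibiotic_prob = 1, seed = 1)
  treat_none <- routine_care_policy(patients, antibiotic_prob = 0, seed = 1)

  f_yes <- simulate_followup(coh, treat_all, cfg, seed = 100)
  f_no <- simulate_followup(coh, treat_none, cfg, seed = 100)
  fail_yes <- mean(assess_failure(f_yes, patients)$clinical_failure, na.rm = TRUE)
  fail_no <- mean(assess_failure(f_no, patients)$clinical_failure, na.rm = TRUE)
  expect_gt(fail_no, fail_yes)
})

test_that("zero loss-to-follow-up leaves no one lost", {
  cfg <- cohort_config(n = 200, seed = 13, ltf_probability = 0)
  coh <- generate_cohort(cfg)
  mgmt <- classify_epoct(cohort_patients(coh))
  f <- simulate_followup(coh, mgmt, cfg)
  out <- assess_failure(f, cohort_patients(coh))
  expect_false(any(out$lost_to_followup))
})

test_that("routine-care policy prescribes at its configured probability", {
  coh <- generate_cohort(cohort_config(n = 3000, seed = 21))
  pol <- routine_care_policy(cohort_patients(coh), seed = 4)
  expect_equal(mean(pol$antibiotic_day0), 0.949, tolerance = 0.015)
})

test_that("null comparison: the same engine in both arms centers the risk difference on zero", {
  rds <- vapply(1:12, function(k) {
    sim <- simulate_trial(cohort_config(n = 800, seed = 3000 + k),
                          engine_a = "epoct", engine_b = "epoct")
    sim$report$estimate[sim$report$label == "clinical_failure_rd"]
  }, numeric(1))
  expect_lt(abs(mean(rds)), 0.9)  # pp; per-replicate SE ~1.1 pp
})

test_that("end-to-end simulated trial: e-POCT arm fails no more than ALMANACH across seeds", {
  for (sd in c(101, 202)) {
    sim <- simulate_trial(cohort_config(n = 2500, seed = sd))
    g <- glance(sim)
    expect_lte(g$failure_a, g$failure_b)
    expect_s3_class(tidy(sim), "tbl_df")
  }
})
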