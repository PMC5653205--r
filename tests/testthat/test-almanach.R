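std <- reference_standards()

test_that("ALMANACH classifies from clinical signs with its own thresholds", {
  # very fast breathing (>= 50/min regardless of age) -> clinical pneumonia
  r <- classify_almanach(new_patient(age_months = 36, weight_kg = 14, cough = TRUE,
                                     respiratory_rate_per_min = 52), std)
  expect_true("clinical_pneumonia" %in% r$classifications[[1]])
  expect_true(r$antibiotic_day0)
  expect_false(r$referral)

  # one convulsion is already severe here (vs two for e-POCT)
  p <- new_patient(convulsions_count = 1, crp_band = "lt10", pct_ug_per_l = 0.4,
                   typhidot_positive = FALSE, urine_dipstick_positive = FALSE)
  expect_true("cns_danger" %in% classify_almanach(p, std)$classifications[[1]])
  expect_false("cns_danger" %in% classify_epoct(p, std)$classifications[[1]])

  # FWS at 18 months with a positive dipstick -> likely bacterial (urinary), antibiotic
  r <- classify_almanach(new_patient(urine_dipstick_positive = TRUE), std)
  expect_true("fws_bacterial" %in% r$classifications[[1]])
  expect_true(r$antibiotic_day0)

  # purulent ear discharge feeds the same likely-bacterial accounting
  r <- classify_almanach(new_patient(ear_discharge = TRUE,
                                     urine_dipstick_positive = FALSE), std)
  expect_true("fws_bacterial" %in% r$classifications[[1]])

  # RR = 50 boundary: inclusive
  r50 <- classify_almanach(new_patient(cough = TRUE, respiratory_rate_per_min = 50), std)
  r49 <- classify_almanach(new_patient(cough = TRUE, respiratory_rate_per_min = 49), std)
  expect_true(r50$antibiotic_day0)
  expect_false(r49$antibiotic_day0)
  expect_true("urti" %in% r49$classifications[[1]])

  # skin lesions: > 4 cm or with red streaks is severe, small single lesions are not
  r <- classify_almanach(new_patient(skin_lesion_kind = "cellulitis",
                                     skin_lesion_diameter_cm = 5), std)
  expect_true("other_severe" %in% r$classifications[[1]])
  expect_true(r$referral)
  r <- classify_almanach(new_patient(skin_lesion_kind = "cellulitis",
                                     skin_lesion_diameter_cm = 2), std)
  expect_true("skin_infection" %in% r$classifications[[1]])
  expect_true(r$antibiotic_day0)  # ALMANACH treats all non-severe skin infections
  expect_false(r$referral)
})

test_that("ALMANACH test ordering: dipstick under 2 years or with dysuria, Typhidot from 2 years", {
  p <- new_patient(age_months = 30, weight_kg = 13, typhidot_positive = NA)
  expect_equal(required_tests_almanach(p, std), "typhidot")

  p <- new_patient(age_months = 10, weight_kg = 8, urine_dipstick_positive = NA)
  expect_equal(required_tests_almanach(p, std), "urine_dipstick")

  # dysuria alone suffices for a dipstick, even with cough
  p <- new_patient(age_months = 30, weight_kg = 13, cough = TRUE, dysuria = TRUE,
                   urine_dipstick_positive = NA)
  expect_equal(required_tests_almanach(p, std), "urine_dipstick")

  # pneumonia branch needs nothing beyond the malaria test
  p <- new_patient(age_months = 10, weight_kg = 8, cough = TRUE,
                   respiratory_rate_per_min = 55,
                   urine_dipstick_positive = NA, typhidot_positive = NA)
  expect_true(is.na(required_tests_almanach(p, std)))

  expect_error(classify_almanach(new_patient(age_months = 30, weight_kg = 13,
                                             typhidot_positive = NA), std),
               "typhidot", class = "epoctr_incomplete_workup_error")
})

test_that("ALMANACH never consumes biomarker or oximetry fields (engine isolation)", {
  base <- new_patient(cough = TRUE, respiratory_rate_per_min = 45)
  perturbed <- dplyr::mutate(base, hb_g_per_l = 30, sao2_percent = 60,
                             glucose_mmol_per_l = 2.0, crp_band = "ge80",
                             pct_ug_per_l = 99)
  a <- classify_almanach(base, std)
  b <- classify_almanach(perturbed, std)
  expect_identical(a$classifications, b$classifications)
  expect_identical(a$referral, b$referral)
  expect_identical(a$antibiotic_day0, b$antibiotic_day0)
})

test_that("behavioral contrast: ALMANACH prescribes for moderate tachypnea where e-POCT does not", {
  # cough, RR in [50, 97th percentile), CRP below the bacterial band
  for (rr in c(50, 54)) {
    p <- new_patient(age_months = 18, cough = TRUE, respiratory_rate_per_min = rr,
                     crp_band = "10_39")
    expect_true(classify_almanach(p, std)$antibiotic_day0)
    expect_false(classify_epoct(p, std)$antibiotic_day0)
  }
})

test_that("engine agrees with the independent naive evaluator on a small lattice", {
  lattice <- make_lattice(small = TRUE)
  res <- classify_almanach(lattice, std)
  naive <- naive_classify(lattice, std, naive_almanach)
  expect_identical(engine_mismatches(res, naive), integer(0))
})
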