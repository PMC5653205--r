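std <- reference_standards()

test_that("e-POCT severe triage refers and treats before referral", {
  # haemoglobin below 60 g/l alone -> severe anaemia, referral
  r <- classify_epoct(new_patient(hb_g_per_l = 55), std)
  expect_setequal(r$classifications[[1]], "severe_anemia")
  expect_true(r$referral)
  expect_true(r$antibiotic_day0)
  expect_equal(r$antibiotic_reason, "severe_anemia")
  expect_true("im_antibiotic" %in% r$treatments[[1]])

  # MUAC below 115 mm counts only above 6 months of age
  r <- classify_epoct(new_patient(age_months = 8, muac_mm = 110, weight_kg = 7), std)
  expect_true("severe_malnutrition" %in% r$classifications[[1]])
  expect_true(r$referral)
  r <- classify_epoct(new_patient(age_months = 5, muac_mm = 110, weight_kg = 6.5,
                                  crp_band = "lt10", pct_ug_per_l = 0.4), std)
  expect_false(r$referral)

  # severe classification + positive mRDT adds severe malaria
  r <- classify_epoct(new_patient(hb_g_per_l = 55, mrdt_positive = TRUE), std)
  expect_setequal(r$classifications[[1]], c("severe_anemia", "severe_malaria"))
  expect_true("antimalarial" %in% r$treatments[[1]])
})

test_that("CRP/PCT gates decide antibiotics in the respiratory and FWS branches", {
  # fever without source, malaria-negative, CRP low but PCT 5.1 -> likely bacterial
  r <- classify_epoct(new_patient(hb_g_per_l = 110, sao2_percent = 98,
                                  crp_band = "10_39", pct_ug_per_l = 5.1), std)
  expect_setequal(r$classifications[[1]], "fws_bacterial")
  expect_true(r$antibiotic_day0)

  # tachypneic cough with low CRP -> viral LRTI, bronchodilator, no antibiotic
  r <- classify_epoct(new_patient(cough = TRUE, respiratory_rate_per_min = 52,
                                  crp_band = "lt10"), std)
  expect_setequal(r$classifications[[1]], "viral_lrti")
  expect_false(r$antibiotic_day0)
  expect_true("bronchodilator" %in% r$treatments[[1]])

  # positive mRDT without severe signs -> uncomplicated malaria, antimalarial only
  r <- classify_epoct(new_patient(mrdt_positive = TRUE), std)
  expect_setequal(r$classifications[[1]], "uncomplicated_malaria")
  expect_false(r$antibiotic_day0)
  expect_true("antimalarial" %in% r$treatments[[1]])

  # nothing but fever, all tests unremarkable -> likely viral FWS, no antibiotic
  r <- classify_epoct(new_patient(crp_band = "lt10", pct_ug_per_l = 0.4), std)
  expect_setequal(r$classifications[[1]], "fws_viral")
  expect_false(r$antibiotic_day0)
})

test_that("threshold boundaries behave exactly as specified", {
  # Hb = 60 is NOT severe (strict <): classified non-severe anaemia instead
  r <- classify_epoct(new_patient(hb_g_per_l = 60, crp_band = "lt10",
                                  pct_ug_per_l = 0.4), std)
  expect_false("severe_anemia" %in% r$classifications[[1]])
  expect_true("non_severe_anemia" %in% r$classifications[[1]])
  expect_true("iron" %in% r$treatments[[1]])

  # PCT = 4.0 IS bacterial (>=)
  r <- classify_epoct(new_patient(crp_band = "lt10", pct_ug_per_l = 4.0), std)
  expect_true("fws_bacterial" %in% r$classifications[[1]])

  # CRP band ge80 IS bacterial (tachypneic but below the severe 97th centile)
  r <- classify_epoct(new_patient(cough = TRUE, respiratory_rate_per_min = 50,
                                  crp_band = "ge80"), std)
  expect_true("bacterial_lrti" %in% r$classifications[[1]])

  # SaO2 = 90 is not hypoxemic; 89 is
  expect_false(classify_epoct(new_patient(sao2_percent = 90, crp_band = "lt10",
                                          pct_ug_per_l = 0.4), std)$referral)
  expect_true(classify_epoct(new_patient(sao2_percent = 89), std)$referral)
})

test_that("the staged POCT cascade orders tests in sequence and only when indicated", {
  # mRDT, Hb, SaO2 first, in order
  p <- new_patient(mrdt_positive = NA, hb_g_per_l = NA, sao2_percent = NA)
  expect_equal(required_tests_epoct(p, std), "mrdt")
  p$mrdt_positive <- FALSE
  expect_equal(required_tests_epoct(p, std), "hb")
  p$hb_g_per_l <- 105
  expect_equal(required_tests_epoct(p, std), "sao2")

  # cough without tachypnea needs no CRP: cascade complete
  p <- new_patient(cough = TRUE, respiratory_rate_per_min = 30)
  expect_true(is.na(required_tests_epoct(p, std)))

  # FWS with negative mRDT and sub-bacterial CRP demands PCT
  p <- new_patient(crp_band = "10_39")
  expect_equal(required_tests_epoct(p, std), "pct")

  # FWS with positive mRDT is the malaria branch: no CRP at all
  p <- new_patient(mrdt_positive = TRUE)
  expect_true(is.na(required_tests_epoct(p, std)))

  # missing required test is an incomplete-workup error naming the test
  expect_error(classify_epoct(new_patient(crp_band = "10_39"), std),
               "pct", class = "epoctr_incomplete_workup_error")
  expect_error(classify_epoct(new_patient(hb_g_per_l = NA), std),
               "hb", class = "epoctr_incomplete_workup_error")
})

test_that("management invariants hold on a random synthetic cohort", {
  coh <- generate_cohort(cohort_config(n = 400, seed = 42))
  res <- classify_epoct(cohort_patients(coh), std, trace = TRUE)

  severe <- vapply(res$classifications,
                   function(cl) any(cl %in% severe_classifications()), logical(1))
  expect_identical(res$referral, severe)
  expect_true(all(res$antibiotic_day0[severe]))

  # antibiotic_reason is always one of the fired classifications
  with_ab <- which(res$antibiotic_day0)
  expect_true(all(mapply(function(reason, cl) reason %in% cl,
                         res$antibiotic_reason[with_ab],
                         res$classifications[with_ab])))

  # rule traces never reference a biomarker absent from tests_performed
  crp_rules_fired <- vapply(seq_len(nrow(res)), function(i) {
    tr <- res$rule_trace[[i]]
    any(tr$fired & tr$rule_id %in% c("bacterial_lrti", "fws_bacterial", "fws_viral"))
  }, logical(1))
  has_crp <- vapply(res$tests_performed, function(x) "crp" %in% x, logical(1))
  fws_cls <- vapply(res$classifications,
                    function(cl) any(c("fws_viral", "fws_bacterial", "bacterial_lrti") %in% cl),
                    logical(1))
  mrdt_neg_fws <- fws_cls & !cohort_patients(coh)$mrdt_positive
  expect_true(all(has_crp[mrdt_neg_fws & crp_rules_fired]))
})

test_that("engine agrees with the independent naive evaluator on a small lattice", {
  lattice <- make_lattice(small = TRUE)
  res <- classify_epoct(lattice, std)
  naive <- naive_classify(lattice, std, naive_epoct)
  expect_identical(engine_mismatches(res, naive), integer(0))
})
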