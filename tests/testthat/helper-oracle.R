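# Independent naive rule evaluators: straight per-row transliterations of the
# two algorithms' published criteria, written without reference to the
# vectorized engine code. They do their own percentile-grid interpolation and
# their own LMS arithmetic, and return (classifications, referral,
# antibiotic) per patient.

naive_grid_value <- function(grid, age, temp) {
  band <- grid[grid$age_lo <= age & grid$age_hi >= age, ]
  band <- band[order(band$temp_c), ]
  t <- min(max(temp, min(band$temp_c)), max(band$temp_c))
  stats::approx(band$temp_c, band$value, xout = t)$y
}

naive_wfa_z <- function(age, sex, weight, std) {
  ref <- std$wfa_reference
  r <- ref[ref$age_months == floor(age) & ref$sex == sex, ]
  ((weight / r$median_kg)^r$lms_l - 1) / (r$lms_l * r$lms_s)
}

naive_gi <- function(stools, vomits) {
  stools > 5 || (stools >= 3 && vomits >= 1) || vomits > 3
}

# e-POCT, one patient at a time; expects a complete POCT panel.
naive_epoct <- function(q, std) {
  rr75 <- naive_grid_value(std$rr75_grid, q$age_months, q$temperature_c)
  rr97 <- naive_grid_value(std$rr97_grid, q$age_months, q$temperature_c)
  hr90 <- naive_grid_value(std$hr90_grid, q$age_months, q$temperature_c)
  wfa <- naive_wfa_z(q$age_months, q$sex, q$weight_kg, std)

  cls <- character()
  if (q$severe_lethargy || q$stiff_neck || q$convulsions_count >= 2) {
    cls <- c(cls, "cns_danger")
  }
  if (q$speech_level == "single_words_or_grunts" ||
      (q$speech_level == "short_phrases_or_short_cries" && q$lower_chest_indrawing) ||
      q$respiratory_rate_per_min >= rr97 ||
      (!is.na(q$sao2_percent) && q$sao2_percent < 90)) {
    cls <- c(cls, "severe_respiratory")
  }
  if (!is.na(q$hb_g_per_l) && q$hb_g_per_l < 60) cls <- c(cls, "severe_anemia")
  if (wfa < -3 || (!is.na(q$muac_mm) && q$muac_mm < 115 && q$age_months > 6)) {
    cls <- c(cls, "severe_malnutrition")
  }
  if (q$not_tolerating_oral_liquids && !is.na(q$heart_rate_per_min) &&
      q$heart_rate_per_min >= hr90) {
    cls <- c(cls, "severe_dehydration")
  }
  if (q$clouding_cornea || q$severe_mouth_ulcers) cls <- c(cls, "other_severe")
  # glucose is measured only when a danger/severe branch demands it
  glucose_demanded <- length(cls) > 0 || q$unable_to_drink ||
    q$not_tolerating_oral_liquids
  if (glucose_demanded && !is.na(q$glucose_mmol_per_l) &&
      q$glucose_mmol_per_l < 3.3) {
    cls <- c(cls, "hypoglycemia")
  }
  severe <- length(cls) > 0
  if (severe && q$mrdt_positive) cls <- c(cls, "severe_malaria")

  crp_hi <- !is.na(q$crp_band) && q$crp_band == "ge80"
  pct_hi <- !is.na(q$pct_ug_per_l) && q$pct_ug_per_l >= 4.0
  gi <- naive_gi(q$diarrhea_stools_24h, q$vomiting_episodes_24h)
  lesion <- !is.na(q$skin_lesion_kind)
  fws <- !q$cough && !gi && !lesion && !q$ear_discharge && !q$dysuria && !severe

  antibiotic <- severe
  if (!severe) {
    if (q$cough && q$respiratory_rate_per_min >= rr75) {
      if (crp_hi) {
        cls <- c(cls, "bacterial_lrti"); antibiotic <- TRUE
      } else {
        cls <- c(cls, "viral_lrti")
      }
    } else if (q$cough) {
      cls <- c(cls, "urti")
    }
    if (q$mrdt_positive) cls <- c(cls, "uncomplicated_malaria")
    if (fws && !q$mrdt_positive) {
      if (crp_hi || pct_hi) {
        cls <- c(cls, "fws_bacterial"); antibiotic <- TRUE
      } else {
        cls <- c(cls, "fws_viral")
      }
    }
    if (lesion && q$skin_lesion_kind %in% c("abscess", "cellulitis",
                                            "impetigo_pyoderma")) {
      antibiotic <- TRUE
    }
  }
  if (gi) cls <- c(cls, "gi_dehydration")
  if (lesion) cls <- c(cls, "skin_infection")
  if (!is.na(q$hb_g_per_l) && q$hb_g_per_l >= 60) {
    cutoff <- if (q$age_months <= 6) 90 else if (q$age_months <= 24) 100 else 110
    if (q$hb_g_per_l < cutoff) cls <- c(cls, "non_severe_anemia")
  }
  list(classifications = cls, referral = severe, antibiotic = antibiotic)
}

# ALMANACH, one patient at a time.
naive_almanach <- function(q, std) {
  cls <- character()
  if (q$severe_lethargy || q$stiff_neck || q$convulsions_count >= 1) {
    cls <- c(cls, "cns_danger")
  }
  if (q$lower_chest_indrawing || q$cyanosis || q$stridor) {
    cls <- c(cls, "severe_respiratory")
  }
  if (q$severe_palmar_pallor) cls <- c(cls, "severe_anemia")
  ndehyd <- sum(q$severe_lethargy, q$sunken_eyes, q$unable_to_drink,
                q$skin_pinch == "very_slow")
  if (q$vomits_everything || ndehyd >= 2) cls <- c(cls, "severe_dehydration")
  if (q$visible_severe_wasting || q$edema_both_feet) {
    cls <- c(cls, "severe_malnutrition")
  }
  lesion <- !is.na(q$skin_lesion_kind)
  lesion_severe <- lesion && (q$skin_lesion_diameter_cm > 4 || q$skin_red_streaks ||
                                q$skin_tender_nodes || q$skin_multiple_abscesses)
  if (q$jaundice || q$tender_swelling_behind_ear || lesion_severe) {
    cls <- c(cls, "other_severe")
  }
  severe <- length(cls) > 0

  gi <- naive_gi(q$diarrhea_stools_24h, q$vomiting_episodes_24h)
  fws <- !q$cough && !gi && !lesion && !severe
  dip <- !is.na(q$urine_dipstick_positive) && q$urine_dipstick_positive
  typ <- !is.na(q$typhidot_positive) && q$typhidot_positive

  antibiotic <- severe
  if (!severe) {
    if (q$cough && q$respiratory_rate_per_min >= 50) {
      cls <- c(cls, "clinical_pneumonia"); antibiotic <- TRUE
    } else if (q$cough) {
      cls <- c(cls, "urti")
    }
    if (q$mrdt_positive) cls <- c(cls, "uncomplicated_malaria")
    bact <- q$ear_discharge ||
      (((fws && q$age_months < 24) || q$dysuria) && dip) ||
      (fws && q$age_months >= 24 && typ)
    if (bact) {
      cls <- c(cls, "fws_bacterial"); antibiotic <- TRUE
    } else if (fws && !q$mrdt_positive) {
      cls <- c(cls, "fws_viral")
    }
    if (lesion && !lesion_severe) antibiotic <- TRUE
  }
  # a small uncomplicated lesion is recorded even alongside a severe
  # classification (multiple classifications are allowed)
  if (lesion && !lesion_severe) cls <- c(cls, "skin_infection")
  nsome <- sum(q$restless_irritable, q$sunken_eyes, q$drinks_eagerly,
               q$skin_pinch == "slow")
  if (nsome >= 2) cls <- c(cls, "gi_dehydration")
  list(classifications = cls, referral = severe, antibiotic = antibiotic)
}

# Run a naive evaluator over a patient tibble; returns list of per-row results.
naive_classify <- function(patients, std, fn) {
  cols <- as.list(patients)
  n <- nrow(patients)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    q <- lapply(cols, `[`, i)
    out[[i]] <- fn(q, std)
  }
  out
}

# Compare engine output against naive results; returns indices of mismatches.
engine_mismatches <- function(engine_result, naive_results) {
  n <- nrow(engine_result)
  bad <- integer()
  for (i in seq_len(n)) {
    nv <- naive_results[[i]]
    if (!setequal(engine_result$classifications[[i]], nv$classifications) ||
        engine_result$referral[i] != nv$referral ||
        engine_result$antibiotic_day0[i] != nv$antibiotic) {
      bad <- c(bad, i)
    }
  }
  bad
}
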