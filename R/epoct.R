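#' Disease classification vocabulary
#'
#' The classification tokens produced by the rule engines. The severe subset
#' triggers referral; a patient can carry more than one classification.
#'
#' @return `classification_levels()`: all tokens; `severe_classifications()`:
#'   the severe subset.
#' @export
classification_levels <- function() {
  c(severe_classifications(),
    "clinical_pneumonia", "urti", "viral_lrti", "bacterial_lrti",
    "fws_viral", "fws_bacterial", "uncomplicated_malaria",
    "gi_dehydration", "skin_infection", "non_severe_anemia")
}

#' @rdname classification_levels
#' @export
severe_classifications <- function() {
  c("cns_danger", "severe_respiratory", "severe_anemia", "severe_malnutrition",
    "severe_dehydration", "hypoglycemia", "other_severe", "severe_malaria")
}

## ---------------------------------------------------------------------------
## Shared predicate helpers (vectorized over a validated patient tibble)

# Significant diarrhea/vomiting: >5 loose stools/24 h, or >=3 loose stools
# with any emesis, or >3 emeses/24 h.
gi_significant <- function(p) {
  p$diarrhea_stools_24h > 5 |
    (p$diarrhea_stools_24h >= 3 & p$vomiting_episodes_24h >= 1) |
    p$vomiting_episodes_24h > 3
}

has_skin_lesion <- function(p) !is.na(p$skin_lesion_kind)

# e-POCT severe rules that need no POCT beyond oximetry/Hb; used both by the
# classifier and by the test-ordering cascade.
epoct_severe_clinical <- function(p, s, rr97, hr90, wfa) {
  list(
    cns_danger = p$severe_lethargy | p$stiff_neck |
      p$convulsions_count >= s$convulsions_severe_epoct,
    severe_respiratory = p$speech_level == "single_words_or_grunts" |
      (p$speech_level == "short_phrases_or_short_cries" & p$lower_chest_indrawing) |
      p$respiratory_rate_per_min >= rr97 |
      (!is.na(p$sao2_percent) & p$sao2_percent < s$sao2_severe_threshold),
    severe_anemia = !is.na(p$hb_g_per_l) & p$hb_g_per_l < s$hb_severe_g_l,
    severe_malnutrition = wfa < s$wfa_z_severe |
      (!is.na(p$muac_mm) & p$muac_mm < s$muac_severe_mm &
         p$age_months > s$muac_min_age_months),
    severe_dehydration = p$not_tolerating_oral_liquids &
      !is.na(p$heart_rate_per_min) & p$heart_rate_per_min >= hr90,
    other_severe = p$clouding_cornea | p$severe_mouth_ulcers
  )
}

# Danger signs that trigger glucose measurement in the severe branch.
epoct_needs_glucose <- function(p, severe_clinical) {
  Reduce(`|`, severe_clinical) | p$unable_to_drink | p$not_tolerating_oral_liquids
}

# Fever without source under e-POCT: no localizing complaint and not severe.
epoct_fws <- function(p, severe_any) {
  !p$cough & !gi_significant(p) & !has_skin_lesion(p) &
    !p$ear_discharge & !p$dysuria & !severe_any
}

## ---------------------------------------------------------------------------

#' Next point-of-care test required by the e-POCT cascade
#'
#' e-POCT stages its POCTs: malaria rapid test, haemoglobin and pulse
#' oximetry for every child; glucose when a severe/danger branch requires it;
#' CRP for coughing children with tachypnea (respiratory rate at or above the
#' 75th percentile for age and temperature) and for fever without source with
#' a negative malaria test; procalcitonin only in the fever-without-source
#' branch when the malaria test is negative and CRP is below the bacterial
#' band. Columns holding `NA` are treated as not-yet-performed.
#'
#' @param patients Validated patient tibble (partial POCT columns allowed).
#' @param standards Threshold registry.
#' @return Character vector: the next test token per patient
#'   (`"mrdt"`, `"hb"`, `"sao2"`, `"glucose"`, `"crp"`, `"pct"`) or `NA`
#'   when the cascade is complete. Total function: never errors on content.
#' @export
required_tests_epoct <- function(patients, standards = reference_standards()) {
  s <- as_standards(standards)
  p <- tibble::as_tibble(patients)
  n <- nrow(p)
  out <- rep(NA_character_, n)

  pending <- is.na(p$mrdt_positive)
  out[pending] <- "mrdt"
  todo <- is.na(out) & is.na(p$hb_g_per_l)
  out[todo] <- "hb"
  todo <- is.na(out) & is.na(p$sao2_percent)
  out[todo] <- "sao2"

  rr97 <- rr_percentile(p$age_months, p$temperature_c, 97, s)
  rr75 <- rr_percentile(p$age_months, p$temperature_c, 75, s)
  hr90 <- hr_percentile_90(p$age_months, p$temperature_c, s)
  wfa <- weight_for_age_z(p$age_months, p$sex, p$weight_kg, s)
  sev <- epoct_severe_clinical(p, s, rr97, hr90, wfa)

  todo <- is.na(out) & epoct_needs_glucose(p, sev) & is.na(p$glucose_mmol_per_l)
  out[todo] <- "glucose"

  hypo <- !is.na(p$glucose_mmol_per_l) & p$glucose_mmol_per_l < s$glucose_hypo_mmol_l
  severe_any <- Reduce(`|`, sev) | hypo
  fws <- epoct_fws(p, severe_any)
  crp_needed <- !severe_any &
    ((p$cough & p$respiratory_rate_per_min >= rr75) | (fws & !p$mrdt_positive))
  todo <- is.na(out) & !is.na(p$mrdt_positive) & crp_needed & is.na(p$crp_band)
  out[todo] <- "crp"

  pct_needed <- fws & !p$mrdt_positive & !is.na(p$crp_band) &
    crp_band_rank(p$crp_band) < crp_band_rank(s$crp_bacterial_band)
  pct_needed[is.na(pct_needed)] <- FALSE
  todo <- is.na(out) & pct_needed & is.na(p$pct_ug_per_l)
  out[todo] <- "pct"
  out
}

#' Classify patients with the e-POCT algorithm
#'
#' Evaluates the e-POCT cascade: the severe block first (CNS danger signs,
#' severe respiratory distress including hypoxemia and severe tachypnea,
#' severe anaemia by haemoglobin, severe malnutrition by weight-for-age
#' z-score and MUAC, severe dehydration with severe tachycardia,
#' hypoglycaemia, and the corneal-clouding/mouth-ulcer trigger), adding a
#' severe-malaria label when any severe classification coincides with a
#' positive malaria rapid test. Non-severe patients then flow through the
#' respiratory branch (CRP-gated bacterial vs viral lower respiratory tract
#' infection, else upper respiratory infection), uncomplicated malaria,
#' significant diarrhea/vomiting, skin lesions, the CRP/PCT-gated fever
#' without source branch, and the age-banded non-severe anaemia rule.
#'
#' Management follows the classification set: referral exactly for severe
#' disease (with a pre-referral intramuscular antibiotic), day-0 antibiotics
#' otherwise only for bacterial lower respiratory tract infection, likely
#' bacterial fever without source, or a bacterial skin lesion (abscess,
#' cellulitis, impetigo/pyoderma), plus branch-specific supportive care.
#'
#' @param patients Validated patient tibble; every POCT the cascade demands
#'   must be present (see [required_tests_epoct()]), otherwise a classed
#'   incomplete-workup error names the missing test.
#' @param standards Threshold registry.
#' @param trace If `TRUE`, attach a `rule_trace` list-column of
#'   (rule_id, fired) tibbles.
#' @return A tibble, one row per patient: `patient_id`, `algorithm`,
#'   `classifications` (list of tokens), `referral`, `antibiotic_day0`,
#'   `antibiotic_reason`, `treatments` (list), `tests_performed` (list), and
#'   optionally `rule_trace`.
#' @examples
#' p <- new_patient(hb_g_per_l = 55)
#' classify_epoct(p)$referral
#' @export
classify_epoct <- function(patients, standards = reference_standards(),
                           trace = FALSE) {
  s <- as_standards(standards)
  p <- validate_patients(patients, s)
  n <- nrow(p)

  missing_test <- required_tests_epoct(p, s)
  if (any(!is.na(missing_test))) {
    i <- which(!is.na(missing_test))[1]
    abort_workup(paste0("incomplete workup: test '", missing_test[i],
                        "' missing for patient ", p$patient_id[i]))
  }

  rr97 <- rr_percentile(p$age_months, p$temperature_c, 97, s)
  rr75 <- rr_percentile(p$age_months, p$temperature_c, 75, s)
  hr90 <- hr_percentile_90(p$age_months, p$temperature_c, s)
  wfa <- weight_for_age_z(p$age_months, p$sex, p$weight_kg, s)

  sev <- epoct_severe_clinical(p, s, rr97, hr90, wfa)
  glucose_needed <- epoct_needs_glucose(p, sev)
  sev$hypoglycemia <- glucose_needed & !is.na(p$glucose_mmol_per_l) &
    p$glucose_mmol_per_l < s$glucose_hypo_mmol_l
  severe_base <- Reduce(`|`, sev)
  sev$severe_malaria <- severe_base & p$mrdt_positive
  severe_any <- severe_base

  crp_bact <- !is.na(p$crp_band) &
    crp_band_rank(p$crp_band) >= crp_band_rank(s$crp_bacterial_band)
  pct_bact <- !is.na(p$pct_ug_per_l) & p$pct_ug_per_l >= s$pct_bacterial_ug_l
  tachypnea75 <- p$respiratory_rate_per_min >= rr75
  fws <- epoct_fws(p, severe_any)
  gi <- gi_significant(p)
  lesion <- has_skin_lesion(p)
  bact_skin <- lesion & p$skin_lesion_kind %in% bacterial_skin_kinds()

  cls <- list(
    cns_danger = sev$cns_danger,
    severe_respiratory = sev$severe_respiratory,
    severe_anemia = sev$severe_anemia,
    severe_malnutrition = sev$severe_malnutrition,
    severe_dehydration = sev$severe_dehydration,
    hypoglycemia = sev$hypoglycemia,
    other_severe = sev$other_severe,
    severe_malaria = sev$severe_malaria,
    # non-severe branches (severe patients are referred before biomarker
    # testing, so CRP/PCT-gated branches apply to non-severe patients only;
    # test-free concomitant findings are still recorded)
    bacterial_lrti = !severe_any & p$cough & tachypnea75 & crp_bact,
    viral_lrti = !severe_any & p$cough & tachypnea75 & !crp_bact,
    urti = !severe_any & p$cough & !tachypnea75,
    uncomplicated_malaria = !severe_any & p$mrdt_positive,
    fws_bacterial = fws & !p$mrdt_positive & (crp_bact | pct_bact),
    fws_viral = fws & !p$mrdt_positive & !(crp_bact | pct_bact),
    gi_dehydration = gi,
    skin_infection = lesion,
    non_severe_anemia = !is.na(p$hb_g_per_l) & p$hb_g_per_l >= s$hb_severe_g_l &
      p$hb_g_per_l < hb_anemia_cutoff(p$age_months, s)
  )

  antibiotic <- severe_any | cls$bacterial_lrti | cls$fws_bacterial |
    (!severe_any & bact_skin)

  reason <- rep(NA_character_, n)
  reason_order <- c(severe_classifications(), "bacterial_lrti", "fws_bacterial",
                    "skin_infection")
  for (nm in rev(reason_order)) {
    hit <- switch(nm, skin_infection = !severe_any & bact_skin, cls[[nm]])
    reason[hit] <- nm
  }
  reason[!antibiotic] <- NA_character_

  treatments <- purrr::map(seq_len(n), function(i) {
    tk <- character()
    if (severe_any[i]) tk <- c(tk, "referral", "im_antibiotic")
    if (!severe_any[i] && antibiotic[i]) tk <- c(tk, "oral_antibiotic")
    if (cls$uncomplicated_malaria[i] || cls$severe_malaria[i]) tk <- c(tk, "antimalarial")
    if (cls$gi_dehydration[i]) tk <- c(tk, "ors")
    if (cls$viral_lrti[i]) tk <- c(tk, "bronchodilator")
    if (cls$non_severe_anemia[i]) tk <- c(tk, "iron")
    if (cls$skin_infection[i] && !bact_skin[i]) tk <- c(tk, "skin_topical")
    c(tk, "antipyretic")
  })

  crp_required <- !severe_any &
    ((p$cough & tachypnea75) | (fws & !p$mrdt_positive))
  pct_required <- fws & !p$mrdt_positive & !is.na(p$crp_band) &
    crp_band_rank(p$crp_band) < crp_band_rank(s$crp_bacterial_band)
  tests <- purrr::map(seq_len(n), function(i) {
    tk <- c("mrdt", "hb", "sao2")
    if (glucose_needed[i]) tk <- c(tk, "glucose")
    if (crp_required[i]) tk <- c(tk, "crp")
    if (isTRUE(pct_required[i])) tk <- c(tk, "pct")
    tk
  })

  res <- tibble::tibble(
    patient_id = p$patient_id,
    algorithm = "epoct",
    classifications = purrr::map(seq_len(n), function(i) {
      names(cls)[vapply(cls, `[`, logical(1), i)]
    }),
    referral = severe_any,
    antibiotic_day0 = antibiotic,
    antibiotic_reason = reason,
    treatments = treatments,
    tests_performed = tests
  )
  if (trace) {
    res$rule_trace <- purrr::map(seq_len(n), function(i) {
      tibble::tibble(rule_id = names(cls),
                     fired = vapply(cls, `[`, logical(1), i))
    })
  }
  class(res) <- c("epoctr_classification", class(res))
  res
}
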