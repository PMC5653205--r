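## ALMANACH: the IMCI-derived electronic comparator algorithm. It relies on
## clinical signs plus the malaria rapid test, urine dipstick and Typhidot;
## it never consumes CRP, PCT, SaO2, Hb or glucose (engine isolation).

almanach_severe <- function(p, s) {
  dehydration_signs <- (p$severe_lethargy) + (p$sunken_eyes) +
    (p$unable_to_drink) + (p$skin_pinch == "very_slow")
  lesion <- has_skin_lesion(p)
  list(
    cns_danger = p$severe_lethargy | p$stiff_neck |
      p$convulsions_count >= s$convulsions_severe_almanach,
    severe_respiratory = p$lower_chest_indrawing | p$cyanosis | p$stridor,
    severe_anemia = p$severe_palmar_pallor,
    severe_dehydration = p$vomits_everything | dehydration_signs >= 2,
    severe_malnutrition = p$visible_severe_wasting | p$edema_both_feet,
    other_severe = p$jaundice | p$tender_swelling_behind_ear |
      (lesion & (p$skin_lesion_diameter_cm > s$skin_lesion_severe_cm |
                   p$skin_red_streaks | p$skin_tender_nodes |
                   p$skin_multiple_abscesses))
  )
}

# Fever without source under ALMANACH: no cough, no significant
# diarrhea/vomiting, no skin lesion, not severe. Ear discharge and dysuria do
# not exclude it here — they feed the likely-bacterial leg directly.
almanach_fws <- function(p, severe_any) {
  !p$cough & !gi_significant(p) & !has_skin_lesion(p) & !severe_any
}

#' Next point-of-care test required by the ALMANACH cascade
#'
#' ALMANACH orders a malaria rapid test for every child; a urine dipstick for
#' children under 2 years with fever without source and for any non-severe
#' child with dysuria; and the Typhidot typhoid assay for children 2 years or
#' older with fever without source.
#'
#' @inheritParams required_tests_epoct
#' @return Character vector: `"mrdt"`, `"urine_dipstick"`, `"typhidot"` or
#'   `NA` when complete.
#' @export
required_tests_almanach <- function(patients, standards = reference_standards()) {
  s <- as_standards(standards)
  p <- tibble::as_tibble(patients)
  out <- rep(NA_character_, nrow(p))
  out[is.na(p$mrdt_positive)] <- "mrdt"

  severe_any <- Reduce(`|`, almanach_severe(p, s))
  fws <- almanach_fws(p, severe_any)
  dip_needed <- !severe_any & ((fws & p$age_months < 24) | p$dysuria)
  todo <- is.na(out) & dip_needed & is.na(p$urine_dipstick_positive)
  out[todo] <- "urine_dipstick"
  typh_needed <- fws & p$age_months >= 24
  todo <- is.na(out) & typh_needed & is.na(p$typhidot_positive)
  out[todo] <- "typhidot"
  out
}

#' Classify patients with the ALMANACH algorithm
#'
#' The IMCI-derived control cascade: severe disease from clinical signs alone
#' (CNS danger signs with a one-convulsion threshold, chest
#' indrawing/cyanosis/stridor, severe palmar pallor, the vomits-everything /
#' two-of-four severe dehydration rule, visible severe wasting or bilateral
#' pedal oedema, and jaundice / mastoid swelling / severe skin lesions);
#' non-severe clinical pneumonia at a respiratory rate of 50/min or more
#' regardless of age, upper respiratory infection otherwise in coughing
#' children, the two-of-four some-dehydration rule, non-severe skin lesions,
#' fever without source split into likely bacterial (purulent ear discharge,
#' positive urine dipstick under 2 years, positive Typhidot at 2 years or
#' older) versus likely viral, and uncomplicated malaria on a positive rapid
#' test. Antibiotics at day 0 go to severe disease, clinical pneumonia,
#' likely bacterial fever without source, and (non-severe) skin infection.
#'
#' @inheritParams classify_epoct
#' @return Same shape as [classify_epoct()], with `algorithm = "almanach"`.
#' @export
classify_almanach <- function(patients, standards = reference_standards(),
                              trace = FALSE) {
  s <- as_standards(standards)
  p <- validate_patients(patients, s)
  n <- nrow(p)

  missing_test <- required_tests_almanach(p, s)
  if (any(!is.na(missing_test))) {
    i <- which(!is.na(missing_test))[1]
    abort_workup(paste0("incomplete workup: test '", missing_test[i],
                        "' missing for patient ", p$patient_id[i]))
  }

  sev <- almanach_severe(p, s)
  severe_any <- Reduce(`|`, sev)
  fws <- almanach_fws(p, severe_any)
  lesion <- has_skin_lesion(p)

  dip_pos <- !is.na(p$urine_dipstick_positive) & p$urine_dipstick_positive
  typh_pos <- !is.na(p$typhidot_positive) & p$typhidot_positive
  fws_bact <- !severe_any &
    (p$ear_discharge |
       ((fws & p$age_months < 24 | p$dysuria) & dip_pos) |
       (fws & p$age_months >= 24 & typh_pos))

  some_dehydration <- (p$restless_irritable) + (p$sunken_eyes) +
    (p$drinks_eagerly) + (p$skin_pinch == "slow")

  cls <- list(
    cns_danger = sev$cns_danger,
    severe_respiratory = sev$severe_respiratory,
    severe_anemia = sev$severe_anemia,
    severe_malnutrition = sev$severe_malnutrition,
    severe_dehydration = sev$severe_dehydration,
    other_severe = sev$other_severe,
    clinical_pneumonia = !severe_any & p$cough &
      p$respiratory_rate_per_min >= s$almanach_very_fast_breathing,
    urti = !severe_any & p$cough &
      p$respiratory_rate_per_min < s$almanach_very_fast_breathing,
    uncomplicated_malaria = !severe_any & p$mrdt_positive,
    fws_bacterial = fws_bact,
    fws_viral = fws & !p$mrdt_positive & !fws_bact,
    gi_dehydration = some_dehydration >= 2,
    skin_infection = lesion &
      !(p$skin_lesion_diameter_cm > s$skin_lesion_severe_cm |
          p$skin_red_streaks | p$skin_tender_nodes | p$skin_multiple_abscesses)
  )

  antibiotic <- severe_any | cls$clinical_pneumonia | cls$fws_bacterial |
    cls$skin_infection

  reason <- rep(NA_character_, n)
  reason_order <- c("cns_danger", "severe_respiratory", "severe_anemia",
                    "severe_malnutrition", "severe_dehydration", "other_severe",
                    "clinical_pneumonia", "fws_bacterial", "skin_infection")
  for (nm in rev(reason_order)) reason[cls[[nm]]] <- nm
  reason[!antibiotic] <- NA_character_

  treatments <- purrr::map(seq_len(n), function(i) {
    tk <- character()
    if (severe_any[i]) tk <- c(tk, "referral", "im_antibiotic")
    if (!severe_any[i] && antibiotic[i]) tk <- c(tk, "oral_antibiotic")
    if (cls$uncomplicated_malaria[i]) tk <- c(tk, "antimalarial")
    if (cls$gi_dehydration[i] || cls$severe_dehydration[i]) tk <- c(tk, "ors")
    c(tk, "antipyretic")
  })

  dip_needed <- !severe_any & ((fws & p$age_months < 24) | p$dysuria)
  typh_needed <- fws & p$age_months >= 24
  tests <- purrr::map(seq_len(n), function(i) {
    tk <- "mrdt"
    if (dip_needed[i]) tk <- c(tk, "urine_dipstick")
    if (typh_needed[i]) tk <- c(tk, "typhidot")
    tk
  })

  res <- tibble::tibble(
    patient_id = p$patient_id,
    algorithm = "almanach",
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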