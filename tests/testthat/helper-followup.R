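# One follow-up observation row with unremarkable defaults.
sim_followup_row <- function(patient_id, day, contact_type = "visit", ...) {
  defaults <- list(
    patient_id = patient_id, day = day, contact_type = contact_type,
    temperature_c = 36.8, fever_reported = FALSE,
    caregiver_considers_ill = FALSE, respiratory_rate_per_min = 30,
    heart_rate_per_min = 120, sao2_percent = 98, cough_history = FALSE,
    lower_chest_indrawing = FALSE, coma = FALSE, convulsions_24h = 0,
    unable_to_drink_or_breastfeed = FALSE, diarrhea_stools_per_day = 0,
    dehydration_requiring_facility_care = FALSE,
    skin_infection_requiring_systemic_or_facility_care = FALSE,
    new_significant_symptom = FALSE, hb_g_per_l = NA_real_,
    hospitalized = FALSE, died = FALSE, antibiotic_given = FALSE)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  tibble::as_tibble(defaults)
}
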