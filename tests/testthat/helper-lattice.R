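# Discretized presentation lattice spanning both engines' decision surfaces,
# including the exact threshold boundaries (RR 50, Hb 60, PCT 4.0, SaO2 90).
# All POCT panels are complete so every cascade precondition is satisfied.

make_lattice <- function(small = FALSE) {
  grid <- tidyr::expand_grid(
    cough = c(TRUE, FALSE),
    respiratory_rate_per_min = if (small) c(35, 50, 70) else c(35, 45, 50, 55, 65, 80),
    crp_band = if (small) c("lt10", "ge80") else c("lt10", "10_39", "40_79", "ge80"),
    pct_ug_per_l = c(0.5, 4.0, 6.0),
    mrdt_positive = c(TRUE, FALSE),
    hb_g_per_l = c(55, 60, 95),
    sao2_percent = if (small) c(90, 97) else c(88, 90, 97),
    age_months = c(4, 18, 30),
    temperature_c = c(37.6, 39.0),
    convulsions_count = if (small) c(0, 1) else c(0, 1, 2),
    diarrhea_stools_24h = c(0, 6),
    skin_lesion_kind = c(NA_character_, "abscess")
  )
  base <- new_patient()
  fixed <- base[setdiff(names(base), names(grid))]
  patients <- dplyr::bind_cols(
    grid,
    fixed[rep(1, nrow(grid)), ]
  )
  patients$patient_id <- sprintf("lat%06d", seq_len(nrow(patients)))
  patients$urine_dipstick_positive <- FALSE
  patients$typhidot_positive <- FALSE
  patients$skin_lesion_diameter_cm <- ifelse(is.na(patients$skin_lesion_kind),
                                             NA_real_, 2)
  patients[names(patient_columns())]
}
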