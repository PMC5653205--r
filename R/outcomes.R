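#' Assess clinical failure by day 7, loss to follow-up, and severe adverse
#' events by day 30
#'
#' Applies the trial's composite primary-outcome definition to follow-up
#' observations. A patient fails clinically if, at any contact through day 7,
#' they develop severe disease (coma, more than 2 convulsions within 24
#' hours, inability to drink or breastfeed, hypoxemia with SaO2 below 90%,
#' severe tachypnea at or above the 97th respiratory-rate percentile for age
#' and temperature, or severe tachycardia at or above the 90th heart-rate
#' percentile); if at the day-3 contact they have clinical pneumonia (history
#' of cough with a respiratory rate of 60/min or more under 12 months, 50/min
#' or more at 12 months and older, or with lower chest indrawing) or
#' dehydration requiring facility-based care; or if at the day-7 contact they
#' still have fever (reported, or measured at 38.0 C or more), clinical
#' pneumonia, diarrhea with 3 or more liquid stools per day, significant
#' dehydration, a serious skin infection, or a new significant symptom not
#' present at day 0. The severe-disease percentile thresholds are resolved
#' through the same registry functions used by the rule engines.
#'
#' Day windows default to the observed follow-up ranges (day 3 contact: days
#' 2-5; day 7 contact: days 6-12) and are configurable through the registry.
#' A patient with no contact in the day-7 window (and not known dead) is
#' lost to follow-up and has an undefined (`NA`) clinical-failure status;
#' population construction decides how that is counted (see
#' [build_populations()]).
#'
#' Severe adverse events by day 30 are deaths (anywhere through day 30) or
#' secondary hospitalizations, i.e., admissions after the initial
#' consultation; a day-0 admission resulting from the primary referral is not
#' a secondary admission.
#'
#' @param followups Validated follow-up tibble (see [followup_columns()]).
#' @param patients Validated baseline tibble; supplies age for the tachypnea
#'   age bands and the percentile lookups.
#' @param standards Threshold registry.
#' @return A tibble with one row per patient: `patient_id`,
#'   `clinical_failure` (logical, `NA` when lost), `failure_day`,
#'   `failure_criteria` (comma-separated tokens), `lost_to_followup`,
#'   `severe_adverse_event`, `sae_kind` (`"death"`, `"secondary_admission"`
#'   or `NA`).
#' @export
assess_failure <- function(followups, patients, standards = reference_standards()) {
  s <- as_standards(standards)
  p <- validate_patients(patients, s)
  f <- validate_followups(followups)
  unknown <- setdiff(unique(f$patient_id), p$patient_id)
  if (length(unknown)) {
    abort_validation(paste0("followups reference unknown patient(s): ",
                            paste(utils::head(unknown, 3), collapse = ", ")))
  }

  f <- dplyr::left_join(
    f,
    dplyr::select(p, "patient_id", baseline_age = "age_months"),
    by = "patient_id"
  )
  # temperature for the percentile lookup: measured if available, else the
  # afebrile lower edge of the grid (clamped there anyway)
  temp_lookup <- dplyr::coalesce(f$temperature_c, 37.5)
  rr97 <- rr_percentile(f$baseline_age, temp_lookup, 97, s)
  hr90 <- hr_percentile_90(f$baseline_age, temp_lookup, s)

  fail_tachypnea <- !is.na(f$respiratory_rate_per_min) & f$cough_history &
    f$respiratory_rate_per_min >= ifelse(f$baseline_age < 12,
                                         s$failure_tachypnea_lt12m,
                                         s$failure_tachypnea_ge12m)
  clinical_pneumonia <- fail_tachypnea | (f$cough_history & f$lower_chest_indrawing)

  crit <- tibble::tibble(
    patient_id = f$patient_id,
    day = f$day,
    coma = f$day <= 7 & f$coma,
    convulsions = f$day <= 7 & f$convulsions_24h > 2,
    unable_to_drink = f$day <= 7 & f$unable_to_drink_or_breastfeed,
    hypoxemia = f$day <= 7 & !is.na(f$sao2_percent) &
      f$sao2_percent < s$sao2_severe_threshold,
    severe_tachypnea = f$day <= 7 & !is.na(f$respiratory_rate_per_min) &
      f$respiratory_rate_per_min >= rr97,
    severe_tachycardia = f$day <= 7 & !is.na(f$heart_rate_per_min) &
      f$heart_rate_per_min >= hr90,
    pneumonia_day3 = f$day >= s$day3_window_lo & f$day <= s$day3_window_hi &
      clinical_pneumonia,
    dehydration_day3 = f$day >= s$day3_window_lo & f$day <= s$day3_window_hi &
      f$dehydration_requiring_facility_care,
    fever_day7 = f$day >= s$day7_window_lo & f$day <= s$day7_window_hi &
      (f$fever_reported | (!is.na(f$temperature_c) &
                             f$temperature_c >= s$fever_threshold_followup_c)),
    pneumonia_day7 = f$day >= s$day7_window_lo & f$day <= s$day7_window_hi &
      clinical_pneumonia,
    diarrhea_day7 = f$day >= s$day7_window_lo & f$day <= s$day7_window_hi &
      f$diarrhea_stools_per_day >= s$diarrhea_failure_stools_per_day,
    dehydration_day7 = f$day >= s$day7_window_lo & f$day <= s$day7_window_hi &
      f$dehydration_requiring_facility_care,
    skin_day7 = f$day >= s$day7_window_lo & f$day <= s$day7_window_hi &
      f$skin_infection_requiring_systemic_or_facility_care,
    new_symptom_day7 = f$day >= s$day7_window_lo & f$day <= s$day7_window_hi &
      f$new_significant_symptom
  )
  crit_names <- setdiff(names(crit), c("patient_id", "day"))

  long <- crit |>
    tidyr::pivot_longer(dplyr::all_of(crit_names),
                        names_to = "criterion", values_to = "fired") |>
    dplyr::filter(.data$fired)

  per_patient_fail <- if (nrow(long)) {
    long |>
      dplyr::summarise(
        failure_day = min(.data$day),
        failure_criteria = paste(unique(.data$criterion[.data$day == min(.data$day)]),
                                 collapse = ","),
        .by = "patient_id"
      )
  } else {
    tibble::tibble(patient_id = character(), failure_day = numeric(),
                   failure_criteria = character())
  }

  contact_info <- f |>
    dplyr::summarise(
      has_day7_contact = any(.data$day >= s$day7_window_lo),
      died30 = any(.data$died & .data$day <= 30),
      death_day = if (any(.data$died)) min(.data$day[.data$died]) else NA_real_,
      secondary_admission = any(.data$hospitalized & .data$day > 0),
      .by = "patient_id"
    )

  out <- tibble::tibble(patient_id = p$patient_id) |>
    dplyr::left_join(contact_info, by = "patient_id") |>
    dplyr::left_join(per_patient_fail, by = "patient_id") |>
    dplyr::mutate(
      has_day7_contact = dplyr::coalesce(.data$has_day7_contact, FALSE),
      died30 = dplyr::coalesce(.data$died30, FALSE),
      secondary_admission = dplyr::coalesce(.data$secondary_admission, FALSE),
      lost_to_followup = !.data$has_day7_contact & !.data$died30,
      clinical_failure = dplyr::case_when(
        !is.na(.data$failure_day) ~ TRUE,
        .data$lost_to_followup ~ NA,
        TRUE ~ FALSE
      ),
      severe_adverse_event = .data$died30 | .data$secondary_admission,
      sae_kind = dplyr::case_when(
        .data$died30 ~ "death",
        .data$secondary_admission ~ "secondary_admission",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select("patient_id", "clinical_failure", "failure_day",
                  "failure_criteria", "lost_to_followup",
                  "severe_adverse_event", "sae_kind")
  out
}

#' Not-cured re-treatment rule at a scheduled contact
#'
#' A child is "not cured" (and is re-treated per the assigned algorithm) if
#' the caregiver considers the child still ill, or the child still has fever
#' (reported, or measured at or above the enrollment fever threshold).
#'
#' @param followups Validated follow-up tibble.
#' @param standards Threshold registry.
#' @return The input with a logical `not_cured` column appended.
#' @export
not_cured <- function(followups, standards = reference_standards()) {
  s <- as_standards(standards)
  f <- validate_followups(followups)
  dplyr::mutate(
    f,
    not_cured = .data$caregiver_considers_ill | .data$fever_reported |
      (!is.na(.data$temperature_c) &
         .data$temperature_c >= s$fever_threshold_enrollment_c)
  )
}

#' Severe adverse events by day 30
#'
#' Convenience wrapper returning the severe-adverse-event accounting alone:
#' death anywhere through day 30, else secondary hospitalization (admission
#' after the initial consultation; primary-referral admissions at day 0 are
#' excluded).
#'
#' @param followups Validated follow-up tibble.
#' @return Tibble: `patient_id`, `severe_adverse_event`, `sae_kind`.
#' @export
assess_sae <- function(followups) {
  f <- validate_followups(followups)
  f |>
    dplyr::summarise(
      died30 = any(.data$died & .data$day <= 30),
      secondary_admission = any(.data$hospitalized & .data$day > 0),
      .by = "patient_id"
    ) |>
    dplyr::mutate(
      severe_adverse_event = .data$died30 | .data$secondary_admission,
      sae_kind = dplyr::case_when(
        .data$died30 ~ "death",
        .data$secondary_admission ~ "secondary_admission",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select("patient_id", "severe_adverse_event", "sae_kind")
}
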