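#' Patient presentation schema
#'
#' Patient presentations are plain tibbles, one row per child at day 0, with
#' the flat column set returned by [patient_columns()]: demographics and
#' anthropometry, the symptom set, vital signs, an optional skin lesion, and
#' staged point-of-care test (POCT) results. Booleans are logical, enums are
#' lowercase tokens, missing values are `NA`.
#'
#' Eligibility invariants (enforced by [validate_patients()]): age 2-59
#' months, weight >= 2.5 kg, axillary temperature >= 37.5 C at enrollment,
#' fever history <= 7 days.
#'
#' @name patient-schema
NULL

skin_lesion_kinds <- function() {
  c("abscess", "cellulitis", "impetigo_pyoderma", "tinea_corporis",
    "pityriasis_versicolor", "candidiasis", "tinea_capitis", "scabies",
    "chicken_pox", "herpes", "larva_migrans", "eczema", "urticaria")
}

bacterial_skin_kinds <- function() c("abscess", "cellulitis", "impetigo_pyoderma")

#' @rdname patient-schema
#' @return `patient_columns()`: named character vector mapping column name to
#'   type ("character", "numeric" or "logical").
#' @export
patient_columns <- function() {
  c(patient_id = "character",
    age_months = "numeric",
    sex = "character",
    weight_kg = "numeric",
    muac_mm = "numeric",
    temperature_c = "numeric",
    fever_duration_days = "numeric",
    # symptom set
    cough = "logical",
    cough_duration_days = "numeric",
    rhinorrhea = "logical",
    diarrhea_stools_24h = "numeric",
    vomiting_episodes_24h = "numeric",
    dysuria = "logical",
    ear_discharge = "logical",
    severe_lethargy = "logical",
    stiff_neck = "logical",
    convulsions_count = "numeric",
    unable_to_drink = "logical",
    not_tolerating_oral_liquids = "logical",
    vomits_everything = "logical",
    sunken_eyes = "logical",
    drinks_eagerly = "logical",
    restless_irritable = "logical",
    skin_pinch = "character",
    lower_chest_indrawing = "logical",
    speech_level = "character",
    stridor = "logical",
    cyanosis = "logical",
    severe_palmar_pallor = "logical",
    jaundice = "logical",
    tender_swelling_behind_ear = "logical",
    visible_severe_wasting = "logical",
    edema_both_feet = "logical",
    clouding_cornea = "logical",
    severe_mouth_ulcers = "logical",
    caregiver_reports_other = "character",
    # skin lesion (kind NA = no lesion)
    skin_lesion_kind = "character",
    skin_lesion_diameter_cm = "numeric",
    skin_red_streaks = "logical",
    skin_tender_nodes = "logical",
    skin_multiple_abscesses = "logical",
    # vital signs
    respiratory_rate_per_min = "numeric",
    heart_rate_per_min = "numeric",
    sao2_percent = "numeric",
    # POCT results (staged; NA = not performed)
    mrdt_positive = "logical",
    hb_g_per_l = "numeric",
    glucose_mmol_per_l = "numeric",
    crp_band = "character",
    pct_ug_per_l = "numeric",
    urine_dipstick_positive = "logical",
    typhidot_positive = "logical",
    hiv_ab_positive = "logical",
    enrollment_day = "character")
}

#' @rdname patient-schema
#' @return `followup_columns()`: the analogous map for follow-up observations.
#' @export
followup_columns <- function() {
  c(patient_id = "character",
    day = "numeric",
    contact_type = "character",
    temperature_c = "numeric",
    fever_reported = "logical",
    caregiver_considers_ill = "logical",
    respiratory_rate_per_min = "numeric",
    heart_rate_per_min = "numeric",
    sao2_percent = "numeric",
    cough_history = "logical",
    lower_chest_indrawing = "logical",
    coma = "logical",
    convulsions_24h = "numeric",
    unable_to_drink_or_breastfeed = "logical",
    diarrhea_stools_per_day = "numeric",
    dehydration_requiring_facility_care = "logical",
    skin_infection_requiring_systemic_or_facility_care = "logical",
    new_significant_symptom = "logical",
    hb_g_per_l = "numeric",
    hospitalized = "logical",
    died = "logical",
    antibiotic_given = "logical")
}

#' Construct one patient presentation row
#'
#' Returns a one-row tibble describing an eligible febrile child with no
#' symptoms beyond fever and normal vitals/POCTs; any field can be overridden
#' by name. Intended for examples, tests and interactive exploration; bulk
#' data come from [read_patients()] or [generate_cohort()].
#'
#' @param ... Named overrides for any column in [patient_columns()].
#' @return A one-row validated-schema tibble (not eligibility-checked).
#' @examples
#' new_patient(cough = TRUE, respiratory_rate_per_min = 55, crp_band = "10_39")
#' @export
new_patient <- function(...) {
  defaults <- list(
    patient_id = "p1", age_months = 18, sex = "male", weight_kg = 10.5,
    muac_mm = 140, temperature_c = 38.2, fever_duration_days = 2,
    cough = FALSE, cough_duration_days = NA_real_, rhinorrhea = FALSE,
    diarrhea_stools_24h = 0, vomiting_episodes_24h = 0, dysuria = FALSE,
    ear_discharge = FALSE, severe_lethargy = FALSE, stiff_neck = FALSE,
    convulsions_count = 0, unable_to_drink = FALSE,
    not_tolerating_oral_liquids = FALSE, vomits_everything = FALSE,
    sunken_eyes = FALSE, drinks_eagerly = FALSE, restless_irritable = FALSE,
    skin_pinch = "normal", lower_chest_indrawing = FALSE,
    speech_level = "normal", stridor = FALSE, cyanosis = FALSE,
    severe_palmar_pallor = FALSE, jaundice = FALSE,
    tender_swelling_behind_ear = FALSE, visible_severe_wasting = FALSE,
    edema_both_feet = FALSE, clouding_cornea = FALSE,
    severe_mouth_ulcers = FALSE, caregiver_reports_other = NA_character_,
    skin_lesion_kind = NA_character_, skin_lesion_diameter_cm = NA_real_,
    skin_red_streaks = FALSE, skin_tender_nodes = FALSE,
    skin_multiple_abscesses = FALSE,
    respiratory_rate_per_min = 32, heart_rate_per_min = 120,
    sao2_percent = 98, mrdt_positive = FALSE, hb_g_per_l = 105,
    glucose_mmol_per_l = 5.0, crp_band = NA_character_,
    pct_ug_per_l = NA_real_, urine_dipstick_positive = NA,
    typhidot_positive = NA, hiv_ab_positive = NA,
    enrollment_day = NA_character_)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort_validation(paste0("unknown patient field(s): ", paste(unknown, collapse = ", ")))
  }
  defaults[names(overrides)] <- overrides
  tibble::as_tibble(defaults)
}

check_schema <- function(data, columns, what) {
  missing <- setdiff(names(columns), names(data))
  if (length(missing)) {
    abort_validation(paste0(what, ": missing column(s): ", paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(data), names(columns))
  if (length(unknown)) {
    abort_validation(paste0(what, ": unknown column(s): ", paste(unknown, collapse = ", ")))
  }
  data[names(columns)]
}

fail_rows <- function(bad, field, what, msg) {
  bad <- which(bad)
  if (length(bad)) {
    abort_validation(paste0(what, ": ", msg, " [field ", field, ", row ",
                            paste(utils::head(bad, 5), collapse = ", "),
                            if (length(bad) > 5) ", ..." else "", "]"))
  }
}

#' Validate patient presentation records
#'
#' Checks the column schema, enum levels, physiological ranges and the
#' enrollment eligibility invariants. Validation is total: every malformed
#' record raises a classed `epoctr_validation_error` naming the field and the
#' offending row; nothing is silently defaulted or dropped.
#'
#' @param patients A data frame following [patient_columns()].
#' @param standards Registry used for the enrollment fever threshold.
#' @return The validated tibble (columns in canonical order), invisibly usable
#'   in a pipe.
#' @export
validate_patients <- function(patients, standards = reference_standards()) {
  standards <- as_standards(standards)
  p <- check_schema(tibble::as_tibble(patients), patient_columns(), "patients")
  w <- "patients"

  fail_rows(is.na(p$patient_id) | !nzchar(p$patient_id), "patient_id", w, "missing id")
  fail_rows(duplicated(p$patient_id), "patient_id", w, "duplicated id")
  fail_rows(is.na(p$age_months) | p$age_months < 2 | p$age_months > 59,
            "age_months", w, "age must be 2-59 months (eligibility)")
  fail_rows(!p$sex %in% c("male", "female"), "sex", w, "must be male/female")
  fail_rows(is.na(p$weight_kg) | p$weight_kg < 2.5, "weight_kg", w,
            "weight must be >= 2.5 kg (eligibility)")
  fail_rows(!is.na(p$muac_mm) & p$muac_mm <= 0, "muac_mm", w, "must be positive")
  fail_rows(is.na(p$temperature_c) | p$temperature_c < standards$fever_threshold_enrollment_c,
            "temperature_c", w, paste0("axillary temperature must be >= ",
                                       standards$fever_threshold_enrollment_c,
                                       " C at enrollment (eligibility)"))
  fail_rows(is.na(p$fever_duration_days) | p$fever_duration_days < 0 |
              p$fever_duration_days > 7, "fever_duration_days", w,
            "fever history must be 0-7 days (eligibility)")

  for (cnt in c("diarrhea_stools_24h", "vomiting_episodes_24h", "convulsions_count")) {
    fail_rows(is.na(p[[cnt]]) | p[[cnt]] < 0, cnt, w, "count must be >= 0")
  }
  fail_rows(!p$skin_pinch %in% c("normal", "slow", "very_slow"), "skin_pinch", w,
            "must be normal/slow/very_slow")
  fail_rows(!p$speech_level %in% c("normal", "short_phrases_or_short_cries",
                                   "single_words_or_grunts"), "speech_level", w,
            "must be normal/short_phrases_or_short_cries/single_words_or_grunts")
  fail_rows(!is.na(p$skin_lesion_kind) & !p$skin_lesion_kind %in% skin_lesion_kinds(),
            "skin_lesion_kind", w,
            paste0("must be one of: ", paste(skin_lesion_kinds(), collapse = ", ")))
  fail_rows(!is.na(p$skin_lesion_kind) & (is.na(p$skin_lesion_diameter_cm) |
                                            p$skin_lesion_diameter_cm < 0),
            "skin_lesion_diameter_cm", w, "lesion requires a diameter >= 0 cm")

  fail_rows(is.na(p$respiratory_rate_per_min) | p$respiratory_rate_per_min <= 0,
            "respiratory_rate_per_min", w, "must be positive")
  fail_rows(!is.na(p$heart_rate_per_min) & p$heart_rate_per_min <= 0,
            "heart_rate_per_min", w, "must be positive")
  fail_rows(!is.na(p$sao2_percent) & (p$sao2_percent <= 0 | p$sao2_percent > 100),
            "sao2_percent", w, "must be in (0, 100]")

  fail_rows(is.na(p$mrdt_positive), "mrdt_positive", w, "mRDT result is required")
  fail_rows(!is.na(p$hb_g_per_l) & p$hb_g_per_l <= 0, "hb_g_per_l", w, "must be positive")
  fail_rows(!is.na(p$glucose_mmol_per_l) & p$glucose_mmol_per_l <= 0,
            "glucose_mmol_per_l", w, "must be positive")
  fail_rows(!is.na(p$crp_band) & !p$crp_band %in% crp_band_levels(), "crp_band", w,
            "must be one of: lt10, 10_39, 40_79, ge80")
  fail_rows(!is.na(p$pct_ug_per_l) & p$pct_ug_per_l < 0, "pct_ug_per_l", w,
            "must be >= 0")
  logicals <- names(patient_columns())[patient_columns() == "logical"]
  required_logical <- setdiff(logicals, c("mrdt_positive", "urine_dipstick_positive",
                                          "typhidot_positive", "hiv_ab_positive"))
  for (lg in required_logical) {
    fail_rows(is.na(p[[lg]]), lg, w, "must be TRUE/FALSE (not missing)")
  }
  p
}

#' Validate follow-up observation records
#'
#' @param followups A data frame following [followup_columns()], one row per
#'   contact (day 3 / day 7 / unscheduled / day 30 phone).
#' @return The validated tibble sorted by patient and day.
#' @export
validate_followups <- function(followups) {
  f <- check_schema(tibble::as_tibble(followups), followup_columns(), "followups")
  w <- "followups"
  fail_rows(is.na(f$patient_id) | !nzchar(f$patient_id), "patient_id", w, "missing id")
  fail_rows(is.na(f$day) | f$day < 0 | f$day > 30, "day", w, "study day must be 0-30")
  fail_rows(!f$contact_type %in% c("visit", "phone", "traced"), "contact_type", w,
            "must be visit/phone/traced")
  fail_rows(!is.na(f$temperature_c) & (f$temperature_c < 30 | f$temperature_c > 43),
            "temperature_c", w, "implausible temperature")
  fail_rows(is.na(f$convulsions_24h) | f$convulsions_24h < 0, "convulsions_24h", w,
            "count must be >= 0")
  fail_rows(is.na(f$diarrhea_stools_per_day) | f$diarrhea_stools_per_day < 0,
            "diarrhea_stools_per_day", w, "count must be >= 0")
  fail_rows(!is.na(f$respiratory_rate_per_min) & f$respiratory_rate_per_min <= 0,
            "respiratory_rate_per_min", w, "must be positive")
  fail_rows(!is.na(f$sao2_percent) & (f$sao2_percent <= 0 | f$sao2_percent > 100),
            "sao2_percent", w, "must be in (0, 100]")
  for (lg in c("fever_reported", "caregiver_considers_ill", "cough_history",
               "lower_chest_indrawing", "coma", "unable_to_drink_or_breastfeed",
               "dehydration_requiring_facility_care",
               "skin_infection_requiring_systemic_or_facility_care",
               "new_significant_symptom", "hospitalized", "died", "antibiotic_given")) {
    fail_rows(is.na(f[[lg]]), lg, w, "must be TRUE/FALSE (not missing)")
  }
  f <- dplyr::arrange(f, .data$patient_id, .data$day)
  # a death terminates follow-up: no later observations for that patient
  death <- if (any(f$died)) {
    f |>
      dplyr::filter(.data$died) |>
      dplyr::summarise(death_day = min(.data$day), .by = "patient_id")
  } else {
    f[0, "patient_id"]
  }
  if (nrow(death)) {
    joined <- dplyr::inner_join(f, death, by = "patient_id")
    bad <- joined$day > joined$death_day
    if (any(bad)) {
      abort_validation(paste0("followups: observations after death for patient ",
                              joined$patient_id[which(bad)[1]]))
    }
  }
  f
}
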