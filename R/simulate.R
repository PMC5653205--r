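#' Synthetic-cohort configuration
#'
#' Parameters of the seeded generative model for a pediatric febrile
#' outpatient cohort (age 2-59 months, axillary temperature >= 37.5 C):
#' a latent-etiology mixture, age structure, condition-conditioned biomarker
#' and vital-sign models, and a management-dependent outcome model in which
#' care that misses the latent condition's required component (antibiotic,
#' referral, antimalarial or supportive care) multiplies the clinical-failure
#' probability. All defaults are an illustrative calibration to the published
#' marginal structure of such cohorts (complaint frequencies, biomarker band
#' frequencies, classification shares), not estimated truth.
#'
#' @param n Cohort size.
#' @param seed Integer root seed; each patient draws from a hierarchical
#'   substream, so enlarging `n` extends the cohort without reshuffling
#'   existing patients.
#' @param etiology_mix Named probability vector over the latent conditions
#'   (normalized if needed).
#' @param age_weights Weights of the 2-11, 12-23 and 24-59 month bands.
#' @param ltf_probability Loss-to-follow-up probability for the day-7
#'   assessment.
#' @param failure_probability_override If non-`NULL`, replaces the whole
#'   condition/appropriateness outcome model with a single iid failure
#'   probability (the design-point mode used for power studies and parameter
#'   recovery).
#' @param base_failure Named per-condition clinical-failure probability under
#'   fully appropriate care.
#' @param multiplier_missing_antibiotic,multiplier_missing_referral,multiplier_missing_supportive,multiplier_unnecessary_antibiotic
#'   Hazard multipliers applied when the delivered management misses (or
#'   needlessly adds) the corresponding component.
#' @param mrdt_sensitivity,mrdt_false_positive Malaria rapid-test error model.
#' @param sae_given_failure,sae_baseline,death_given_sae Severe-adverse-event
#'   model (secondary hospitalization / death by day 30).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 1000,
                          seed = 1,
                          etiology_mix = NULL,
                          age_weights = c(`2_11` = 0.44, `12_23` = 0.33, `24_59` = 0.23),
                          ltf_probability = 0.004,
                          failure_probability_override = NULL,
                          base_failure = NULL,
                          multiplier_missing_antibiotic = 3,
                          multiplier_missing_referral = 4,
                          multiplier_missing_supportive = 2,
                          multiplier_unnecessary_antibiotic = 1.3,
                          mrdt_sensitivity = 0.97,
                          mrdt_false_positive = 0.01,
                          sae_given_failure = 0.15,
                          sae_baseline = 0.002,
                          death_given_sae = 0.04) {
  default_mix <- c(
    viral_urti = 0.240, viral_lrti = 0.220, bacterial_pneumonia = 0.015,
    malaria = 0.110, uti = 0.012, typhoid = 0.002,
    severe_anemia_state = 0.012, severe_malnutrition_state = 0.030,
    gastroenteritis = 0.130, skin_condition = 0.045,
    fws_viral_state = 0.180, fws_bacterial_state = 0.004
  )
  mix <- etiology_mix %||% default_mix
  if (is.null(names(mix)) || !all(names(mix) %in% names(default_mix)) ||
      any(mix < 0) || sum(mix) <= 0) {
    abort_config("etiology_mix must be a named non-negative vector over the known conditions")
  }
  full <- stats::setNames(rep(0, length(default_mix)), names(default_mix))
  full[names(mix)] <- mix
  mix <- full / sum(full)

  default_fail <- c(
    viral_urti = 0.015, viral_lrti = 0.030, bacterial_pneumonia = 0.050,
    malaria = 0.020, uti = 0.030, typhoid = 0.050,
    severe_anemia_state = 0.040, severe_malnutrition_state = 0.040,
    gastroenteritis = 0.025, skin_condition = 0.015,
    fws_viral_state = 0.010, fws_bacterial_state = 0.040
  )
  bf <- base_failure %||% default_fail
  if (!all(names(default_fail) %in% names(bf)) || any(bf < 0 | bf > 1)) {
    abort_config("base_failure must cover every condition with probabilities in [0, 1]")
  }

  if (!is.numeric(n) || length(n) != 1 || n < 1) abort_config("n must be a positive count")
  if (any(age_weights < 0) || sum(age_weights) <= 0 || length(age_weights) != 3) {
    abort_config("age_weights must be 3 non-negative weights")
  }
  probs <- c(ltf_probability, mrdt_sensitivity, mrdt_false_positive,
             sae_given_failure, sae_baseline, death_given_sae)
  if (any(probs < 0 | probs > 1)) abort_config("probabilities must be in [0, 1]")
  if (!is.null(failure_probability_override) &&
      (failure_probability_override < 0 || failure_probability_override > 1)) {
    abort_config("failure_probability_override must be in [0, 1]")
  }

  structure(list(
    n = as.integer(n), seed = as.integer(seed), etiology_mix = mix,
    age_weights = age_weights / sum(age_weights),
    ltf_probability = ltf_probability,
    failure_probability_override = failure_probability_override,
    base_failure = bf[names(default_fail)],
    multiplier_missing_antibiotic = multiplier_missing_antibiotic,
    multiplier_missing_referral = multiplier_missing_referral,
    multiplier_missing_supportive = multiplier_missing_supportive,
    multiplier_unnecessary_antibiotic = multiplier_unnecessary_antibiotic,
    mrdt_sensitivity = mrdt_sensitivity,
    mrdt_false_positive = mrdt_false_positive,
    sae_given_failure = sae_given_failure,
    sae_baseline = sae_baseline,
    death_given_sae = death_given_sae
  ), class = "cohort_config")
}

#' Latent condition to required care
#'
#' The explicit map from each latent condition to the care it requires;
#' the appropriateness of delivered management (and hence the failure-hazard
#' multiplier) is computed against this table.
#'
#' @return Tibble: `condition`, `needs_antibiotic`, `needs_antimalarial`,
#'   `needs_referral`, `supportive` (treatment token or `NA`).
#' @export
condition_care_map <- function() {
  tibble::tribble(
    ~condition,                 ~needs_antibiotic, ~needs_antimalarial, ~needs_referral, ~supportive,
    "viral_urti",               FALSE,             FALSE,               FALSE,           NA_character_,
    "viral_lrti",               FALSE,             FALSE,               FALSE,           "bronchodilator",
    "bacterial_pneumonia",      TRUE,              FALSE,               FALSE,           NA_character_,
    "malaria",                  FALSE,             TRUE,                FALSE,           NA_character_,
    "uti",                      TRUE,              FALSE,               FALSE,           NA_character_,
    "typhoid",                  TRUE,              FALSE,               FALSE,           NA_character_,
    "severe_anemia_state",      FALSE,             FALSE,               TRUE,            NA_character_,
    "severe_malnutrition_state",FALSE,             FALSE,               TRUE,            NA_character_,
    "gastroenteritis",          FALSE,             FALSE,               FALSE,           "ors",
    "skin_condition",           FALSE,             FALSE,               FALSE,           NA_character_,
    "fws_viral_state",          FALSE,             FALSE,               FALSE,           NA_character_,
    "fws_bacterial_state",      TRUE,              FALSE,               FALSE,           NA_character_
  )
}

# Hierarchical per-patient substream: patient i's draws depend only on
# (seed, i, stream), so a cohort can be extended without reshuffling.
patient_seed <- function(seed, i, stream = 0L) {
  as.integer((as.double(seed %% 1000003L) * 2039 + as.double(i) * 7919 +
                as.double(stream) * 104729) %% 2147483629)
}

sample1 <- function(x, prob = NULL) x[sample.int(length(x), 1L, prob = prob)]

#' Generate a synthetic febrile cohort
#'
#' Draws `config$n` patient presentations (with their latent conditions)
#' satisfying the enrollment invariants: latent etiology from the configured
#' mixture, age from banded weights, vitals from age-band baselines plus
#' condition offsets, and staged POCT results from condition-conditioned
#' models (malaria rapid test with configured sensitivity, elevated CRP/PCT
#' bands for bacterial conditions, low haemoglobin for the severe-anaemia
#' state, and so on). Deterministic under (config, seed).
#'
#' @param config A [cohort_config()].
#' @return Tibble of validated patient rows with a `latent_condition` column
#'   appended. The strict patient schema rejects extra columns, so strip the
#'   simulator-only columns with [cohort_patients()] before classifying.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) abort_config("config must be a cohort_config()")
  n <- config$n
  conditions <- names(config$etiology_mix)
  std <- reference_standards()

  rows <- vector("list", n)
  withr::local_preserve_seed()
  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i))
    rows[[i]] <- {
      cond <- sample1(conditions, prob = config$etiology_mix)
      band <- sample1(c("2_11", "12_23", "24_59"), prob = config$age_weights)
      age <- switch(band,
                    "2_11" = sample1(2:11),
                    "12_23" = sample1(12:23),
                    "24_59" = sample1(24:59))
      sex <- sample1(c("male", "female"), prob = c(0.54, 0.46))
      temp <- min(37.5 + stats::rgamma(1, shape = 1.4, scale = 0.45), 41.0)
      fever_days <- sample1(1:5, prob = c(0.62, 0.20, 0.10, 0.06, 0.02))

      z <- if (cond == "severe_malnutrition_state") stats::rnorm(1, -3.6, 0.35) else
        stats::rnorm(1, -0.8, 1.1)
      z <- max(min(z, 4), -5)
      weight <- max(wfa_weight_at_z(age, sex, z, std), 2.6)
      muac <- max(stats::rnorm(1, 145 + 10 * z, 5), 80)

      resp_cond <- cond %in% c("viral_urti", "viral_lrti", "bacterial_pneumonia")
      fws_cond <- cond %in% c("fws_viral_state", "fws_bacterial_state", "uti",
                              "typhoid", "severe_anemia_state",
                              "severe_malnutrition_state", "malaria")
      cough <- if (resp_cond) stats::runif(1) < 0.97 else
        if (fws_cond) FALSE else stats::runif(1) < 0.12

      rr_base <- switch(band, "2_11" = 40, "12_23" = 37, "24_59" = 30)
      rr_off <- switch(cond, viral_lrti = 12, bacterial_pneumonia = 18,
                       viral_urti = 4, 0)
      rr <- max(round(stats::rnorm(1, rr_base + rr_off + 2 * (temp - 37.5), 5)), 16)
      hr <- max(round(stats::rnorm(1, 135 + 8 * (temp - 37.5), 14)), 70)
      sao2 <- if (cond == "bacterial_pneumonia" && stats::runif(1) < 0.04) {
        sample1(86:89)
      } else min(round(stats::rnorm(1, 98, 1.2)), 100)
      hb <- if (cond == "severe_anemia_state") max(stats::rnorm(1, 52, 6), 25) else
        min(max(stats::rnorm(1, 97, 14), 61), 180)
      glucose <- max(stats::rnorm(1, 5.0, 0.8), 2.0)
      if (stats::runif(1) < 0.004) glucose <- stats::runif(1, 2.5, 3.2)

      gi_cond <- cond == "gastroenteritis"
      stools <- if (gi_cond) 3 + stats::rpois(1, 2.5) else
        if (!fws_cond && stats::runif(1) < 0.06) sample1(1:2) else 0
      vomit <- if (gi_cond) stats::rpois(1, 1.2) else
        if (!fws_cond && stats::runif(1) < 0.05) sample1(1:2) else 0
      # keep the significant-GI trigger coherent with the latent label
      if (gi_cond && stools <= 5 && !(stools >= 3 && vomit >= 1) && vomit <= 3) {
        stools <- 6
      }

      lesion <- cond == "skin_condition"
      lesion_kind <- if (lesion) {
        sample1(c("abscess", "impetigo_pyoderma", "cellulitis", "scabies",
                  "tinea_corporis", "chicken_pox", "eczema"),
                prob = c(0.18, 0.20, 0.05, 0.22, 0.15, 0.10, 0.10))
      } else NA_character_
      lesion_diam <- if (lesion) round(min(stats::rgamma(1, 2, rate = 1) + 0.5, 8), 1) else NA_real_

      mrdt <- if (cond == "malaria") stats::runif(1) < config$mrdt_sensitivity else
        stats::runif(1) < config$mrdt_false_positive

      bacterial <- cond %in% c("bacterial_pneumonia", "uti", "typhoid", "fws_bacterial_state")
      crp_probs <- if (bacterial) c(0.05, 0.15, 0.20, 0.60) else
        if (cond == "malaria") c(0.30, 0.40, 0.20, 0.10) else c(0.66, 0.28, 0.05, 0.01)
      crp <- sample1(crp_band_levels(), prob = crp_probs)
      pct <- if (bacterial) round(stats::rlnorm(1, log(6), 0.8), 2) else
        round(stats::rlnorm(1, log(0.3), 0.9), 2)
      dipstick <- if (cond == "uti") stats::runif(1) < 0.9 else stats::runif(1) < 0.08
      typhidot <- if (cond == "typhoid") stats::runif(1) < 0.7 else stats::runif(1) < 0.005

      sunken <- gi_cond && stats::runif(1) < 0.30
      list(
        patient_id = sprintf("sim%05d", i), age_months = age, sex = sex,
        weight_kg = round(weight, 2), muac_mm = round(muac),
        temperature_c = round(temp, 1), fever_duration_days = fever_days,
        cough = cough,
        cough_duration_days = if (cough) sample1(1:5) else NA_real_,
        rhinorrhea = resp_cond && stats::runif(1) < 0.6,
        diarrhea_stools_24h = stools, vomiting_episodes_24h = vomit,
        dysuria = cond == "uti" && stats::runif(1) < 0.3,
        ear_discharge = !fws_cond && !lesion && stats::runif(1) < 0.015,
        severe_lethargy = stats::runif(1) < 0.002,
        stiff_neck = stats::runif(1) < 0.001,
        convulsions_count = if (stats::runif(1) < 0.004) 1 else 0,
        unable_to_drink = stats::runif(1) < 0.002,
        not_tolerating_oral_liquids = gi_cond && stats::runif(1) < 0.02,
        vomits_everything = gi_cond && stats::runif(1) < 0.01,
        sunken_eyes = sunken,
        drinks_eagerly = gi_cond && stats::runif(1) < 0.35,
        restless_irritable = gi_cond && stats::runif(1) < 0.40,
        skin_pinch = if (gi_cond && stats::runif(1) < 0.25) "slow" else "normal",
        lower_chest_indrawing = cond == "bacterial_pneumonia" && stats::runif(1) < 0.25,
        speech_level = "normal",
        stridor = stats::runif(1) < 0.001,
        cyanosis = stats::runif(1) < 0.0005,
        severe_palmar_pallor = cond == "severe_anemia_state" && stats::runif(1) < 0.25,
        jaundice = stats::runif(1) < 0.001,
        tender_swelling_behind_ear = stats::runif(1) < 0.001,
        visible_severe_wasting = cond == "severe_malnutrition_state" && stats::runif(1) < 0.02,
        edema_both_feet = stats::runif(1) < 0.0005,
        clouding_cornea = FALSE, severe_mouth_ulcers = stats::runif(1) < 0.001,
        caregiver_reports_other = NA_character_,
        skin_lesion_kind = lesion_kind,
        skin_lesion_diameter_cm = lesion_diam,
        skin_red_streaks = lesion && stats::runif(1) < 0.03,
        skin_tender_nodes = lesion && stats::runif(1) < 0.03,
        skin_multiple_abscesses = lesion && lesion_kind == "abscess" && stats::runif(1) < 0.1,
        respiratory_rate_per_min = rr, heart_rate_per_min = hr,
        sao2_percent = sao2, mrdt_positive = mrdt, hb_g_per_l = round(hb),
        glucose_mmol_per_l = round(glucose, 1), crp_band = crp,
        pct_ug_per_l = pct, urine_dipstick_positive = dipstick,
        typhidot_positive = typhidot,
        hiv_ab_positive = stats::runif(1) < 0.012,
        enrollment_day = NA_character_,
        latent_condition = cond
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  validate_patients(dplyr::select(out, -"latent_condition"))
  out
}

#' Strip simulator-only columns for engine input
#'
#' @param cohort Output of [generate_cohort()].
#' @return The patient tibble without the `latent_condition` column.
#' @export
cohort_patients <- function(cohort) {
  dplyr::select(tibble::as_tibble(cohort),
                -dplyr::any_of(c("latent_condition", "arm")))
}

# Appropriateness of delivered management vs the latent condition's needs;
# returns the failure-probability multiplier.
failure_multiplier <- function(condition, management_row, config) {
  care <- condition_care_map()
  need <- care[care$condition == condition, ]
  mult <- 1
  treatments <- management_row$treatments[[1]]
  got_antimalarial <- "antimalarial" %in% treatments
  if (need$needs_antibiotic && !management_row$antibiotic_day0) {
    mult <- mult * config$multiplier_missing_antibiotic
  }
  if (need$needs_referral && !management_row$referral) {
    mult <- mult * config$multiplier_missing_referral
  }
  if (need$needs_antimalarial && !got_antimalarial) {
    mult <- mult * config$multiplier_missing_antibiotic
  }
  if (!is.na(need$supportive) && !(need$supportive %in% treatments)) {
    mult <- mult * config$multiplier_missing_supportive
  }
  if (!need$needs_antibiotic && management_row$antibiotic_day0 &&
      !management_row$referral) {
    mult <- mult * config$multiplier_unnecessary_antibiotic
  }
  mult
}

#' Simulate management-dependent follow-up trajectories
#'
#' For each patient, draws a clinical-failure indicator whose probability is
#' the latent condition's base failure probability multiplied by the
#' configured factor for every missing (or needless) management component,
#' then emits the day-3 and day-7 contacts (plus unscheduled severe events,
#' secondary hospitalizations, deaths, and the day-30 phone call) whose
#' recorded fields realize that outcome under the trial's failure
#' definitions. Loss to follow-up removes the day-7 window contacts at the
#' configured rate. Deterministic under (config, seed).
#'
#' @param cohort Output of [generate_cohort()] (needs `latent_condition`).
#' @param management Classification tibble for these patients, from one of
#'   the engines (or the routine-care policy).
#' @param config A [cohort_config()].
#' @param seed Integer seed for the follow-up streams (defaults to
#'   `config$seed + 1`).
#' @return A validated follow-up tibble.
#' @export
simulate_followup <- function(cohort, management, config = cohort_config(),
                              seed = NULL) {
  if (!inherits(config, "cohort_config")) abort_config("config must be a cohort_config()")
  if (!"latent_condition" %in% names(cohort)) {
    abort_validation("cohort must carry latent_condition (from generate_cohort)")
  }
  seed <- seed %||% (config$seed + 1L)
  stopifnot(nrow(cohort) == nrow(management),
            all(cohort$patient_id == management$patient_id))
  n <- nrow(cohort)

  blank_obs <- function(id, day, type) {
    list(patient_id = id, day = day, contact_type = type,
         temperature_c = NA_real_, fever_reported = FALSE,
         caregiver_considers_ill = FALSE,
         respiratory_rate_per_min = NA_real_, heart_rate_per_min = NA_real_,
         sao2_percent = NA_real_, cough_history = FALSE,
         lower_chest_indrawing = FALSE, coma = FALSE, convulsions_24h = 0,
         unable_to_drink_or_breastfeed = FALSE, diarrhea_stools_per_day = 0,
         dehydration_requiring_facility_care = FALSE,
         skin_infection_requiring_systemic_or_facility_care = FALSE,
         new_significant_symptom = FALSE, hb_g_per_l = NA_real_,
         hospitalized = FALSE, died = FALSE, antibiotic_given = FALSE)
  }

  all_obs <- vector("list", n)
  withr::local_preserve_seed()
  for (i in seq_len(n)) {
    cond <- cohort$latent_condition[i]
    id <- cohort$patient_id[i]
    age <- cohort$age_months[i]
    mgmt <- management[i, ]
    set.seed(patient_seed(seed, i, stream = 1L))
    all_obs[[i]] <- {
      p_fail <- if (!is.null(config$failure_probability_override)) {
        config$failure_probability_override
      } else {
        min(config$base_failure[[cond]] * failure_multiplier(cond, mgmt, config), 0.95)
      }
      fail <- stats::runif(1) < p_fail
      ltf <- stats::runif(1) < config$ltf_probability
      resolved_by_day3 <- !fail && stats::runif(1) < 0.78

      obs <- list()
      d3 <- blank_obs(id, 3, "visit")
      if (!resolved_by_day3) {
        d3$temperature_c <- round(stats::runif(1, 37.6, 38.9), 1)
        d3$fever_reported <- TRUE
        d3$caregiver_considers_ill <- TRUE
      } else {
        d3$temperature_c <- round(stats::runif(1, 36.3, 37.2), 1)
      }
      d3$respiratory_rate_per_min <- max(round(stats::rnorm(1, 30, 4)), 18)
      d3$antibiotic_given <- mgmt$antibiotic_day0

      d7 <- blank_obs(id, 7, if (resolved_by_day3) "phone" else "visit")
      d7$temperature_c <- round(stats::runif(1, 36.3, 37.3), 1)
      d7$respiratory_rate_per_min <- max(round(stats::rnorm(1, 28, 4)), 18)

      sae <- FALSE
      death <- FALSE
      if (fail) {
        resp_like <- cond %in% c("viral_urti", "viral_lrti", "bacterial_pneumonia")
        kind <- if (resp_like) {
          if (stats::runif(1) < 0.65) "pneumonia_d3" else "fever_d7"
        } else if (cond == "gastroenteritis") {
          if (stats::runif(1) < 0.6) "diarrhea_d7" else "fever_d7"
        } else if (cond == "skin_condition") {
          "skin_d7"
        } else if (stats::runif(1) < 0.12) "severe_any" else "fever_d7"
        if (kind == "pneumonia_d3") {
          d3$cough_history <- TRUE
          thr <- if (age < 12) 60 else 50
          d3$respiratory_rate_per_min <- thr + sample1(0:8)
          d3$temperature_c <- round(stats::runif(1, 37.8, 39.2), 1)
          d3$fever_reported <- TRUE
          d3$caregiver_considers_ill <- TRUE
          if (stats::runif(1) < 0.3) d3$lower_chest_indrawing <- TRUE
        } else if (kind == "fever_d7") {
          d7$contact_type <- "visit"
          d7$temperature_c <- round(stats::runif(1, 38.1, 39.4), 1)
          d7$fever_reported <- TRUE
          d7$caregiver_considers_ill <- TRUE
        } else if (kind == "diarrhea_d7") {
          d7$contact_type <- "visit"
          d7$diarrhea_stools_per_day <- 3 + stats::rpois(1, 2)
          d7$caregiver_considers_ill <- TRUE
        } else if (kind == "skin_d7") {
          d7$contact_type <- "visit"
          d7$skin_infection_requiring_systemic_or_facility_care <- TRUE
          d7$caregiver_considers_ill <- TRUE
        } else { # unscheduled severe event
          du <- blank_obs(id, sample1(2:6), "visit")
          du$temperature_c <- round(stats::runif(1, 38.0, 40.0), 1)
          du$fever_reported <- TRUE
          du$caregiver_considers_ill <- TRUE
          if (stats::runif(1) < 0.5) du$sao2_percent <- sample1(85:89) else du$convulsions_24h <- 3
          obs <- c(obs, list(du))
        }
        sae <- stats::runif(1) < config$sae_given_failure
      } else {
        sae <- stats::runif(1) < config$sae_baseline
      }

      obs <- c(obs, list(d3))
      if (!ltf) obs <- c(obs, list(d7))

      if (sae && !ltf) {
        sae_day <- sample1(2:20)
        death <- stats::runif(1) < config$death_given_sae
        dh <- blank_obs(id, sae_day, "visit")
        dh$hospitalized <- TRUE
        dh$caregiver_considers_ill <- TRUE
        if (death) dh$died <- TRUE
        # death terminates follow-up; drop any scheduled contact on/after it
        obs <- Filter(function(o) !(death && o$day >= sae_day), obs)
        obs <- c(obs, list(dh))
      }
      if (!ltf && !death) obs <- c(obs, list(blank_obs(id, 30, "phone")))
      obs
    }
  }
  validate_followups(dplyr::bind_rows(unlist(all_obs, recursive = FALSE)))
}

resolve_engine <- function(engine) {
  if (is.function(engine)) return(engine)
  switch(engine,
         epoct = classify_epoct,
         almanach = classify_almanach,
         routine = routine_care_policy,
         abort_config(paste0("unknown engine: ", engine)))
}

#' Routine-care policy stub
#'
#' A documentation-of-practice policy rather than an algorithm: prescribes an
#' antibiotic with a configured probability (default 0.949, mirroring
#' observed routine prescription rates) and refers rarely; no POCT cascade
#' beyond the malaria test.
#'
#' @param patients Validated patient tibble.
#' @param standards Threshold registry (unused; kept for engine
#'   interchangeability).
#' @param antibiotic_prob,referral_prob Prescription/referral probabilities.
#' @param seed Integer seed.
#' @return A classification tibble in the engine output shape.
#' @export
routine_care_policy <- function(patients, standards = reference_standards(),
                                antibiotic_prob = 0.949, referral_prob = 0.004,
                                seed = 1) {
  p <- validate_patients(patients, as_standards(standards))
  n <- nrow(p)
  draws <- withr::with_seed(seed, {
    list(ab = stats::runif(n) < antibiotic_prob,
         ref = stats::runif(n) < referral_prob)
  })
  tibble::tibble(
    patient_id = p$patient_id,
    algorithm = "routine",
    classifications = rep(list(character()), n),
    referral = draws$ref,
    antibiotic_day0 = draws$ab | draws$ref,
    antibiotic_reason = NA_character_,
    treatments = purrr::map(seq_len(n), function(i) {
      tk <- character()
      if (draws$ref[i]) tk <- c(tk, "referral")
      if (draws$ab[i] || draws$ref[i]) tk <- c(tk, "oral_antibiotic")
      if (p$mrdt_positive[i]) tk <- c(tk, "antimalarial")
      c(tk, "antipyretic")
    }),
    tests_performed = rep(list("mrdt"), n)
  )
}

#' Simulate a full randomized comparison of two management policies
#'
#' The end-to-end loop: generate a cohort, block-randomize patients between
#' two pluggable engines, classify each arm, simulate management-dependent
#' follow-up, assess outcomes, construct the ITT and PP populations, and
#' compute the arm-level effect estimates (risk difference, risk ratio,
#' non-inferiority decision) for clinical failure, day-0 antibiotic
#' prescription, primary referral and severe adverse events.
#'
#' @param config A [cohort_config()]; `config$n` is the total across arms.
#' @param engine_a,engine_b Engine names (`"epoct"`, `"almanach"`,
#'   `"routine"`) or functions `patients -> classification tibble`.
#' @param standards Threshold registry.
#' @param margin_pp Non-inferiority margin in percentage points.
#' @return Object of class `trial_sim`: list with `patients`, `assignment`,
#'   `classification`, `followups`, `outcomes`, `report` (effect-estimate
#'   tibble), and `decision`.
#' @export
simulate_trial <- function(config = cohort_config(),
                           engine_a = "epoct", engine_b = "almanach",
                           standards = reference_standards(),
                           margin_pp = NULL) {
  s <- as_standards(standards)
  margin_pp <- margin_pp %||% s$noninferiority_margin_pp
  cohort <- generate_cohort(config)
  assignment <- block_randomize(nrow(cohort), block_size = 4,
                                seed = config$seed + 2L, arms = c("a", "b"))
  cohort$arm <- assignment$arm

  fa <- resolve_engine(engine_a)
  fb <- resolve_engine(engine_b)
  ca <- cohort[cohort$arm == "a", ]
  cb <- cohort[cohort$arm == "b", ]
  ma <- fa(cohort_patients(ca), s)
  mb <- fb(cohort_patients(cb), s)

  foa <- simulate_followup(ca, ma, config, seed = config$seed + 3L)
  fob <- simulate_followup(cb, mb, config, seed = config$seed + 4L)

  oa <- assess_failure(foa, cohort_patients(ca), s)
  ob <- assess_failure(fob, cohort_patients(cb), s)
  oa$arm <- "a"; ob$arm <- "b"
  outcomes <- build_populations(dplyr::bind_rows(oa, ob))

  mgmt <- dplyr::bind_rows(
    dplyr::mutate(ma, arm = "a"),
    dplyr::mutate(mb, arm = "b")
  )

  pp <- outcomes[outcomes$in_pp, ]
  t_fail <- two_by_two(sum(pp$clinical_failure[pp$arm == "a"]), sum(pp$arm == "a"),
                       sum(pp$clinical_failure[pp$arm == "b"]), sum(pp$arm == "b"),
                       "arm_a", "arm_b")
  t_ab <- two_by_two(sum(mgmt$antibiotic_day0[mgmt$arm == "a"]), sum(mgmt$arm == "a"),
                     sum(mgmt$antibiotic_day0[mgmt$arm == "b"]), sum(mgmt$arm == "b"),
                     "arm_a", "arm_b")
  t_ref <- two_by_two(sum(mgmt$referral[mgmt$arm == "a"]), sum(mgmt$arm == "a"),
                      sum(mgmt$referral[mgmt$arm == "b"]), sum(mgmt$arm == "b"),
                      "arm_a", "arm_b")
  t_sae <- two_by_two(sum(pp$severe_adverse_event[pp$arm == "a"]), sum(pp$arm == "a"),
                      sum(pp$severe_adverse_event[pp$arm == "b"]), sum(pp$arm == "b"),
                      "arm_a", "arm_b")

  safe_rr <- function(t, label) {
    est <- tryCatch(risk_ratio(t), error = function(e) NULL)
    if (is.null(est)) NULL else dplyr::mutate(est, label = label)
  }
  report <- dplyr::bind_rows(
    dplyr::mutate(risk_difference(t_fail), label = "clinical_failure_rd"),
    safe_rr(t_fail, "clinical_failure_rr"),
    safe_rr(t_ab, "antibiotic_day0_rr"),
    safe_rr(t_ref, "primary_referral_rr"),
    safe_rr(t_sae, "severe_adverse_event_rr")
  )
  rd <- report[report$label == "clinical_failure_rd", ]
  structure(list(
    patients = cohort, assignment = assignment,
    classification = mgmt, followups = dplyr::bind_rows(foa, fob),
    outcomes = outcomes, report = report,
    decision = noninferiority_decision(rd, margin_pp),
    margin_pp = margin_pp, config = config
  ), class = "trial_sim")
}

#' @export
print.trial_sim <- function(x, ...) {
  cat("<trial_sim> n =", nrow(x$patients), "\n")
  print(tidy(x))
  cat("non-inferiority decision (margin", x$margin_pp, "pp):", x$decision, "\n")
  invisible(x)
}

#' @method tidy trial_sim
#' @export
tidy.trial_sim <- function(x, ...) {
  x$report[c("label", "measure", "estimate", "conf.low", "conf.high", "p.value")]
}

#' @method glance trial_sim
#' @export
glance.trial_sim <- function(x, ...) {
  pp <- x$outcomes[x$outcomes$in_pp, ]
  tibble::tibble(
    n_randomized = nrow(x$patients),
    n_pp = nrow(pp),
    failure_a = mean(pp$clinical_failure[pp$arm == "a"]),
    failure_b = mean(pp$clinical_failure[pp$arm == "b"]),
    decision = x$decision
  )
}

#' Design-point trial simulation for power
#'
#' Replicates the trial design at a fixed failure probability in both arms.
#' Under the simulator's design-point override, clinical failure is iid
#' Bernoulli, so each replicate's arm-level failure counts are exactly
#' Binomial(n_per_arm, p); this function draws them directly, applies the
#' Wald risk-difference interval and the strict non-inferiority rule, and
#' reports the declaration rate (the empirical power at the design point).
#'
#' @param reps Number of replicate trials.
#' @param n_per_arm Patients per arm.
#' @param p Failure probability in both arms.
#' @param margin_pp Margin in percentage points.
#' @param seed Integer seed.
#' @return Tibble: `reps`, `declared`, `rate`.
#' @export
simulate_design_point_trials <- function(reps = 1000, n_per_arm = 1570,
                                         p = 0.10, margin_pp = 3, seed = 1) {
  declared <- withr::with_seed(seed, {
    ea <- stats::rbinom(reps, n_per_arm, p)
    eb <- stats::rbinom(reps, n_per_arm, p)
    vapply(seq_len(reps), function(i) {
      rd <- risk_difference(two_by_two(ea[i], n_per_arm, eb[i], n_per_arm))
      noninferiority_decision(rd, margin_pp) == "non_inferior"
    }, logical(1))
  })
  n_declared <- sum(declared)
  tibble::tibble(reps = reps, declared = n_declared, rate = n_declared / reps)
}

#' Empirical coverage of the Katz risk-ratio interval
#'
#' Simulates 2x2 tables at a known true risk ratio and reports how often the
#' Katz log-method interval covers it.
#'
#' @param reps Number of simulated tables.
#' @param n_a,n_b Arm sizes.
#' @param p_a,p_b True event probabilities (true RR = p_a/p_b).
#' @param seed Integer seed.
#' @return Tibble: `reps`, `usable` (tables with events in both arms),
#'   `coverage`.
#' @export
katz_coverage_sim <- function(reps = 2000, n_a = 500, n_b = 500,
                              p_a = 0.15, p_b = 0.10, seed = 1) {
  true_rr <- p_a / p_b
  withr::with_seed(seed, {
    ea <- stats::rbinom(reps, n_a, p_a)
    eb <- stats::rbinom(reps, n_b, p_b)
    ok <- ea > 0 & eb > 0
    covered <- vapply(which(ok), function(i) {
      est <- risk_ratio(two_by_two(ea[i], n_a, eb[i], n_b))
      est$conf.low <= true_rr && true_rr <= est$conf.high
    }, logical(1))
    tibble::tibble(reps = reps, usable = sum(ok), coverage = mean(covered))
  })
}
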