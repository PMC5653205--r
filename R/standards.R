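#' Reference standards: the single home of every clinical cutoff
#'
#' Both rule engines and the outcome engine resolve every numeric threshold
#' through this registry, so a cutoff can be changed (or audited) in exactly
#' one place. Scalar thresholds default to the values used by the e-POCT /
#' ALMANACH algorithms; the age- and temperature-dependent respiratory-rate
#' and heart-rate percentile curves ship as editable tabulated grids that are
#' declared approximations (the original curves are external references and
#' are not published alongside the algorithms). Users with access to the
#' published curves can substitute their own grids.
#'
#' Units are fixed across the package: haemoglobin g/l, glucose mmol/l,
#' procalcitonin ug/l, MUAC mm (11.5 cm = 115 mm), temperature degrees C.
#'
#' @param ... Named scalar overrides for any threshold listed in Details.
#' @param rr75_grid,rr97_grid,hr90_grid Optional replacement percentile grids:
#'   data frames with columns `age_lo`, `age_hi` (months, closed bands),
#'   `temp_c` and `value`, with `value` non-decreasing in `temp_c` within each
#'   age band.
#' @param wfa_reference Optional replacement growth reference: a data frame
#'   with columns `age_months`, `sex`, `median_kg`, `lms_l`, `lms_s` (LMS
#'   parameters per month and sex). Defaults to the bundled synthetic
#'   reference (see [weight_for_age_z()]).
#'
#' @details Scalar registry entries and defaults:
#' `sao2_severe_threshold` (90 %), `hb_severe_g_l` (60),
#' `hb_anemia_cutoff_2_6m` (90), `hb_anemia_cutoff_7_24m` (100),
#' `hb_anemia_cutoff_25_59m` (110), `glucose_hypo_mmol_l` (3.3),
#' `crp_bacterial_band` ("ge80"), `pct_bacterial_ug_l` (4.0),
#' `wfa_z_severe` (-3), `muac_severe_mm` (115), `muac_min_age_months` (6),
#' `skin_lesion_severe_cm` (4), `almanach_very_fast_breathing` (50/min any
#' age), `almanach_fast_breathing_lt12m` (50), `almanach_fast_breathing_ge12m`
#' (40), `failure_tachypnea_lt12m` (60), `failure_tachypnea_ge12m` (50),
#' `fever_threshold_enrollment_c` (37.5), `fever_threshold_followup_c` (38.0),
#' `diarrhea_failure_stools_per_day` (3), `noninferiority_margin_pp` (3.0),
#' `convulsions_severe_epoct` (2, criterion is >=),
#' `convulsions_severe_almanach` (1, criterion is >=),
#' `day3_window_lo` (2), `day3_window_hi` (5), `day7_window_lo` (6),
#' `day7_window_hi` (12).
#'
#' @return An object of class `epoctr_standards` (a named list).
#' @examples
#' std <- reference_standards()
#' std$hb_severe_g_l
#' rr_percentile(8, 38.5, percentile = 97, standards = std)
#' @export
reference_standards <- function(...,
                                rr75_grid = NULL,
                                rr97_grid = NULL,
                                hr90_grid = NULL,
                                wfa_reference = NULL) {
  std <- default_scalar_standards()
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      abort_config("scalar overrides must be named")
    }
    unknown <- setdiff(names(overrides), names(std))
    if (length(unknown)) {
      abort_config(paste0("unknown threshold(s): ", paste(unknown, collapse = ", ")))
    }
    std[names(overrides)] <- overrides
  }
  validate_scalar_standards(std)

  std$rr75_grid <- validate_percentile_grid(rr75_grid %||% default_rr75_grid(), "rr75_grid")
  std$rr97_grid <- validate_percentile_grid(rr97_grid %||% default_rr97_grid(), "rr97_grid")
  std$hr90_grid <- validate_percentile_grid(hr90_grid %||% default_hr90_grid(), "hr90_grid")
  std$wfa_reference <- build_wfa_reference(wfa_reference)

  structure(std, class = "epoctr_standards")
}

# Scalar defaults; every threshold must be present and strictly positive
# (wfa_z_severe is the one signed exception).
default_scalar_standards <- function() {
  list(
    sao2_severe_threshold = 90,
    hb_severe_g_l = 60,
    hb_anemia_cutoff_2_6m = 90,
    hb_anemia_cutoff_7_24m = 100,
    hb_anemia_cutoff_25_59m = 110,
    glucose_hypo_mmol_l = 3.3,
    crp_bacterial_band = "ge80",
    pct_bacterial_ug_l = 4.0,
    wfa_z_severe = -3,
    muac_severe_mm = 115,
    muac_min_age_months = 6,
    skin_lesion_severe_cm = 4,
    almanach_very_fast_breathing = 50,
    almanach_fast_breathing_lt12m = 50,
    almanach_fast_breathing_ge12m = 40,
    failure_tachypnea_lt12m = 60,
    failure_tachypnea_ge12m = 50,
    fever_threshold_enrollment_c = 37.5,
    fever_threshold_followup_c = 38.0,
    diarrhea_failure_stools_per_day = 3,
    noninferiority_margin_pp = 3.0,
    convulsions_severe_epoct = 2,
    convulsions_severe_almanach = 1,
    day3_window_lo = 2,
    day3_window_hi = 5,
    day7_window_lo = 6,
    day7_window_hi = 12
  )
}

validate_scalar_standards <- function(std) {
  required <- names(default_scalar_standards())
  for (nm in required) {
    val <- std[[nm]]
    if (is.null(val) || (is.atomic(val) && length(val) == 1 && is.na(val))) {
      abort_config(paste0("missing threshold: ", nm))
    }
  }
  numeric_fields <- setdiff(required, c("crp_bacterial_band", "wfa_z_severe"))
  for (nm in numeric_fields) {
    v <- std[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort_config(paste0("threshold must be a single positive number: ", nm))
    }
  }
  if (!std$crp_bacterial_band %in% crp_band_levels()) {
    abort_config("crp_bacterial_band must be one of: lt10, 10_39, 40_79, ge80")
  }
  if (!is.numeric(std$wfa_z_severe) || !is.finite(std$wfa_z_severe)) {
    abort_config("wfa_z_severe must be a finite number")
  }
  invisible(std)
}

crp_band_levels <- function() c("lt10", "10_39", "40_79", "ge80")

# CRP lateral-flow readout is semi-quantitative: compare bands by rank.
crp_band_rank <- function(band) match(band, crp_band_levels())

#' Read a standards configuration from a YAML file
#'
#' The YAML document mirrors the scalar registry fields of
#' [reference_standards()]; percentile-curve grids may be supplied as
#' auxiliary CSV files (columns `age_lo`, `age_hi`, `temp_c`, `value`) via the
#' keys `rr75_grid_csv`, `rr97_grid_csv`, `hr90_grid_csv`, and a replacement
#' growth reference via `wfa_reference_csv`. Missing scalar keys fall back to
#' the package defaults; set `require_all: true` in the file to reject any
#' omission instead.
#'
#' @param path Path to the YAML configuration.
#' @return An `epoctr_standards` object.
#' @export
read_standards <- function(path) {
  if (!file.exists(path)) abort_config(paste0("standards file not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort_config("standards config must be a YAML mapping")
  require_all <- isTRUE(cfg$require_all)
  cfg$require_all <- NULL

  grid_keys <- c("rr75_grid_csv", "rr97_grid_csv", "hr90_grid_csv")
  grids <- lapply(grid_keys, function(k) {
    if (is.null(cfg[[k]])) return(NULL)
    p <- cfg[[k]]
    if (!file.exists(p)) p <- file.path(dirname(path), cfg[[k]])
    if (!file.exists(p)) abort_config(paste0("grid file not found: ", cfg[[k]]))
    utils::read.csv(p)
  })
  names(grids) <- c("rr75_grid", "rr97_grid", "hr90_grid")
  wfa <- NULL
  if (!is.null(cfg$wfa_reference_csv)) {
    p <- cfg$wfa_reference_csv
    if (!file.exists(p)) p <- file.path(dirname(path), cfg$wfa_reference_csv)
    if (!file.exists(p)) abort_config(paste0("growth reference file not found: ", cfg$wfa_reference_csv))
    wfa <- utils::read.csv(p)
  }
  cfg[c(grid_keys, "wfa_reference_csv")] <- NULL

  if (require_all) {
    missing <- setdiff(names(default_scalar_standards()), names(cfg))
    if (length(missing)) {
      abort_config(paste0("missing threshold: ", paste(missing, collapse = ", ")))
    }
  }
  do.call(reference_standards, c(cfg, grids, list(wfa_reference = wfa)))
}

as_standards <- function(standards) {
  if (is.null(standards)) return(reference_standards())
  if (!inherits(standards, "epoctr_standards")) {
    abort_config("`standards` must be created by reference_standards() or read_standards()")
  }
  standards
}

#' @export
print.epoctr_standards <- function(x, ...) {
  cat("<epoctr_standards>\n")
  scalars <- x[setdiff(names(x), c("rr75_grid", "rr97_grid", "hr90_grid", "wfa_reference"))]
  cat(paste0("  ", names(scalars), " = ", unlist(lapply(scalars, format)), collapse = "\n"), "\n")
  cat("  + percentile grids: rr75, rr97, hr90 (age band x temperature)\n")
  cat("  + weight-for-age LMS reference (", nrow(x$wfa_reference), " rows )\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Percentile grids: tabulated defaults, piecewise-linear in temperature,
## clamped at grid edges, age resolved to a closed band.
## The default values below are stated approximations, not published curves.

default_grid <- function(values) {
  temps <- seq(37.5, 40.5, by = 0.5)
  bands <- data.frame(age_lo = c(2, 12, 24), age_hi = c(11, 23, 59))
  out <- do.call(rbind, lapply(seq_len(3), function(i) {
    data.frame(age_lo = bands$age_lo[i], age_hi = bands$age_hi[i],
               temp_c = temps, value = values[[i]])
  }))
  tibble::as_tibble(out)
}

default_rr75_grid <- function() {
  default_grid(list(
    seq(48, 60, by = 2),   # 2-11 months
    seq(42, 54, by = 2),   # 12-23 months
    seq(36, 48, by = 2)    # 24-59 months
  ))
}

default_rr97_grid <- function() {
  default_grid(list(
    seq(64, 76, by = 2),
    seq(58, 70, by = 2),
    seq(50, 62, by = 2)
  ))
}

default_hr90_grid <- function() {
  default_grid(list(
    seq(170, 194, by = 4),
    seq(162, 186, by = 4),
    seq(150, 174, by = 4)
  ))
}

validate_percentile_grid <- function(grid, name) {
  needed <- c("age_lo", "age_hi", "temp_c", "value")
  if (!is.data.frame(grid) || !all(needed %in% names(grid))) {
    abort_config(paste0(name, " must have columns age_lo, age_hi, temp_c, value"))
  }
  grid <- tibble::as_tibble(grid[needed])
  if (any(!is.finite(grid$value)) || any(grid$value <= 0)) {
    abort_config(paste0(name, ": values must be positive and finite"))
  }
  bands <- unique(grid[c("age_lo", "age_hi")])
  for (i in seq_len(nrow(bands))) {
    sub <- grid[grid$age_lo == bands$age_lo[i] & grid$age_hi == bands$age_hi[i], ]
    sub <- sub[order(sub$temp_c), ]
    if (is.unsorted(sub$value)) {
      abort_validation(paste0(name, ": values must be non-decreasing in temperature ",
                              "within age band ", bands$age_lo[i], "-", bands$age_hi[i]))
    }
  }
  grid
}

# Vectorized grid lookup shared by rr_percentile()/hr_percentile_90().
grid_lookup <- function(grid, age_months, temperature_c) {
  n <- max(length(age_months), length(temperature_c))
  age_months <- rep_len(age_months, n)
  temperature_c <- rep_len(temperature_c, n)
  out <- rep(NA_real_, n)
  bands <- unique(grid[c("age_lo", "age_hi")])
  for (i in seq_len(nrow(bands))) {
    sub <- grid[grid$age_lo == bands$age_lo[i] & grid$age_hi == bands$age_hi[i], ]
    sub <- sub[order(sub$temp_c), ]
    sel <- !is.na(age_months) & age_months >= bands$age_lo[i] & age_months <= bands$age_hi[i]
    if (!any(sel)) next
    tt <- pmin(pmax(temperature_c[sel], min(sub$temp_c)), max(sub$temp_c))
    out[sel] <- stats::approx(sub$temp_c, sub$value, xout = tt, rule = 2)$y
  }
  if (anyNA(out[!is.na(age_months)])) {
    bad <- age_months[is.na(out) & !is.na(age_months)]
    abort_range(paste0("age outside percentile grid range: ", bad[1], " months"))
  }
  out
}

#' Respiratory-rate percentile threshold for age and temperature
#'
#' Returns the respiratory-rate threshold (breaths/min) at the requested
#' percentile for a child of the given age and axillary temperature, looked up
#' from the tabulated curves in the standards registry (piecewise-linear in
#' temperature, clamped at the grid edges). Both rule engines and the outcome
#' engine call this same function, so the thresholds cannot drift apart.
#'
#' @param age_months Age in months (vectorized).
#' @param temperature_c Axillary temperature in degrees C (vectorized).
#' @param percentile Either 75 or 97.
#' @param standards An `epoctr_standards` registry.
#' @return Numeric vector of thresholds in breaths/min.
#' @export
rr_percentile <- function(age_months, temperature_c, percentile = 97,
                          standards = reference_standards()) {
  standards <- as_standards(standards)
  grid <- switch(as.character(percentile),
                 "75" = standards$rr75_grid,
                 "97" = standards$rr97_grid,
                 abort_config("percentile must be 75 or 97"))
  grid_lookup(grid, age_months, temperature_c)
}

#' Heart-rate 90th-percentile threshold for age and temperature
#'
#' @inheritParams rr_percentile
#' @return Numeric vector of thresholds in beats/min.
#' @export
hr_percentile_90 <- function(age_months, temperature_c,
                             standards = reference_standards()) {
  standards <- as_standards(standards)
  grid_lookup(standards$hr90_grid, age_months, temperature_c)
}

## ---------------------------------------------------------------------------
## Weight-for-age z-score via the LMS transform.
##
## The bundled growth reference is a SYNTHETIC approximation: monthly LMS
## rows expanded by monotone spline from a small set of anchor medians, with
## constant L and S. It reproduces the shape and scale of an under-five
## weight-for-age standard but is not the WHO 2006 table; substitute the real
## LMS table via reference_standards(wfa_reference = ...) for clinical use.

build_wfa_reference <- function(wfa_reference = NULL) {
  if (is.null(wfa_reference)) {
    path <- system.file("extdata", "wfa_lms_synthetic.csv", package = "epoctr")
    if (!nzchar(path)) {
      # during development (package not installed)
      path <- file.path("inst", "extdata", "wfa_lms_synthetic.csv")
    }
    wfa_reference <- utils::read.csv(path)
  }
  needed <- c("age_months", "sex", "median_kg", "lms_l", "lms_s")
  if (!is.data.frame(wfa_reference) || !all(needed %in% names(wfa_reference))) {
    abort_config("wfa_reference must have columns age_months, sex, median_kg, lms_l, lms_s")
  }
  monthly <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    sub <- wfa_reference[wfa_reference$sex == sx, ]
    sub <- sub[order(sub$age_months), ]
    if (nrow(sub) < 2) abort_config(paste0("wfa_reference: need rows for sex ", sx))
    ages <- seq(min(sub$age_months), max(sub$age_months))
    if (nrow(sub) == length(ages) && all(sub$age_months == ages)) {
      m <- sub$median_kg
      l <- sub$lms_l
      s <- sub$lms_s
    } else {
      m <- stats::splinefun(sub$age_months, sub$median_kg, method = "hyman")(ages)
      l <- stats::approx(sub$age_months, sub$lms_l, xout = ages, rule = 2)$y
      s <- stats::approx(sub$age_months, sub$lms_s, xout = ages, rule = 2)$y
    }
    data.frame(age_months = ages, sex = sx, median_kg = m, lms_l = l, lms_s = s)
  }))
  tibble::as_tibble(monthly)
}

#' Weight-for-age z-score
#'
#' LMS-based weight-for-age standard-deviation score:
#' \eqn{z = ((w/M)^L - 1) / (L S)} with the month- and sex-specific LMS
#' parameters from the growth reference in the standards registry. Severe
#' malnutrition screening uses z below -3.
#'
#' @param age_months Age in completed months (vectorized).
#' @param sex "male" or "female" (vectorized).
#' @param weight_kg Weight in kg (vectorized).
#' @param standards An `epoctr_standards` registry.
#' @return Numeric vector of z-scores.
#' @export
weight_for_age_z <- function(age_months, sex, weight_kg,
                             standards = reference_standards()) {
  standards <- as_standards(standards)
  ref <- standards$wfa_reference
  n <- max(length(age_months), length(sex), length(weight_kg))
  age_months <- rep_len(as.numeric(age_months), n)
  sex <- rep_len(as.character(sex), n)
  weight_kg <- rep_len(as.numeric(weight_kg), n)
  if (any(!sex %in% c("male", "female"))) {
    abort_validation("sex must be 'male' or 'female'")
  }
  age_floor <- floor(age_months)
  if (any(age_floor < min(ref$age_months) | age_floor > max(ref$age_months), na.rm = TRUE)) {
    abort_range("age outside growth-reference range")
  }
  key <- paste(age_floor, sex)
  refkey <- paste(ref$age_months, ref$sex)
  idx <- match(key, refkey)
  m <- ref$median_kg[idx]
  l <- ref$lms_l[idx]
  s <- ref$lms_s[idx]
  ((weight_kg / m)^l - 1) / (l * s)
}

# Inverse LMS: the weight at a given z for (age, sex); used by the simulator
# and by the reference-table read-back tests.
wfa_weight_at_z <- function(age_months, sex, z, standards = reference_standards()) {
  standards <- as_standards(standards)
  ref <- standards$wfa_reference
  n <- max(length(age_months), length(sex), length(z))
  age_months <- rep_len(floor(as.numeric(age_months)), n)
  sex <- rep_len(as.character(sex), n)
  z <- rep_len(as.numeric(z), n)
  idx <- match(paste(age_months, sex), paste(ref$age_months, ref$sex))
  m <- ref$median_kg[idx]
  l <- ref$lms_l[idx]
  s <- ref$lms_s[idx]
  m * (1 + l * s * z)^(1 / l)
}

# Age-banded haemoglobin anaemia cutoff (g/l); closed month bands.
hb_anemia_cutoff <- function(age_months, standards) {
  dplyr::case_when(
    age_months <= 6 ~ standards$hb_anemia_cutoff_2_6m,
    age_months <= 24 ~ standards$hb_anemia_cutoff_7_24m,
    TRUE ~ standards$hb_anemia_cutoff_25_59m
  )
}
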