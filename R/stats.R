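#' Arm-level 2x2 event table
#'
#' The unit of every effect estimate: event and total counts for two arms
#' (by convention arm "a" is the intervention and arm "b" the comparator).
#'
#' @param events_a,total_a,events_b,total_b Non-negative counts with
#'   `events <= total` and `total > 0`.
#' @param label_a,label_b Arm labels.
#' @return A one-row tibble of class `two_by_two`.
#' @examples
#' two_by_two(37, 1586, 65, 1583, "e-POCT", "ALMANACH")
#' @export
two_by_two <- function(events_a, total_a, events_b, total_b,
                       label_a = "a", label_b = "b") {
  counts <- c(events_a, total_a, events_b, total_b)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      events_a > total_a || events_b > total_b || total_a <= 0 || total_b <= 0) {
    abort_validation("two_by_two requires 0 <= events <= total and totals > 0")
  }
  structure(
    tibble::tibble(events_a = events_a, total_a = total_a,
                   events_b = events_b, total_b = total_b,
                   label_a = label_a, label_b = label_b),
    class = c("two_by_two", class(tibble::tibble()))
  )
}

as_two_by_two <- function(t) {
  if (inherits(t, "two_by_two")) return(t)
  if (is.data.frame(t) &&
      all(c("events_a", "total_a", "events_b", "total_b") %in% names(t)) &&
      nrow(t) == 1) {
    return(two_by_two(t$events_a, t$total_a, t$events_b, t$total_b,
                      t$label_a %||% "a", t$label_b %||% "b"))
  }
  abort_validation("expected a two_by_two table (see two_by_two())")
}

new_effect_estimate <- function(t, measure, point, lo, hi, conf.level, p = NA_real_) {
  structure(
    tibble::tibble(measure = measure,
                   label_a = t$label_a, label_b = t$label_b,
                   events_a = t$events_a, total_a = t$total_a,
                   events_b = t$events_b, total_b = t$total_b,
                   estimate = point, conf.low = lo, conf.high = hi,
                   conf.level = conf.level, p.value = p),
    class = c("effect_estimate", class(tibble::tibble()))
  )
}

#' Risk ratio with Katz log-method confidence interval
#'
#' Point estimate \eqn{(a/n_a)/(b/n_b)} with the Katz interval
#' \eqn{\exp(\log RR \pm z_{1-\alpha/2}\sqrt{1/a - 1/n_a + 1/b - 1/n_b})},
#' the classical large-sample interval used by standard epi-table routines.
#' No continuity correction is applied by default; zero events in the
#' comparator arm make the estimate undefined and raise an error unless
#' `zero_correction = TRUE` adds 0.5 to every cell.
#'
#' @param t A [two_by_two()] table (or a one-row data frame with the same
#'   count columns).
#' @param conf.level Confidence level (default 0.95).
#' @param zero_correction Opt-in 0.5 cell correction for zero cells.
#' @return A one-row `effect_estimate` tibble with the chi-squared p-value.
#' @examples
#' risk_ratio(two_by_two(37, 1586, 65, 1583))
#' @export
risk_ratio <- function(t, conf.level = 0.95, zero_correction = FALSE) {
  t <- as_two_by_two(t)
  a <- t$events_a; na <- t$total_a; b <- t$events_b; nb <- t$total_b
  if ((a == 0 || b == 0) && zero_correction) {
    a <- a + 0.5; b <- b + 0.5; na <- na + 1; nb <- nb + 1
  }
  if (b == 0) {
    abort_validation("risk ratio undefined: zero events in comparator arm (set zero_correction = TRUE to opt in to a 0.5 correction)")
  }
  rr <- (a / na) / (b / nb)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  if (a == 0) {
    lo <- 0
    hi <- Inf
  } else {
    se <- sqrt(1 / a - 1 / na + 1 / b - 1 / nb)
    lo <- exp(log(rr) - z * se)
    hi <- exp(log(rr) + z * se)
  }
  p <- tryCatch(chi_squared(t)$p.value, error = function(e) NA_real_)
  new_effect_estimate(t, "risk_ratio", rr, lo, hi, conf.level, p)
}

#' Risk difference in percentage points with Wald confidence interval
#'
#' \eqn{100 (p_a - p_b)} with the Wald interval
#' \eqn{\pm z \cdot 100 \sqrt{p_a q_a / n_a + p_b q_b / n_b}}.
#'
#' @inheritParams risk_ratio
#' @return A one-row `effect_estimate` tibble (units: percentage points).
#' @examples
#' risk_difference(two_by_two(37, 1586, 65, 1583))
#' @export
risk_difference <- function(t, conf.level = 0.95) {
  t <- as_two_by_two(t)
  pa <- t$events_a / t$total_a
  pb <- t$events_b / t$total_b
  rd <- 100 * (pa - pb)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  se <- 100 * sqrt(pa * (1 - pa) / t$total_a + pb * (1 - pb) / t$total_b)
  p <- tryCatch(chi_squared(t)$p.value, error = function(e) NA_real_)
  new_effect_estimate(t, "risk_difference_pp", rd, rd - z * se, rd + z * se,
                      conf.level, p)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction, matching the convention of classical
#' epi-table procedures.
#'
#' @inheritParams risk_ratio
#' @return Tibble with `statistic`, `df`, `p.value`.
#' @export
chi_squared <- function(t) {
  t <- as_two_by_two(t)
  m <- matrix(c(t$events_a, t$total_a - t$events_a,
                t$events_b, t$total_b - t$events_b),
              nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort_validation("degenerate 2x2 table: a margin is zero")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p.value = ht$p.value)
}

#' Non-inferiority decision from a risk-difference estimate
#'
#' Declares non-inferiority when the upper bound of the two-sided 95%
#' confidence interval of the risk difference (equivalently a one-sided
#' 97.5% bound) lies strictly below the margin; otherwise the result is
#' inconclusive. The comparison is strict: a bound exactly on the margin is
#' not inside it.
#'
#' @param rd An `effect_estimate` from [risk_difference()] (or anything with
#'   a `conf.high` in percentage points).
#' @param margin_pp Non-inferiority margin in percentage points (> 0);
#'   default 3.
#' @return `"non_inferior"` or `"inconclusive"`.
#' @examples
#' noninferiority_decision(risk_difference(two_by_two(37, 1586, 65, 1583)))
#' @export
noninferiority_decision <- function(rd, margin_pp = 3) {
  if (!is.numeric(margin_pp) || length(margin_pp) != 1 || margin_pp <= 0) {
    abort_config("margin_pp must be a single positive number")
  }
  hi <- if (is.data.frame(rd)) rd$conf.high else rd
  if (length(hi) != 1 || !is.finite(hi)) {
    abort_validation("need a single finite upper confidence bound")
  }
  if (hi < margin_pp) "non_inferior" else "inconclusive"
}

#' Number needed to treat
#'
#' \eqn{\lceil 100 / |RD| \rceil} for a risk difference in percentage points.
#'
#' @param rd An `effect_estimate` from [risk_difference()] or a single risk
#'   difference in percentage points.
#' @return Integer NNT.
#' @examples
#' nnt(risk_difference(two_by_two(37, 1586, 65, 1583)))  # 57
#' @export
nnt <- function(rd) {
  point <- if (is.data.frame(rd)) rd$estimate else rd
  if (length(point) != 1 || !is.finite(point) || point == 0) {
    abort_validation("NNT undefined for a zero (or non-finite) risk difference")
  }
  as.integer(ceiling(100 / abs(point)))
}

#' Sample size for a non-inferiority comparison of two proportions
#'
#' Per-arm \eqn{n = \lceil (z_{1-\alpha} + z_{power})^2 (p_a q_a + p_b q_b) /
#' margin^2 \rceil}, with a one-sided alpha; returns both arms combined.
#'
#' @param p_a,p_b Assumed event proportions in the two arms (0-1).
#' @param margin Non-inferiority margin on the proportion scale (e.g. 0.03).
#' @param power Target power (default 0.8).
#' @param one_sided_alpha One-sided type-I error (default 0.025).
#' @return Tibble with `n_per_arm` and `n_total`.
#' @examples
#' noninferiority_sample_size(0.10, 0.10, 0.03)  # 1570 per arm, 3140 total
#' @export
noninferiority_sample_size <- function(p_a, p_b, margin, power = 0.8,
                                       one_sided_alpha = 0.025) {
  vals <- c(p_a, p_b, margin, power, one_sided_alpha)
  if (any(!is.finite(vals))) abort_config("all inputs must be finite")
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) {
    abort_config("proportions must be in (0, 1)")
  }
  if (margin <= 0 || power <= 0 || power >= 1) {
    abort_config("margin must be > 0 and power in (0, 1)")
  }
  z <- stats::qnorm(1 - one_sided_alpha) + stats::qnorm(power)
  n <- ceiling(z^2 * (p_a * (1 - p_a) + p_b * (1 - p_b)) / margin^2)
  tibble::tibble(n_per_arm = as.integer(n), n_total = as.integer(2 * n))
}

#' Mantel-Haenszel stratified risk ratio
#'
#' Pools per-stratum 2x2 tables with the Mantel-Haenszel weights
#' \eqn{RR_{MH} = \sum_i a_i n_{b,i} / N_i \; / \; \sum_i b_i n_{a,i} / N_i},
#' with the Greenland-Robins variance for the confidence interval, plus a
#' chi-squared heterogeneity statistic comparing stratum-specific log risk
#' ratios against the pooled estimate.
#'
#' @param strata A data frame with one row per stratum and columns
#'   `events_a`, `total_a`, `events_b`, `total_b` (e.g. built by binding
#'   [two_by_two()] rows).
#' @param conf.level Confidence level.
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`,
#'   `het_statistic`, `het_df`, `het_p.value`, `n_strata`.
#' @export
mantel_haenszel_rr <- function(strata, conf.level = 0.95) {
  if (!is.data.frame(strata) || nrow(strata) < 1 ||
      !all(c("events_a", "total_a", "events_b", "total_b") %in% names(strata))) {
    abort_validation("strata must have >= 1 row with events/total columns")
  }
  a <- strata$events_a; na <- strata$total_a
  b <- strata$events_b; nb <- strata$total_b
  if (any(a > na | b > nb | na <= 0 | nb <= 0 | a < 0 | b < 0)) {
    abort_validation("invalid stratum counts")
  }
  N <- na + nb
  num <- sum(a * nb / N)
  den <- sum(b * na / N)
  if (den == 0 || num == 0) {
    abort_validation("Mantel-Haenszel risk ratio undefined: zero pooled events")
  }
  rr <- num / den
  # Greenland-Robins variance of log(RR_MH)
  P <- sum(((a + b) * na * nb / N - a * b) / N^2)
  se <- sqrt(P / (num * den))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)

  # heterogeneity: Cochran-style chi-squared of stratum log RRs around pooled
  ok <- a > 0 & b > 0
  het_df <- max(sum(ok) - 1, 0)
  if (het_df > 0) {
    lrr_i <- log((a[ok] / na[ok]) / (b[ok] / nb[ok]))
    w_i <- 1 / (1 / a[ok] - 1 / na[ok] + 1 / b[ok] - 1 / nb[ok])
    het <- sum(w_i * (lrr_i - log(rr))^2)
    het_p <- stats::pchisq(het, het_df, lower.tail = FALSE)
  } else {
    het <- NA_real_; het_p <- NA_real_
  }
  tibble::tibble(
    measure = "mantel_haenszel_rr",
    estimate = rr,
    conf.low = exp(log(rr) - z * se),
    conf.high = exp(log(rr) + z * se),
    conf.level = conf.level,
    het_statistic = het, het_df = het_df, het_p.value = het_p,
    n_strata = nrow(strata)
  )
}

#' Kaplan-Meier curve for days to fever resolution
#'
#' Product-limit estimator with right censoring, fitted with
#' [survival::survfit()]. The event marks fever resolution; censored
#' observations are children still febrile at last contact.
#'
#' @param data Data frame with the time and event columns.
#' @param time,event Column names (strings) of the day and the 0/1 resolution
#'   indicator.
#' @param by Optional grouping column (e.g. arm).
#' @return Object of class `km_fit`: a list with the `survfit` fit and a tidy
#'   step tibble (`time`, `n.risk`, `n.event`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, and `group` when `by` is given).
#' @export
kaplan_meier <- function(data, time = "day", event = "resolved", by = NULL) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort_validation("kaplan_meier needs a non-empty data frame")
  }
  if (!all(c(time, event) %in% names(data))) {
    abort_validation("time/event columns not found")
  }
  if (any(data[[time]] < 0, na.rm = TRUE)) abort_validation("times must be >= 0")
  df <- data.frame(.time = data[[time]], .event = as.integer(data[[event]]))
  if (!is.null(by)) {
    df$.group <- as.character(data[[by]])
    fit <- survival::survfit(survival::Surv(.time, .event) ~ .group, data = df)
    groups <- rep(sub("^\\.group=", "", names(fit$strata)), fit$strata)
  } else {
    fit <- survival::survfit(survival::Surv(.time, .event) ~ 1, data = df)
    groups <- rep(NA_character_, length(fit$time))
  }
  steps <- tibble::tibble(
    group = groups, time = fit$time, n.risk = fit$n.risk,
    n.event = fit$n.event, estimate = fit$surv,
    std.error = fit$std.err, conf.low = fit$lower, conf.high = fit$upper
  )
  structure(list(fit = fit, steps = steps, grouped = !is.null(by)),
            class = "km_fit")
}

#' Query a Kaplan-Meier step function at given days
#'
#' @param km A `km_fit` from [kaplan_meier()].
#' @param days Days at which to evaluate the survival (still-febrile)
#'   probability.
#' @param group Stratum label when the fit is grouped.
#' @return Numeric vector of survival probabilities.
#' @export
survival_at <- function(km, days, group = NULL) {
  stopifnot(inherits(km, "km_fit"))
  steps <- km$steps
  if (km$grouped) {
    if (is.null(group)) abort_validation("grouped fit: supply `group`")
    steps <- steps[steps$group == group, ]
    if (nrow(steps) == 0) abort_validation(paste0("unknown group: ", group))
  }
  vapply(days, function(d) {
    idx <- steps$time <= d
    if (!any(idx)) 1 else steps$estimate[max(which(idx))]
  }, numeric(1))
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> product-limit estimate,", length(x$fit$time), "time points\n")
  print(utils::head(x$steps, 10))
  invisible(x)
}

#' Block randomization
#'
#' Assigns `n` subjects to two arms in permuted blocks, balanced within each
#' block; deterministic given the seed.
#'
#' @param n Number of subjects.
#' @param block_size Even block size (default 4).
#' @param seed Integer seed.
#' @param arms Two arm labels.
#' @return Tibble with `position`, `block`, `arm`.
#' @export
block_randomize <- function(n, block_size = 4, seed = 1,
                            arms = c("a", "b")) {
  if (block_size %% 2 != 0 || block_size <= 0) {
    abort_config("block_size must be a positive even number")
  }
  if (length(arms) != 2) abort_config("exactly two arms are supported")
  n_blocks <- ceiling(n / block_size)
  assignments <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_blocks), function(b) {
      sample(rep(arms, block_size / 2))
    }))
  })
  tibble::tibble(position = seq_len(n),
                 block = rep(seq_len(n_blocks), each = block_size)[seq_len(n)],
                 arm = assignments[seq_len(n)])
}

#' Construct intention-to-treat and per-protocol analysis populations
#'
#' ITT comprises all randomized patients, with lost-to-follow-up counted as
#' clinical failures; PP comprises patients who received the intervention and
#' completed the day-7 assessment (withdrawals and lost-to-follow-up
#' excluded).
#'
#' @param outcomes Tibble with at least `patient_id`, `clinical_failure`
#'   (logical, `NA` allowed when lost) and `lost_to_followup`; an optional
#'   `withdrew` column marks consent withdrawals (excluded from both
#'   populations' denominators except ITT, where withdrawals are retained
#'   only if `withdrawals_in_itt = TRUE`).
#' @param withdrawals_in_itt Keep withdrawals in the ITT denominator
#'   (counted as failures); default `FALSE`.
#' @return The input with logical `in_itt`, `in_pp` and `failure_itt`
#'   columns; `failure_itt` is the ITT failure indicator (lost = failure).
#' @export
build_populations <- function(outcomes, withdrawals_in_itt = FALSE) {
  needed <- c("patient_id", "clinical_failure", "lost_to_followup")
  if (!all(needed %in% names(outcomes))) {
    abort_validation(paste0("outcomes must have columns: ",
                            paste(needed, collapse = ", ")))
  }
  out <- tibble::as_tibble(outcomes)
  withdrew <- if ("withdrew" %in% names(out)) out$withdrew else FALSE
  withdrew <- dplyr::coalesce(withdrew, FALSE)
  out$in_itt <- if (withdrawals_in_itt) TRUE else !withdrew
  out$in_pp <- !withdrew & !out$lost_to_followup & !is.na(out$clinical_failure)
  out$failure_itt <- dplyr::coalesce(out$clinical_failure, TRUE) | out$lost_to_followup
  out
}

## ---------------------------------------------------------------------------
## broom-style methods and plots

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy effect_estimate
#' @export
tidy.effect_estimate <- function(x, ...) {
  tibble::as_tibble(x)[c("measure", "estimate", "conf.low", "conf.high",
                         "conf.level", "p.value")]
}

#' @method glance effect_estimate
#' @export
glance.effect_estimate <- function(x, ...) {
  tibble::tibble(
    measure = x$measure,
    p_a = x$events_a / x$total_a,
    p_b = x$events_b / x$total_b,
    n = x$total_a + x$total_b
  )
}

#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) x$steps

#' @method glance km_fit
#' @export
glance.km_fit <- function(x, ...) {
  below <- x$steps$time[x$steps$estimate <= 0.5]
  tibble::tibble(n = sum(x$fit$n), events = sum(x$fit$n.event),
                 median_time = if (length(below)) min(below) else NA_real_)
}

#' Forest-style plot of effect estimates
#'
#' @param estimates One or more `effect_estimate` rows bound together; a
#'   `label` column (e.g. outcome name) is used for the y axis if present.
#' @param margin_pp Optional non-inferiority margin drawn as a dashed line
#'   (meaningful for risk differences).
#' @return A ggplot object.
#' @export
plot_effects <- function(estimates, margin_pp = NULL) {
  df <- tibble::as_tibble(estimates)
  if (!"label" %in% names(df)) df$label <- paste0(df$measure, " ", seq_len(nrow(df)))
  null_line <- if (all(df$measure == "risk_difference_pp")) 0 else 1
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = null_line, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = unique(df$measure)[1], y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(margin_pp)) {
    p <- p + ggplot2::geom_vline(xintercept = margin_pp, linetype = "dashed",
                                 colour = "blue")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  steps <- object$steps
  # prepend S(0) = 1 for drawing
  starts <- steps |>
    dplyr::summarise(time = 0, estimate = 1,
                     .by = dplyr::any_of("group"))
  df <- dplyr::bind_rows(starts, steps[c(names(starts))])
  aes <- if (object$grouped) {
    ggplot2::aes(x = .data$time, y = .data$estimate, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$time, y = .data$estimate)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "day", y = "proportion still febrile") +
    ggplot2::theme_minimal()
}
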