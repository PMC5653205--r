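test_that("risk ratio (Katz) reproduces hand-checked values and symmetry", {
  est <- risk_ratio(two_by_two(37, 1586, 65, 1583))
  expect_equal(round(est$estimate, 2), 0.57)
  expect_equal(round(est$conf.low, 2), 0.38)
  expect_equal(round(est$conf.high, 2), 0.85)

  est <- risk_ratio(two_by_two(10, 1586, 24, 1583))
  expect_equal(round(c(est$estimate, est$conf.low, est$conf.high), 2),
               c(0.42, 0.20, 0.87))

  # equal proportions: point exactly 1, CI spans 1
  est <- risk_ratio(two_by_two(5, 100, 5, 100))
  expect_equal(est$estimate, 1)
  expect_true(est$conf.low < 1 && est$conf.high > 1)

  # zero comparator events: undefined without the opt-in correction
  expect_error(risk_ratio(two_by_two(3, 100, 0, 100)),
               class = "epoctr_validation_error")
  expect_silent(risk_ratio(two_by_two(3, 100, 0, 100), zero_correction = TRUE))

  # oracle equivalence on random tables against a direct formula evaluation
  withr::with_seed(99, {
    for (k in 1:50) {
      na <- sample(50:2000, 1); nb <- sample(50:2000, 1)
      a <- sample(1:(na / 2), 1); b <- sample(1:(nb / 2), 1)
      est <- risk_ratio(two_by_two(a, na, b, nb))
      rr <- (a / na) / (b / nb)
      se <- sqrt(1 / a - 1 / na + 1 / b - 1 / nb)
      expect_equal(est$estimate, rr)
      expect_equal(est$conf.low, exp(log(rr) - qnorm(0.975) * se))
      expect_equal(est$conf.high, exp(log(rr) + qnorm(0.975) * se))
    }
  })
})

test_that("risk difference (Wald, percentage points) matches the printed table values", {
  est <- risk_difference(two_by_two(182, 1586, 470, 1583))
  expect_equal(round(est$estimate, 1), -18.2)
  expect_equal(round(c(est$conf.low, est$conf.high), 1), c(-21.0, -15.5))

  # identical arms: 0 with a CI symmetric about 0
  est <- risk_difference(two_by_two(20, 400, 20, 400))
  expect_equal(est$estimate, 0)
  expect_equal(est$conf.low, -est$conf.high)

  # primary-outcome table: the unrounded point is -1.77 pp (prints as -1.7/-1.8
  # depending on rounding convention), CI (-3.0, -0.5)
  est <- risk_difference(two_by_two(37, 1586, 65, 1583))
  expect_equal(est$estimate, -1.7732, tolerance = 1e-4)
  expect_equal(round(c(est$conf.low, est$conf.high), 1), c(-3.0, -0.5))
})

test_that("chi-squared is Pearson without continuity correction, 2x2 only", {
  expect_equal(chi_squared(two_by_two(37, 1586, 65, 1583))$p.value, 0.005,
               tolerance = 0.1)
  expect_equal(round(chi_squared(two_by_two(37, 1586, 65, 1583))$p.value, 3), 0.005)
  expect_equal(chi_squared(two_by_two(5, 100, 5, 100))$p.value, 1)
  expect_error(chi_squared(two_by_two(0, 50, 0, 50)),
               class = "epoctr_validation_error")
  expect_error(risk_ratio(data.frame(a = 1)), class = "epoctr_validation_error")
})

test_that("non-inferiority decision is strict at the margin", {
  rd <- risk_difference(two_by_two(37, 1586, 65, 1583))
  expect_equal(noninferiority_decision(rd, 3), "non_inferior")
  expect_equal(noninferiority_decision(3.0, 3), "inconclusive")  # boundary excluded
  expect_equal(noninferiority_decision(2.9, 3), "non_inferior")
  expect_error(noninferiority_decision(rd, -1), class = "epoctr_config_error")
})

test_that("number needed to treat", {
  expect_equal(nnt(risk_difference(two_by_two(37, 1586, 65, 1583))), 57L)
  expect_equal(nnt(-50), 2L)
  expect_equal(nnt(-0.9), 112L)
  expect_error(nnt(0), class = "epoctr_validation_error")
})

test_that("non-inferiority sample size reproduces the design and is monotone in the margin", {
  n <- noninferiority_sample_size(0.10, 0.10, 0.03, power = 0.80,
                                  one_sided_alpha = 0.025)
  expect_equal(n$n_total, 3140L)
  expect_equal(n$n_per_arm, 1570L)

  expect_equal(noninferiority_sample_size(0.05, 0.05, 0.05)$n_total, 598L)

  n2 <- noninferiority_sample_size(0.10, 0.10, 0.06)
  expect_lt(n2$n_total, n$n_total)
  expect_error(noninferiority_sample_size(0, 0.1, 0.03),
               class = "epoctr_config_error")
})

test_that("Mantel-Haenszel pooled risk ratio: reduction, pooling, and oracle equivalence", {
  one <- two_by_two(12, 200, 20, 210)
  mh <- mantel_haenszel_rr(one)
  expect_equal(mh$estimate, risk_ratio(one)$estimate)

  two_same <- dplyr::bind_rows(one, one)
  expect_equal(mantel_haenszel_rr(two_same)$estimate, risk_ratio(one)$estimate)

  strata <- withr::with_seed(7, {
    dplyr::bind_rows(lapply(1:5, function(i) {
      na <- sample(100:500, 1); nb <- sample(100:500, 1)
      two_by_two(rbinom(1, na, 0.08) + 1, na, rbinom(1, nb, 0.12) + 1, nb)
    }))
  })
  mh <- mantel_haenszel_rr(strata)

  # brute-force re-implementation of the pooled estimator and its variance
  num <- den <- P <- 0
  for (i in seq_len(nrow(strata))) {
    a <- strata$events_a[i]; na <- strata$total_a[i]
    b <- strata$events_b[i]; nb <- strata$total_b[i]
    N <- na + nb
    num <- num + a * nb / N
    den <- den + b * na / N
    P <- P + ((a + b) * na * nb / N - a * b) / N^2
  }
  expect_equal(mh$estimate, num / den)
  expect_equal(mh$conf.low, exp(log(num / den) - qnorm(0.975) * sqrt(P / (num * den))))

  # cross-check against an independent published implementation
  fit <- metafor::rma.mh(ai = strata$events_a, bi = strata$total_a - strata$events_a,
                         ci = strata$events_b, di = strata$total_b - strata$events_b,
                         measure = "RR")
  expect_equal(unname(exp(fit$beta[1])), mh$estimate, tolerance = 1e-8)
})

test_that("Kaplan-Meier product-limit estimate matches a hand-computed risk-set table", {
  df <- data.frame(day = c(1, 1, 2, 3, 3, 4, 6, 6, 8, 10),
                   resolved = c(1, 0, 1, 1, 1, 0, 1, 0, 1, 0))
  km <- kaplan_meier(df)
  expect_equal(survival_at(km, c(1, 2, 3, 6, 8)),
               c(0.9, 0.7875, 0.5625, 0.421875, 0.2109375))
  expect_equal(survival_at(km, 0.5), 1)

  # all events at day 1
  km <- kaplan_meier(data.frame(day = rep(1, 4), resolved = 1))
  expect_equal(survival_at(km, 1), 0)

  # no events at all: survival stays 1
  km <- kaplan_meier(data.frame(day = 1:5, resolved = 0))
  expect_true(all(km$steps$estimate == 1))

  expect_error(kaplan_meier(data.frame()), class = "epoctr_validation_error")

  grouped <- kaplan_meier(data.frame(day = c(df$day, df$day),
                                     resolved = c(df$resolved, rep(0, 10)),
                                     arm = rep(c("a", "b"), each = 10)), by = "arm")
  expect_equal(survival_at(grouped, 3, group = "a"), 0.5625)
  expect_equal(survival_at(grouped, 10, group = "b"), 1)
})

test_that("block randomization balances every block and is seed-deterministic", {
  r <- block_randomize(8, block_size = 4, seed = 5)
  counts <- table(r$block, r$arm)
  expect_true(all(counts == 2))
  expect_identical(r, block_randomize(8, block_size = 4, seed = 5))
  expect_false(identical(r$arm, block_randomize(8, 4, seed = 6)$arm))
  expect_error(block_randomize(8, block_size = 3), class = "epoctr_config_error")

  # a partial final block is still internally balanced up to rounding
  r <- block_randomize(10, block_size = 4, seed = 1)
  expect_equal(nrow(r), 10)
  expect_true(all(table(r$block[1:8], r$arm[1:8]) == 2))
})

test_that("ITT counts the lost as failures; PP excludes them", {
  outcomes <- tibble::tibble(
    patient_id = sprintf("p%03d", 1:100),
    clinical_failure = c(rep(TRUE, 10), rep(FALSE, 85), rep(NA, 5)),
    lost_to_followup = c(rep(FALSE, 95), rep(TRUE, 5))
  )
  pops <- build_populations(outcomes)
  expect_equal(sum(pops$in_itt), 100)
  expect_equal(sum(pops$in_pp), 95)
  itt_failures <- sum(pops$failure_itt[pops$in_itt])
  pp_failures <- sum(pops$clinical_failure[pops$in_pp])
  expect_equal(itt_failures, pp_failures + 5)
})
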