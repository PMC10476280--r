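# Off-rate estimators, Kaplan-Meier, log-rank, t-test, tail proportions.

part_row <- function(ternary_s = 0, nonternary_s = 0, ever = FALSE,
                     off = TRUE, t3 = 0, t5 = 0) {
  dur <- ternary_s + nonternary_s
  tibble::tibble(spot = 1L, onset_s = 0, end_s = dur, duration_s = dur,
                 t1 = ternary_s - t5, t2 = 0, t3 = t3,
                 t4 = nonternary_s - t3, t5 = t5,
                 ternary_s = ternary_s, nonternary_s = nonternary_s,
                 overlap_s = ternary_s, ever_ternary = ever,
                 arrival_class = if (ever) "partner_first" else "none",
                 right_censored = !off, off_event_observed = off)
}

test_that("off-rate formula: N events over summed pool time, in per hour", {
  # 10 ternary residences, all detaching, 1000 s total -> 36 /h
  parts <- dplyr::bind_rows(lapply(1:10, function(i)
    part_row(ternary_s = 100, ever = TRUE, off = TRUE)))
  k <- estimate_offrate(parts, "ternary")
  expect_equal(k$k_per_h, 36)
  expect_equal(k$n_off, 10L)

  # 5 detachments + 1 right-censored residence over 2000 s -> 9 /h
  parts2 <- dplyr::bind_rows(
    lapply(1:5, function(i) part_row(nonternary_s = 1500 / 5, off = TRUE)),
    part_row(nonternary_s = 500, off = FALSE))
  k2 <- estimate_offrate(parts2, "non_ternary")
  expect_equal(k2$k_per_h, 5 / 2000 * 3600)
  expect_equal(k2$n_off, 5L)
})

test_that("T3 time accrues to the non-ternary pool without an off-event", {
  # one residence: T3 = 60 s then T5 = 40 s, detaching at the end
  parts <- part_row(ternary_s = 40, nonternary_s = 60, ever = TRUE,
                    off = TRUE, t3 = 60, t5 = 40)
  kt <- estimate_offrate(parts, "ternary")
  kn <- estimate_offrate(parts, "non_ternary")
  expect_equal(kt$n_off, 1L)            # the detachment is ternary (ever_ternary)
  expect_equal(kt$total_time_s, 40)
  expect_equal(kn$n_off, 0L)            # partner arrival is not an off-event
  expect_equal(kn$total_time_s, 60)
})

test_that("the rate estimator recovers simulated exponential dwells", {
  set.seed(51)
  for (k_true in c(15, 25, 40)) {
    dwell <- rexp(1000, k_true / 3600)
    cens <- runif(1000) < 0.03          # < 5% censoring adds time, no events
    est <- offrate_from_durations(dwell, cens)
    expect_lt(abs(est$k_per_h - k_true), 3 * k_true / sqrt(est$n_off))
  }
  # relative bias < 2% at n = 5000 (averaged over replicates)
  ks <- replicate(30, offrate_from_durations(rexp(5000, 25 / 3600))$k_per_h)
  expect_lt(abs(mean(ks) / 25 - 1), 0.02)
})

test_that("KM estimate matches the hand-computed examples", {
  f <- km_estimate(c(1, 2, 3))
  expect_equal(f$curve$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(f$median_s, 2)

  all_cens <- km_estimate(c(1, 2, 3), censored = c(TRUE, TRUE, TRUE))
  expect_true(all(all_cens$curve$surv == 1))
  expect_true(is.na(all_cens$median_s))

  worked <- km_estimate(c(5, 8, 12, 20, 25), c(FALSE, TRUE, FALSE, TRUE, FALSE))
  s <- worked$curve$surv[worked$curve$n_event > 0]
  expect_equal(s, c(0.8, 0.8 * 2 / 3, 0), tolerance = 1e-12)
  expect_equal(worked$median_s, 25)
  expect_equal(worked$n_censored, 2)
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(53)
  x <- rexp(400, 1 / 100)
  f <- km_estimate(x)
  emp <- vapply(f$curve$time, function(t) mean(x > t), 0)
  expect_equal(f$curve$surv, emp, tolerance = 1e-12)
  # and agrees with the naive product-limit oracle under censoring
  cens <- runif(400) < 0.2
  f2 <- km_estimate(x, cens)
  o <- oracle_km(x, !cens)
  got <- f2$curve$surv[f2$curve$n_event > 0]
  expect_equal(got, o$surv, tolerance = 1e-12)
})

test_that("KM median is consistent with ln(2)/k on exponential dwells", {
  set.seed(57)
  k <- 30 / 3600
  x <- rexp(600, k)
  cens <- runif(600) < 0.03
  f <- km_estimate(x, cens)
  target <- log(2) / k
  # the pointwise band contains 0.5 between these crossings
  ci_lo <- min(f$curve$time[f$curve$lower <= 0.5])
  ci_hi <- min(f$curve$time[f$curve$upper <= 0.5])
  expect_gte(target, ci_lo)
  expect_lte(target, ci_hi)
})

test_that("log-rank test matches the hand-enumerated worked example", {
  got <- logrank_test(c(2, 4), c(FALSE, FALSE), c(1, 3), c(FALSE, TRUE))
  want <- oracle_logrank(c(2, 4), c(TRUE, TRUE), c(1, 3), c(TRUE, FALSE))
  expect_equal(got$statistic, want, tolerance = 1e-10)
  # hand arithmetic for the same data: (O-E)^2 / V = (1/6)^2 / 0.47222
  expect_equal(want, (1 / 6)^2 / (0.25 + 2 / 9), tolerance = 1e-12)
})

test_that("log-rank is symmetric and null on identical groups", {
  x <- c(3, 7, 9, 14); cen <- c(FALSE, FALSE, TRUE, FALSE)
  same <- logrank_test(x, cen, x, cen)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  set.seed(61)
  a <- rexp(80, 1 / 90); b <- rexp(120, 1 / 60)
  ab <- logrank_test(a, durations_b = b)
  ba <- logrank_test(b, durations_b = a)
  expect_equal(ab$statistic, ba$statistic, tolerance = 1e-10)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-10)
})

test_that("replicate-rate comparison handles identical and degenerate inputs", {
  same <- compare_rates(c(10, 12, 14), c(10, 12, 14))
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  ident <- compare_rates(c(10, 10, 10), c(10, 10, 10))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_warning(deg <- compare_rates(c(10, 10, 10), c(20, 20, 20)), "zero")
  expect_equal(deg$p_value, 0)
  expect_error(compare_rates(10, c(1, 2)), "2 replicates")
  # agrees with stats::t.test on regular input
  a <- c(25, 29, 31); b <- c(20, 22, 19)
  got <- compare_rates(a, b)
  want <- t.test(a, b, var.equal = TRUE)
  expect_equal(got$p_value, want$p.value)
})

test_that("short/long proportions use strict cuts and the exponential tail", {
  got <- short_long_proportions(c(60, 400, 100), 120, 300)
  expect_equal(got$p_short, 2 / 3)
  expect_equal(got$p_long, 1 / 3)
  flat <- short_long_proportions(rep(200, 10), 120, 300)
  expect_equal(c(flat$p_short, flat$p_long), c(0, 0))
  set.seed(63)
  x <- rexp(10000, 30 / 3600)   # mean 120 s
  sl <- short_long_proportions(x)
  expect_lt(abs(sl$p_short - (1 - exp(-1))), 0.015)
  expect_lt(abs(sl$p_long - exp(-2.5)), 0.009)
})

test_that("tidy and glance expose the fitted curves in broom form", {
  f <- km_estimate(c(5, 8, 12, 20, 25), c(FALSE, TRUE, FALSE, TRUE, FALSE))
  td <- tidy(f)
  expect_true(all(c("time", "estimate", "conf.low", "conf.high") %in% names(td)))
  gl <- glance(f)
  expect_equal(gl$n, 5)
  expect_equal(gl$median_s, 25)
  parts <- part_row(ternary_s = 100, ever = TRUE)
  expect_equal(glance(estimate_offrate(parts, "ternary"))$k_per_h, 36)
})
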