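# Colocalization, ternary partition and occupancy accounting.

mk_pulses <- function(df) {
  tibble::tibble(spot = df$spot, channel = df$channel, onset_s = df$onset,
                 end_s = df$onset + df$dur, duration_s = df$dur,
                 n_frames = as.integer(df$dur / 5),
                 right_censored = if (is.null(df$cens)) FALSE else df$cens,
                 present_at_start = df$onset == 0)
}

test_that("endpoint colocalization: identity, disjoint and greedy matching", {
  a <- tibble::tibble(spot = 1:5, r = c(10, 20, 30, 40, 50), c = 10,
                      area = 9, persistency = 1)
  expect_equal(endpoint_colocalization(a, a)$fraction, 100)
  b <- dplyr::mutate(a, r = r + 100)
  expect_equal(endpoint_colocalization(a, b)$fraction, 0)
  # one query spot can satisfy only one reference
  ref2 <- tibble::tibble(spot = 1:2, r = c(10, 11), c = 10, area = 9, persistency = 1)
  q1 <- tibble::tibble(spot = 1L, r = 10.2, c = 10, area = 9, persistency = 1)
  expect_equal(endpoint_colocalization(ref2, q1, match_radius = 2)$n_colocalized, 1L)
  # empty reference: fraction undefined, not zero
  empty <- a[0, ]
  expect_true(is.na(endpoint_colocalization(empty, a)$fraction))
})

test_that("simulated endpoint occupancy falls in the binomial interval", {
  set.seed(10)
  n <- 1000
  ref <- tibble::tibble(spot = 1:n, r = runif(n, 10, 990), c = runif(n, 10, 990),
                        area = 9, persistency = 1)
  occupied <- runif(n) < 0.5
  q <- ref[occupied, ]
  q$r <- q$r + rnorm(sum(occupied), 0, 0.2)   # localization jitter
  got <- endpoint_colocalization(ref, q, match_radius = 2)
  p_hat <- got$fraction / 100
  expect_lt(abs(p_hat - mean(occupied)), 0.01)          # matching is exact here
  expect_lt(abs(p_hat - 0.5), 2 * sqrt(0.25 / n) + 0.01) # binomial interval
})

test_that("the three canonical partition cases reproduce their splits", {
  # partner first: partner [0,100], focal [50,150] -> all 100 s ternary (T1)
  p1 <- dplyr::bind_rows(
    mk_pulses(list(spot = 1, channel = "g", onset = 50, dur = 100)),
    mk_pulses(list(spot = 1, channel = "r", onset = 0, dur = 100)))
  r1 <- partition_residences(p1, "g", "r")
  expect_equal(r1$t1, 100); expect_equal(r1$ternary_s, 100)
  expect_equal(r1$nonternary_s, 0)
  expect_equal(r1$arrival_class, "partner_first")

  # partner last: focal [0,100], partner onset 60 -> T3 = 60, T5 = 40
  p2 <- dplyr::bind_rows(
    mk_pulses(list(spot = 1, channel = "g", onset = 0, dur = 100)),
    mk_pulses(list(spot = 1, channel = "r", onset = 60, dur = 30)))
  r2 <- partition_residences(p2, "g", "r")
  expect_equal(r2$t3, 60); expect_equal(r2$t5, 40)
  expect_equal(r2$ternary_s, 40); expect_equal(r2$nonternary_s, 60)
  expect_true(r2$ever_ternary)

  # partner never present: focal [0,100] alone -> T4 = 100
  p3 <- mk_pulses(list(spot = 1, channel = "g", onset = 0, dur = 100))
  r3 <- partition_residences(p3, "g", "r")
  expect_equal(r3$t4, 100); expect_false(r3$ever_ternary)
  expect_equal(r3$arrival_class, "none")
})

test_that("ternary status is carried forward past partner departures", {
  # partner leaves at 90 and returns 120-130; all time from 60 stays ternary
  p <- dplyr::bind_rows(
    mk_pulses(list(spot = 1, channel = "g", onset = 0, dur = 200)),
    mk_pulses(list(spot = 1, channel = "r", onset = 60, dur = 30)),
    mk_pulses(list(spot = 1, channel = "r", onset = 120, dur = 10)))
  r <- partition_residences(p, "g", "r")
  expect_equal(r$t3, 60); expect_equal(r$t5, 140)
  expect_equal(r$overlap_s, 40)
})

test_that("arrival classification honours the inclusive co-arrival window", {
  expect_equal(classify_arrival(100, 103), "co_arrival")
  expect_equal(classify_arrival(200, 50), "partner_first")
  expect_equal(classify_arrival(100, 105), "co_arrival")     # boundary inclusive
  expect_equal(classify_arrival(100, 105.1), "partner_last")
  expect_equal(classify_arrival(c(0, 0), c(-10, 10)), c("partner_first", "partner_last"))
})

test_that("a co-arriving partner makes the whole residence ternary (T2)", {
  p <- dplyr::bind_rows(
    mk_pulses(list(spot = 1, channel = "g", onset = 100, dur = 80)),
    mk_pulses(list(spot = 1, channel = "r", onset = 105, dur = 40)))
  r <- partition_residences(p, "g", "r")
  expect_equal(r$t2, 80)
  expect_equal(r$arrival_class, "co_arrival")
})

test_that("time conservation holds on random pulse configurations", {
  set.seed(17)
  times <- (0:119) * 5
  pulses <- dplyr::bind_rows(lapply(1:300, function(s) {
    g <- derive_pulses(runif(120) < 0.3, times, min_on_frames = 2)
    r <- derive_pulses(runif(120) < 0.3, times, min_on_frames = 2)
    dplyr::bind_rows(dplyr::mutate(g, spot = s, channel = "g"),
                     dplyr::mutate(r, spot = s, channel = "r"))
  }))
  part <- partition_residences(pulses, "g", "r")
  expect_equal(part$ternary_s + part$nonternary_s, part$duration_s)
  expect_true(all(part$t5 == 0 | part$t3 > 0))  # T5 implies a preceding T3
  # exactly one category pair per residence
  cats <- (part$t1 > 0) + (part$t2 > 0) + (part$t4 > 0) + (part$t3 + part$t5 > 0)
  expect_true(all(cats == 1))
})

test_that("self-partnering makes every residence T2 with occupancy 1", {
  set.seed(23)
  times <- (0:119) * 5
  pulses <- dplyr::bind_rows(lapply(1:50, function(s) {
    g <- derive_pulses(runif(120) < 0.3, times, min_on_frames = 2)
    dplyr::mutate(g, spot = s, channel = "g")
  }))
  both <- dplyr::bind_rows(pulses, dplyr::mutate(pulses, channel = "g2"))
  part <- partition_residences(both, "g", "g2")
  expect_true(all(part$t2 == part$duration_s))
  expect_equal(occupancy_fraction(part), 1)
})

test_that("partner-first fraction matches the ground-truth interval oracle", {
  # classification through pulses must agree with a direct interval-overlap
  # scan on the same data expressed as ground-truth intervals
  set.seed(29)
  times <- (0:239) * 5
  pulses <- dplyr::bind_rows(lapply(1:200, function(s) {
    g <- derive_pulses(runif(240) < 0.25, times, min_on_frames = 2)
    r <- derive_pulses(runif(240) < 0.25, times, min_on_frames = 2)
    dplyr::bind_rows(dplyr::mutate(g, spot = s, channel = "g"),
                     dplyr::mutate(r, spot = s, channel = "r"))
  }))
  part <- partition_residences(pulses, "g", "r")
  got <- mean(part$arrival_class[part$ever_ternary] == "partner_first")
  f_iv <- with(pulses[pulses$channel == "g", ],
               data.frame(spot = spot, t_start = onset_s, t_end = end_s))
  p_iv <- with(pulses[pulses$channel == "r", ],
               data.frame(spot = spot, t_start = onset_s, t_end = end_s))
  want <- oracle_partner_first_fraction(f_iv, p_iv)
  expect_equal(got, want)
  # arrival classes are exhaustive over ternary events
  cls <- part$arrival_class[part$ever_ternary]
  expect_equal(mean(cls == "partner_first") + mean(cls == "partner_last") +
                 mean(cls == "co_arrival"), 1)
})

test_that("occupancy fraction follows the overlap-time definition", {
  full <- dplyr::bind_rows(
    mk_pulses(list(spot = 1, channel = "g", onset = 0, dur = 100)),
    mk_pulses(list(spot = 1, channel = "r", onset = 0, dur = 100)))
  expect_equal(occupancy_fraction(partition_residences(full, "g", "r")), 1)
  half <- dplyr::bind_rows(
    mk_pulses(list(spot = 1, channel = "g", onset = 0, dur = 100)),
    mk_pulses(list(spot = 1, channel = "r", onset = 0, dur = 50)))
  expect_equal(occupancy_fraction(partition_residences(half, "g", "r")), 0.5)
  alone <- mk_pulses(list(spot = 1, channel = "g", onset = 0, dur = 100))
  expect_true(is.na(occupancy_fraction(partition_residences(alone, "g", "r"))))
})

test_that("independent partner occupancy is recovered near its programmed level", {
  # long focal residences against a partner ON ~30% of the time, independent:
  # conditioning on >= 1 overlap is then almost vacuous and the occupancy
  # fraction approaches the programmed 0.3
  set.seed(37)
  times <- (0:539) * 5
  pulses <- dplyr::bind_rows(lapply(1:150, function(s) {
    len <- sample(40:80, 1)                       # 200-400 s focal residence
    start <- sample(1:(540 - len), 1)
    g_on <- rep(FALSE, 540); g_on[start:(start + len - 1)] <- TRUE
    g <- derive_pulses(g_on, times, min_on_frames = 2)
    r <- derive_pulses(rep(runif(54) < 0.3, each = 10), times, min_on_frames = 2)
    dplyr::bind_rows(dplyr::mutate(g, spot = s, channel = "g"),
                     dplyr::mutate(r, spot = s, channel = "r"))
  }))
  part <- partition_residences(pulses, "g", "r")
  occ <- occupancy_fraction(part)
  # conditioning on >= 1 overlap drops zero-overlap windows, shifting the
  # fraction a few percent above the programmed marginal 0.3
  expect_gt(occ, 0.28); expect_lt(occ, 0.38)
  # the computation itself agrees exactly with a brute-force interval scan
  f_iv <- pulses[pulses$channel == "g", ]
  p_iv <- pulses[pulses$channel == "r", ]
  num <- 0; den <- 0
  for (i in seq_len(nrow(f_iv))) {
    hit <- p_iv$spot == f_iv$spot[i] & p_iv$onset_s < f_iv$end_s[i] &
      p_iv$end_s > f_iv$onset_s[i]
    if (!any(hit)) next
    num <- num + sum(pmin(p_iv$end_s[hit], f_iv$end_s[i]) -
                       pmax(p_iv$onset_s[hit], f_iv$onset_s[i]))
    den <- den + f_iv$duration_s[i]
  }
  expect_equal(occ, num / den)
})

test_that("residences per spot is a plain ratio with guarded edge cases", {
  spots <- tibble::tibble(spot = 1:100)
  expect_equal(residences_per_spot(mk_pulses(list(spot = integer(), channel = character(),
                                                  onset = numeric(), dur = numeric())),
                                   spots), 0)
  p <- mk_pulses(list(spot = rep(1:50, each = 5), channel = "g",
                      onset = rep(0, 250), dur = rep(10, 250)))
  expect_equal(residences_per_spot(p, 1000), 0.25)
  expect_true(is.na(residences_per_spot(p, 0)))
})

test_that("overlapping focal pulses are rejected", {
  bad <- dplyr::bind_rows(
    mk_pulses(list(spot = 1, channel = "g", onset = 0, dur = 100)),
    mk_pulses(list(spot = 1, channel = "g", onset = 50, dur = 100)))
  expect_error(partition_residences(bad, "g", "r"), "overlapping")
})
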