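# Independent brute-force oracles, deliberately written as naive frame scans
# so they share no code path with the package implementations.

# Pulse derivation oracle: frame-by-frame scan. Bridges interior OFF gaps of
# at most `gap` frames, then collects maximal ON runs of at least `minlen`
# frames, with onset/duration/censor conventions applied literally.
oracle_pulses <- function(on, times, minlen = 2, gap = 0) {
  n <- length(on)
  on[is.na(on)] <- FALSE
  if (gap > 0) {
    # mark OFF frames as bridged if an ON frame occurs within `gap` frames
    # on both sides
    bridged <- on
    i <- 1
    while (i <= n) {
      if (!on[i]) {
        j <- i
        while (j <= n && !on[j]) j <- j + 1
        run_len <- j - i
        if (i > 1 && j <= n && run_len <= gap) bridged[i:(j - 1)] <- TRUE
        i <- j
      } else i <- i + 1
    }
    on <- bridged
  }
  interval <- if (n > 1) times[2] - times[1] else 1
  out <- NULL
  i <- 1
  while (i <= n) {
    if (on[i]) {
      j <- i
      while (j <= n && on[j]) j <- j + 1
      len <- j - i
      if (len >= minlen) {
        out <- rbind(out, data.frame(
          onset_s = times[i], duration_s = len * interval,
          right_censored = (j - 1) == n, present_at_start = i == 1))
      }
      i <- j
    } else i <- i + 1
  }
  if (is.null(out)) data.frame(onset_s = numeric(), duration_s = numeric(),
                               right_censored = logical(),
                               present_at_start = logical()) else out
}

# Kaplan-Meier product-limit oracle: literal definition, no survival pkg.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    d <- sum(time == ts[i] & event)
    r <- sum(time >= ts[i])
    s <- s * (1 - d / r)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}

# Two-group log-rank oracle: hand-enumerated risk sets, chi-square form
# sum(O - E)^2 / sum(V) for group A.
oracle_logrank <- function(ta, ea, tb, eb) {
  time <- c(ta, tb); event <- c(ea, eb)
  grp_a <- c(rep(TRUE, length(ta)), rep(FALSE, length(tb)))
  ts <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n_a <- sum(at_risk & grp_a)
    d <- sum(time == t & event)
    d_a <- sum(time == t & event & grp_a)
    O <- O + d_a
    E <- E + d * n_a / n
    if (n > 1) V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Interval-overlap oracle on ground-truth intervals (no imaging): fraction of
# focal intervals whose first overlapping partner interval started at or
# before (within `window`) the focal start.
oracle_partner_first_fraction <- function(focal, partner, window = 5) {
  classes <- character(nrow(focal))
  for (i in seq_len(nrow(focal))) {
    hit <- partner$spot == focal$spot[i] &
      partner$t_start < focal$t_end[i] & partner$t_end > focal$t_start[i]
    if (!any(hit)) { classes[i] <- "none"; next }
    d <- min(partner$t_start[hit]) - focal$t_start[i]
    classes[i] <- if (abs(d) <= window) "co_arrival" else if (d < 0) "partner_first" else "partner_last"
  }
  tern <- classes != "none"
  if (!any(tern)) return(NA_real_)
  mean(classes[tern] == "partner_first")
}

# small standard schedule used across tests (10 min keeps suites fast)
test_schedule <- function(total_s = 600) {
  acq_schedule(total_s, c(dna = 60, green = 5, red = 5))
}
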