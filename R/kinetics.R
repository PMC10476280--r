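#' Pooled off-rate estimate (events per observed residence time)
#'
#' Estimates the detachment rate of a residence pool as
#' `k = N_off / sum(T)`, converted to events per hour. For the ternary pool,
#' `N_off` counts residences that ever became ternary and ended in an
#' observed detachment, and the time pool is the ternary time
#' `sum(T1 + T2 + T5)`. For the non-ternary pool, `N_off` counts detachments
#' of residences that never became ternary, and the time pool is
#' `sum(T3 + T4)` (a T3 segment that ends by partner arrival is a transition
#' into T5, not an off-event: each residence's single off-event is assigned
#' to the ternary pool iff it ever became ternary). Right-censored residences
#' contribute time but no event ("included as unweighted"). On uncensored
#' exponential dwell data this estimator is the maximum-likelihood rate.
#'
#' @param partitions Tibble from [partition_residences()].
#' @param pool `"ternary"` or `"non_ternary"`.
#' @return One-row tibble of class `rate_estimate`: `pool`, `n_off`,
#'   `n_pulses`, `total_time_s`, `k_per_h`, `se_k` (asymptotic `k/sqrt(N)`).
#' @export
estimate_offrate <- function(partitions, pool = c("ternary", "non_ternary")) {
  pool <- match.arg(pool)
  if (pool == "ternary") {
    rows <- partitions[partitions$ever_ternary, , drop = FALSE]
    total <- sum(rows$ternary_s)
    n_off <- sum(rows$off_event_observed)
  } else {
    total <- sum(partitions$nonternary_s)
    rows <- partitions[!partitions$ever_ternary, , drop = FALSE]
    n_off <- sum(rows$off_event_observed)
  }
  if (total <= 0) {
    return(new_rate_estimate(tibble::tibble(
      pool = pool, n_off = n_off, n_pulses = nrow(rows),
      total_time_s = total, k_per_h = NA_real_, se_k = NA_real_)))
  }
  k <- n_off / total * 3600
  new_rate_estimate(tibble::tibble(
    pool = pool, n_off = as.integer(n_off), n_pulses = nrow(rows),
    total_time_s = total, k_per_h = k,
    se_k = if (n_off > 0) k / sqrt(n_off) else NA_real_))
}

new_rate_estimate <- function(tbl) {
  structure(tbl, class = c("rate_estimate", class(tbl)))
}

#' Off-rate as N/sum(T) on a plain duration pool
#'
#' Convenience form of the same estimator for a pool of dwell times with
#' censor flags (e.g. photobleach controls or simulated dwells).
#'
#' @param durations_s Dwell times in seconds.
#' @param censored Logical; `TRUE` rows add time but no event.
#' @return One-row `rate_estimate` tibble (`pool = "all"`).
#' @export
offrate_from_durations <- function(durations_s, censored = logical(length(durations_s))) {
  stopifnot(length(durations_s) == length(censored))
  total <- sum(durations_s)
  n_off <- sum(!censored)
  if (total <= 0) stop("total observed time must be positive")
  k <- n_off / total * 3600
  new_rate_estimate(tibble::tibble(
    pool = "all", n_off = as.integer(n_off), n_pulses = length(durations_s),
    total_time_s = total, k_per_h = k,
    se_k = if (n_off > 0) k / sqrt(n_off) else NA_real_))
}

#' Kaplan-Meier survival estimate of residence lifetimes
#'
#' Product-limit estimate with Greenwood variance and log-log 95% confidence
#' intervals (via [survival::survfit()]). Right-censored lifetimes are
#' included unweighted: they inflate the risk set but trigger no event. The
#' median is the step-function convention: the smallest observed time with
#' `S(t) <= 0.5`, `NA` when the curve never reaches 0.5 (e.g. all censored).
#'
#' @param durations_s Observed lifetimes (s), positive.
#' @param censored Logical right-censor flags, aligned with `durations_s`.
#' @return Object of class `km_fit`: list with `curve` (tibble: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `lower`, `upper`), `median_s`,
#'   `n`, `n_censored`, and the underlying `survfit` object.
#' @export
km_estimate <- function(durations_s, censored = logical(length(durations_s))) {
  stopifnot(length(durations_s) == length(censored), all(durations_s > 0))
  fit <- survival::survfit(
    survival::Surv(durations_s, !censored) ~ 1,
    conf.type = "log-log")
  curve <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv,
    lower = ifelse(is.na(fit$lower) & fit$surv == 0, 0, fit$lower),
    upper = ifelse(is.na(fit$upper) & fit$surv == 0, 0, fit$upper))
  med <- {
    hit <- curve$time[curve$surv <= 0.5]
    if (length(hit)) min(hit) else NA_real_
  }
  structure(list(curve = curve, median_s = med,
                 n = length(durations_s), n_censored = sum(censored),
                 fit = fit),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n = %d (%d censored), median = %s s\n",
              x$n, x$n_censored,
              if (is.na(x$median_s)) "undefined" else format(x$median_s)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square (1 df) on right-censored lifetimes,
#' via [survival::survdiff()]. The chi-square upper-tail p is reported (the
#' conventional "two-tailed" log-rank p).
#'
#' @param durations_a,durations_b Lifetimes (s) of the two groups.
#' @param censored_a,censored_b Right-censor flags.
#' @return One-row tibble of class `kin_test`: `kind`, `statistic`,
#'   `p_value`, `n_a`, `n_b`.
#' @export
logrank_test <- function(durations_a, censored_a = logical(length(durations_a)),
                         durations_b, censored_b = logical(length(durations_b))) {
  stopifnot(length(durations_a) > 0, length(durations_b) > 0)
  if (sum(!censored_a) + sum(!censored_b) == 0)
    stop("log-rank test undefined: no events in either group")
  time <- c(durations_a, durations_b)
  event <- c(!censored_a, !censored_b)
  group <- rep(c("a", "b"), c(length(durations_a), length(durations_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  structure(tibble::tibble(
    kind = "log_rank", statistic = sd$chisq,
    p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
    n_a = length(durations_a), n_b = length(durations_b)),
    class = c("kin_test", "tbl_df", "tbl", "data.frame"))
}

#' Compare replicate-level off-rates by unpaired t-test
#'
#' Two-tailed unpaired equal-variance t-test on per-replicate rate
#' estimates. Degenerate zero-variance inputs return `p = 1` when the means
#' are equal and `p = 0` (with a warning) when they differ.
#'
#' @param rates_a,rates_b Numeric vectors of per-replicate rates (>= 2 each).
#' @return One-row `kin_test` tibble: `kind`, `statistic`, `p_value`,
#'   `n_a`, `n_b`, `mean_a`, `mean_b`.
#' @export
compare_rates <- function(rates_a, rates_b) {
  if (length(rates_a) < 2 || length(rates_b) < 2)
    stop("need at least 2 replicates per group")
  pooled_var <- stats::var(rates_a) + stats::var(rates_b)
  if (pooled_var == 0) {
    same <- isTRUE(all.equal(mean(rates_a), mean(rates_b)))
    if (!same) warning("zero replicate variance with unequal means; p -> 0")
    res <- tibble::tibble(kind = "unpaired_t_two_tailed",
                          statistic = if (same) 0 else Inf,
                          p_value = if (same) 1 else 0,
                          n_a = length(rates_a), n_b = length(rates_b),
                          mean_a = mean(rates_a), mean_b = mean(rates_b))
    return(structure(res, class = c("kin_test", class(res))))
  }
  tt <- stats::t.test(rates_a, rates_b, var.equal = TRUE,
                      alternative = "two.sided")
  res <- tibble::tibble(kind = "unpaired_t_two_tailed",
                        statistic = unname(tt$statistic),
                        p_value = tt$p.value,
                        n_a = length(rates_a), n_b = length(rates_b),
                        mean_a = mean(rates_a), mean_b = mean(rates_b))
  structure(res, class = c("kin_test", class(res)))
}

#' Short / long residence proportions
#'
#' Fraction of residences shorter than `short_cut` and longer than
#' `long_cut` seconds (strict inequalities on both sides).
#'
#' @param durations_s Residence durations (s).
#' @param short_cut,long_cut Cut points (s), `short_cut < long_cut`.
#' @return One-row tibble: `p_short`, `p_long`, `n`.
#' @export
short_long_proportions <- function(durations_s, short_cut = 120, long_cut = 300) {
  stopifnot(short_cut > 0, long_cut > short_cut)
  if (!length(durations_s)) stop("empty duration set")
  tibble::tibble(p_short = mean(durations_s < short_cut),
                 p_long = mean(durations_s > long_cut),
                 n = length(durations_s))
}

#' Photobleach-control survival curve
#'
#' Runs the standard binarize/derive-pulses path on traces from an
#' immobilized-fluorophore control (every spot initially ON, loss by
#' bleaching only) and returns the Kaplan-Meier curve of ON durations — the
#' bleaching survival against which residence lifetimes are judged for
#' photobleaching limitation.
#'
#' @param traces Trace tibble from [extract_traces()].
#' @param threshold,min_on_frames,max_gap_frames Pulse policy (see
#'   [binarize_traces()] and [derive_pulses()]).
#' @return A [km_estimate()] `km_fit` of pulse durations.
#' @export
photobleach_control_lifetimes <- function(traces, threshold = 3,
                                          min_on_frames = 2, max_gap_frames = 0) {
  pulses <- derive_pulses(binarize_traces(traces, threshold),
                          min_on_frames = min_on_frames,
                          max_gap_frames = max_gap_frames)
  if (!nrow(pulses)) stop("no pulses detected in control traces")
  km_estimate(pulses$duration_s, pulses$right_censored)
}
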