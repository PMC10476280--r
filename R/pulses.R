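#' Binarize z-normalized traces into ON/OFF series
#'
#' A frame is ON iff its z-value is at or above the channel threshold.
#' Non-finite z-values are marked OFF with a warning (the frame is recorded
#' as invalid upstream).
#'
#' @param traces Trace tibble from [extract_traces()] (columns `spot`,
#'   `channel`, `frame`, `t`, `z`).
#' @param threshold z threshold; scalar, or named by channel.
#' @return The input tibble with a logical `on` column.
#' @export
binarize_traces <- function(traces, threshold = 3) {
  thr <- if (is.null(names(threshold))) {
    rep(threshold[1], nrow(traces))
  } else {
    miss <- setdiff(unique(traces$channel), names(threshold))
    if (length(miss)) stop("no threshold for channel(s): ", paste(miss, collapse = ", "))
    unname(threshold[traces$channel])
  }
  z <- traces$z
  bad <- !is.finite(z)
  if (any(bad)) {
    warning(sum(bad), " non-finite z-values treated as OFF")
    z[bad] <- -Inf
  }
  traces$on <- z >= thr
  traces
}

# run-length pulse derivation on one logical series; returns a data.frame
pulses_one <- function(on, times, interval, min_on_frames, max_gap_frames) {
  n <- length(on)
  on[is.na(on)] <- FALSE
  if (max_gap_frames > 0 && any(on)) {
    r <- rle(on)
    # OFF runs no longer than the gap, strictly between ON runs, become ON
    k <- length(r$lengths)
    inner_off <- !r$values & r$lengths <= max_gap_frames &
      seq_len(k) > 1 & seq_len(k) < k
    r$values[inner_off] <- TRUE
    on <- inverse.rle(r)
  }
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_on_frames
  if (!any(keep)) {
    return(data.frame(onset_s = numeric(), end_s = numeric(),
                      duration_s = numeric(), n_frames = integer(),
                      right_censored = logical(), present_at_start = logical()))
  }
  s <- starts[keep]; e <- ends[keep]
  nf <- e - s + 1L
  data.frame(onset_s = times[s],
             duration_s = nf * interval,
             end_s = times[s] + nf * interval,
             n_frames = nf,
             right_censored = e == n,
             present_at_start = s == 1L)[, c("onset_s", "end_s", "duration_s",
                                             "n_frames", "right_censored",
                                             "present_at_start")]
}

#' Derive residence pulses from binarized traces
#'
#' Maximal runs of ON frames become pulses, after bridging interior OFF gaps
#' of at most `max_gap_frames` frames and discarding runs shorter than
#' `min_on_frames`. Conventions: onset is the time of the first ON frame;
#' each detected frame contributes one full frame interval, so
#' `duration = n_frames * interval` and `end = onset + duration` (a
#' single-frame event lasts exactly one interval). A run that includes the
#' final frame is flagged `right_censored` (its true duration exceeds the
#' observed one); a run that includes the first frame is flagged
#' `present_at_start` but is not additionally censored.
#'
#' @param binarized Tibble from [binarize_traces()] (needs `spot`, `channel`,
#'   `t`, `on`), or a bare logical vector together with `times`.
#' @param times Frame times (s), required when `binarized` is a logical
#'   vector.
#' @param min_on_frames Minimum run length in frames.
#' @param max_gap_frames Maximum interior OFF gap (frames) bridged into a
#'   pulse.
#' @return Tibble: `spot`, `channel`, `onset_s`, `end_s`, `duration_s`,
#'   `n_frames`, `right_censored`, `present_at_start`.
#' @export
derive_pulses <- function(binarized, times = NULL, min_on_frames = 2,
                          max_gap_frames = 0) {
  stopifnot(min_on_frames >= 1, max_gap_frames >= 0)
  if (is.logical(binarized)) {
    stopifnot(!is.null(times), length(times) == length(binarized))
    interval <- if (length(times) > 1) times[2] - times[1] else 1
    out <- pulses_one(binarized, times, interval, min_on_frames, max_gap_frames)
    out <- tibble::as_tibble(out)
    return(dplyr::mutate(out, spot = 1L, channel = "ch", .before = 1))
  }
  stopifnot(all(c("spot", "channel", "t", "on") %in% names(binarized)))
  grp <- dplyr::group_by(binarized, .data$spot, .data$channel)
  out <- dplyr::reframe(grp, {
    ts <- .data$t
    interval <- if (length(ts) > 1) ts[2] - ts[1] else 1
    pulses_one(.data$on, ts, interval, min_on_frames, max_gap_frames)
  })
  tibble::as_tibble(out)
}

#' Count photobleaching steps in an intensity trace
#'
#' Counts discrete downward intensity drops by piecewise-constant
#' change-point segmentation: recursive binary splitting minimising residual
#' sum of squares, a split being accepted when it reduces the RSS by more
#' than `penalty * sigma^2 * log(n)` (sigma estimated robustly from
#' first differences). Downward jumps between consecutive segment means
#' smaller than `min_drop_frac` of the trace's full amplitude are not
#' counted; traces whose amplitude never exceeds `min_amplitude` score 0.
#'
#' @param intensity Numeric intensity trace (one spot, continuous
#'   illumination, initially ON).
#' @param min_drop_frac Minimum counted drop, as a fraction of the trace's
#'   overall amplitude (max - min of segment means).
#' @param penalty Penalty multiplier on `sigma^2 * log(n)` per split.
#' @param min_amplitude Absolute amplitude below which the trace is treated
#'   as empty (0 steps).
#' @return Integer number of downward steps.
#' @export
count_bleach_steps <- function(intensity, min_drop_frac = 0.25, penalty = 6,
                               min_amplitude = NULL) {
  x <- as.numeric(intensity)
  n <- length(x)
  if (n < 4) return(0L)
  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (is.null(min_amplitude)) min_amplitude <- 5 * max(sigma, 1e-12)
  if (diff(range(x)) < min_amplitude) return(0L)
  pen <- penalty * max(sigma, 1e-12)^2 * log(n)
  cps <- sort(binseg_cps(x, 1L, n, pen, min_seg = 2L))
  bounds <- c(0L, cps, n)
  means <- vapply(seq_len(length(bounds) - 1L), function(i) {
    mean(x[(bounds[i] + 1L):bounds[i + 1L]])
  }, 0)
  if (length(means) < 2) return(0L)
  drops <- -diff(means)
  amp <- max(means) - min(means)
  sum(drops >= min_drop_frac * amp)
}

# recursive binary segmentation on x[lo:hi]; returns change points (last
# index of the left segment, in full-series coordinates)
binseg_cps <- function(x, lo, hi, pen, min_seg = 2L) {
  n <- hi - lo + 1L
  if (n < 2L * min_seg) return(integer())
  seg <- x[lo:hi]
  cs <- cumsum(seg); cs2 <- cumsum(seg^2)
  tot_rss <- cs2[n] - cs[n]^2 / n
  ks <- min_seg:(n - min_seg)
  rss_l <- cs2[ks] - cs[ks]^2 / ks
  nr <- n - ks
  rss_r <- (cs2[n] - cs2[ks]) - (cs[n] - cs[ks])^2 / nr
  gain <- tot_rss - (rss_l + rss_r)
  k <- ks[which.max(gain)]
  if (max(gain) <= pen) return(integer())
  cp <- lo + k - 1L
  c(binseg_cps(x, lo, cp, pen, min_seg), cp,
    binseg_cps(x, cp + 1L, hi, pen, min_seg))
}

#' Write pulses to CSV
#' @param pulses Pulse tibble from [derive_pulses()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pulses <- function(pulses, path) {
  readr::write_csv(pulses, path)
  invisible(path)
}

#' @rdname write_pulses
#' @export
read_pulses <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    spot = readr::col_integer(), channel = readr::col_character(),
    onset_s = readr::col_double(), end_s = readr::col_double(),
    duration_s = readr::col_double(), n_frames = readr::col_integer(),
    right_censored = readr::col_logical(),
    present_at_start = readr::col_logical()
  ))
}
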