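#' Endpoint colocalization between two spot maps
#'
#' Scores the single-snapshot assay: a reference (DNA) spot is colocalized
#' iff at least one query (protein) spot centroid lies within `match_radius`
#' px. Matching is greedy nearest-neighbour with each query spot used at most
#' once.
#'
#' @param reference,query `spot_map` tibbles in the same drift-corrected
#'   frame of reference.
#' @param match_radius Maximum centroid distance (px) to call a match.
#' @return One-row tibble: `n_reference`, `n_colocalized`, `fraction`
#'   (percent; `NA` when the reference map is empty), `match_radius`.
#' @export
endpoint_colocalization <- function(reference, query, match_radius = 2) {
  n_ref <- nrow(reference)
  if (n_ref == 0) {
    return(tibble::tibble(n_reference = 0L, n_colocalized = 0L,
                          fraction = NA_real_, match_radius = match_radius))
  }
  n_col <- 0L
  if (nrow(query)) {
    d <- outer(reference$r, query$r, "-")^2 + outer(reference$c, query$c, "-")^2
    cand <- which(d <= match_radius^2, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d[cand])
      used_ref <- logical(n_ref); used_q <- logical(nrow(query))
      for (i in ord) {
        ri <- cand[i, 1]; qi <- cand[i, 2]
        if (!used_ref[ri] && !used_q[qi]) {
          used_ref[ri] <- TRUE; used_q[qi] <- TRUE
          n_col <- n_col + 1L
        }
      }
    }
  }
  tibble::tibble(n_reference = n_ref, n_colocalized = n_col,
                 fraction = 100 * n_col / n_ref, match_radius = match_radius)
}

#' Classify relative arrival order of two residences
#'
#' Residence initiations within `window` seconds of each other (inclusive)
#' count as simultaneous co-arrival; otherwise the earlier onset defines the
#' order.
#'
#' @param focal_onset,partner_onset Onset times (s); vectorized.
#' @param window Co-arrival window (s).
#' @return Character vector: `"co_arrival"`, `"partner_first"` or
#'   `"partner_last"`.
#' @export
classify_arrival <- function(focal_onset, partner_onset, window = 5) {
  d <- partner_onset - focal_onset
  dplyr::case_when(
    abs(d) <= window ~ "co_arrival",
    d < 0 ~ "partner_first",
    TRUE ~ "partner_last"
  )
}

#' Partition focal residences into ternary / non-ternary time
#'
#' Implements the ternary residence-time accounting for a focal protein
#' (e.g. the CENP-A histone) against a partner protein at the same DNA spot.
#' For each focal pulse:
#'
#' * a partner pulse overlapping it and present at (or co-arriving within
#'   `co_window` s of) the focal onset makes the **entire** focal duration
#'   ternary — category T1 (partner first) or T2 (co-arrival);
#' * a partner first arriving during the focal pulse splits it: time before
#'   the first partner arrival is non-ternary (T3) and **all** time from that
#'   arrival to the focal end is ternary (T5), irrespective of later partner
#'   departures (partner turnover and partner photobleaching are
#'   indistinguishable, so ternary status is carried forward);
#' * a focal pulse never overlapped by a partner pulse is entirely
#'   non-ternary (T4).
#'
#' Only partner pulses that overlap the focal pulse in time are considered.
#' A single frame of overlap suffices to set `ever_ternary`. Right-censored
#' focal pulses accrue time to the pools but contribute no off-event
#' (`off_event_observed = FALSE`).
#'
#' @param pulses Pulse tibble from [derive_pulses()] holding both channels.
#' @param focal_channel,partner_channel Channel labels.
#' @param co_window Co-arrival window (s), inclusive.
#' @return Tibble, one row per focal pulse: `spot`, `onset_s`, `end_s`,
#'   `duration_s`, `t1`, `t2`, `t3`, `t4`, `t5` (seconds in each category),
#'   `ternary_s`, `nonternary_s`, `overlap_s` (time the partner was actually
#'   present during the focal pulse), `ever_ternary`, `arrival_class`,
#'   `right_censored`, `off_event_observed`.
#' @export
partition_residences <- function(pulses, focal_channel, partner_channel,
                                 co_window = 5) {
  focal <- pulses[pulses$channel == focal_channel, , drop = FALSE]
  partner <- pulses[pulses$channel == partner_channel, , drop = FALSE]
  if (!nrow(focal)) {
    return(tibble::tibble(spot = integer(), onset_s = numeric(), end_s = numeric(),
                          duration_s = numeric(), t1 = numeric(), t2 = numeric(),
                          t3 = numeric(), t4 = numeric(), t5 = numeric(),
                          ternary_s = numeric(), nonternary_s = numeric(),
                          overlap_s = numeric(), ever_ternary = logical(),
                          arrival_class = character(), right_censored = logical(),
                          off_event_observed = logical()))
  }
  # reject overlapping focal pulses at one spot (impossible after derive_pulses)
  chk <- dplyr::arrange(focal, .data$spot, .data$onset_s)
  chk <- dplyr::group_by(chk, .data$spot)
  ov <- dplyr::summarise(chk, bad = dplyr::n() > 1 &&
                           any(.data$onset_s[-1] < .data$end_s[-dplyr::n()]))
  if (any(ov$bad)) stop("overlapping focal pulses at one spot")
  n <- nrow(focal)
  t1 <- t2 <- t3 <- t4 <- t5 <- overlap <- numeric(n)
  ever <- logical(n)
  cls <- character(n)
  p_by_spot <- split(seq_len(nrow(partner)), partner$spot)
  for (i in seq_len(n)) {
    f_on <- focal$onset_s[i]; f_end <- focal$end_s[i]; f_dur <- focal$duration_s[i]
    cand <- p_by_spot[[as.character(focal$spot[i])]]
    if (!is.null(cand)) {
      hit <- cand[partner$onset_s[cand] < f_end & partner$end_s[cand] > f_on]
    } else hit <- integer()
    if (length(hit)) {
      overlap[i] <- sum(pmin(partner$end_s[hit], f_end) -
                          pmax(partner$onset_s[hit], f_on))
      first_onset <- min(partner$onset_s[hit])
      cls[i] <- classify_arrival(f_on, first_onset, co_window)
      if (cls[i] == "partner_first") {
        t1[i] <- f_dur
      } else if (cls[i] == "co_arrival") {
        t2[i] <- f_dur
      } else {
        t3[i] <- first_onset - f_on
        t5[i] <- f_dur - t3[i]
      }
      ever[i] <- TRUE
    } else {
      t4[i] <- f_dur
      cls[i] <- "none"
    }
  }
  tibble::tibble(
    spot = focal$spot, onset_s = focal$onset_s, end_s = focal$end_s,
    duration_s = focal$duration_s,
    t1 = t1, t2 = t2, t3 = t3, t4 = t4, t5 = t5,
    ternary_s = t1 + t2 + t5, nonternary_s = t3 + t4,
    overlap_s = overlap, ever_ternary = ever, arrival_class = cls,
    right_censored = focal$right_censored,
    off_event_observed = !focal$right_censored)
}

#' Partner co-occupancy fraction of focal residence time
#'
#' Fraction of total focal residence time during which the partner was
#' actually present, over ternary-forming residences: the sum of true
#' partner-overlap time divided by the sum of focal durations (not the
#' carry-forward ternary convention).
#'
#' @param partitions Tibble from [partition_residences()].
#' @return A single fraction in `[0, 1]`, `NA` if no ternary residences.
#' @export
occupancy_fraction <- function(partitions) {
  tern <- partitions[partitions$ever_ternary, , drop = FALSE]
  if (!nrow(tern)) return(NA_real_)
  sum(tern$overlap_s) / sum(tern$duration_s)
}

#' Average number of residences per DNA spot
#'
#' @param pulses Pulse tibble (one channel, or filter by `channel`).
#' @param spots A `spot_map` (or the number of spots).
#' @param channel Optional channel label to filter `pulses`.
#' @return A single number: pulses per detected DNA spot; `NA` for zero
#'   spots.
#' @export
residences_per_spot <- function(pulses, spots, channel = NULL) {
  if (!is.null(channel)) pulses <- pulses[pulses$channel == channel, , drop = FALSE]
  n_spots <- if (is.numeric(spots)) spots else nrow(spots)
  if (n_spots == 0) return(NA_real_)
  nrow(pulses) / n_spots
}
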