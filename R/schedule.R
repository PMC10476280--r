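#' Acquisition schedule for a multi-channel time-lapse
#'
#' Defines the common time base of a CoSMoS acquisition: a total duration and
#' a per-channel frame cadence. Frame times for a channel run `0, dt, 2*dt,
#' ...` and include a frame at the total duration when it falls on the grid,
#' so a 45-minute acquisition at 5 s cadence has `floor(2700/5) + 1 = 541`
#' frames.
#'
#' @param total_s Total acquisition duration in seconds.
#' @param intervals Named numeric vector of frame intervals in seconds, one
#'   per channel (names are channel labels, e.g. `c(dna = 60, green = 5)`).
#' @param dna_channel Name of the channel that images the DNA template
#'   (spot-defining reference). Must be one of `names(intervals)`.
#'
#' @return An object of class `acq_schedule`: a list with `total_s`,
#'   `intervals`, `dna_channel`, and `frame_times` (named list of numeric
#'   vectors, seconds).
#' @examples
#' sched <- acq_schedule(2700, c(dna = 60, green = 5, red = 5))
#' length(sched$frame_times$green)  # 541
#' @export
acq_schedule <- function(total_s = 2700,
                         intervals = c(dna = 60, green = 5, red = 5),
                         dna_channel = "dna") {
  stopifnot(is.numeric(total_s), length(total_s) == 1, total_s > 0)
  if (is.null(names(intervals)) || any(names(intervals) == ""))
    stop("`intervals` must be a named vector of channel frame intervals")
  if (any(intervals <= 0)) stop("frame intervals must be positive")
  if (!dna_channel %in% names(intervals))
    stop("`dna_channel` must name one of the channels in `intervals`")
  frame_times <- lapply(intervals, function(dt) seq(0, by = dt, length.out = floor(total_s / dt) + 1))
  structure(
    list(total_s = total_s, intervals = intervals,
         dna_channel = dna_channel, frame_times = frame_times),
    class = "acq_schedule"
  )
}

#' @export
print.acq_schedule <- function(x, ...) {
  cat("<acq_schedule> ", x$total_s, " s total\n", sep = "")
  for (ch in names(x$intervals)) {
    cat(sprintf("  %s%s: every %g s, %d frames\n", ch,
                if (ch == x$dna_channel) " (DNA)" else "",
                x$intervals[[ch]], length(x$frame_times[[ch]])))
  }
  invisible(x)
}

#' Frame times of one channel
#' @param schedule An [acq_schedule()].
#' @param channel Channel label.
#' @return Numeric vector of frame times in seconds.
#' @export
frame_times <- function(schedule, channel) {
  stopifnot(inherits(schedule, "acq_schedule"))
  ft <- schedule$frame_times[[channel]]
  if (is.null(ft)) stop("unknown channel: ", channel)
  ft
}

#' Protein (non-DNA) channel labels of a schedule
#' @inheritParams frame_times
#' @export
protein_channels <- function(schedule) {
  setdiff(names(schedule$intervals), schedule$dna_channel)
}
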