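#' Multi-frame image stack for one channel
#'
#' A light container for one channel of a time-lapse: an ordered list of
#' equally sized numeric matrices (indexed `[row, col]`) plus their frame
#' times in seconds.
#'
#' @param frames List of numeric matrices, all the same dimension.
#' @param frame_times Numeric vector of frame times (s), one per frame.
#' @param channel Channel label.
#' @param pixel_size Pixel size (um/px).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_times, channel = "ch", pixel_size = 0.11) {
  stopifnot(is.list(frames), length(frames) == length(frame_times))
  if (length(frames)) {
    d <- dim(frames[[1]])
    ok <- vapply(frames, function(f) identical(dim(f), d), TRUE)
    if (!all(ok)) stop("all frames must share one dimension")
  }
  structure(list(frames = frames, frame_times = as.numeric(frame_times),
                 channel = channel, pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- if (length(x$frames)) paste(dim(x$frames[[1]]), collapse = " x ") else "empty"
  cat(sprintf("<image_stack> channel '%s': %d frames of %s px\n",
              x$channel, length(x$frames), d))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

# additive Gaussian spot rendered into a local window of `img`
add_gaussian <- function(img, r0, c0, amp, sigma) {
  half <- ceiling(4 * sigma)
  rr <- max(1, floor(r0) - half):min(nrow(img), ceiling(r0) + half)
  cc <- max(1, floor(c0) - half):min(ncol(img), ceiling(c0) + half)
  if (!length(rr) || !length(cc)) return(img)
  g <- exp(-(outer((rr - r0)^2, (cc - c0)^2, "+")) / (2 * sigma^2))
  img[rr, cc] <- img[rr, cc] + amp * g
  img
}

#' Render a ground-truth simulation into multi-channel image stacks
#'
#' For each channel and scheduled frame time, every spot whose species is ON
#' at that instant contributes a 2-D Gaussian of sd `psf_sigma` and peak
#' `spot_amplitude` at its drift-displaced centroid, summed onto a constant
#' background. The DNA channel renders the always-present template marker at
#' `dna_amplitude`. Noise follows `params$noise`: Poisson shot noise on
#' (background + signal), additive Gaussian, or none.
#'
#' @param truth A `ground_truth` from [simulate_pulse_trains()].
#' @param params The [sim_params()] used for the simulation (defaults to the
#'   one stored in `truth`).
#' @param schedule The [acq_schedule()] (defaults to the one in `truth`).
#' @return Named list of [image_stack()] objects, one per channel.
#' @export
render_movie <- function(truth, params = truth$params, schedule = truth$schedule) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(params$seed + 104729L)  # rendering noise decoupled from kinetics
  field <- params$field
  drift_fun <- params$drift
  spots <- truth$spots
  # pre-check drift keeps centroids inside the field
  if (!is.null(drift_fun) && nrow(spots)) {
    d_end <- drift_fun(schedule$total_s)
    r_all <- c(spots$r, spots$r + d_end[1]); c_all <- c(spots$c, spots$c + d_end[2])
    if (any(r_all < 1) || any(r_all > field[1]) || any(c_all < 1) || any(c_all > field[2]))
      stop("drift displaces spot centroids outside the field")
  }
  iv <- truth$intervals
  out <- list()
  for (ch in names(schedule$intervals)) {
    times <- schedule$frame_times[[ch]]
    is_dna <- identical(ch, schedule$dna_channel)
    ch_iv <- if (is_dna) NULL else iv[iv$channel == ch, , drop = FALSE]
    frames <- vector("list", length(times))
    for (fi in seq_along(times)) {
      t <- times[fi]
      img <- matrix(params$background_mean, field[1], field[2])
      d <- if (is.null(drift_fun)) c(0, 0) else drift_fun(t)
      if (nrow(spots)) {
        if (is_dna) {
          on_idx <- spots$spot
          amp <- params$dna_amplitude
        } else {
          # half-open intervals [t_start, t_end)
          on_idx <- unique(ch_iv$spot[ch_iv$t_start <= t & t < ch_iv$t_end])
          # intervals truncated exactly at total_s should be ON at the final frame
          on_idx <- unique(c(on_idx, ch_iv$spot[ch_iv$cause == "end" & t == ch_iv$t_end]))
          amp <- params$spot_amplitude
        }
        for (i in on_idx) {
          img <- add_gaussian(img, spots$r[i] + d[1], spots$c[i] + d[2],
                              amp, params$psf_sigma)
        }
      }
      if (params$noise == "poisson") {
        img <- matrix(stats::rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
        if (params$gaussian_sd > 0)
          img <- img + matrix(stats::rnorm(length(img), 0, params$gaussian_sd),
                              nrow(img), ncol(img))
      } else if (params$noise == "gaussian" && params$gaussian_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, params$gaussian_sd),
                            nrow(img), ncol(img))
      }
      frames[[fi]] <- img
    }
    out[[ch]] <- image_stack(frames, times, channel = ch,
                             pixel_size = params$pixel_size)
  }
  out
}

#' Simulate photobleaching staircase traces
#'
#' Render mode for step-count validation: each trace represents a spot
#' carrying `m` fluorophores, each bleaching independently with exponential
#' lifetime at rate `k_bleach`, producing a piecewise-constant intensity
#' staircase (amplitude x number of surviving fluorophores) observed on a
#' frame grid with additive Gaussian noise.
#'
#' @param n Number of traces.
#' @param m Fluorophores per spot.
#' @param k_bleach Bleaching rate, events per hour per fluorophore.
#' @param schedule An [acq_schedule()]; the first protein channel's frame
#'   grid is used.
#' @param amplitude Intensity contribution of one fluorophore (a.u.).
#' @param noise_sd Additive Gaussian noise sd (a.u.); `amplitude / noise_sd`
#'   is the per-fluorophore SNR.
#' @param seed Integer seed.
#' @return Tibble: `trace`, `t`, `intensity`, plus per-trace `true_steps`
#'   (number of bleach events inside the acquisition window).
#' @export
simulate_bleach_staircases <- function(n = 200, m = 2, k_bleach = 20,
                                       schedule = acq_schedule(),
                                       amplitude = 100, noise_sd = 20,
                                       seed = 1L) {
  stopifnot(n >= 1, m >= 1, k_bleach > 0)
  set.seed(seed)
  ch <- protein_channels(schedule)[1]
  times <- schedule$frame_times[[ch]]
  res <- vector("list", n)
  for (i in seq_len(n)) {
    bleach_t <- sort(stats::rexp(m, k_bleach / 3600))
    level <- vapply(times, function(t) sum(bleach_t > t), 0)
    intensity <- amplitude * level + stats::rnorm(length(times), 0, noise_sd)
    res[[i]] <- tibble::tibble(trace = i, t = times, intensity = intensity,
                               true_steps = sum(bleach_t < max(times)))
  }
  dplyr::bind_rows(res)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Frames are written in time order as 32-bit float pages. The acquisition
#' schedule and channel metadata travel in a YAML sidecar written by
#' [write_run_sidecar()].
#'
#' @param stack An [image_stack()].
#' @param path TIFF file path.
#' @param frame_times,channel,pixel_size Metadata to attach on read-back.
#' @return `write_stack_tiff()` returns `path` invisibly;
#'   `read_stack_tiff()` returns an [image_stack()].
#' @export
write_stack_tiff <- function(stack, path) {
  sc <- max(1, max(vapply(stack$frames, max, 1)))
  tiff::writeTIFF(lapply(stack$frames, function(f) f / sc), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, frame_times, channel = "ch", pixel_size = 0.11) {
  pages <- tiff::readTIFF(path, all = TRUE)
  image_stack(pages, frame_times, channel = channel, pixel_size = pixel_size)
}
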