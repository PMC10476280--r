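#' Simulation parameters for a synthetic CoSMoS field
#'
#' Bundles the geometry, kinetics, optics and noise settings used to simulate
#' a field of surface-tethered DNA templates with stochastically binding
#' labeled proteins. Defaults emulate the acquisition geometry of a typical
#' single-molecule TIRF experiment: a 512 x 512 px EMCCD field at 0.11 um/px
#' carrying on the order of 1,000 immobile template spots.
#'
#' Kinetic rates are given per hour per spot. For each protein species, a
#' spot alternates OFF -> ON with exponential waiting time at rate `k_on`,
#' and ON -> OFF at total rate `k_off + k_bleach`; the termination cause of
#' each ON interval is detachment with probability `k_off/(k_off+k_bleach)`
#' and photobleaching otherwise (competing exponential risks).
#'
#' @param n_spots Number of DNA template spots to place.
#' @param field Field size in pixels, `c(rows, cols)`.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param spot_min_separation Minimum centre-to-centre spot distance (px).
#' @param kinetics Named list, one entry per protein species (names must
#'   match protein channel labels of the schedule), each a list with
#'   `k_on`, `k_off`, `k_bleach` in events per hour.
#' @param psf_sigma Gaussian PSF standard deviation in pixels.
#' @param spot_amplitude Peak signal of a single bound fluorophore, in
#'   photons above background.
#' @param dna_amplitude Peak signal of the DNA template marker (photons).
#' @param background_mean Mean background level in photons.
#' @param noise Noise model: `"poisson"` (shot noise on signal+background)
#'   or `"gaussian"` (additive, sd = `gaussian_sd`), or `"none"`.
#' @param gaussian_sd Additive read-noise sd (photons); used when
#'   `noise = "gaussian"`, and optionally added on top of Poisson noise.
#' @param drift Drift function of time (seconds) returning `c(dr, dc)` pixel
#'   displacement, e.g. [drift_linear()]; `NULL` for no drift.
#' @param initial_occupancy Probability that a spot starts in the ON state.
#' @param edge_margin Minimum distance from spot centre to the field edge
#'   (px); must leave room for background annuli and drift.
#' @param seed Integer seed for reproducible simulation.
#'
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_spots = 1000,
                       field = c(512, 512),
                       pixel_size = 0.11,
                       spot_min_separation = 8,
                       kinetics = list(
                         green = list(k_on = 1.5, k_off = 30, k_bleach = 8),
                         red   = list(k_on = 1.5, k_off = 20, k_bleach = 8)
                       ),
                       psf_sigma = 1.3,
                       spot_amplitude = 150,
                       dna_amplitude = 150,
                       background_mean = 100,
                       noise = c("poisson", "gaussian", "none"),
                       gaussian_sd = 0,
                       drift = NULL,
                       initial_occupancy = 0,
                       edge_margin = 12,
                       seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_spots >= 0, length(field) == 2, all(field > 0),
            pixel_size > 0, spot_min_separation > 0, psf_sigma > 0,
            spot_amplitude >= 0, dna_amplitude >= 0, background_mean >= 0,
            gaussian_sd >= 0, initial_occupancy >= 0, initial_occupancy <= 1)
  for (sp in names(kinetics)) {
    k <- kinetics[[sp]]
    if (!all(c("k_on", "k_off", "k_bleach") %in% names(k)))
      stop("kinetics for '", sp, "' must supply k_on, k_off, k_bleach")
    if (any(unlist(k[c("k_on", "k_off", "k_bleach")]) < 0))
      stop("kinetic rates must be non-negative (species '", sp, "')")
  }
  # crude capacity check: random sequential placement needs headroom
  usable <- prod(pmax(field - 2 * edge_margin, 0))
  if (n_spots > 0 && usable / (spot_min_separation^2) < n_spots)
    stop("field cannot accommodate ", n_spots, " spots at separation ",
         spot_min_separation, " px")
  if (!is.null(drift) && !is.function(drift)) stop("`drift` must be a function of time or NULL")
  structure(
    list(n_spots = as.integer(n_spots), field = as.integer(field),
         pixel_size = pixel_size, spot_min_separation = spot_min_separation,
         kinetics = kinetics, psf_sigma = psf_sigma,
         spot_amplitude = spot_amplitude, dna_amplitude = dna_amplitude,
         background_mean = background_mean, noise = noise,
         gaussian_sd = gaussian_sd, drift = drift,
         initial_occupancy = initial_occupancy,
         edge_margin = edge_margin, seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Linear (optionally wobbling) stage-drift model
#'
#' Returns a drift function `f(t) -> c(dr, dc)` in pixels describing smooth
#' lateral stage drift: a linear component plus an optional sinusoidal wobble.
#'
#' @param vr,vc Drift velocity in px per second along rows / columns.
#' @param wobble_amp Amplitude of sinusoidal wobble (px), applied to both axes.
#' @param wobble_period Wobble period in seconds.
#' @return A function of time (s) returning a length-2 displacement (px).
#' @export
drift_linear <- function(vr = 0, vc = 0, wobble_amp = 0, wobble_period = 600) {
  force(vr); force(vc); force(wobble_amp); force(wobble_period)
  function(t) {
    w <- if (wobble_amp > 0) wobble_amp * sin(2 * pi * t / wobble_period) else 0
    c(vr * t + w, vc * t + w)
  }
}

# -- spot placement: random sequential adsorption with minimum separation ----
place_spots <- function(n, field, min_sep, margin) {
  if (n == 0) {
    return(tibble::tibble(spot = integer(), r = numeric(), c = numeric()))
  }
  lo <- margin + 1
  hi_r <- field[1] - margin
  hi_c <- field[2] - margin
  if (hi_r <= lo || hi_c <= lo) stop("edge_margin leaves no usable field")
  rs <- numeric(n); cs <- numeric(n)
  placed <- 0L; tries <- 0L; max_tries <- 2000L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " spots at separation ", min_sep, " px")
    r <- stats::runif(1, lo, hi_r); c <- stats::runif(1, lo, hi_c)
    if (placed == 0L ||
        min((rs[seq_len(placed)] - r)^2 + (cs[seq_len(placed)] - c)^2) >= min_sep^2) {
      placed <- placed + 1L
      rs[placed] <- r; cs[placed] <- c
    }
  }
  tibble::tibble(spot = seq_len(n), r = rs, c = cs)
}

# -- continuous-time two-state trajectory for one spot/species --------------
# Returns a data.frame of ON intervals [t_start, t_end) with cause.
sim_one_train <- function(k_on, k_off, k_bleach, total_s, start_on) {
  k_on_s <- k_on / 3600; k_off_s <- k_off / 3600; k_bl_s <- k_bleach / 3600
  k_term <- k_off_s + k_bl_s
  t <- 0; on <- start_on
  starts <- numeric(); ends <- numeric(); causes <- character()
  while (t < total_s) {
    if (!on) {
      if (k_on_s <= 0) break
      t <- t + stats::rexp(1, k_on_s)
      if (t >= total_s) break
      on <- TRUE
    } else {
      t_start <- t
      if (k_term <= 0) {  # absorbing ON state
        starts <- c(starts, t_start); ends <- c(ends, total_s)
        causes <- c(causes, "end")
        break
      }
      dwell <- stats::rexp(1, k_term)
      t_end <- t_start + dwell
      if (t_end >= total_s) {
        starts <- c(starts, t_start); ends <- c(ends, total_s)
        causes <- c(causes, "end")
        break
      }
      cause <- if (stats::runif(1) < k_off_s / k_term) "detachment" else "bleach"
      starts <- c(starts, t_start); ends <- c(ends, t_end)
      causes <- c(causes, cause)
      t <- t_end; on <- FALSE
    }
  }
  data.frame(t_start = starts, t_end = ends, cause = causes,
             stringsAsFactors = FALSE)
}

#' Simulate ground-truth binding pulse trains
#'
#' Draws, for every spot and protein species, an alternating OFF/ON
#' trajectory in continuous time (Gillespie-style): OFF waiting times are
#' exponential at `k_on`, ON dwell times exponential at `k_off + k_bleach`,
#' and each completed ON interval's termination cause is sampled
#' proportionally to `k_off` vs `k_bleach`. Intervals still ON at the end of
#' the acquisition are truncated and flagged `"end"` (end-of-acquisition,
#' i.e. right-censored).
#'
#' @param params A [sim_params()] object.
#' @param schedule An [acq_schedule()]; its `total_s` bounds all intervals.
#' @return An object of class `ground_truth`: list with `spots` (tibble:
#'   `spot`, `r`, `c` true centroids in px) and `intervals` (tibble: `spot`,
#'   `channel`, `t_start`, `t_end` in s, `cause` in
#'   `c("detachment", "bleach", "end")`).
#' @examples
#' p <- sim_params(n_spots = 5, field = c(64, 64), seed = 2)
#' s <- acq_schedule(600, c(dna = 60, green = 5, red = 5))
#' gt <- simulate_pulse_trains(p, s)
#' @export
simulate_pulse_trains <- function(params, schedule) {
  stopifnot(inherits(params, "sim_params"), inherits(schedule, "acq_schedule"))
  if (any(vapply(schedule$frame_times, length, 1L) == 0))
    stop("schedule has a channel with zero frames")
  species <- names(params$kinetics)
  missing_ch <- setdiff(species, protein_channels(schedule))
  if (length(missing_ch))
    stop("kinetics species without a matching schedule channel: ",
         paste(missing_ch, collapse = ", "))
  set.seed(params$seed)
  spots <- place_spots(params$n_spots, params$field,
                       params$spot_min_separation, params$edge_margin)
  total_s <- schedule$total_s
  res <- list()
  for (sp in species) {
    k <- params$kinetics[[sp]]
    for (i in seq_len(params$n_spots)) {
      start_on <- stats::runif(1) < params$initial_occupancy
      iv <- sim_one_train(k$k_on, k$k_off, k$k_bleach, total_s, start_on)
      if (nrow(iv)) {
        iv$spot <- i; iv$channel <- sp
        res[[length(res) + 1L]] <- iv
      }
    }
  }
  intervals <- if (length(res)) {
    tibble::as_tibble(do.call(rbind, res))[, c("spot", "channel", "t_start", "t_end", "cause")]
  } else {
    tibble::tibble(spot = integer(), channel = character(),
                   t_start = numeric(), t_end = numeric(), cause = character())
  }
  structure(list(spots = spots, intervals = intervals,
                 params = params, schedule = schedule),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", nrow(x$spots), " spots, ",
      nrow(x$intervals), " ON intervals\n", sep = "")
  invisible(x)
}

#' Write / read ground-truth intervals as CSV
#'
#' One row per ON interval (`spot`, `channel`, `t_start`, `t_end`, `cause`)
#' so that downstream pipeline output can be joined against the truth.
#'
#' @param truth A `ground_truth` object (or its `intervals` tibble).
#' @param path Output CSV path.
#' @return `export_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the intervals tibble.
#' @export
export_ground_truth <- function(truth, path) {
  iv <- if (inherits(truth, "ground_truth")) truth$intervals else truth
  readr::write_csv(iv, path)
  invisible(path)
}

#' @rdname export_ground_truth
#' @export
read_ground_truth <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    spot = readr::col_integer(), channel = readr::col_character(),
    t_start = readr::col_double(), t_end = readr::col_double(),
    cause = readr::col_character()
  ))
}
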