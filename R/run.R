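#' Default analysis policies
#'
#' All thresholds of the pipeline in one list, each overridable. These are
#' echoed verbatim into every run manifest.
#'
#' @param z_threshold Pulse binarization z threshold (per channel if named).
#' @param min_on_frames,max_gap_frames Pulse policy.
#' @param nmads Spot-detection MAD multiplier.
#' @param size_range Spot area limits (px).
#' @param min_persistency Minimum fraction of DNA frames a spot must appear in.
#' @param link_radius Spot linking radius across DNA frames (px).
#' @param aperture_radius,annulus Trace extraction geometry (px).
#' @param match_radius Colocalization / pulse-to-spot match radius (px).
#' @param co_window Co-arrival window (s).
#' @param drift_method Drift estimation method.
#' @return Named list of class `run_policies`.
#' @export
run_policies <- function(z_threshold = 3, min_on_frames = 2, max_gap_frames = 0,
                         nmads = 4, size_range = c(2, 30), min_persistency = 0.5,
                         link_radius = 2, aperture_radius = 3, annulus = c(5, 8),
                         match_radius = 2, co_window = 5,
                         drift_method = "auto") {
  structure(as.list(environment()), class = "run_policies")
}

#' Simulate a field and write movie + sidecar + ground truth
#'
#' @param params [sim_params()].
#' @param schedule [acq_schedule()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the `ground_truth`, the stack list and the
#'   file paths written (one TIFF per channel, YAML sidecar, truth CSV).
#' @export
run_simulate <- function(params, schedule, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_pulse_trains(params, schedule)
  stacks <- render_movie(truth, params, schedule)
  paths <- character()
  for (ch in names(stacks)) {
    p <- file.path(out_dir, paste0("channel_", ch, ".tif"))
    write_stack_tiff(stacks[[ch]], p)
    paths[ch] <- p
  }
  truth_path <- file.path(out_dir, "ground_truth.csv")
  export_ground_truth(truth, truth_path)
  sidecar <- file.path(out_dir, "acquisition.yaml")
  write_run_sidecar(sidecar, params, schedule)
  invisible(list(truth = truth, stacks = stacks,
                 paths = c(paths, truth = truth_path, sidecar = sidecar)))
}

#' Write / read the acquisition sidecar
#'
#' YAML sidecar recording the schedule and (for simulations) the generating
#' parameters, so movies on disk are self-describing.
#'
#' @param path YAML path.
#' @param params Optional [sim_params()] (drift functions are recorded by
#'   presence only).
#' @param schedule [acq_schedule()].
#' @return `path` invisibly; `read_run_sidecar()` returns a list with
#'   `schedule` rebuilt as an `acq_schedule`.
#' @export
write_run_sidecar <- function(path, params = NULL, schedule) {
  obj <- list(schedule = list(total_s = schedule$total_s,
                              intervals = as.list(schedule$intervals),
                              dna_channel = schedule$dna_channel))
  if (!is.null(params)) {
    p <- unclass(params)
    p$drift <- if (is.null(p$drift)) "none" else "custom"
    obj$sim_params <- p
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_sidecar
#' @export
read_run_sidecar <- function(path) {
  obj <- yaml::read_yaml(path)
  s <- obj$schedule
  obj$schedule <- acq_schedule(s$total_s, unlist(s$intervals), s$dna_channel)
  obj
}

#' Endpoint colocalization run (single-snapshot mode)
#'
#' Detects spots on a DNA snapshot (persistency filter bypassed) and on each
#' protein snapshot, then scores endpoint colocalization per protein channel.
#' With a list of fields, returns per-field fractions plus across-field mean
#' and s.d.
#'
#' @param dna_frame Numeric matrix (DNA snapshot), or list of matrices (one
#'   per field).
#' @param protein_frames Named list of protein snapshots (or list of such
#'   lists, parallel to `dna_frame`).
#' @param policies [run_policies()].
#' @return List with `per_field` (tibble: field, channel, n_reference,
#'   n_colocalized, fraction) and `summary` (tibble: channel, mean_fraction,
#'   sd_fraction, n_fields).
#' @export
run_endpoint <- function(dna_frame, protein_frames, policies = run_policies()) {
  single <- is.matrix(dna_frame)
  dna_fields <- if (single) list(dna_frame) else dna_frame
  prot_fields <- if (single) list(protein_frames) else protein_frames
  stopifnot(length(dna_fields) == length(prot_fields))
  rows <- list()
  for (fi in seq_along(dna_fields)) {
    dna_stack <- image_stack(list(dna_fields[[fi]]), 0, channel = "dna")
    ref <- detect_dna_spots(dna_stack, nmads = policies$nmads,
                            size_range = policies$size_range,
                            min_persistency = 0, link_radius = policies$link_radius)
    for (ch in names(prot_fields[[fi]])) {
      q_stack <- image_stack(list(prot_fields[[fi]][[ch]]), 0, channel = ch)
      q <- detect_dna_spots(q_stack, nmads = policies$nmads,
                            size_range = policies$size_range,
                            min_persistency = 0, link_radius = policies$link_radius)
      res <- endpoint_colocalization(ref, q, policies$match_radius)
      rows[[length(rows) + 1L]] <- dplyr::mutate(res, field = fi, channel = ch,
                                                 .before = 1)
    }
  }
  per_field <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(per_field, .data$channel),
    mean_fraction = mean(.data$fraction), sd_fraction = stats::sd(.data$fraction),
    n_fields = dplyr::n(), .groups = "drop")
  list(per_field = per_field, summary = summary)
}

#' Full time-lapse pipeline run
#'
#' Orchestrates the complete analysis: drift estimation on the DNA channel,
#' drift correction of all channels, DNA spot detection, trace extraction,
#' pulse binarization/derivation, ternary partitioning of a focal channel
#' against a partner channel, off-rate estimation, Kaplan-Meier curves and a
#' ternary vs non-ternary log-rank test. Accepts either rendered stacks or
#' simulation inputs.
#'
#' @param stacks Named list of [image_stack()] (all channels incl. DNA), or
#'   `NULL` to simulate from `params`.
#' @param schedule [acq_schedule()].
#' @param params [sim_params()], used when `stacks` is `NULL`.
#' @param focal_channel,partner_channel Protein channels for the ternary
#'   analysis (default: first and second protein channel; partitioning is
#'   skipped if only one protein channel exists).
#' @param policies [run_policies()].
#' @param correct_drift Set `FALSE` to skip drift estimation/correction (e.g.
#'   for drift-free simulations).
#' @return List of class `cosmos_run`: `spots`, `traces`, `pulses`,
#'   `partitions`, `rates` (tibble), `km` (list of `km_fit` per pool),
#'   `tests` (tibble), `drift` (`drift_model` or NULL), `manifest`.
#' @export
run_timelapse <- function(stacks = NULL, schedule, params = NULL,
                          focal_channel = NULL, partner_channel = NULL,
                          policies = run_policies(), correct_drift = TRUE) {
  truth <- NULL
  if (is.null(stacks)) {
    stopifnot(!is.null(params))
    truth <- simulate_pulse_trains(params, schedule)
    stacks <- render_movie(truth, params, schedule)
  }
  dna_ch <- schedule$dna_channel
  prot_ch <- intersect(names(stacks), protein_channels(schedule))
  if (is.null(focal_channel)) focal_channel <- prot_ch[1]
  if (is.null(partner_channel) && length(prot_ch) > 1)
    partner_channel <- prot_ch[2]

  drift <- NULL
  if (correct_drift) {
    drift <- estimate_drift(stacks[[dna_ch]], method = policies$drift_method)
    stacks <- lapply(stacks, apply_drift_correction, drift = drift)
  }
  spots <- detect_dna_spots(stacks[[dna_ch]], nmads = policies$nmads,
                            size_range = policies$size_range,
                            min_persistency = policies$min_persistency,
                            link_radius = policies$link_radius)
  traces <- dplyr::bind_rows(lapply(prot_ch, function(ch) {
    extract_traces(stacks[[ch]], spots,
                   aperture_radius = policies$aperture_radius,
                   annulus = policies$annulus)
  }))
  traces <- traces[traces$valid, , drop = FALSE]
  pulses <- if (nrow(traces)) {
    derive_pulses(binarize_traces(traces, policies$z_threshold),
                  min_on_frames = policies$min_on_frames,
                  max_gap_frames = policies$max_gap_frames)
  } else {
    derive_pulses(binarize_traces(
      tibble::tibble(spot = integer(), channel = character(),
                     frame = integer(), t = numeric(), z = numeric()),
      policies$z_threshold))
  }

  partitions <- NULL; rates <- NULL; km <- list(); tests <- NULL
  if (!is.null(partner_channel) && nrow(pulses)) {
    partitions <- partition_residences(pulses, focal_channel, partner_channel,
                                       co_window = policies$co_window)
    if (nrow(partitions)) {
      rates <- dplyr::bind_rows(estimate_offrate(partitions, "ternary"),
                                estimate_offrate(partitions, "non_ternary"))
      tern <- partitions[partitions$ever_ternary, ]
      nont <- partitions[!partitions$ever_ternary, ]
      if (nrow(tern)) km$ternary <- km_estimate(tern$duration_s, tern$right_censored)
      if (nrow(nont)) km$non_ternary <- km_estimate(nont$duration_s, nont$right_censored)
      if (nrow(tern) && nrow(nont) &&
          sum(!tern$right_censored) + sum(!nont$right_censored) > 0) {
        tests <- logrank_test(tern$duration_s, tern$right_censored,
                              nont$duration_s, nont$right_censored)
      }
    }
  }
  focal <- pulses[pulses$channel == focal_channel, , drop = FALSE]
  if (nrow(focal)) km$focal <- km_estimate(focal$duration_s, focal$right_censored)

  manifest <- list(
    schedule = list(total_s = schedule$total_s,
                    intervals = as.list(schedule$intervals),
                    dna_channel = schedule$dna_channel),
    policies = unclass(policies),
    focal_channel = focal_channel, partner_channel = partner_channel,
    seed = if (!is.null(params)) params$seed else NA_integer_,
    n_spots_detected = nrow(spots),
    package_version = as.character(utils::packageVersion("cosmokin")))

  structure(list(spots = spots, traces = traces, pulses = pulses,
                 partitions = partitions, rates = rates, km = km,
                 tests = tests, drift = drift, truth = truth,
                 manifest = manifest),
            class = "cosmos_run")
}

#' @export
print.cosmos_run <- function(x, ...) {
  cat("<cosmos_run>\n")
  cat("  spots:", nrow(x$spots), " pulses:", nrow(x$pulses), "\n")
  if (!is.null(x$rates)) {
    for (i in seq_len(nrow(x$rates)))
      cat(sprintf("  k_%s = %.1f /h (N = %d)\n", x$rates$pool[i],
                  x$rates$k_per_h[i], x$rates$n_off[i]))
  }
  invisible(x)
}

#' Statistics-only run from a pulse table
#'
#' Skip-imaging mode: computes partitions, off-rates, Kaplan-Meier curves and
#' the ternary vs non-ternary log-rank test directly from a pulse CSV/tibble,
#' yielding statistics identical to the image-path run on the same pulses.
#'
#' @param pulses Pulse tibble (or CSV path) as written by [write_pulses()].
#' @param focal_channel,partner_channel Channel labels.
#' @param co_window Co-arrival window (s).
#' @return List with `partitions`, `rates`, `km`, `tests` (as in
#'   [run_timelapse()]).
#' @export
run_stats <- function(pulses, focal_channel, partner_channel, co_window = 5) {
  if (is.character(pulses)) pulses <- read_pulses(pulses)
  partitions <- partition_residences(pulses, focal_channel, partner_channel,
                                     co_window = co_window)
  rates <- dplyr::bind_rows(estimate_offrate(partitions, "ternary"),
                            estimate_offrate(partitions, "non_ternary"))
  tern <- partitions[partitions$ever_ternary, ]
  nont <- partitions[!partitions$ever_ternary, ]
  km <- list()
  if (nrow(tern)) km$ternary <- km_estimate(tern$duration_s, tern$right_censored)
  if (nrow(nont)) km$non_ternary <- km_estimate(nont$duration_s, nont$right_censored)
  tests <- NULL
  if (nrow(tern) && nrow(nont) &&
      sum(!tern$right_censored) + sum(!nont$right_censored) > 0) {
    tests <- logrank_test(tern$duration_s, tern$right_censored,
                          nont$duration_s, nont$right_censored)
  }
  list(partitions = partitions, rates = rates, km = km, tests = tests)
}
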