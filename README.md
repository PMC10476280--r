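# cosmokin

Residence-lifetime kinetics for single-molecule TIRF colocalization (CoSMoS)
experiments, in R.

In a CoSMoS assay, individual DNA template molecules are tethered to a
coverslip and imaged by multi-channel TIRF time-lapse while fluorescently
labeled proteins bind and release. cosmokin implements the full analysis
path from raw image stacks to kinetic statistics, for experimentalists who
need per-template dwell-time kinetics with proper censoring:

- **image pipeline** — sub-pixel drift estimation (FFT phase correlation or
  cross-correlation) and correction, DNA-template spot detection with size and
  time-persistency filters, per-spot background-subtracted, z-normalized
  intensity traces;
- **pulse detection** — ON/OFF binarization at a z-threshold, residence pulses
  with onset/duration on the frame grid, right-censor annotation, photobleach
  step counting by change-point segmentation;
- **residence analysis** — endpoint colocalization, ternary (two-protein)
  residence partitioning into the T1–T5 time categories, arrival-order
  classes with an inclusive 5 s co-arrival window, partner co-occupancy,
  residences per template;
- **survival kinetics** — pooled off-rates `k = N_off / ΣT` (per hour) with the
  ternary/non-ternary event-assignment convention, Kaplan–Meier survival with
  log–log 95% bands, log-rank tests, replicate-level t-tests, short/long
  residence proportions;
- **simulator** — a stochastic two-state binding generator with
  photobleaching as a competing risk, rendered into realistic multi-channel
  movies (Gaussian PSFs, Poisson noise, programmable drift), so every stage
  is testable by parameter recovery against known ground truth.

The central statistic: residences are pooled by whether they ever coincided
with a partner protein at the same template ("ternary"), and each pool's
off-rate is estimated as observed detachments over total observed residence
time,

    k_t = N_t / Σ(T1 + T2 + T5)      k_n = N_n / Σ(T3 + T4)

with right-censored residences contributing time but no event. See the
methods vignette (`vignettes/cosmokin-methods.Rmd`) for the category
definitions and estimator properties.

## Worked example

Simulate a 45-minute acquisition (protein channels every 5 s, DNA channel
every 60 s) of 200 templates with two protein species at different
detachment rates, then run the full pipeline:

```r
library(cosmokin)

sched <- acq_schedule(2700, c(dna = 60, green = 5, red = 5))
params <- sim_params(
  n_spots = 200, field = c(256, 256), spot_min_separation = 10,
  kinetics = list(green = list(k_on = 2, k_off = 30, k_bleach = 4),
                  red   = list(k_on = 2, k_off = 20, k_bleach = 4)),
  drift = drift_linear(vr = 0.003, vc = -0.0025), seed = 208)
run <- run_timelapse(schedule = sched, params = params)
run
#> <cosmos_run>
#>   spots: 200  pulses: 517
#>   k_ternary = 32.3 /h (N = 31)
#>   k_non_ternary = 30.0 /h (N = 208)
```

All 200 templates are recovered and yield 517 residence pulses. The focal
(green) channel's programmed total loss rate is `k_off + k_bleach = 34 /h`;
both pools sit near it (30–32 /h, slightly low from frame-grid quantization
at 5 s cadence) because the red channel here is independent of the green, so
ternary status carries no real stabilization. Channel-level rate and
survival summary:

```r
pg <- dplyr::filter(run$pulses, channel == "green")
offrate_from_durations(pg$duration_s, pg$right_censored)$k_per_h
#> [1] 30.32247
glance(run$km$focal)
#> # A tibble: 1 × 4
#>       n n_censored median_s events
#>   <int>      <int>    <dbl>  <dbl>
#> 1   249         10       80    239
```

The Kaplan–Meier median of 80 s against `ln(2)/34 h⁻¹ ≈ 73 s` programmed
(one frame of grid bias plus sampling spread).
`autoplot(run$km$focal)` draws the survival curve with its 95% band and
censor marks; `plot_pulse_raster(run$pulses)` draws the per-template
residence raster.

A thin command-line wrapper with `simulate`, `timelapse`, `stats` and
`endpoint` subcommands lives at `inst/cli/cosmokin.R`.

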