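---
title: "Residence-lifetime kinetics from single-molecule colocalization data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residence-lifetime kinetics from single-molecule colocalization data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosmokin)
library(dplyr)
```

## The measurement and its model

Colocalization single-molecule spectroscopy (CoSMoS) tethers individual DNA
template molecules to a passivated coverslip and watches, by TIRF microscopy,
fluorescently labeled proteins from solution arrive at and depart from each
template. The observable per template and protein is a sequence of *residences*:
contiguous intervals during which the protein's signal colocalizes with the
DNA spot. cosmokin turns multi-channel time-lapse stacks into those residences
and into the kinetic statistics built on them.

The kinetic model underneath is a memoryless two-state process per spot and
protein species. An unoccupied spot acquires a protein with exponential
waiting time at rate $k_{on}$; a bound protein is lost at total rate
$k_{off} + k_{bleach}$, where detachment and photobleaching are competing
exponential risks: an observed residence ends by detachment with probability
$k_{off}/(k_{off}+k_{bleach})$. Residences still ON at the end of acquisition
are right-censored: their true duration exceeds the observed one, so they
contribute observation time but no event.

Two estimators sit at the core:

* **Pooled off-rate** $\hat k = N_{off} / \sum T$, detachment events over total
  observed residence time, reported per hour. On uncensored exponential data
  this is the maximum-likelihood rate, and censored residences are handled
  correctly by construction (time without an event).
* **Kaplan–Meier survival** of residence durations with Greenwood variance and
  log–log 95% bands, with the median defined as the smallest observed time at
  which $S(t) \le 0.5$ (step-function convention, no interpolation).

### Ternary residence accounting

The scientific question the partition answers is whether a partner protein at
the same template stabilizes the focal protein. Each focal residence is split
into five time categories relative to the partner:

| category | meaning | pool |
|---|---|---|
| T1 | partner present at focal arrival; full residence | ternary |
| T2 | co-arrival (onsets within the 5 s window, inclusive); full residence | ternary |
| T3 | focal time before the partner's first arrival | non-ternary |
| T4 | residence during which the partner never appeared | non-ternary |
| T5 | focal time from the partner's first arrival to the focal end | ternary |

Because partner turnover and partner photobleaching cannot be distinguished,
ternary status is *carried forward*: once a partner has arrived during a focal
residence, all remaining focal time is ternary regardless of later partner
departures. This also controls selection bias: long focal residences are more
likely ever to meet a partner, so for partner-last events only the
post-arrival time (T5) enters the ternary pool, while T1/T2 events enter in
full because partner presence at onset is independent of how long the
residence will last.

Off-events are assigned by the same convention: a residence's single observed
detachment counts toward the ternary pool iff the residence ever became
ternary, otherwise toward the non-ternary pool. A T3 segment that ends by
partner arrival is a transition, not a detachment. The pooled rates are then
$k_t = N_t / \sum(T_1+T_2+T_5)$ and $k_n = N_n / \sum(T_3+T_4)$.

The *co-occupancy fraction* is deliberately different from the carry-forward
convention: it is the fraction of focal residence time during which the
partner was actually present (true interval overlap), over ternary-forming
residences. Note that conditioning on at least one overlap excludes
zero-overlap residences, so on independent channels the measured fraction
sits a few percent above the partner's marginal occupancy; the package's
tests quantify this against a brute-force interval scan.

## The image pipeline and its parameters

All defaults assume the acquisition geometry the package was designed around:
a 512 px field at 0.11 µm/px, protein channels imaged every 5 s and the DNA
channel every 60 s for 45 min (541 protein frames, 46 DNA frames, one shared
time base of 2,700 s).

* **Drift.** Estimated on the DNA channel per frame relative to frame 1, by
  FFT phase correlation (default) or plain cross-correlation
  (`translation_fit`, preferred automatically when cumulative displacement
  exceeds 5 px), with separable parabolic sub-pixel refinement. Displacements
  at protein frame times are linearly interpolated between DNA frames, and
  every channel is resampled by bilinear interpolation (edges filled with the
  frame median). On simulated movies with programmed drift the residual error
  is well under 0.1 px.
* **Spot detection.** A global threshold binarizes every DNA frame; connected
  components of 2–30 px (diffraction-limited footprints at this pixel size)
  are linked across frames within 2 px (templates are immobile after
  correction); spots detected in fewer than half of the DNA frames are
  dropped. The threshold is centre + 4 × scale, where the centre is the
  median of the temporal-median image and the scale is the *median per-frame
  MAD*. The temporal median itself has its shot noise suppressed by roughly
  the square root of the frame count, so a MAD taken on it would sit far
  below the single-frame noise the binarization actually operates on; the
  per-frame MAD keeps the false-positive rate at or below a couple of
  components per field. Single-snapshot (endpoint) mode bypasses the
  persistency filter.
* **Traces.** Per spot and frame, the raw value is the mean over a 3 px
  aperture disc; local background is the median over a (5, 8) px annulus
  excluding pixels within the aperture radius of other spots (preventing
  bleed-through from bright neighbours). The background-subtracted series is
  z-normalized with one robust (median, scaled-MAD) pair per trace, the scale
  floored at the frame-to-frame noise estimate `mad(diff(x))/sqrt(2)`. This
  makes z-values invariant to affine gain/offset changes and gives constant
  traces z = 0. One consequence worth knowing: a trace that is ON for most of
  the acquisition has its median at the ON level and will not binarize —
  robust centring presumes a mostly-OFF baseline, which holds at the sparse
  occupancies the assay is designed for.
* **Pulses.** Frame `i` is ON iff `z >= 3`; maximal ON runs of at least 2
  frames become pulses (no gap bridging by default). Three MAD-units with a
  two-frame minimum suppress single-frame shot noise at 5 s cadence without
  biasing against the ~60–100 s dwells of interest. Durations follow the
  grid convention `duration = n_frames × interval` with onset at the first ON
  frame's timestamp, so a single-frame event lasts exactly one interval; a
  run containing the final frame is right-censored, and a run containing the
  first frame is flagged `present_at_start` but not additionally censored.
  Note the right-edge consequence: a censored run's `end = onset + duration`
  may exceed the nominal acquisition end by up to one interval, since every
  detected frame contributes a full interval.
* **Step counting.** Photobleach staircases are segmented by recursive binary
  splitting on residual sum of squares with penalty `6 σ² log n` (σ robustly
  estimated from first differences); downward jumps of at least 25% of the
  trace's amplitude count as steps. The penalty and drop fraction were fixed
  on noise-free staircases plus the simulator's SNR-5 regime before being
  frozen.

## The simulator: what it emulates and what it does not

The generator draws ground-truth pulse trains in continuous time
(Gillespie-style) and renders them only at scheduled frame times, so an ON
interval that covers no frame time is invisible *by construction* — that is a
property of the measurement, not a defect to correct. Rendering sums 2-D
Gaussian PSFs (σ = 1.3 px, peak amplitude in photons above background) onto a
constant background with Poisson shot noise (optionally additive Gaussian read
noise), under configurable smooth drift (linear plus optional sinusoidal
wobble). Spots are placed by random sequential adsorption with a minimum
separation; a separate staircase mode gives each spot `m` independently
bleaching fluorophores for step-count validation.

Deliberately not modelled: evanescent-field depth and polarization, EMCCD
gain-register statistics, chromatic offsets between channels (channels are
assumed co-registered, as the analysis assumes), and mobile particles.
Passing parameter-recovery tests therefore demonstrates the *analysis* is
correct under the stated noise model — not that real movies lack
registration offsets, non-uniform illumination, or correlated background, all
of which would have to be handled upstream.

The default field of ~1,000 spots in 512² px matches the surface densities
the assay typically reports; tests and the acceptance script run a scaled
field (200 spots in 256², 541 frames) chosen so the full imaging round trip
completes in about a minute while keeping per-spot statistics in the hundreds
of pulses.

## Numerical and design choices

* Coordinates are (row, col) in R's 1-based convention with pixel centres at
  integers; all displacements in px.
* Grid quantization biases durations upward by roughly half a frame minus
  threshold losses; at 5 s frames against 100–180 s mean dwells the pooled
  rate estimator lands a few percent below the programmed loss rate, which is
  why estimator-accuracy tests run at ground-truth level while end-to-end
  tests assert ordering and discrimination.
* Degenerate inputs: constant frames give zero drift with a warning;
  noise-only fields give empty (not erroneous) spot maps; all-censored pools
  give survival ≡ 1 with an undefined median; zero-variance replicate rates
  give p = 1 (equal means) or p → 0 with a warning (unequal).
* The log-rank chi-square (1 df) upper-tail p is reported as the conventional
  "two-tailed" p without directional halving; replicate off-rates are
  compared by a two-tailed equal-variance t-test, and rate uncertainty is
  reported as the per-pool asymptotic `k/sqrt(N)` alongside replicate spread.
* Ambiguities resolved as package conventions: the co-arrival window is
  inclusive at exactly 5 s (one frame at the protein cadence); only partner
  pulses that actually overlap the focal pulse count toward ternary status
  (a partner that departed before the focal onset does not); T1 and T2 are
  distinguished in the output for audit but pooled in the rate estimator;
  `present_at_start` residences are retained uncensored, carrying their flag
  so sensitivity analyses can exclude them.

## A worked example

```{r example, eval = FALSE}
sched <- acq_schedule(2700, c(dna = 60, green = 5, red = 5))
params <- sim_params(
  n_spots = 200, field = c(256, 256), spot_min_separation = 10,
  kinetics = list(green = list(k_on = 2, k_off = 30, k_bleach = 4),
                  red   = list(k_on = 2, k_off = 20, k_bleach = 4)),
  drift = drift_linear(vr = 0.003, vc = -0.0025), seed = 1)
run <- run_timelapse(schedule = sched, params = params)

run$rates                      # pooled ternary / non-ternary off-rates
glance(run$km$focal)           # KM median of the focal channel
autoplot(run$km$focal)         # survival curve with 95% band
plot_pulse_raster(run$pulses)  # per-template residence raster
```

## Known limitations

* Binarization uses a single global z-threshold per channel; fields with
  strongly varying per-spot brightness may need per-spot thresholds.
* The pooled off-rate assumes exponential dwells; biphasic dwell mixtures are
  summarized but not deconvolved (no parametric mixture fitting, no Cox
  regression).
* Drift is translation-only; rotation or magnification drift is out of scope.
* Step counting assumes piecewise-constant intensity; blinking fluorophores
  inflate counts.
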