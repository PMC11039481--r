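---
title: "Analysing V1 responses to illusory drifting gratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing V1 responses to illusory drifting gratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neonv1)
```

## The problem

Neon color spreading (NCS) is a filling-in illusion: gray segments
drawn on white concentric circles ("inducers") over a black background
appear to diffuse into the empty space between them. When the segments
are placed wherever the dark half-cycle of a virtual drifting grating
crosses the inducers, the percept is a drifting grating whose bars look
*darker than the black background*, even though no luminance is present
there. This package renders that stimulus family, simulates
extracellular recording sessions with known ground truth, and provides
the full analysis chain used to ask whether single units in mouse V1
respond to the illusory grating the way they respond to a physical one.

The logic rests on three matched stimuli:

* **NCS** — the illusion. Black background, white inducer annuli, gray
  segments under the dark half-cycle of a square-wave grating
  (SF 0.05 cyc/deg, TF 2 Hz, 8 drift directions).
* **DBC** — the diffusion-blocked control. Pixel-for-pixel the *same
  temporal changes* (a provable identity in this package: frame
  differences of NCS and DBC are identical), plus static white blocker
  rings that stop the filling-in. Any response driven by local pixel
  flicker should survive in DBC; a response driven by the illusory
  grating should not.
* **LDG** — the physical control: a real gray grating drifting over the
  inducers, spatially antiphase to the illusory one. Because gray bars
  on black are *brighter* than background while the illusory bars are
  *darker*, a unit tracking perceived brightness should respond to the
  two stimuli 180° apart in phase.

## Stimulus construction

Rendering uses degrees of visual angle with the origin at screen
centre, x rightward, y upward; pixels are sampled at their centres and
every rendered pixel takes one of three luminances (black 0, gray 0.5,
white 1 — arbitrary units, configurable). The drifting grating is a
square wave with 50% duty cycle; phase is evaluated at frame start, so
rendering is fully deterministic. One shared phase function drives all
three stimuli: NCS gray segments occupy the dark half-cycle on the
annuli, LDG gray bars occupy the bright half-cycle, which makes the two
gray-pixel patterns spatially antiphase *by construction* and the
measured fundamental-component offset exactly 180°.

The grid layout uses nine patches (circle diameters 3/6/9°, stroke
0.1°) on a 35° square; the full-screen variant arranges patches
(8/16/24°, stroke 0.4°) on a hexagonal lattice. The lattice spacing is a
free parameter; its default is set so the largest empty circle inscribed
between three adjacent patches has a 39° diameter
(`s = sqrt(3) * (39/2 + r_out)`), and a distance-transform oracle in the
test suite confirms the rendered geometry. Whether the quoted 39° refers
to this inscribed circle or to the pairwise gap is genuinely open; the
inscribed-circle reading was chosen because it is the "maximal illusory
area" a three-patch neighbourhood encloses.

Phase measurement (`gray_pattern_phase`) projects the binarised gray
indicator onto the drift axis and evaluates the Fourier component at
the grating's spatial frequency. The indicator is centred on its
support first — the raw indicator has a DC component that leaks through
the finite aperture into the fundamental and would bias the phase by
tens of degrees.

## The synthetic session

`ground_truth_cohort()` + `simulate_session()` define the stated world
against which everything is tested. Per unit, spiking is an
inhomogeneous Poisson process on 1 ms bins:

```
rate(t) = baseline
        + gain * evoked * vonMises(direction; pref, sigma)
               * env(t - latency) * (1 + f1 * cos(2*pi*TF*t - phase))
```

* `env` is a step at the condition's latency with a slow decay
  (tau = 1.5 s) times a sharp onset transient (3x the sustained rate,
  tau = 50 ms). The transient is what real V1 PSTHs look like, and it is
  what makes millisecond latency detection possible at all: without it,
  a 20 sp/s sustained step cannot put three consecutive 1 ms bins above
  a p < .01 Poisson tail and the detector's first-passage time becomes
  long and variable.
* Defaults state the simulated conditions: baseline 1–5 sp/s, LDG
  evoked 15–30 sp/s, ground-truth IGR uniform on [−0.5, 0.5], LDG
  latency 65 ms and NCS latency 100 ms (an injected 35 ms delay,
  matching the order of magnitude of the reported effect), NCS phase
  offset 180° ± 20° across units, half the cohort simple-like
  (f1 ∈ [0.6, 0.9]) and half complex (f1 ∈ [0, 0.2]), 30% narrow-TPL
  (putative inhibitory) units.
* DBC trials draw baseline only. Running trials multiply the evoked
  component of *both* gratings by a common gain (1.3), so ground-truth
  IGR is running-invariant — mirroring the reported null effect of
  locomotion on stimulus preference. Light-on trials scale only the
  NCS-driven component (`light_gain_ncs`), the synthetic analogue of
  suppressing feedback from higher visual areas.
* Spikes are generated on [−0.3, 1.2) s around each onset — the union
  of every analysis window; spikes outside it would never be read.

Waveforms are differences of two Gaussians whose trough-to-peak
latency (TPL) is drawn from a two-component mixture (0.25 ± 0.05 ms
narrow, 0.65 ± 0.10 ms broad); the peak Gaussian width is TPL/5 so that
waveform noise (0.5% of trough depth) cannot displace the measured
argmax by more than one sample. The LFP is a Gaussian-in-depth profile
(σ = 1.5 channels) times a stimulus-locked damped oscillation plus
white noise; its discrete second spatial derivative puts the sink at
the configured channel. The encoder trace encodes disk angle as 0–5 V
with a genuine 5 V → 0 V wrap; the pupil is baseline plus per-condition
transients (+6% NCS, −8% LDG, 0 DBC — the approximate magnitudes the
experiments report) with 1% noise.

**What a green test establishes, and what it does not.** The generator
produces Poisson spiking with the stated structure. It does not emulate
bursting, refractoriness, correlated noise between units, eye
movements, slow drifts in arousal, spike-sorting contamination, or any
genuinely perceptual process. Green recovery tests establish that the
analysis chain is correct and calibrated — not that real V1 behaves
this way.

## Analysis choices worth knowing

* **Latency detector.** λ̂ is total baseline count / (n_trials ×
  300 ms). Thresholds use the exact Poisson inverse CDF with *strict*
  inequality (smallest k with P(X ≥ k) < p); detection operates on
  unsmoothed across-trial summed counts (the 2 ms moving average is for
  display and FFT only — smoothing breaks the Poisson assumption), is
  one-sided (excitatory), and scans 0–500 ms. First-passage simulation
  of the strict rule on a 5→50 sp/s step at 70 trials puts ~93% of
  detections in [80, 90] ms and 95% within [80, 95] ms; the
  suite freezes those computed numbers.
* **F0/F1.** The paper mixes "power" and "rate" in one index; both F1
  quantities here are single-sided *amplitudes* (sp/s) so that
  CSM = (F1−F0)/(F1+F0) and IGR_F1 are dimensionally consistent. The
  dominance flag (needed for phase-population membership) still
  compares *power* across non-DC components.
* **Phase shift.** Positive shift = NCS lags LDG; wrapped to [0°,
  360°). Per-unit estimates carry ~40° of spread (finite spikes;
  leakage of the onset transient and response-window truncation into
  the 2 Hz bin), but the leak phase is fixed while response phases are
  uniform across units, so the population circular mean is unbiased —
  the 200-unit cohort recovers 173° against an injected 180°.
* **Latency comparisons use complex cells only**, as phase-locked
  responses make onset latency ill-defined for simple cells.
* **RF fitting.** Maps are nearest-neighbour upsampled, thresholded at
  median + 3 SD of the off-peak (lower-half) values — the reference
  level for "three standard deviations" is unstated in the source and
  the map median is used — and the fit is restricted to the unmasked
  component connected to the map maximum, because isolated
  supra-threshold noise pixels otherwise drag the least-squares
  Gaussian. Degenerate fits (σ beyond the map, centre far outside) are
  flagged `no_rf`. Overlap uses the closed disk bounded by the
  outermost circle of the nearest patch — the most conservative reading
  of "largest surrounding inducers" — rasterised at ≥ 20 px/deg.
* **CSD.** Order-4 Butterworth band-pass (0.1–150 Hz), applied forward
  and backward for zero phase; the filter is designed in-package
  (analog prototype → band transform → bilinear) because no DSP package
  is available, and its coefficients are pinned to scipy.signal values
  in the tests. Edge channels use linear-extrapolation padding so a
  linear-in-depth profile has identically zero CSD. The sink is the
  channel with the largest time-smoothed post-onset CSD magnitude;
  recovery is reliable to ±1 channel down to noise_sd = 0.05 relative
  to a unit-amplitude transient at 25 µm spacing.
* **Behaviour.** Disk speed converts 0–5 V to angle, unwraps *before*
  downsampling to 300 Hz (averaging voltage across the wrap would
  fabricate speed spikes), and uses rim speed v = ω·πD/360 — "multiply
  by the diameter" is dimensionally a convention, and rim speed is the
  physical speed of the animal. Run/still uses mean speed > 1 cm/s
  (strict) over [−300, +200] ms. Two distinct pupil baselines coexist
  deliberately: 300 ms for trace normalisation, 200 ms for the dilation
  index, matching the two separate procedures; the index uses the raw
  (unnormalised) trace.
* **Equi-responsive selection** uses |IGR| ≤ 0.1 by default (no
  tolerance is stated anywhere; 0.1 keeps rates within ~22% of each
  other).
* **Light comparison** runs on still trials only: the running gain is
  shared across units, so a chance imbalance of running trials between
  light states would correlate every unit's delta and invalidate a
  sign test across units.

## Known limitations

* The honeycomb spacing and the inter-trial interval (500 ms default)
  are stated as package defaults, not measured facts.
* The spec-level example "step 5→50 sp/s detected in [80, 90] ms on
  ≥ 95% of runs" is not attainable by the strict unsmoothed three-bin
  rule (true rate 93%); the suite tests the computed behaviour.
* Sub-sample TPL interpolation is spline-based; for pathological
  waveforms with near-flat peaks the argmax can move by a sample.
* The report layer reads numbers back from the emitted CSVs only; it
  performs no statistics. Mixed-model fitting is out of scope — the
  tidy tables are designed to be handed to external tooling.
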