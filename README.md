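# neonv1

Stimulus synthesis and spike-train analysis for studying how mouse
primary visual cortex (V1) responds to an **illusory drifting grating**
produced by achromatic neon color spreading (NCS), for systems
neuroscientists working with extracellular laminar recordings.

An NCS stimulus consists of patches of white concentric circles
("inducers") on a black background. Wherever the dark half-cycle of a
virtual square-wave grating (spatial frequency 0.05 cyc/deg, temporal
frequency 2 Hz) crosses an inducer, the white pixels are replaced by
gray. Human observers perceive gray diffusing out of the segments: an
illusory grating with bars darker than the black background, drifting
with the virtual grating. Two controls complete the design:

- **DBC** (diffusion-blocked control): pixel-wise identical temporal
  changes, but each inducer circle is sandwiched by static white blocker
  rings that abolish the filling-in.
- **LDG** (luminance-defined grating): a physical gray grating drifting
  over the inducers, spatially antiphase (180°) to the illusory one.

## What the package computes

| quantity | definition |
|---|---|
| IGR | (R(NCS) − R(LDG)) / (R(NCS) + R(LDG)) on evoked rates |
| IGR_F1 | same contrast on F1 amplitudes |
| CSM | (F1 − F0)/(F1 + F0) from the LDG response; < 0 ⇒ complex cell |
| surround modulation | (max R(<30°) − R(45°)) / max R(<30°) from size tuning |
| NCS delay index | (Lat(NCS) − Lat(rect)) / (Lat(NCS) + Lat(rect)) |
| response latency | first run of 3 consecutive 1 ms PSTH bins above the one-sided Poisson(λ̂) tail at p < .01, .01, .05 |
| phase shift | arg F1(NCS) − arg F1(LDG), wrapped to [0°, 360°) |

plus receptive-field Gaussian fits with FWHM-ellipse/inducer overlap,
trough-to-peak-latency (TPL) mixture classification of putative
inhibitory vs excitatory units, current-source-density (CSD) sink
localisation, running-speed extraction from rotary-encoder voltage, and
a pupillometry dilation index (S − B)/(S + B).

A first-class synthetic-session generator (`ground_truth_cohort()`,
`simulate_session()`) emulates direction-tuned Poisson units with
controlled latencies, F1 phase offsets, E/I waveform bimodality, a
laminar LFP sink, running gain and pupil transients — so every analysis
stage is testable against known ground truth without any data download.

## Worked example

```r
library(neonv1)

cohort <- ground_truth_cohort(n_units = 30, seed = 5)   # known truth
trials <- condition_table(trials_per_condition = 70, order_seed = 5)
bundle <- simulate_session(cohort, trials, seed = 5)

m  <- unit_metrics(bundle)            # per-unit indices and latencies
response_partition(m)
#>     both ldg_only ncs_only     none
#>       30        0        0        0

ph <- phase_summary(m)                # F1-dominant units only
ph$n                                  # 13
ph$mean_deg                           # 202.0  (injected offset: 180)
ph$rayleigh_p                         # 7.8e-06

cx <- bundle$ground_truth$f1_ratio < 0.3          # complex cells
mean(m$latency_ncs[cx] - m$latency_ldg[cx], na.rm = TRUE)
#> 34.79                                (injected difference: 35 ms)

beh <- behavior_summary(bundle)
beh$dilation
#>   condition dilation_index
#> 1       DBC    0.0010
#> 2       LDG   -0.0335      # constriction to the physical grating
#> 3       NCS    0.0256      # dilation to the illusory darkening
```

Every unit here responds to both gratings (with 70 trials the detector
is near-ceiling for these rates); DBC evokes nothing. The phase shifts
cluster around the injected 180° antiphase — with only 13 F1-dominant
units the sample circular mean still carries ±30° of noise (per-unit
phase estimates have ≈40° spread from finite spikes and window-edge
leakage); on the 200-unit acceptance cohort the mean lands at 173°,
inside the [170°, 190°] acceptance band. The NCS response is delayed by
~35 ms, and the pupil dilates to illusory darkening while constricting
to physical brightening.

## Command line

```sh
Rscript inst/cli/neonv1.R simulate --seed 1 --outdir session_out
Rscript inst/cli/neonv1.R analyze  --seed 1 --outdir results_out
Rscript inst/cli/neonv1.R report   --outdir results_out
```

See `vignettes/illusory-grating-analysis.Rmd` for the model, parameter
choices, and what the synthetic generator does and does not emulate.
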