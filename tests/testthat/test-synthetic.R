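# Synthetic recording generator: seeded determinism, Poisson statistics,
# waveform/TPL construction, LFP sink geometry, behaviour traces.

test_that("spike simulation is deterministic and respects ground truth", {
  cohort <- ground_truth_cohort(n_units = 2, seed = 9)
  trials <- condition_table(trials_per_condition = 10, order_seed = 9)
  a <- simulate_unit_spikes(cohort[1, ], trials, seed = 9)
  b <- simulate_unit_spikes(cohort[1, ], trials, seed = 9)
  expect_identical(a, b)
  c2 <- simulate_unit_spikes(cohort[1, ], trials, seed = 10)
  expect_false(identical(a, c2))
})

test_that("zero evoked rate: NCS trials are statistically baseline", {
  cohort <- ground_truth_cohort(n_units = 1, seed = 4)
  cohort$evoked_rate_ncs <- 0
  trials <- condition_table(trials_per_condition = 40, order_seed = 4)
  sp <- simulate_unit_spikes(cohort[1, ], trials, seed = 4)
  tr_ncs <- trials[trials$condition == "NCS", ]
  n_stim <- sum(sapply(tr_ncs$onset_s, function(on)
    sum(sp$t_s >= on & sp$t_s < on + 1)))
  # Poisson check: observed count within 4 SD of baseline expectation
  mu <- cohort$baseline_rate * nrow(tr_ncs)
  expect_lt(abs(n_stim - mu), 4 * sqrt(mu))
})

test_that("DBC trials draw baseline only (chi-square against expectation)", {
  b <- small_bundle()
  gt <- b$ground_truth
  tr_dbc <- b$trials[b$trials$condition == "DBC", ]
  for (u in gt$unit_id[1:4]) {
    sp <- b$spikes$t_s[b$spikes$unit_id == u]
    n <- sum(sapply(tr_dbc$onset_s, function(on)
      sum(sp >= on & sp < on + 1)))
    mu <- gt$baseline_rate[gt$unit_id == u] * nrow(tr_dbc)
    expect_lt(abs(n - mu), 4 * sqrt(mu) + 1)
  }
})

test_that("phase-locked unit: PSTH power peaks at the drive frequency", {
  # FFT oracle on the analytic rate is the frequency of the modulation;
  # the PSTH of a deeply modulated unit must recover it
  cohort <- ground_truth_cohort(n_units = 1, seed = 11)
  cohort$f1_ratio <- 1
  trials <- condition_table(trials_per_condition = 70, order_seed = 11)
  suppressWarnings(sp <- simulate_unit_spikes(cohort[1, ], trials, seed = 11))
  pref <- wrap_deg(round(cohort$preferred_direction[1] / 45) * 45)
  p <- build_psth(sp, trials, condition = "LDG", direction = pref)
  sel <- p$bin_start_ms >= 0 & p$bin_start_ms < 1000
  spec <- Mod(fft(p$rate[sel]) / sum(sel))^2
  non_dc <- 2:500
  expect_equal(non_dc[which.max(spec[non_dc])] - 1, 2)  # 2 Hz
})

test_that("waveforms: measured TPL matches the drawn value", {
  cohort <- ground_truth_cohort(n_units = 30, seed = 13)
  wf <- simulate_waveforms(cohort, seed = 13)
  sr <- attr(wf, "sample_rate")
  meas <- apply(wf, 1, tpl, sample_rate = sr, upsample = 4)
  expect_true(all(abs(meas - cohort$tpl_ms) <= 1000 / sr + 1e-9))
})

test_that("TPL cohort is bimodal and threshold-classifiable", {
  cohort <- ground_truth_cohort(n_units = 350, seed = 17)
  wf <- simulate_waveforms(cohort, seed = 17)
  meas <- apply(wf, 1, tpl, sample_rate = attr(wf, "sample_rate"),
                upsample = 4)
  # density oracle: a genuine dip between the component means
  d <- density(meas, bw = 0.03)
  in_gap <- d$x > 0.3 & d$x < 0.6
  pk1 <- max(d$y[d$x <= 0.3]); pk2 <- max(d$y[d$x >= 0.6])
  expect_lt(min(d$y[in_gap]), 0.7 * min(pk1, pk2))
  # Bayes-oracle classification accuracy for well-separated means
  fit <- ei_threshold(meas)
  acc <- mean(fit$labels == cohort$cell_class)
  expect_gte(acc, 0.95)
})

test_that("LFP sink geometry and SNR robustness", {
  clean <- simulate_lfp_csd(n_channels = 24, sink_channel = 9,
                            noise_sd = 0, seed = 1)
  cs <- csd(clean)
  peak_ch <- unname(which(abs(cs) == max(abs(cs)), arr.ind = TRUE)[1, 1])
  expect_equal(peak_ch, 9)
  # linear-in-depth voltage annihilated
  lin <- outer(1:10, rep(1, 50)) * 3.7
  expect_equal(max(abs(csd(lin))), 0, tolerance = 1e-12)
  # sink recovered within +/-1 channel at the generator's stated SNR
  # (noise_sd 0.05 against a unit-amplitude transient)
  for (s in 1:5) {
    noisy <- simulate_lfp_csd(n_channels = 24, sink_channel = 9,
                              noise_sd = 0.05, seed = s)
    snk <- find_csd_sink(csd(noisy))
    expect_lte(abs(snk$channel - 9), 1)
  }
})

test_that("behaviour: run fraction, encoder wrap, pupil signs", {
  trials <- condition_table(trials_per_condition = 4, order_seed = 3)
  still <- simulate_behavior(trials, run_fraction = 0, seed = 3)
  expect_true(all(!still$run_truth))
  sp <- disk_speed(still$encoder)
  lab <- classify_run_still(sp, trials)
  expect_true(all(lab == "still"))

  beh <- simulate_behavior(trials, run_fraction = 0.5, seed = 3)
  sp <- disk_speed(beh$encoder)
  lab <- classify_run_still(sp, trials)
  expect_equal(lab == "run", beh$run_truth)

  # unwrap oracle: during constant running the speed trace never spikes
  # even though the voltage wraps 5 V -> 0 V
  i_run <- which(beh$run_truth)[1]
  on <- trials$onset_s[i_run]
  wrapped <- any(abs(diff(beh$encoder$voltage[
    beh$encoder$t_s > on - 0.4 & beh$encoder$t_s < on + 1])) > 2.5)
  seg <- sp$speed_cmps[sp$t_s > on - 0.3 & sp$t_s < on + 1]
  expect_lt(diff(range(seg)), 0.5)

  di <- dilation_index(beh$pupil, trials)
  m <- tapply(di$dilation_index, di$condition, mean)
  expect_gt(m[["NCS"]], 0.01)
  expect_lt(m[["LDG"]], -0.01)
  expect_lt(abs(m[["DBC"]]), 0.01)
})

test_that("bundle round-trips through plain-text serialization", {
  cohort <- ground_truth_cohort(n_units = 3, seed = 21)
  trials <- condition_table(trials_per_condition = 3, order_seed = 21)
  pres <- render_rf_rectangles(display_geometry(), order_seed = 21,
                               n_sweeps = 1, render = FALSE)$presentations
  b <- suppressWarnings(
    simulate_session(cohort, trials, seed = 21, rf_presentations = pres))
  d <- tempfile("bundle_")
  write_recording_bundle(b, d)
  b2 <- read_recording_bundle(d)
  expect_equal(b2$spikes$t_s, b$spikes$t_s, tolerance = 1e-12)
  expect_equal(unname(b2$waveforms), unname(b$waveforms), tolerance = 1e-12)
  expect_equal(b2$run_truth, b$run_truth)
  expect_equal(b2$ground_truth$preferred_direction,
               b$ground_truth$preferred_direction, tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
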