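# Synthetic recording sessions with known ground truth: direction-tuned
# inhomogeneous-Poisson spiking, difference-of-Gaussian waveforms with a
# bimodal trough-to-peak latency (TPL) mixture, laminar LFP with a
# localized stimulus-locked sink, rotary-encoder voltage and pupil traces.

#' Ground-truth unit cohort
#'
#' Draws a cohort of synthetic V1 units. Defaults state the simulated
#' world: half simple-like (deep F1 modulation), half complex; ~30%
#' putative inhibitory (narrow TPL); ground-truth illusory-grating response
#' (IGR) indices uniform on \[-0.5, 0.5\]; LDG response latency 65 ms and
#' NCS latency 100 ms (a 35 ms injected delay); NCS response phase offset
#' 180 deg with 20 deg between-unit jitter.
#'
#' @param n_units cohort size.
#' @param seed RNG seed.
#' @param p_simple fraction of simple-like (phase-locked) units.
#' @param p_inhib fraction of putative inhibitory units.
#' @param tuning_sigma_deg direction tuning width (von Mises sigma-
#'   equivalent, deg).
#' @param baseline_range,evoked_ldg_range uniform ranges (sp/s).
#' @param igr_range uniform range of the ground-truth IGR.
#' @param latency_ldg_ms,latency_ncs_ms,latency_rect_ms response latencies.
#' @param phase_offset_mean,phase_offset_sd NCS-vs-LDG F1 phase offset
#'   distribution (deg).
#' @param tpl_means,tpl_sds TPL mixture components (ms), inhibitory first.
#' @param light_gain_ncs,light_gain_ldg multiplicative gain applied to the
#'   evoked component on light-on trials.
#' @return data.frame, one row per unit, class `ground_truth_cohort`.
#' @export
ground_truth_cohort <- function(n_units = 200, seed = 1,
                                p_simple = 0.5, p_inhib = 0.3,
                                tuning_sigma_deg = 30,
                                baseline_range = c(1, 5),
                                evoked_ldg_range = c(15, 30),
                                igr_range = c(-0.5, 0.5),
                                latency_ldg_ms = 65, latency_ncs_ms = 100,
                                latency_rect_ms = 50,
                                phase_offset_mean = 180,
                                phase_offset_sd = 20,
                                tpl_means = c(0.25, 0.65),
                                tpl_sds = c(0.05, 0.10),
                                light_gain_ncs = 1, light_gain_ldg = 1) {
  with_seed(seed, {
    simple <- runif(n_units) < p_simple
    inhib <- runif(n_units) < p_inhib
    igr <- runif(n_units, igr_range[1], igr_range[2])
    ldg <- runif(n_units, evoked_ldg_range[1], evoked_ldg_range[2])
    tpl <- ifelse(inhib,
                  pmax(0.12, rnorm(n_units, tpl_means[1], tpl_sds[1])),
                  pmax(0.35, rnorm(n_units, tpl_means[2], tpl_sds[2])))
    data.frame(
      unit_id = seq_len(n_units),
      preferred_direction = runif(n_units, 0, 360),
      tuning_width = tuning_sigma_deg,
      baseline_rate = runif(n_units, baseline_range[1], baseline_range[2]),
      evoked_rate_ldg = ldg,
      evoked_rate_ncs = ldg * (1 + igr) / (1 - igr),
      igr_true = igr,
      latency_ldg = latency_ldg_ms,
      latency_ncs = latency_ncs_ms,
      latency_rect = latency_rect_ms,
      f1_ratio = ifelse(simple, runif(n_units, 0.6, 0.9),
                        runif(n_units, 0, 0.2)),
      response_phase_ldg = runif(n_units, 0, 360),
      phase_offset_ncs = wrap_deg(rnorm(n_units, phase_offset_mean,
                                        phase_offset_sd)),
      cell_class = ifelse(inhib, "I", "E"),
      tpl_ms = tpl,
      rf_x = runif(n_units, -10, 10),
      rf_y = runif(n_units, -10, 10),
      rf_sigma_x = runif(n_units, 1.5, 3),
      rf_sigma_y = runif(n_units, 1.5, 3),
      surround_index_true = runif(n_units, -0.2, 0.8),
      depth_um = runif(n_units, 0, 800),
      light_gain_ncs = light_gain_ncs,
      light_gain_ldg = light_gain_ldg,
      stringsAsFactors = FALSE
    ) -> gt
    class(gt) <- c("ground_truth_cohort", "data.frame")
    gt
  })
}

# von Mises direction gain in [exp(-2*kappa), 1]; sigma in degrees
vm_gain <- function(direction, preferred, sigma_deg) {
  kappa <- 1 / deg2rad(sigma_deg)^2
  exp(kappa * (cos(deg2rad(direction - preferred)) - 1))
}

# analytic instantaneous rate (sp/s) of one unit for one trial group at
# relative times t (s, stimulus onset at 0)
unit_rate_profile <- function(unit, condition, direction, t, tf = 2,
                              duration_s = 1, tau_s = 1.5,
                              onset_boost = 3, tau_onset_s = 0.05,
                              gain = 1) {
  r <- rep(unit$baseline_rate, length(t))
  if (condition %in% c("NCS", "LDG")) {
    amp <- switch(condition, NCS = unit$evoked_rate_ncs,
                  LDG = unit$evoked_rate_ldg)
    lat <- switch(condition, NCS = unit$latency_ncs,
                  LDG = unit$latency_ldg) / 1000
    phase <- switch(condition,
                    LDG = unit$response_phase_ldg,
                    NCS = unit$response_phase_ldg + unit$phase_offset_ncs)
    on <- t >= lat & t < duration_s
    # slow sustained decay plus a sharp onset transient, the typical
    # cortical PSTH shape (and what makes 1 ms latency detection crisp)
    env <- exp(-(t[on] - lat) / tau_s) *
      (1 + onset_boost * exp(-(t[on] - lat) / tau_onset_s))
    mod <- 1 + unit$f1_ratio * cos(2 * pi * tf * t[on] - deg2rad(phase))
    r[on] <- r[on] + gain * amp * vm_gain(direction,
                                          unit$preferred_direction,
                                          unit$tuning_width) * env * mod
  }
  neg <- r < 0
  if (any(neg)) {
    warnf("negative instantaneous rate clipped at 0")
    r[neg] <- 0
  }
  r
}

#' Simulate inhomogeneous-Poisson spikes for one unit
#'
#' Rate model: baseline plus a direction-tuned evoked component that steps
#' on at the condition's latency, decays exponentially (tau), and is
#' multiplied by `1 + f1_ratio * cos(2 pi TF t - phase)` for grating
#' conditions. DBC trials draw baseline only. Light-on trials scale the
#' evoked component by the unit's per-condition light gain; running trials
#' by `run_gain`. Spikes are generated on 1 ms bins over \[-0.3, 1.2) s
#' around each onset (the union of all analysis windows).
#'
#' @param unit one row of a [ground_truth_cohort()].
#' @param trials trial table from [condition_table()].
#' @param run_trials logical vector per trial (running) or `NULL`.
#' @param run_gain multiplicative evoked gain on running trials.
#' @param tf grating temporal frequency (Hz).
#' @param tau_s evoked-envelope decay constant (s).
#' @param onset_boost,tau_onset_s amplitude (multiple of the sustained
#'   evoked rate) and decay (s) of the onset transient.
#' @param seed RNG seed.
#' @return data.frame: unit_id, trial_id, t_s (absolute session time).
#' @export
simulate_unit_spikes <- function(unit, trials, run_trials = NULL,
                                 run_gain = 1.3, tf = 2, tau_s = 1.5,
                                 onset_boost = 3, tau_onset_s = 0.05,
                                 seed = 1) {
  if (is.null(run_trials)) run_trials <- rep(FALSE, nrow(trials))
  dt <- 0.001
  t_rel <- seq(-0.3, 1.2 - dt, by = dt)
  key <- paste(trials$condition, trials$direction, run_trials, trials$light)
  groups <- split(seq_len(nrow(trials)), key)
  with_seed(seed + unit$unit_id * 1000L, {
    out <- vector("list", length(groups))
    gi <- 0L
    for (idx in groups) {
      gi <- gi + 1L
      cond <- as.character(trials$condition[idx[1]])
      dir <- trials$direction[idx[1]]
      gain <- 1
      if (run_trials[idx[1]]) gain <- gain * run_gain
      if (isTRUE(trials$light[idx[1]])) {
        gain <- gain * switch(cond, NCS = unit$light_gain_ncs,
                              LDG = unit$light_gain_ldg, 1)
      }
      r <- unit_rate_profile(unit, cond, dir, t_rel, tf = tf,
                             tau_s = tau_s, onset_boost = onset_boost,
                             tau_onset_s = tau_onset_s, gain = gain)
      counts <- rpois(length(t_rel), r * dt * length(idx))
      tot <- sum(counts)
      if (tot == 0L) { out[[gi]] <- NULL; next }
      rel <- rep(t_rel, counts) + runif(tot, 0, dt)
      tr <- sample(idx, tot, replace = TRUE)
      out[[gi]] <- data.frame(trial_id = trials$trial_id[tr],
                              t_s = trials$onset_s[tr] + rel)
    }
    sp <- do.call(rbind, out)
    if (is.null(sp)) sp <- data.frame(trial_id = integer(), t_s = numeric())
    sp <- sp[order(sp$t_s), ]
    data.frame(unit_id = unit$unit_id, trial_id = sp$trial_id, t_s = sp$t_s)
  })
}

#' Simulate RF-mapping spikes for one unit
#'
#' Rectangle responses: a transient evoked component (latency
#' `latency_rect`) whose amplitude follows the unit's 2-D Gaussian RF
#' evaluated at the rectangle centre, with a brief onset transient
#' (doubled rate for the first 25 ms) as in the grating simulation.
#'
#' @param unit one cohort row.
#' @param presentations presentation table from [render_rf_rectangles()].
#' @param grid_shape c(rows, cols) of the mapping grid.
#' @param screen_deg screen extent (deg).
#' @param peak_rate sustained evoked rate at the RF centre (sp/s).
#' @param response_ms response duration after latency (ms).
#' @param seed RNG seed.
#' @return data.frame: unit_id, presentation, t_s (absolute).
#' @export
simulate_rf_spikes <- function(unit, presentations, grid_shape = c(8, 13),
                               screen_deg = c(35, 35), peak_rate = 60,
                               response_ms = 80, seed = 1) {
  pitch <- screen_deg / c(grid_shape[2], grid_shape[1])
  cx <- (presentations$col - (grid_shape[2] + 1) / 2) * pitch[1]
  cy <- ((grid_shape[1] + 1) / 2 - presentations$row) * pitch[2]
  amp <- peak_rate * exp(-((cx - unit$rf_x)^2 / (2 * unit$rf_sigma_x^2) +
                           (cy - unit$rf_y)^2 / (2 * unit$rf_sigma_y^2)))
  dt <- 0.001
  period <- diff(presentations$onset_s[1:2])
  t_rel <- seq(0, period - dt, by = dt)
  lat <- unit$latency_rect / 1000
  with_seed(seed + unit$unit_id * 1000L + 7L, {
    on <- t_rel >= lat & t_rel < lat + response_ms / 1000
    boost <- t_rel >= lat & t_rel < lat + 0.025
    # rate matrix: bins x presentations
    r <- matrix(unit$baseline_rate, length(t_rel), nrow(presentations))
    r[on, ] <- r[on, ] + rep(amp, each = sum(on))
    r[boost, ] <- r[boost, ] + rep(amp, each = sum(boost))
    counts <- array(rpois(length(r), r * dt), dim(r))
    tot <- sum(counts)
    if (tot == 0L)
      return(data.frame(unit_id = integer(), presentation = integer(),
                        t_s = numeric()))
    nz <- which(counts > 0, arr.ind = TRUE)
    reps <- counts[counts > 0]
    bin <- rep(nz[, 1], reps)
    pres_i <- rep(nz[, 2], reps)
    data.frame(unit_id = unit$unit_id,
               presentation = presentations$presentation[pres_i],
               t_s = presentations$onset_s[pres_i] + t_rel[bin] +
                 runif(tot, 0, dt))
  })
}

#' Simulate mean spike waveforms
#'
#' Each waveform is a difference of two Gaussians: a trough followed by a
#' peak separated by the unit's drawn TPL, sampled at `sample_rate`. The
#' cohort's TPL values follow a two-component Gaussian mixture (narrow =
#' putative inhibitory, broad = excitatory).
#'
#' @param cohort a [ground_truth_cohort()].
#' @param sample_rate waveform sampling rate (Hz).
#' @param n_samples samples per waveform.
#' @param noise_sd additive Gaussian noise (fraction of trough depth).
#' @param seed RNG seed.
#' @return matrix units x samples, rownames = unit_id; attribute
#'   `sample_rate`.
#' @export
simulate_waveforms <- function(cohort, sample_rate = 30000,
                               n_samples = 121, noise_sd = 0.005, seed = 1) {
  t_ms <- (seq_len(n_samples) - 1) / sample_rate * 1000
  t0 <- t_ms[round(n_samples / 4)]
  with_seed(seed + 13L, {
    w <- t(vapply(seq_len(nrow(cohort)), function(i) {
      tpl <- cohort$tpl_ms[i]
      s1 <- 0.08
      s2 <- max(0.06, tpl / 5)   # peak sharp enough that noise cannot
                                 # displace the argmax by > 1 sample
      wf <- -exp(-(t_ms - t0)^2 / (2 * s1^2)) +
        0.5 * exp(-(t_ms - t0 - tpl)^2 / (2 * s2^2))
      wf + rnorm(n_samples, 0, noise_sd)
    }, numeric(n_samples)))
    rownames(w) <- cohort$unit_id
    attr(w, "sample_rate") <- sample_rate
    w
  })
}

#' Simulate laminar LFP with a localized stimulus-locked sink
#'
#' The voltage profile is a Gaussian in depth centred on `sink_channel`
#' multiplied by a stimulus-locked transient, plus an optional linear
#' depth gradient (which the CSD annihilates) and white noise.
#'
#' @param n_channels electrode channels (ordered by depth).
#' @param sink_channel channel of the current sink.
#' @param fs sampling rate (Hz) after downsampling.
#' @param duration_s trace duration (s).
#' @param onset_s stimulus onset (s).
#' @param sigma_ch spatial width of the sink (channels).
#' @param noise_sd white-noise SD (signal amplitude is 1).
#' @param linear_gradient slope of an added linear-in-depth component.
#' @param seed RNG seed.
#' @return matrix channels x time with attributes `fs` and `onset_s`.
#' @export
simulate_lfp_csd <- function(n_channels = 32, sink_channel = 12, fs = 1000,
                             duration_s = 1, onset_s = 0.2, sigma_ch = 1.5,
                             noise_sd = 0.05, linear_gradient = 0,
                             seed = 1) {
  if (n_channels < 3) stopf("need at least 3 channels")
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  s <- ifelse(t >= onset_s,
              -exp(-(t - onset_s) / 0.05) * sin(2 * pi * (t - onset_s) / 0.1),
              0)
  prof <- exp(-(seq_len(n_channels) - sink_channel)^2 / (2 * sigma_ch^2))
  lfp <- outer(prof, s) + linear_gradient * outer(seq_len(n_channels), t * 0 + 1)
  with_seed(seed + 29L, {
    lfp <- lfp + matrix(rnorm(length(lfp), 0, noise_sd),
                        n_channels, length(t))
  })
  attr(lfp, "fs") <- fs
  attr(lfp, "onset_s") <- onset_s
  lfp
}

#' Simulate running-disk encoder voltage and pupil trace
#'
#' The rotary encoder maps disk angle to 0..5 V (wrapping at 5 V -> 0 V).
#' A stated fraction of trials are "running" (speed above threshold in the
#' classification window). The pupil is a baseline plus per-condition
#' transients: dilation for NCS, constriction for LDG, none for DBC,
#' emulating the opposing pupillary responses to illusory darkening versus
#' physical brightening.
#'
#' @param trials trial table.
#' @param run_fraction fraction of running trials.
#' @param run_speed_cmps running speed (cm/s).
#' @param pupil_effects named amplitudes (fraction of baseline) per
#'   condition.
#' @param disk_diameter_cm running-disk diameter.
#' @param fs_encoder,fs_pupil sampling rates (Hz).
#' @param pupil_noise_sd pupil noise (fraction of baseline).
#' @param seed RNG seed.
#' @return list: encoder (t_s, voltage), pupil (t_s, diameter), run_truth
#'   (logical per trial row).
#' @export
simulate_behavior <- function(trials, run_fraction = 0.3,
                              run_speed_cmps = 5,
                              pupil_effects = c(NCS = 0.06, LDG = -0.08,
                                                DBC = 0),
                              disk_diameter_cm = 20,
                              fs_encoder = 1000, fs_pupil = 45,
                              pupil_noise_sd = 0.01, seed = 1) {
  t_end <- max(trials$offset_s) + 1
  with_seed(seed + 41L, {
    run_truth <- runif(nrow(trials)) < run_fraction
    # speed profile: run trials move at run_speed over [-0.5, +1.2] s
    te <- seq(0, t_end, by = 1 / fs_encoder)
    speed <- rep(0, length(te))
    for (i in which(run_truth)) {
      on <- te >= trials$onset_s[i] - 0.5 & te <= trials$onset_s[i] + 1.2
      speed[on] <- run_speed_cmps
    }
    # rim speed v = omega_deg * pi * D / 360  =>  omega_deg = v*360/(pi*D)
    omega <- speed * 360 / (pi * disk_diameter_cm)
    angle <- cumsum(omega) / fs_encoder
    voltage <- (angle %% 360) / 360 * 5
    encoder <- data.frame(t_s = te, voltage = voltage)

    tp <- seq(0, t_end, by = 1 / fs_pupil)
    base <- 1
    pupil <- rep(base, length(tp))
    shape <- function(dt) {
      ifelse(dt < 0, 0,
             ifelse(dt <= 1, pmin(dt / 0.3, 1), exp(-(dt - 1) / 0.5)))
    }
    for (i in seq_len(nrow(trials))) {
      amp <- pupil_effects[[as.character(trials$condition[i])]] %||% 0
      dt <- tp - trials$onset_s[i]
      sel <- dt >= 0 & dt <= 3
      pupil[sel] <- pupil[sel] + base * amp * shape(dt[sel])
    }
    pupil <- pupil + rnorm(length(tp), 0, pupil_noise_sd * base)
    list(encoder = encoder,
         pupil = data.frame(t_s = tp, diameter = pupil),
         run_truth = run_truth)
  })
}

#' Simulate a complete synthetic session
#'
#' Orchestrates trials, behaviour, spikes (with running gain), RF-mapping
#' spikes, waveforms and laminar LFP into a single `recording_bundle` with
#' the ground truth attached.
#'
#' @param cohort a [ground_truth_cohort()].
#' @param trials trial table; default the 24-condition, 70-trial design.
#' @param seed master RNG seed.
#' @param tf grating temporal frequency (Hz).
#' @param run_gain evoked-rate gain on running trials.
#' @param run_fraction fraction of running trials.
#' @param rf_presentations RF-mapping presentation table, or `NULL` to
#'   build the default 8 x 13 sweep.
#' @param n_channels,sink_channel laminar probe geometry.
#' @param ... passed to [simulate_behavior()].
#' @return a `recording_bundle`: list(spikes, rf_spikes, rf_presentations,
#'   waveforms, lfp, encoder, pupil, trials, run_truth, ground_truth).
#' @export
simulate_session <- function(cohort, trials = NULL, seed = 1, tf = 2,
                             run_gain = 1.3, run_fraction = 0.3,
                             rf_presentations = NULL,
                             n_channels = 32, sink_channel = 12, ...) {
  if (is.null(trials)) trials <- condition_table(order_seed = seed)
  beh <- simulate_behavior(trials, run_fraction = run_fraction,
                           seed = seed, ...)
  if (is.null(rf_presentations)) {
    rf_presentations <- render_rf_rectangles(
      display_geometry(), order_seed = seed, n_sweeps = 20,
      render = FALSE)$presentations
  }
  spikes <- data.table::rbindlist(lapply(seq_len(nrow(cohort)), function(i) {
    simulate_unit_spikes(cohort[i, ], trials, run_trials = beh$run_truth,
                         run_gain = run_gain, tf = tf, seed = seed)
  }))
  rf_spikes <- data.table::rbindlist(lapply(seq_len(nrow(cohort)),
                                            function(i) {
    simulate_rf_spikes(cohort[i, ], rf_presentations, seed = seed)
  }))
  structure(list(
    spikes = as.data.frame(spikes),
    rf_spikes = as.data.frame(rf_spikes),
    rf_presentations = rf_presentations,
    waveforms = simulate_waveforms(cohort, seed = seed),
    lfp = simulate_lfp_csd(n_channels, sink_channel, seed = seed),
    encoder = beh$encoder,
    pupil = beh$pupil,
    trials = trials,
    run_truth = beh$run_truth,
    ground_truth = cohort
  ), class = "recording_bundle")
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf(paste0("<recording_bundle: %d units, %d trials, %d spikes, ",
                     "%d LFP channels>\n"),
              nrow(x$ground_truth), nrow(x$trials), nrow(x$spikes),
              nrow(x$lfp)))
  invisible(x)
}

#' Write / read a recording bundle as plain-text files
#'
#' @param bundle a `recording_bundle`.
#' @param dir target directory.
#' @return invisibly, `dir` (write) or the bundle (read).
#' @export
write_recording_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                         row.names = FALSE)
  wr(bundle$spikes, "spikes.csv")
  wr(bundle$rf_spikes, "rf_spikes.csv")
  wr(bundle$rf_presentations, "rf_presentations.csv")
  wr(bundle$trials, "trials.csv")
  wr(bundle$encoder, "encoder.csv")
  wr(bundle$pupil, "pupil.csv")
  utils::write.table(bundle$waveforms, file.path(dir, "waveforms.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(bundle$lfp, file.path(dir, "lfp.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(waveform_sample_rate = attr(bundle$waveforms, "sample_rate"),
               lfp_fs = attr(bundle$lfp, "fs"),
               lfp_onset_s = attr(bundle$lfp, "onset_s"),
               run_truth = bundle$run_truth)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$ground_truth, file.path(dir,
                                                      "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @rdname write_recording_bundle
#' @export
read_recording_bundle <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  wf <- as.matrix(utils::read.table(file.path(dir, "waveforms.csv"),
                                    sep = ","))
  dimnames(wf) <- NULL
  attr(wf, "sample_rate") <- meta$waveform_sample_rate
  lfp <- as.matrix(utils::read.table(file.path(dir, "lfp.csv"), sep = ","))
  dimnames(lfp) <- NULL
  attr(lfp, "fs") <- meta$lfp_fs
  attr(lfp, "onset_s") <- meta$lfp_onset_s
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  structure(list(spikes = rd("spikes.csv"), rf_spikes = rd("rf_spikes.csv"),
                 rf_presentations = rd("rf_presentations.csv"),
                 waveforms = wf, lfp = lfp, encoder = rd("encoder.csv"),
                 pupil = rd("pupil.csv"), trials = rd("trials.csv"),
                 run_truth = meta$run_truth, ground_truth = gt),
            class = "recording_bundle")
}
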