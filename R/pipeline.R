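# Session-level analysis: per-unit rates and metrics tables, population
# summaries (response partition, phase distribution, E/I comparison,
# light-on/off comparison, behaviour), and the end-to-end pipeline with a
# small command-line front end.

utils::globalVariables(c(
  "unit_id", "trial_id", "n_stim", "n_base", "condition", "direction",
  "light", "run", "rate", "baseline_rate", "delta", "rate_on", "rate_off",
  ".N", ".SD", "J"
))

#' Per-unit, per-condition evoked rates
#'
#' Counts spikes in the 1 s stimulus window and the 300 ms pre-onset
#' baseline of every trial, and returns baseline-subtracted (rectified)
#' trial-averaged rates grouped by unit, condition, direction and,
#' optionally, running state and light.
#'
#' @param bundle a `recording_bundle`.
#' @param run_labels optional per-trial "run"/"still" labels; defaults to
#'   the bundle's ground-truth labels when present.
#' @param stim_s stimulus duration (s).
#' @return list: `rates` (data.table: unit_id, condition, direction,
#'   light, run, rate, n_trials) and `baseline` (unit_id, baseline_rate).
#' @export
unit_condition_rates <- function(bundle, run_labels = NULL, stim_s = 1) {
  tr <- data.table::as.data.table(bundle$trials)
  sp <- data.table::as.data.table(bundle$spikes)
  if (is.null(run_labels)) {
    run_labels <- if (!is.null(bundle$run_truth))
      ifelse(bundle$run_truth, "run", "still") else rep("still", nrow(tr))
  }
  tr[, run := run_labels]
  win_start <- tr$onset_s - 0.3
  idx <- findInterval(sp$t_s, win_start)
  valid <- idx >= 1
  rel <- sp$t_s[valid] - tr$onset_s[pmax(idx[valid], 1)]
  keep <- rel >= -0.3 & rel < stim_s
  cnt <- data.table::data.table(unit_id = sp$unit_id[valid][keep],
                                trial_id = tr$trial_id[idx[valid][keep]],
                                rel = rel[keep])
  per_trial <- cnt[, .(n_stim = sum(rel >= 0), n_base = sum(rel < 0)),
                   by = .(unit_id, trial_id)]
  grid <- data.table::CJ(unit_id = sort(unique(bundle$spikes$unit_id)),
                         trial_id = tr$trial_id)
  per_trial <- per_trial[grid, on = c("unit_id", "trial_id")]
  per_trial[is.na(n_stim), `:=`(n_stim = 0L, n_base = 0L)]
  per_trial <- per_trial[tr[, .(trial_id, condition, direction, light, run)],
                         on = "trial_id"]
  baseline <- per_trial[, .(baseline_rate = sum(n_base) / (.N * 0.3)),
                        by = unit_id]
  rates <- per_trial[, .(rate = mean(n_stim) / stim_s, n_trials = .N),
                     by = .(unit_id, condition, direction, light, run)]
  rates <- rates[baseline, on = "unit_id"]
  rates[, rate := pmax(rate - baseline_rate, 0)]
  list(rates = rates[, .(unit_id, condition, direction, light, run,
                         rate, n_trials)],
       baseline = baseline)
}

# per-unit spike times relative to trial onset, for fast PSTH building
spikes_relative <- function(bundle, window = c(-0.3, 1.0)) {
  tr <- bundle$trials
  sp <- bundle$spikes
  idx <- findInterval(sp$t_s, tr$onset_s + window[1])
  valid <- idx >= 1
  rel <- sp$t_s[valid] - tr$onset_s[pmax(idx[valid], 1)]
  keep <- rel >= window[1] & rel < window[2]
  data.table::data.table(unit_id = sp$unit_id[valid][keep],
                         trial_id = tr$trial_id[idx[valid][keep]],
                         rel = rel[keep])
}

# assemble a psth object from relative spike times of selected trials
psth_from_rel <- function(rel, n_trials, window = c(-0.3, 1.0),
                          binwidth_s = 0.001) {
  nb <- round(diff(window) / binwidth_s)
  counts <- tabulate(pmin(nb, 1L + floor((rel - window[1]) / binwidth_s)),
                     nb)
  bin_start_ms <- (window[1] + (seq_len(nb) - 1) * binwidth_s) * 1000
  bl <- bin_start_ms >= -300 & bin_start_ms < 0
  structure(list(bin_start_ms = bin_start_ms, counts = counts,
                 rate = smooth_psth_counts(counts) / (n_trials * binwidth_s),
                 n_trials = n_trials, binwidth_s = binwidth_s,
                 baseline_rate = if (any(bl))
                   sum(counts[bl]) / (n_trials * sum(bl) * binwidth_s)
                 else 0),
            class = "psth")
}

snap_to_grid <- function(angle, step = 45) wrap_deg(round(angle / step) * step)

#' Per-unit metrics table
#'
#' For every unit: LDG/NCS direction tuning and spline-interpolated
#' preferred angles; PSTHs at the (LDG-defined) preferred direction;
#' evoked flags and Poisson-detector latencies for NCS/LDG/DBC; F0/F1,
#' CSM, IGR, IGR_F1 and the NCS-LDG F1 phase shift.
#'
#' @param bundle a `recording_bundle`.
#' @param tf grating temporal frequency (Hz).
#' @param scan_ms latency scan window (ms).
#' @return data.frame, one row per unit.
#' @export
unit_metrics <- function(bundle, tf = 2, scan_ms = c(0, 500)) {
  ucr <- unit_condition_rates(bundle)
  rates <- ucr$rates[light == FALSE,
                     .(rate = sum(rate * n_trials) / sum(n_trials)),
                     by = .(unit_id, condition, direction)]
  rel <- spikes_relative(bundle)
  data.table::setkey(rel, unit_id)
  tr <- data.table::as.data.table(bundle$trials)
  units <- sort(unique(bundle$ground_truth$unit_id))
  out <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[i]
    ru <- rates[unit_id == u]
    curve_ldg <- ru[condition == "LDG"][order(direction)]
    curve_ncs <- ru[condition == "NCS"][order(direction)]
    if (nrow(curve_ldg) < 2) next
    pa_ldg <- preferred_angle(curve_ldg$direction, curve_ldg$rate)
    pa_ncs <- if (nrow(curve_ncs) >= 2)
      preferred_angle(curve_ncs$direction, curve_ncs$rate) else
        list(angle = NA_real_)
    pref <- snap_to_grid(pa_ldg$angle)
    if (!pref %in% curve_ldg$direction)
      pref <- curve_ldg$direction[which.max(curve_ldg$rate)]
    sel_tr <- function(cond) tr$trial_id[tr$condition == cond &
                                         tr$direction == pref &
                                         tr$light == FALSE]
    mk <- function(cond) {
      ids <- sel_tr(cond)
      psth_from_rel(rel[J(u)][trial_id %in% ids, rel], length(ids))
    }
    p_ncs <- mk("NCS"); p_ldg <- mk("LDG"); p_dbc <- mk("DBC")
    det_ncs <- detect_evoked_and_latency(p_ncs, scan_ms)
    det_ldg <- detect_evoked_and_latency(p_ldg, scan_ms)
    det_dbc <- detect_evoked_and_latency(p_dbc, scan_ms)
    ff_ncs <- f0_f1(p_ncs, tf); ff_ldg <- f0_f1(p_ldg, tf)
    r_ncs <- ru[condition == "NCS" & direction == pref, rate]
    r_ldg <- ru[condition == "LDG" & direction == pref, rate]
    r_ncs <- if (length(r_ncs)) r_ncs else 0
    r_ldg <- if (length(r_ldg)) r_ldg else 0
    out[[i]] <- data.frame(
      unit_id = u,
      baseline_rate = ucr$baseline[unit_id == u, baseline_rate],
      preferred_ldg = pa_ldg$angle, preferred_ncs = pa_ncs$angle,
      pref_grid = pref,
      rate_ncs = r_ncs, rate_ldg = r_ldg,
      evoked_ncs = det_ncs$evoked, evoked_ldg = det_ldg$evoked,
      evoked_dbc = det_dbc$evoked,
      latency_ncs = det_ncs$latency_ms, latency_ldg = det_ldg$latency_ms,
      f0_ldg = ff_ldg$f0, f1_ldg = ff_ldg$f1,
      f0_ncs = ff_ncs$f0, f1_ncs = ff_ncs$f1,
      f1_dominant = ff_ldg$f1_dominant && ff_ncs$f1_dominant,
      igr = igr(r_ncs, r_ldg),
      igr_f1 = igr_f1(ff_ncs$f1, ff_ldg$f1),
      csm = csm(ff_ldg$f1, ff_ldg$f0),
      phase_shift = if (ff_ncs$f1 > 0 && ff_ldg$f1 > 0)
        wrap_deg(ff_ncs$phase_deg - ff_ldg$phase_deg) else NA_real_
    )
  }
  do.call(rbind, out)
}

#' Responsive-unit partition
#'
#' Counts units responding to both NCS and LDG, LDG only, NCS only, or
#' neither (the pie-chart partition of the population).
#'
#' @param metrics a [unit_metrics()] table.
#' @return named integer vector (both, ldg_only, ncs_only, none).
#' @export
response_partition <- function(metrics) {
  c(both = sum(metrics$evoked_ncs & metrics$evoked_ldg),
    ldg_only = sum(!metrics$evoked_ncs & metrics$evoked_ldg),
    ncs_only = sum(metrics$evoked_ncs & !metrics$evoked_ldg),
    none = sum(!metrics$evoked_ncs & !metrics$evoked_ldg))
}

#' Population phase-shift summary
#'
#' Circular mean, confidence interval and Rayleigh test of the NCS-LDG F1
#' phase shifts of F1-dominant units.
#'
#' @param metrics a [unit_metrics()] table.
#' @return list(n, mean_deg, ci_deg, rayleigh_z, rayleigh_p).
#' @export
phase_summary <- function(metrics) {
  ph <- metrics$phase_shift[metrics$f1_dominant & !is.na(metrics$phase_shift)]
  if (length(ph) < 2) return(list(n = length(ph), mean_deg = NA_real_,
                                  ci_deg = c(NA_real_, NA_real_),
                                  rayleigh_z = NA_real_,
                                  rayleigh_p = NA_real_))
  cm <- circular_mean_ci(ph)
  rt <- rayleigh_test(ph)
  list(n = length(ph), mean_deg = cm$mean_deg, ci_deg = cm$ci_deg,
       rayleigh_z = rt$z, rayleigh_p = rt$p)
}

#' Light-on versus light-off comparison
#'
#' Per-unit evoked-rate change under optogenetic light for NCS and LDG,
#' with a two-sided sign test on the per-unit deltas per condition.
#' Restricted to still trials: the running gain is shared by all units,
#' so a chance imbalance of running trials between light states would
#' correlate every unit's delta and invalidate the sign test.
#'
#' @param bundle a `recording_bundle` whose trials include light-on.
#' @return list: `per_unit` (unit_id, condition, rate_off, rate_on,
#'   delta) and `tests` (condition, n, n_negative, p_sign).
#' @export
light_comparison <- function(bundle) {
  ucr <- unit_condition_rates(bundle)
  r <- ucr$rates[condition %in% c("NCS", "LDG") & run == "still",
                 .(rate = sum(rate * n_trials) / sum(n_trials)),
                 by = .(unit_id, condition, light)]
  w <- data.table::dcast(r, unit_id + condition ~ light, value.var = "rate")
  data.table::setnames(w, c("FALSE", "TRUE"), c("rate_off", "rate_on"))
  w[, delta := rate_on - rate_off]
  tests <- w[, {
    nz <- delta[delta != 0]
    list(n = length(nz), n_negative = sum(nz < 0),
         p_sign = if (length(nz)) binom.test(sum(nz < 0),
                                             length(nz))$p.value else NA_real_)
  }, by = condition]
  list(per_unit = as.data.frame(w), tests = as.data.frame(tests))
}

#' E/I classification and comparison table
#'
#' Measures TPL on each unit's mean waveform, fits the two-Gaussian
#' mixture threshold, and summarises IGR by putative class.
#'
#' @param bundle a `recording_bundle`.
#' @param metrics a [unit_metrics()] table (for IGR by class).
#' @return list(threshold_ms, labels, by_class).
#' @export
ei_metrics <- function(bundle, metrics = NULL) {
  sr <- attr(bundle$waveforms, "sample_rate")
  tpls <- apply(bundle$waveforms, 1, tpl, sample_rate = sr, upsample = 4)
  if (sum(is.finite(tpls)) < 50) {
    warnf("too few units (%d) for the TPL mixture fit; labels unset",
          sum(is.finite(tpls)))
    return(list(threshold_ms = NA_real_,
                labels = rep(NA_character_, length(tpls)),
                tpl_ms = tpls, separated = NA, by_class = NULL))
  }
  fit <- ei_threshold(tpls)
  by_class <- NULL
  if (!is.null(metrics)) {
    df <- data.frame(unit_id = as.integer(rownames(bundle$waveforms)),
                     tpl_ms = tpls, class = fit$labels)
    m <- merge(metrics, df, by = "unit_id")
    by_class <- aggregate(cbind(igr, igr_f1) ~ class,
                          data = m[!is.na(m$igr), ],
                          FUN = function(x) mean(abs(x), na.rm = TRUE))
  }
  list(threshold_ms = fit$threshold_ms, labels = fit$labels,
       tpl_ms = tpls, separated = fit$separated, by_class = by_class)
}

#' Behaviour summary
#'
#' Run/still classification from the encoder trace, IGR computed
#' separately on run and still trials, and per-condition mean dilation
#' indices.
#'
#' @param bundle a `recording_bundle`.
#' @return list(run_labels, igr_by_state, dilation).
#' @export
behavior_summary <- function(bundle) {
  speed <- disk_speed(bundle$encoder)
  run_labels <- classify_run_still(speed, bundle$trials)
  ucr <- unit_condition_rates(bundle, run_labels = run_labels)
  r <- ucr$rates[condition %in% c("NCS", "LDG") & light == FALSE,
                 .(rate = sum(rate * n_trials) / sum(n_trials)),
                 by = .(unit_id, condition, run)]
  w <- data.table::dcast(r, unit_id + run ~ condition, value.var = "rate")
  w <- w[!is.na(w$NCS) & !is.na(w$LDG) & (w$NCS + w$LDG) > 0, ]
  w$igr <- igr(w$NCS, w$LDG)
  di <- dilation_index(bundle$pupil, bundle$trials)
  dil <- aggregate(dilation_index ~ condition, data = di, FUN = mean)
  list(run_labels = run_labels,
       igr_by_state = as.data.frame(w),
       dilation = dil)
}

#' RF metrics per unit
#'
#' Maps, fits and summarises receptive fields from the RF-mapping session:
#' overlap with the nearest inducer patch, distance to it, rectangle
#' latency and the NCS delay index.
#'
#' @param bundle a `recording_bundle`.
#' @param metrics a [unit_metrics()] table (for NCS latencies).
#' @param layout inducer layout for overlap computations.
#' @param grid_shape,screen_deg RF-mapping geometry.
#' @return data.frame per unit.
#' @export
rf_metrics <- function(bundle, metrics = NULL,
                       layout = inducer_layout_grid(),
                       grid_shape = c(8, 13), screen_deg = c(35, 35)) {
  pres <- bundle$rf_presentations
  pitch <- screen_deg / c(grid_shape[2], grid_shape[1])
  xs <- (seq_len(grid_shape[2]) - (grid_shape[2] + 1) / 2) * pitch[1]
  ys <- ((grid_shape[1] + 1) / 2 - seq_len(grid_shape[1])) * pitch[2]
  units <- sort(unique(bundle$ground_truth$unit_id))
  out <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[i]
    map <- rf_response_map(bundle$rf_spikes, pres, u, grid_shape)
    rf <- fit_rf(map, x = xs, y = ys)
    if (rf$no_rf) {
      out[[i]] <- data.frame(unit_id = u, no_rf = TRUE, rf_x = NA_real_,
                             rf_y = NA_real_, rf_sx = NA_real_,
                             rf_sy = NA_real_, overlap = NA_real_,
                             distance_deg = NA_real_,
                             latency_rect = NA_real_,
                             ncs_delay_index = NA_real_)
      next
    }
    ov <- overlap_ratio(rf, layout)
    dist <- rf_inducer_distance(rf, layout)
    cells <- expand.grid(row = seq_len(grid_shape[1]),
                         col = seq_len(grid_shape[2]))
    cx <- (cells$col - (grid_shape[2] + 1) / 2) * pitch[1]
    cy <- ((grid_shape[1] + 1) / 2 - cells$row) * pitch[2]
    inside <- ((cx - rf$center[1]) / pmax(rf$sigma[1], 1))^2 +
              ((cy - rf$center[2]) / pmax(rf$sigma[2], 1))^2 <= 1
    lat_rect <- if (any(inside))
      rectangle_latency(bundle$rf_spikes, pres, cells[inside, ], u)
      else NA_real_
    lat_ncs <- if (!is.null(metrics))
      metrics$latency_ncs[match(u, metrics$unit_id)] else NA_real_
    out[[i]] <- data.frame(
      unit_id = u, no_rf = FALSE,
      rf_x = rf$center[1], rf_y = rf$center[2],
      rf_sx = rf$sigma[1], rf_sy = rf$sigma[2],
      overlap = ov, distance_deg = dist, latency_rect = lat_rect,
      ncs_delay_index = if (is.finite(lat_ncs) && is.finite(lat_rect))
        ncs_delay_index(lat_ncs, lat_rect) else NA_real_)
  }
  do.call(rbind, out)
}

#' Run the full synthetic pipeline
#'
#' Builds the trial design, simulates a session from a ground-truth
#' cohort, runs every analysis stage and writes tidy CSV tables plus a
#' JSON summary and a run log to `outdir`.
#'
#' @param config named list (or path to a JSON file): n_units,
#'   trials_per_condition, seed, light (logical), light_gain_ncs,
#'   run_fraction, tf, and any [ground_truth_cohort()] override.
#' @param outdir output directory.
#' @return invisibly, the list of result tables.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("neonv1_")) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stopf("config must be a list or JSON path")
  bad <- setdiff(names(config),
                 c("n_units", "trials_per_condition", "seed", "light",
                   "light_gain_ncs", "light_gain_ldg", "run_fraction",
                   "tf", "n_channels", "sink_channel"))
  if (length(bad)) stopf("unknown config field(s): %s",
                         paste(bad, collapse = ", "))
  n_units <- config$n_units %||% 50
  tpc <- config$trials_per_condition %||% 70
  seed <- config$seed %||% 1
  tf <- config$tf %||% 2
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cohort <- ground_truth_cohort(
    n_units = n_units, seed = seed,
    light_gain_ncs = config$light_gain_ncs %||% 1,
    light_gain_ldg = config$light_gain_ldg %||% 1)
  trials <- condition_table(trials_per_condition = tpc, order_seed = seed,
                            light = isTRUE(config$light))
  bundle <- simulate_session(cohort, trials, seed = seed, tf = tf,
                             run_fraction = config$run_fraction %||% 0.3,
                             n_channels = config$n_channels %||% 32,
                             sink_channel = config$sink_channel %||% 12)
  metrics <- unit_metrics(bundle, tf = tf)
  part <- response_partition(metrics)
  ph <- phase_summary(metrics)
  ei <- ei_metrics(bundle, metrics)
  beh <- behavior_summary(bundle)
  rfm <- rf_metrics(bundle, metrics)
  res <- list(metrics = metrics, partition = part, phase = ph, ei = ei,
              behavior = beh, rf = rfm)
  if (isTRUE(config$light)) res$light <- light_comparison(bundle)
  utils::write.csv(metrics, file.path(outdir, "unit_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(rfm, file.path(outdir, "rf_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(unit_id = as.integer(
                     rownames(bundle$waveforms)),
                   tpl_ms = ei$tpl_ms, class = ei$labels),
                   file.path(outdir, "ei_labels.csv"), row.names = FALSE)
  utils::write.csv(beh$igr_by_state, file.path(outdir, "igr_by_state.csv"),
                   row.names = FALSE)
  utils::write.csv(beh$dilation, file.path(outdir, "dilation_index.csv"),
                   row.names = FALSE)
  if (!is.null(res$light)) {
    utils::write.csv(res$light$per_unit,
                     file.path(outdir, "light_per_unit.csv"),
                     row.names = FALSE)
    utils::write.csv(res$light$tests, file.path(outdir, "light_tests.csv"),
                     row.names = FALSE)
  }
  summary <- list(config = config, partition = as.list(part), phase = ph,
                  ei_threshold_ms = ei$threshold_ms,
                  dilation = setNames(as.list(beh$dilation$dilation_index),
                                      beh$dilation$condition))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(c(sprintf("neonv1 %s", as.character(utils::packageVersion("neonv1"))),
               sprintf("seed: %s", seed),
               sprintf("n_units: %d, trials/condition: %d", n_units, tpc),
               sprintf("R: %s", R.version.string)),
             file.path(outdir, "run_log.txt"))
  invisible(res)
}

#' Render a human-readable report from pipeline results
#'
#' Writes `report.md` (and a PDF of summary panels) from the CSV tables
#' produced by [run_pipeline()]; every number in the report is read back
#' from a CSV cell, nothing is recomputed.
#'
#' @param results_dir directory written by [run_pipeline()].
#' @param plots logical; render the PDF panels.
#' @return invisibly, the path to `report.md`.
#' @export
report <- function(results_dir, plots = TRUE) {
  need <- c("unit_metrics.csv", "summary.json")
  missing <- need[!file.exists(file.path(results_dir, need))]
  if (length(missing))
    stopf("missing pipeline outputs: %s", paste(missing, collapse = ", "))
  s <- jsonlite::read_json(file.path(results_dir, "summary.json"),
                           simplifyVector = TRUE)
  m <- utils::read.csv(file.path(results_dir, "unit_metrics.csv"))
  lines <- c(
    "# Synthetic session report", "",
    "## Responsive-unit partition",
    sprintf("- both: %s, LDG only: %s, NCS only: %s, none: %s",
            s$partition$both, s$partition$ldg_only, s$partition$ncs_only,
            s$partition$none), "",
    "## Phase shift (F1-dominant units)",
    {
      fmt <- function(x, d = 2) {
        if (is.null(x) || length(x) == 0 || !is.numeric(x) || is.na(x))
          "n/a" else formatC(x, digits = d, format = "g")
      }
      sprintf("- n = %s, circular mean = %s deg, CI = [%s, %s], Rayleigh Z = %s (p = %s)",
              s$phase$n, fmt(s$phase$mean_deg, 5), fmt(s$phase$ci_deg[1], 5),
              fmt(s$phase$ci_deg[2], 5), fmt(s$phase$rayleigh_z, 4),
              fmt(s$phase$rayleigh_p, 3))
    }, "",
    "## E/I threshold",
    sprintf("- TPL threshold: %s ms",
            if (is.numeric(s$ei_threshold_ms))
              sprintf("%.3f", s$ei_threshold_ms) else "n/a"), "",
    "## Pupil dilation index (condition means)",
    paste(sprintf("- %s: %.4f", names(s$dilation), unlist(s$dilation)),
          collapse = "\n"))
  out <- file.path(results_dir, "report.md")
  writeLines(lines, out)
  if (plots) {
    grDevices::pdf(file.path(results_dir, "report_panels.pdf"), 7, 7)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(2, 2))
    ph <- m$phase_shift[m$f1_dominant & !is.na(m$phase_shift)]
    if (length(ph))
      graphics::hist(ph, breaks = 24, main = "F1 phase shift (deg)",
                     xlab = "deg")
    if (any(!is.na(m$igr)))
      graphics::hist(m$igr, breaks = 20, main = "IGR", xlab = "index")
    if (any(!is.na(m$csm)))
      graphics::hist(m$csm, breaks = 20, main = "CSM", xlab = "index")
    di_f <- file.path(results_dir, "dilation_index.csv")
    if (file.exists(di_f)) {
      di <- utils::read.csv(di_f)
      graphics::barplot(di$dilation_index, names.arg = di$condition,
                        main = "Dilation index")
    }
  }
  invisible(out)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `analyze`, `report`, `stimgen`, each accepting
#' `--config <json>`, `--seed <int>`, `--outdir <dir>`. Returns an exit
#' status (0 ok, 1 input error, 2 internal error) for use with
#' `quit(status = ...)`.
#'
#' @param args character vector of CLI arguments.
#' @return integer exit status, invisibly.
#' @export
neonv1_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parse_opts <- function(a) {
    opts <- list()
    i <- 1
    while (i <= length(a)) {
      if (grepl("^--", a[i])) {
        opts[[sub("^--", "", a[i])]] <- if (i < length(a)) a[i + 1] else NA
        i <- i + 2
      } else i <- i + 1
    }
    opts
  }
  status <- tryCatch({
    if (length(args) == 0)
      stopf("usage: neonv1 <simulate|analyze|report|stimgen> [--config f] [--seed n] [--outdir d]")
    cmd <- args[1]
    opts <- parse_opts(args[-1])
    seed <- as.integer(opts$seed %||% 1)
    outdir <- opts$outdir %||% "neonv1_out"
    cfg <- if (!is.null(opts$config)) opts$config else list()
    switch(cmd,
      simulate = {
        if (is.character(cfg))
          cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
        cfg$seed <- seed
        cohort <- ground_truth_cohort(n_units = cfg$n_units %||% 50,
                                      seed = seed)
        trials <- condition_table(
          trials_per_condition = cfg$trials_per_condition %||% 70,
          order_seed = seed)
        bundle <- simulate_session(cohort, trials, seed = seed)
        write_recording_bundle(bundle, outdir)
      },
      analyze = {
        if (is.character(cfg))
          cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
        cfg$seed <- seed
        run_pipeline(cfg, outdir)
      },
      report = report(opts$outdir %||% "neonv1_out"),
      stimgen = {
        geo <- display_geometry()
        lay <- inducer_layout_grid()
        g <- grating_spec(direction = as.numeric(opts$direction %||% 0))
        write_frame_stack(render_ncs(geo, lay, g, duration = 0.5),
                          file.path(outdir, "ncs"))
        write_frame_stack(render_ldg(geo, lay, g, duration = 0.5),
                          file.path(outdir, "ldg"))
      },
      stopf("unknown subcommand '%s'", cmd))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("usage:|unknown|config|missing", conditionMessage(e))) 1L
    else 2L
  })
  invisible(status)
}
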