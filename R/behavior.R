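# Behavioural traces: running-disk speed from rotary-encoder voltage,
# run/still trial classification, pupil normalization and the pupil
# dilation index.

#' Disk speed from rotary-encoder voltage
#'
#' Voltage 0-5 V maps to disk angle 0-360 deg. The angle is unwrapped
#' across the 5 V -> 0 V discontinuity at the input rate, downsampled to
#' `fs_out` by bin-averaging, and differentiated; linear (rim) speed is
#' `|d angle/dt| * pi * D / 360` for disk diameter D.
#'
#' @param encoder data.frame (t_s, voltage) sampled uniformly.
#' @param disk_diameter_cm disk diameter (cm).
#' @param fs_out output sampling rate (Hz), default 300.
#' @return data.frame (t_s, speed_cmps).
#' @export
disk_speed <- function(encoder, disk_diameter_cm = 20, fs_out = 300) {
  v <- encoder$voltage
  if (any(v < 0 | v > 5)) {
    warnf("encoder voltage outside [0, 5] V clipped")
    v <- pmin(5, pmax(0, v))
  }
  theta <- v / 5 * 360
  d <- diff(theta)
  d <- (d + 180) %% 360 - 180        # unwrap: steps into (-180, 180]
  theta_u <- cumsum(c(theta[1], d))  # continuous angle
  fs_in <- 1 / median(diff(encoder$t_s))
  dec <- max(1L, round(fs_in / fs_out))
  nb <- floor(length(theta_u) / dec)
  idx <- rep(seq_len(nb), each = dec)
  th_ds <- tapply(theta_u[seq_len(nb * dec)], idx, mean)
  t_ds <- tapply(encoder$t_s[seq_len(nb * dec)], idx, mean)
  dt <- dec / fs_in
  sp <- abs(diff(th_ds)) / dt * pi * disk_diameter_cm / 360
  data.frame(t_s = as.numeric(t_ds[-1]), speed_cmps = as.numeric(sp))
}

#' Classify trials as running or still
#'
#' A trial is "run" when the mean speed over the 500 ms window starting
#' 300 ms before stimulus onset exceeds 1 cm/s (strict inequality).
#'
#' @param speed data.frame (t_s, speed_cmps) from [disk_speed()].
#' @param trials trial table with `onset_s`.
#' @param threshold_cmps speed threshold (cm/s).
#' @param window window relative to onset (s).
#' @return character vector "run"/"still" per trial row.
#' @export
classify_run_still <- function(speed, trials, threshold_cmps = 1,
                               window = c(-0.3, 0.2)) {
  vapply(trials$onset_s, function(on) {
    sel <- speed$t_s >= on + window[1] & speed$t_s < on + window[2]
    m <- if (any(sel)) mean(speed$speed_cmps[sel]) else 0
    if (m > threshold_cmps) "run" else "still"
  }, character(1))
}

#' Baseline-normalized per-trial pupil traces
#'
#' `(p(t) - b) / b` with `b` the mean pupil size over the 300 ms before
#' stimulus onset. Trials whose baseline window has no valid samples are
#' dropped (with a message).
#'
#' @param pupil data.frame (t_s, diameter).
#' @param trials trial table.
#' @param baseline_s baseline duration before onset (s).
#' @param window trace window relative to onset (s).
#' @return data.frame (trial_id, t_rel_s, norm_diameter), long format.
#' @export
normalize_pupil <- function(pupil, trials, baseline_s = 0.3,
                            window = c(-0.3, 2)) {
  out <- vector("list", nrow(trials))
  dropped <- 0L
  for (i in seq_len(nrow(trials))) {
    on <- trials$onset_s[i]
    bsel <- pupil$t_s >= on - baseline_s & pupil$t_s < on
    b <- mean(pupil$diameter[bsel], na.rm = TRUE)
    if (!any(bsel) || !is.finite(b) ||
        any(is.na(pupil$diameter[bsel]))) {
      dropped <- dropped + 1L
      next
    }
    sel <- pupil$t_s >= on + window[1] & pupil$t_s < on + window[2]
    out[[i]] <- data.frame(trial_id = trials$trial_id[i],
                           t_rel_s = pupil$t_s[sel] - on,
                           norm_diameter = (pupil$diameter[sel] - b) / b)
  }
  if (dropped > 0)
    message(sprintf("normalize_pupil: dropped %d trial(s) with missing baseline",
                    dropped))
  do.call(rbind, out) %||% data.frame(trial_id = integer(),
                                      t_rel_s = numeric(),
                                      norm_diameter = numeric())
}

#' Pupil dilation index
#'
#' `(S - B) / (S + B)` with `B` the mean raw pupil size over the 0.2 s
#' before stimulus onset and `S` the mean over the 1 s stimulus window.
#' Positive values indicate dilation (perceived darkening), negative
#' constriction.
#'
#' @param pupil data.frame (t_s, diameter), raw (unnormalized) sizes.
#' @param trials trial table.
#' @param baseline_s pre-onset baseline duration (s).
#' @param stim_s stimulus window duration (s).
#' @return data.frame (trial_id, condition, dilation_index).
#' @export
dilation_index <- function(pupil, trials, baseline_s = 0.2, stim_s = 1) {
  di <- vapply(seq_len(nrow(trials)), function(i) {
    on <- trials$onset_s[i]
    B <- mean(pupil$diameter[pupil$t_s >= on - baseline_s & pupil$t_s < on])
    S <- mean(pupil$diameter[pupil$t_s >= on & pupil$t_s < on + stim_s])
    if (!is.finite(B) || !is.finite(S) || (S + B) == 0) return(NA_real_)
    (S - B) / (S + B)
  }, numeric(1))
  data.frame(trial_id = trials$trial_id,
             condition = trials$condition,
             dilation_index = di)
}
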