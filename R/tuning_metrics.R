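# Direction/size tuning and the scalar response indices: the illusory
# grating response index (IGR) and its F1 variant, the complex-simple
# modulation (CSM) index, the surround modulation index, and the NCS
# delay index. All are contrast ratios (a - b)/(a + b) bounded in [-1, 1]
# for non-negative inputs.

contrast_ratio <- function(a, b) {
  out <- (a - b) / (a + b)
  out[(a + b) == 0] <- NA_real_
  out
}

#' Illusory grating response index (IGR)
#'
#' `(R(NCS) - R(LDG)) / (R(NCS) + R(LDG))` on trial-averaged evoked rates.
#' Positive values indicate a larger response to the illusory (NCS)
#' grating. Undefined (NA) when both rates are 0.
#'
#' @param r_ncs,r_ldg non-negative evoked rates (sp/s); vectorised.
#' @return index in \[-1, 1\] or NA.
#' @export
igr <- function(r_ncs, r_ldg) {
  if (any(r_ncs < 0 | r_ldg < 0, na.rm = TRUE))
    stopf("igr expects non-negative rates")
  contrast_ratio(r_ncs, r_ldg)
}

#' IGR on F1 amplitudes
#'
#' As [igr()] but computed on the amplitudes of the F1 (stimulus temporal
#' frequency) response component.
#'
#' @param f1_ncs,f1_ldg non-negative F1 amplitudes.
#' @return index in \[-1, 1\] or NA.
#' @export
igr_f1 <- function(f1_ncs, f1_ldg) {
  if (any(f1_ncs < 0 | f1_ldg < 0, na.rm = TRUE))
    stopf("igr_f1 expects non-negative amplitudes")
  contrast_ratio(f1_ncs, f1_ldg)
}

#' Complex-simple modulation (CSM) index
#'
#' `(F1 - F0) / (F1 + F0)` computed from the LDG response. Positive:
#' phase-locked (simple cell); negative: spatially invariant (complex
#' cell).
#'
#' @param f1 F1 amplitude (sp/s).
#' @param f0 mean rate (sp/s).
#' @return index in \[-1, 1\] or NA.
#' @export
csm <- function(f1, f0) contrast_ratio(f1, f0)

#' NCS delay index
#'
#' `(Latency(NCS) - Latency(rectangle)) / (sum)`: the NCS response latency
#' relative to the unit's generic feed-forward (rectangle) latency.
#'
#' @param lat_ncs,lat_rect latencies (ms), both > 0.
#' @return index in \[-1, 1\].
#' @export
ncs_delay_index <- function(lat_ncs, lat_rect) {
  out <- contrast_ratio(lat_ncs, lat_rect)
  out[!(lat_ncs > 0 & lat_rect > 0)] <- NA_real_
  out
}

#' Surround modulation index
#'
#' `(max(R(<30 deg)) - R(45 deg)) / max(R(<30 deg))` on a size-tuning
#' curve: negative for facilitative cells, positive for suppressive cells.
#'
#' @param sizes patch diameters (deg).
#' @param responses trial-averaged evoked rates (sp/s) per size.
#' @return scalar index, or NA if the small-size maximum is <= 0.
#' @export
surround_modulation <- function(sizes, responses) {
  small <- sizes < 30
  if (!any(small) || !any(sizes == 45))
    stopf("size curve must include sizes < 30 deg and 45 deg")
  m <- max(responses[small])
  if (m <= 0) return(NA_real_)
  (m - responses[sizes == 45][1]) / m
}

#' F0/F1 Fourier decomposition of a PSTH
#'
#' F0 is the mean rate over the stimulus window; F1 is the single-sided
#' amplitude of the discrete Fourier component at the grating temporal
#' frequency, computed from the smoothed PSTH rate. A unit is F1-dominant
#' when the F1 power exceeds the power of every other non-zero frequency.
#'
#' @param psth a [build_psth()] result covering the full stimulus window.
#' @param tf grating temporal frequency (Hz).
#' @param stim_window stimulus window (s) relative to onset.
#' @return list(f0, f1, phase_deg, f1_dominant). `phase_deg` is the
#'   response phase: the rate is maximal at `t = phase/(360 tf)`.
#' @export
f0_f1 <- function(psth, tf = 2, stim_window = c(0, 1)) {
  sel <- psth$bin_start_ms >= stim_window[1] * 1000 &
         psth$bin_start_ms < stim_window[2] * 1000
  r <- psth$rate[sel]
  dur <- sum(sel) * psth$binwidth_s
  if (dur < 1 / tf) stopf("stimulus window shorter than one cycle")
  n <- length(r)
  sp <- fft(r) / n
  freqs <- (seq_len(n) - 1) / dur
  k1 <- which.min(abs(freqs - tf))
  if (abs(freqs[k1] - tf) > 1e-9)
    warnf("tf %g Hz is not an exact DFT frequency of the window", tf)
  f0 <- Re(sp[1])
  f1 <- 2 * Mod(sp[k1])
  half <- 2:(floor(n / 2) + 1)
  pw <- Mod(sp[half])^2
  dominant <- f1 > 0 && all(pw[half != k1] < pw[half == k1][1])
  list(f0 = f0, f1 = f1,
       phase_deg = wrap_deg(-rad2deg(Arg(sp[k1]))),
       f1_dominant = dominant)
}

#' Direction tuning curve and interpolated preferred angle
#'
#' Fits a periodic cubic spline through the 8-point direction tuning curve
#' and returns the argmax on a dense grid (default 1 deg), giving a more
#' precise preferred-angle estimate than the sampled maximum.
#'
#' @param angles sampled directions (deg), typically 0, 45, ..., 315.
#' @param responses trial-averaged responses (sp/s).
#' @param grid_step evaluation grid step (deg).
#' @return list(angle, untuned, grid, fit): the preferred angle (deg), a
#'   flat-curve flag, and the dense spline evaluation.
#' @export
preferred_angle <- function(angles, responses, grid_step = 1) {
  o <- order(angles)
  angles <- angles[o]; responses <- responses[o]
  if (diff(range(responses)) == 0) {
    return(list(angle = angles[1], untuned = TRUE, grid = NULL, fit = NULL))
  }
  grid <- seq(0, 360 - grid_step, by = grid_step)
  s <- spline(c(angles, angles[1] + 360), c(responses, responses[1]),
              method = "periodic", xout = grid)
  list(angle = wrap_deg(s$x[which.max(s$y)]), untuned = FALSE,
       grid = s$x, fit = s$y)
}

#' Wrapped difference between two preferred angles
#'
#' @param angle_a,angle_b angles in degrees.
#' @return difference wrapped to \[-180, 180).
#' @export
delta_preferred <- function(angle_a, angle_b) {
  wrap_deg(angle_a - angle_b, lower = -180)
}
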