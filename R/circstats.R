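# Circular statistics for F1 response phases: NCS-vs-LDG phase shift,
# circular mean with a dispersion-based confidence interval, and the
# Rayleigh test of non-uniformity.

#' F1 phase shift between NCS and LDG responses
#'
#' The phase of the F1 (stimulus temporal frequency) component of the NCS
#' response minus that of the LDG response, wrapped to \[0, 360).
#' Positive values mean the NCS response lags the LDG response. Intended
#' for F1-dominant units.
#'
#' @param psth_ncs,psth_ldg PSTHs of the same unit under the two stimuli.
#' @param tf grating temporal frequency (Hz).
#' @param stim_window stimulus window (s).
#' @return phase shift (deg), or NA if either F1 amplitude is 0.
#' @export
f1_phase_shift <- function(psth_ncs, psth_ldg, tf = 2,
                           stim_window = c(0, 1)) {
  a <- f0_f1(psth_ncs, tf, stim_window)
  b <- f0_f1(psth_ldg, tf, stim_window)
  if (a$f1 <= 1e-9 || b$f1 <= 1e-9) return(NA_real_)
  wrap_deg(a$phase_deg - b$phase_deg)
}

#' Circular mean and confidence interval
#'
#' Mean direction `arg(sum(exp(i theta)))` with Fisher's dispersion-based
#' confidence interval: the circular dispersion is
#' `delta = (1 - rho2) / (2 Rbar^2)` with `rho2` the mean second-moment
#' cosine, the circular standard error is `sqrt(delta / n)`, and the CI
#' half-width is `asin(z * se)`.
#'
#' @param phases_deg angles in degrees.
#' @param conf confidence level.
#' @return list(mean_deg, ci_deg = c(lo, hi), rbar, n).
#' @export
circular_mean_ci <- function(phases_deg, conf = 0.95) {
  n <- length(phases_deg)
  if (n < 2) stopf("need at least 2 phases")
  th <- deg2rad(phases_deg)
  z <- sum(exp(1i * th))
  mu <- Arg(z)
  rbar <- Mod(z) / n
  rho2 <- mean(cos(2 * (th - mu)))
  delta <- (1 - rho2) / (2 * rbar^2)
  se <- sqrt(delta / n)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  half <- if (q * se >= 1) 180 else rad2deg(asin(q * se))
  mean_deg <- wrap_deg(rad2deg(mu))
  list(mean_deg = mean_deg,
       ci_deg = c(mean_deg - half, mean_deg + half),
       rbar = rbar, n = n)
}

#' Rayleigh test of circular uniformity
#'
#' `Z = n * Rbar^2` with the standard approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))`, `R = n * Rbar`.
#'
#' @param phases_deg angles in degrees.
#' @return list(z, p, rbar, n).
#' @export
rayleigh_test <- function(phases_deg) {
  n <- length(phases_deg)
  if (n < 2) stopf("need at least 2 phases")
  th <- deg2rad(phases_deg)
  r <- Mod(sum(exp(1i * th)))
  rbar <- r / n
  z <- n * rbar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - r^2)) - (1 + 2 * n))
  list(z = z, p = min(1, p), rbar = rbar, n = n)
}
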