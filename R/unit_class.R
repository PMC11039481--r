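# Waveform-based E/I classification and laminar analysis: trough-to-peak
# latency (TPL), two-Gaussian mixture threshold, LFP band-pass filtering,
# current-source density (CSD), and sink-relative depth labels.

#' Trough-to-peak latency of a spike waveform
#'
#' Time from the global trough to the subsequent maximum. Undefined when
#' the waveform's global maximum precedes its global minimum (e.g. a
#' time-reversed waveform) or the trough is the last sample.
#'
#' @param waveform numeric vector (mean waveform samples).
#' @param sample_rate sampling rate (Hz).
#' @param upsample integer spline-interpolation factor for sub-sample
#'   precision (1 = none).
#' @return TPL in ms, or NA when undefined.
#' @export
tpl <- function(waveform, sample_rate, upsample = 1) {
  w <- waveform
  n <- length(w)
  fs <- sample_rate
  if (upsample > 1) {
    s <- spline(seq_len(n), w, n = n * upsample)
    w <- s$y
    # spline grid is uniform over [1, n]; spacing in original samples:
    fs <- sample_rate / ((n - 1) / (length(w) - 1))
    n <- length(w)
  }
  i_min <- which.min(w)
  i_max <- which.max(w)
  if (i_max <= i_min || i_min == n) return(NA_real_)
  post_peak <- i_min - 1L + which.max(w[i_min:n])
  (post_peak - i_min) / fs * 1000
}

#' E/I classification threshold from the TPL distribution
#'
#' Fits a two-component Gaussian mixture to the TPL values by EM; the
#' classification threshold is the intersection of the two component
#' densities between the component means. TPL below threshold -> putative
#' inhibitory (narrow-spiking, "I"); above -> excitatory ("E").
#'
#' @param tpl_values TPL values (ms), typically >= 50 units.
#' @param max_iter,tol EM controls.
#' @return list(threshold_ms, labels, means, sds, weights, separated).
#'   `separated` is FALSE (with a warning) when the means are closer than
#'   the pooled SD.
#' @export
ei_threshold <- function(tpl_values, max_iter = 500, tol = 1e-8) {
  x <- tpl_values[is.finite(tpl_values)]
  n <- length(x)
  if (n < 50) stopf("need at least 50 TPL values")
  # init: split at the median
  m <- c(mean(x[x <= median(x)]), mean(x[x > median(x)]))
  s <- rep(sd(x) / 2, 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, m[1], s[1])
    d2 <- w[2] * dnorm(x, m[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    w <- c(mean(g), 1 - mean(g))
    m <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    s <- c(sqrt(sum(g * (x - m[1])^2) / sum(g)),
           sqrt(sum((1 - g) * (x - m[2])^2) / sum(1 - g)))
    s <- pmax(s, 1e-4)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (m[1] > m[2]) { m <- rev(m); s <- rev(s); w <- rev(w) }
  thr <- density_intersection(m, s, w)
  pooled <- sqrt(mean(s^2))
  separated <- (m[2] - m[1]) >= pooled
  if (!separated)
    warnf("TPL mixture components poorly separated (means %.3f / %.3f ms)",
          m[1], m[2])
  labels <- ifelse(tpl_values < thr, "I", "E")
  labels[!is.finite(tpl_values)] <- NA_character_
  list(threshold_ms = thr, labels = labels, means = m, sds = s,
       weights = w, separated = separated)
}

# intersection of two weighted normal densities between the means
density_intersection <- function(m, s, w) {
  f <- function(x) w[1] * dnorm(x, m[1], s[1]) - w[2] * dnorm(x, m[2], s[2])
  lo <- m[1]; hi <- m[2]
  if (f(lo) * f(hi) > 0) return(mean(m))  # fallback: midpoint
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# ---- Butterworth band-pass (zero-phase) -------------------------------
# Order-n analog Butterworth low-pass prototype -> band transform ->
# bilinear transform. Implemented here because no DSP package is
# available in the target environment; verified against scipy.signal.

butter_bandpass <- function(order, low_hz, high_hz, fs) {
  # prewarped analog band edges
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP poles
  # low-pass -> band-pass: each pole splits into two
  pb <- p_lp * bw / 2
  p_bp <- c(pb + sqrt(pb^2 - w0^2), pb - sqrt(pb^2 - w0^2))
  z_bp <- rep(0 + 0i, order)
  k_bp <- bw^order
  # bilinear transform
  fs2 <- 2 * fs
  zd <- (fs2 + z_bp) / (fs2 - z_bp)
  pd <- (fs2 + p_bp) / (fs2 - p_bp)
  kd <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# direct-form II transposed IIR filter
iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  z <- numeric(n - 1)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    if (n > 2) {
      z[1:(n - 2)] <- b[2:(n - 1)] * x[i] + z[2:(n - 1)] - a[2:(n - 1)] * y[i]
    }
    z[n - 1] <- b[n] * x[i] - a[n] * y[i]
  }
  y
}

# zero-phase (forward-backward) filtering with odd-symmetric edge padding
filtfilt_fb <- function(b, a, x) {
  npad <- min(3 * (max(length(a), length(b)) - 1) * 10, length(x) - 1)
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)]
  xe <- c(pre, x, post)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(npad + 1):(npad + length(x))]
}

#' Band-pass filter an LFP array
#'
#' Order-4 Butterworth band-pass (default 0.1-150 Hz) applied forward and
#' backward (zero phase) to each channel.
#'
#' @param lfp matrix channels x time, or a numeric vector.
#' @param fs sampling rate (Hz).
#' @param low_hz,high_hz band edges (Hz).
#' @param order filter order.
#' @return filtered array of the same shape.
#' @export
lfp_bandpass <- function(lfp, fs, low_hz = 0.1, high_hz = 150, order = 4) {
  ba <- butter_bandpass(order, low_hz, high_hz, fs)
  if (is.matrix(lfp)) {
    out <- t(apply(lfp, 1, function(ch) filtfilt_fb(ba$b, ba$a, ch)))
    attributes(out) <- attributes(lfp)[c("dim", "fs", "onset_s")]
    out
  } else {
    filtfilt_fb(ba$b, ba$a, lfp)
  }
}

#' Current-source density (CSD)
#'
#' Negative discrete second spatial derivative of the LFP across the
#' electrode sites: `-(V[c-1] - 2 V[c] + V[c+1]) / spacing^2`. Edge
#' channels are padded by linear extrapolation, so any spatially linear
#' voltage profile has identically zero CSD (duplication padding would
#' leave spurious edge sources).
#'
#' @param lfp matrix channels x time (ordered by depth).
#' @param spacing_um inter-site spacing (micrometres).
#' @return CSD matrix channels x time (V / um^2 scale).
#' @export
csd <- function(lfp, spacing_um = 25) {
  if (!is.matrix(lfp) || nrow(lfp) < 3) stopf("need at least 3 channels")
  n <- nrow(lfp)
  vp <- rbind(2 * lfp[1, ] - lfp[2, ], lfp, 2 * lfp[n, ] - lfp[n - 1, ])
  out <- -(vp[1:n, , drop = FALSE] - 2 * vp[2:(n + 1), , drop = FALSE] +
           vp[3:(n + 2), , drop = FALSE]) / spacing_um^2
  attr(out, "fs") <- attr(lfp, "fs")
  attr(out, "onset_s") <- attr(lfp, "onset_s")
  out
}

# linear spatial interpolation of a CSD map for display
interpolate_csd <- function(csd_mat, factor = 4) {
  n <- nrow(csd_mat)
  zi <- seq(1, n, length.out = (n - 1) * factor + 1)
  out <- matrix(0, length(zi), ncol(csd_mat))
  for (j in seq_len(ncol(csd_mat)))
    out[, j] <- approx(seq_len(n), csd_mat[, j], zi)$y
  out
}

#' Locate the stimulus-locked CSD sink
#'
#' Each channel is smoothed in time (boxcar), and the sink channel is the
#' one with the largest post-onset CSD magnitude; the sink time is that
#' channel's magnitude peak.
#'
#' @param csd_mat CSD matrix channels x time.
#' @param fs sampling rate (Hz); taken from attributes if absent.
#' @param onset_s stimulus onset (s).
#' @param smooth_samples boxcar width for temporal smoothing (samples).
#' @return list(channel, t_s) or channel NA when no sink exists.
#' @export
find_csd_sink <- function(csd_mat, fs = NULL, onset_s = NULL,
                          smooth_samples = 11) {
  fs <- fs %||% attr(csd_mat, "fs")
  onset_s <- onset_s %||% attr(csd_mat, "onset_s") %||% 0
  if (smooth_samples > 1) {
    k <- rep(1 / smooth_samples, smooth_samples)
    csd_mat <- t(apply(csd_mat, 1, function(r) {
      y <- stats::filter(r, k, sides = 2)
      y[is.na(y)] <- 0
      as.numeric(y)
    }))
  }
  i0 <- max(1L, floor(onset_s * (fs %||% 1)) + 1L)
  m <- abs(csd_mat[, i0:ncol(csd_mat), drop = FALSE])
  if (max(m) == 0) return(list(channel = NA_integer_, t_s = NA_real_))
  per_ch <- apply(m, 1, max)
  ch <- which.max(per_ch)
  t_i <- which.max(m[ch, ])
  list(channel = as.integer(ch),
       t_s = if (!is.null(fs)) onset_s + (t_i - 1) / fs else NA_real_)
}

#' Sink-relative laminar depth label
#'
#' Channels within `band` of the earliest sink are "granular"; shallower
#' channels "supragranular"; deeper ones "infragranular". Only relative
#' labels are assigned (no anatomical layer boundaries).
#'
#' @param csd_mat CSD matrix channels x time.
#' @param unit_channel channel of the unit.
#' @param band half-width of the granular band (channels).
#' @param ... passed to [find_csd_sink()].
#' @return character label, or NA when no sink is found.
#' @export
assign_relative_depth <- function(csd_mat, unit_channel, band = 2, ...) {
  sink <- find_csd_sink(csd_mat, ...)
  if (is.na(sink$channel)) return(NA_character_)
  d <- unit_channel - sink$channel
  if (abs(d) <= band) "granular"
  else if (d < 0) "supragranular"
  else "infragranular"
}
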