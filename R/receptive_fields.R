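# Receptive-field estimation from rectangle-mapping responses: response
# maps, masked 2-D Gaussian fits with an FWHM ellipse, RF-inducer overlap
# and distance, and retinotopic reversal-point detection along a probe.

#' Rectangle-mapping response map
#'
#' Mean evoked rate per grid cell, baseline-subtracted. The response
#' window follows each rectangle onset; the baseline is taken from the
#' pre-onset window across all presentations.
#'
#' @param rf_spikes data.frame (unit_id, t_s) of RF-session spikes.
#' @param presentations presentation table (row, col, onset_s).
#' @param unit_id unit to map.
#' @param grid_shape c(rows, cols).
#' @param window_ms response window after onset (ms).
#' @param baseline_ms pre-onset baseline window (ms, negative start).
#' @return matrix rows x cols of baseline-subtracted rates (sp/s).
#' @export
rf_response_map <- function(rf_spikes, presentations, unit_id,
                            grid_shape = c(8, 13), window_ms = c(0, 100),
                            baseline_ms = c(-50, 0)) {
  cells <- table(factor(presentations$row, levels = seq_len(grid_shape[1])),
                 factor(presentations$col, levels = seq_len(grid_shape[2])))
  if (any(cells == 0)) stopf("grid cell(s) with zero presentations")
  sp <- rf_spikes$t_s[rf_spikes$unit_id == unit_id]
  sp <- sort(sp)
  resp <- matrix(0, grid_shape[1], grid_shape[2])
  base_count <- 0
  w <- window_ms / 1000; b <- baseline_ms / 1000
  for (i in seq_len(nrow(presentations))) {
    rel <- sp - presentations$onset_s[i]
    resp[presentations$row[i], presentations$col[i]] <-
      resp[presentations$row[i], presentations$col[i]] +
      sum(rel >= w[1] & rel < w[2])
    base_count <- base_count + sum(rel >= b[1] & rel < b[2])
  }
  n_per_cell <- as.matrix(cells)
  rate <- resp / (n_per_cell * diff(w))
  base_rate <- base_count / (nrow(presentations) * diff(b))
  unname(rate - base_rate)
}

# nearest-neighbour upsample of a matrix by an integer factor
nn_upsample <- function(m, f) {
  m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f),
    drop = FALSE]
}

# 4-connected flood fill from the location of the maximum of `values`
# restricted to TRUE cells of `mask`
connected_to_max <- function(mask, values) {
  values[!mask] <- -Inf
  start <- which(values == max(values), arr.ind = TRUE)[1, ]
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  stack <- list(start)
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    r <- p[1]; c <- p[2]
    if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask)) next
    if (out[r, c] || !mask[r, c]) next
    out[r, c] <- TRUE
    stack <- c(stack, list(c(r - 1, c), c(r + 1, c), c(r, c - 1),
                           c(r, c + 1)))
  }
  out
}

#' Fit a 2-D Gaussian receptive field
#'
#' The map is nearest-neighbour upsampled, pixels below
#' `median + mask_nsd * SD(off-peak)` are masked (off-peak = the lower
#' half of the map values), and a rotated 2-D Gaussian is least-squares
#' fitted to the unmasked pixels. Initialisation uses the masked map's
#' centroid and second moments.
#'
#' @param map response map (matrix), e.g. from [rf_response_map()].
#' @param x,y coordinates of the map columns / rows (deg); defaults are
#'   cell indices.
#' @param upsample_factor integer nearest-neighbour upsampling factor.
#' @param mask_nsd masking threshold in off-peak SDs above the median.
#' @return an object of class `receptive_field`: center (x, y), sigma
#'   (sx, sy), rotation (deg), amplitude, fwhm (semi-axes a, b, rotation),
#'   fit_residual, no_rf (flag). When no pixel survives masking, `no_rf`
#'   is TRUE and the other fields are NA.
#' @export
fit_rf <- function(map, x = seq_len(ncol(map)), y = seq_len(nrow(map)),
                   upsample_factor = 4, mask_nsd = 3) {
  f <- max(1L, as.integer(upsample_factor))
  up <- nn_upsample(map, f)
  xu <- seq(x[1], x[length(x)], length.out = ncol(up))
  yu <- seq(y[1], y[length(y)], length.out = nrow(up))
  v <- as.vector(up)
  off <- v[v <= median(v)]
  s_off <- sd(off)
  if (!is.finite(s_off) || s_off == 0) s_off <- sd(v)
  thr <- median(v) + mask_nsd * s_off
  keep <- is.finite(v) & v > thr & !is.na(thr)
  no_rf <- structure(list(center = c(NA_real_, NA_real_),
                          sigma = c(NA_real_, NA_real_),
                          rotation = NA_real_, amplitude = NA_real_,
                          fwhm = c(a = NA_real_, b = NA_real_,
                                   rotation = NA_real_),
                          fit_residual = NA_real_, no_rf = TRUE),
                     class = "receptive_field")
  if (!any(keep) || s_off == 0 || !is.finite(thr)) return(no_rf)
  # keep only the unmasked component connected to the map maximum:
  # isolated supra-threshold noise pixels otherwise drag the fit
  keep_m <- matrix(keep, nrow(up), ncol(up))
  keep_m <- connected_to_max(keep_m, up)
  keep <- as.vector(keep_m)
  if (!any(keep)) return(no_rf)
  X <- matrix(xu, nrow(up), ncol(up), byrow = TRUE)[keep]
  Y <- matrix(yu, nrow(up), ncol(up))[keep]
  V <- v[keep]
  wsum <- sum(V)
  if (wsum <= 0) return(no_rf)
  cx <- sum(X * V) / wsum; cy <- sum(Y * V) / wsum
  sx0 <- sqrt(max(sum((X - cx)^2 * V) / wsum, 1e-4))
  sy0 <- sqrt(max(sum((Y - cy)^2 * V) / wsum, 1e-4))
  p0 <- c(log(max(V)), cx, cy, log(sx0), log(sy0), 0)
  obj <- function(p) {
    a <- exp(p[1]); sx <- exp(p[4]); sy <- exp(p[5]); th <- p[6]
    dx <- X - p[2]; dy <- Y - p[3]
    u <- dx * cos(th) + dy * sin(th)
    w <- -dx * sin(th) + dy * cos(th)
    sum((V - a * exp(-(u^2 / (2 * sx^2) + w^2 / (2 * sy^2))))^2)
  }
  fit <- optim(p0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  a <- exp(fit$par[1]); sx <- exp(fit$par[4]); sy <- exp(fit$par[5])
  # degenerate fits (sigma beyond the map, centre far outside) carry no
  # usable RF and would break downstream geometry
  span_x <- diff(range(x)); span_y <- diff(range(y))
  if (!all(is.finite(fit$par)) || sx > span_x || sy > span_y ||
      fit$par[2] < min(x) - span_x / 2 || fit$par[2] > max(x) + span_x / 2 ||
      fit$par[3] < min(y) - span_y / 2 || fit$par[3] > max(y) + span_y / 2)
    return(no_rf)
  rot <- wrap_deg(rad2deg(fit$par[6]), lower = -90)
  k <- sqrt(2 * log(2))
  structure(list(center = c(x = fit$par[2], y = fit$par[3]),
                 sigma = c(sx = sx, sy = sy),
                 rotation = rot, amplitude = a,
                 fwhm = c(a = k * sx, b = k * sy, rotation = rot),
                 fit_residual = fit$value, no_rf = FALSE),
            class = "receptive_field")
}

#' @export
print.receptive_field <- function(x, ...) {
  if (x$no_rf) cat("<receptive_field: no RF>\n")
  else cat(sprintf(
    "<receptive_field: center (%.2f, %.2f), sigma (%.2f, %.2f), rot %.1f>\n",
    x$center[1], x$center[2], x$sigma[1], x$sigma[2], x$rotation))
  invisible(x)
}

#' RF-inducer overlap ratio
#'
#' Fraction of the RF's FWHM ellipse covered by the inducer disk (the
#' closed disk bounded by the outermost circle of the nearest patch),
#' computed by pixel rasterisation.
#'
#' @param rf a fitted [fit_rf()] object with centre in degrees.
#' @param layout an inducer layout.
#' @param resolution rasterisation density (px/deg, >= 20).
#' @return overlap fraction in \[0, 1\].
#' @export
overlap_ratio <- function(rf, layout, resolution = 20) {
  if (isTRUE(rf$no_rf)) stopf("no valid RF fit")
  d2 <- (layout$centers[, 1] - rf$center[1])^2 +
        (layout$centers[, 2] - rf$center[2])^2
  pc <- layout$centers[which.min(d2), ]
  rad <- max(layout$diameters) / 2
  a <- rf$fwhm[["a"]]; b <- rf$fwhm[["b"]]
  th <- deg2rad(rf$rotation)
  half <- max(a, b)
  xs <- seq(rf$center[1] - half, rf$center[1] + half, by = 1 / resolution)
  ys <- seq(rf$center[2] - half, rf$center[2] + half, by = 1 / resolution)
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  dx <- X - rf$center[1]; dy <- Y - rf$center[2]
  u <- dx * cos(th) + dy * sin(th)
  w <- -dx * sin(th) + dy * cos(th)
  in_ell <- (u / a)^2 + (w / b)^2 <= 1
  in_disk <- (X - pc[1])^2 + (Y - pc[2])^2 <= rad^2
  n_ell <- sum(in_ell)
  if (n_ell == 0) return(0)
  sum(in_ell & in_disk) / n_ell
}

#' Distance from an RF centre to the nearest inducer patch centre
#'
#' @param rf a fitted [fit_rf()] object (centre in degrees).
#' @param layout an inducer layout.
#' @return Euclidean distance (deg); ties broken by patch index order.
#' @export
rf_inducer_distance <- function(rf, layout) {
  if (isTRUE(rf$no_rf)) return(NA_real_)
  d <- sqrt((layout$centers[, 1] - rf$center[1])^2 +
            (layout$centers[, 2] - rf$center[2])^2)
  d[which.min(d)]
}

#' Detect retinotopic reversal points along a probe
#'
#' Finds the channels where the along-probe progression of RF azimuth
#' reverses direction (after running-mean smoothing); these reversal
#' points delimit visual areas on oblique penetrations.
#'
#' @param centers_x ordered RF azimuths (deg), one per channel.
#' @param smooth_window running-mean window (channels, odd).
#' @return integer indices (1-based) of the turning-point channels; empty
#'   for a monotone progression.
#' @export
detect_retinotopic_reversals <- function(centers_x, smooth_window = 3) {
  n <- length(centers_x)
  if (n < 3) stopf("need at least 3 channels with RF centres")
  x <- centers_x
  if (smooth_window > 1) {
    h <- floor(smooth_window / 2)
    xp <- c(rep(x[1], h), x, rep(x[n], h))
    x <- vapply(seq_len(n), function(i) mean(xp[i:(i + 2 * h)]), 0)
  }
  d <- diff(x)
  s <- sign(d)
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  # carry the last non-zero sign through flat stretches
  s_f <- s
  last <- 0
  for (i in seq_along(s_f)) {
    if (s_f[i] == 0) s_f[i] <- last else last <- s_f[i]
  }
  idx <- which(s_f[-1] != s_f[-length(s_f)] & s_f[-1] != 0 &
               s_f[-length(s_f)] != 0)
  as.integer(idx + 1L)
}
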