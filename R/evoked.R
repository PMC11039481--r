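# PSTH construction and the Poisson-deviation evoked/latency detector:
# spontaneous activity in the 300 ms pre-onset window is modelled as
# Poisson; the response latency is the first run of three consecutive
# 1 ms bins whose across-trial summed counts exceed the one-sided Poisson
# upper tail at p < .01, .01, .05.

# smallest k >= 1 with P(X >= k) < p under Poisson(mu), strict inequality
poisson_threshold <- function(mu, p) {
  if (mu <= 0) return(1L)
  k <- qpois(1 - p, mu)
  while (1 - ppois(k - 1, mu) >= p) k <- k + 1L
  while (k > 1 && 1 - ppois(k - 2, mu) < p) k <- k - 1L
  as.integer(k)
}

# count-conserving ~2 ms moving average (1-2-1 kernel, repeated edges)
smooth_psth_counts <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  xp <- c(x[1], x, x[n])
  (xp[1:n] + 2 * xp[2:(n + 1)] + xp[3:(n + 2)]) / 4
}

#' Build a peristimulus time histogram
#'
#' Counts are summed across the selected trials on 1 ms bins aligned to
#' stimulus onset; the baseline (spontaneous) rate is estimated from the
#' 300 ms pre-onset window. The smoothed rate uses a 2 ms moving average;
#' evoked/latency detection operates on the unsmoothed counts.
#'
#' @param spikes data.frame with columns `t_s` (and optionally `unit_id`).
#' @param trials trial table with `onset_s`; rows are pre-filtered by
#'   `condition` / `direction` / `light` if those columns exist.
#' @param condition,direction,light optional trial filters.
#' @param unit_id optional spike filter.
#' @param window analysis window relative to onset (s).
#' @param binwidth_s bin width (s), default 1 ms.
#' @param baseline_window baseline window (s), default \[-0.3, 0).
#' @return an object of class `psth`: bin_start_ms, counts, rate (smoothed
#'   sp/s), n_trials, baseline_rate (sp/s).
#' @export
build_psth <- function(spikes, trials, condition = NULL, direction = NULL,
                       light = NULL, unit_id = NULL,
                       window = c(-0.3, 1.0), binwidth_s = 0.001,
                       baseline_window = c(-0.3, 0)) {
  if (!is.null(condition)) trials <- trials[trials$condition %in% condition, ]
  if (!is.null(direction)) trials <- trials[trials$direction %in% direction, ]
  if (!is.null(light) && "light" %in% names(trials))
    trials <- trials[trials$light == light, ]
  if (nrow(trials) == 0) stopf("no trials selected")
  if (!is.null(unit_id)) spikes <- spikes[spikes$unit_id %in% unit_id, ]
  edges <- seq(window[1], window[2], by = binwidth_s)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  if (nrow(spikes) > 0) {
    ts <- sort(spikes$t_s)
    for (i in seq_len(nrow(trials))) {
      rel <- ts - trials$onset_s[i]
      rel <- rel[rel >= window[1] & rel < window[2]]
      if (length(rel))
        counts <- counts + tabulate(
          pmin(nb, 1L + floor((rel - window[1]) / binwidth_s)), nb)
    }
  }
  bin_start_ms <- edges[-length(edges)] * 1000
  bl <- bin_start_ms >= baseline_window[1] * 1000 &
        bin_start_ms < baseline_window[2] * 1000
  baseline_rate <- if (any(bl))
    sum(counts[bl]) / (nrow(trials) * sum(bl) * binwidth_s) else 0
  structure(list(bin_start_ms = bin_start_ms,
                 counts = counts,
                 rate = smooth_psth_counts(counts) /
                   (nrow(trials) * binwidth_s),
                 n_trials = nrow(trials),
                 binwidth_s = binwidth_s,
                 baseline_rate = baseline_rate),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth: %d bins of %g ms, %d trials, baseline %.2f sp/s>\n",
              length(x$counts), x$binwidth_s * 1000, x$n_trials,
              x$baseline_rate))
  invisible(x)
}

#' Detect a visually evoked response and its latency
#'
#' Scans the post-onset bins of an (unsmoothed) PSTH for the first run of
#' three consecutive bins whose summed-across-trial counts exceed the
#' one-sided upper tail of Poisson(lambda_hat * n_trials * binwidth) at
#' p < .01, .01, .05; the latency is the start time of the first bin of
#' the run. Deviations are one-sided (excitatory).
#'
#' @param psth a [build_psth()] result.
#' @param scan_ms post-onset scan window (ms).
#' @param p_first,p_third tail probabilities for bins 1-2 and bin 3.
#' @return list(evoked = logical, latency_ms = numeric or NA,
#'   baseline_rate, thresholds).
#' @export
detect_evoked_and_latency <- function(psth, scan_ms = c(0, 500),
                                      p_first = 0.01, p_third = 0.05) {
  mu <- psth$baseline_rate * psth$n_trials * psth$binwidth_s
  sel <- which(psth$bin_start_ms >= scan_ms[1] &
               psth$bin_start_ms < scan_ms[2])
  res <- list(evoked = FALSE, latency_ms = NA_real_,
              baseline_rate = psth$baseline_rate,
              thresholds = c(NA_integer_, NA_integer_))
  if (length(sel) < 3) return(res)
  if (mu <= 0 && sum(psth$counts[sel]) == 0) return(res)
  k1 <- poisson_threshold(mu, p_first)
  k3 <- poisson_threshold(mu, p_third)
  res$thresholds <- c(first = k1, third = k3)
  cc <- psth$counts[sel]
  n <- length(cc)
  hit <- which(cc[seq_len(n - 2)] >= k1 & cc[2:(n - 1)] >= k1 &
               cc[3:n] >= k3)
  if (length(hit)) {
    res$evoked <- TRUE
    res$latency_ms <- psth$bin_start_ms[sel[hit[1]]]
  }
  res
}

#' Rectangle-response latency
#'
#' Applies the same Poisson deviation detector to a PSTH aligned to the
#' onsets of RF-mapping rectangles presented at the RF-containing grid
#' cells ("rectangle latency", a generic feed-forward latency measure).
#'
#' @param rf_spikes data.frame (unit_id, presentation, t_s).
#' @param presentations presentation table.
#' @param cells data.frame(row, col) of grid cells inside the unit's RF.
#' @param unit_id unit to analyse.
#' @param window PSTH window (s) relative to rectangle onset.
#' @param scan_ms detector scan window (ms).
#' @return latency in ms, or `NA` if not evoked.
#' @export
rectangle_latency <- function(rf_spikes, presentations, cells, unit_id,
                              window = c(-0.1, 0.2), scan_ms = c(0, 200)) {
  sel <- interaction(presentations$row, presentations$col) %in%
    interaction(cells$row, cells$col)
  pres <- presentations[sel, ]
  if (nrow(pres) == 0) return(NA_real_)
  sp <- rf_spikes[rf_spikes$unit_id == unit_id, ]
  fake_trials <- data.frame(onset_s = pres$onset_s)
  psth <- build_psth(sp, fake_trials, window = window,
                     baseline_window = c(window[1], 0))
  det <- detect_evoked_and_latency(psth, scan_ms = scan_ms)
  if (det$evoked) det$latency_ms else NA_real_
}

#' Select equi-responsive complex cells
#'
#' Units whose NCS and LDG evoked rates are matched:
#' `|R(NCS) - R(LDG)| / (R(NCS) + R(LDG)) <= tolerance` (i.e. |IGR| below
#' tolerance), restricted to complex cells (CSM < 0) when a `csm` column
#' is present.
#'
#' @param metrics data.frame with columns `rate_ncs`, `rate_ldg` and
#'   optionally `csm`.
#' @param tolerance |IGR| tolerance (default 0.1).
#' @return the selected rows of `metrics`.
#' @export
select_equiresponsive <- function(metrics, tolerance = 0.1) {
  denom <- metrics$rate_ncs + metrics$rate_ldg
  keep <- denom > 0 &
    abs(metrics$rate_ncs - metrics$rate_ldg) / denom <= tolerance
  if ("csm" %in% names(metrics)) keep <- keep & !is.na(metrics$csm) &
      metrics$csm < 0
  metrics[which(keep), ]
}
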