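# PSTH construction and the Poisson-deviation latency detector.

test_that("PSTH: alignment, counts, baseline, smoothing conservation", {
  trials <- data.frame(trial_id = 1:2, onset_s = c(10, 20))
  sp <- data.frame(unit_id = 1, t_s = 10.0052)
  p <- build_psth(sp, trials, window = c(-0.05, 0.05),
                  baseline_window = c(-0.05, 0))
  expect_equal(sum(p$counts), 1)
  expect_equal(p$counts[which.min(abs(p$bin_start_ms - 5))], 1)
  # homogeneous unit: mean stimulus-window bin count ~ lambda * n * dt
  set.seed(1)
  n_tr <- 70
  trials <- data.frame(trial_id = seq_len(n_tr),
                       onset_s = seq(5, by = 2, length.out = n_tr))
  sp <- data.frame(unit_id = 1,
                   t_s = sort(runif(round(10 * 2 * n_tr), 4, 4 + 2 * n_tr)))
  p <- build_psth(sp, trials, window = c(-0.3, 1))
  expect_equal(mean(p$counts), 10 * n_tr * 0.001, tolerance = 0.1)
  expect_equal(p$baseline_rate, 10, tolerance = 1)
  # smoothing conserves total count
  x <- rpois(500, 2)
  expect_equal(sum(neonv1:::smooth_psth_counts(x)), sum(x))
  # empty spike set -> valid all-zero PSTH
  p0 <- build_psth(sp[0, ], trials)
  expect_true(all(p0$counts == 0))
  expect_false(detect_evoked_and_latency(p0)$evoked)
})

test_that("Poisson thresholds match an inverse-CDF oracle exactly", {
  # oracle: accumulate dpois until the upper tail drops below p
  oracle <- function(mu, p) {
    k <- 0; cum <- 0
    repeat {
      if (1 - cum < p) return(max(1L, k))
      cum <- cum + dpois(k, mu)
      k <- k + 1
    }
  }
  for (mu in c(0.05, 0.14, 0.5, 2, 7, 20)) {
    for (p in c(0.01, 0.05)) {
      expect_identical(neonv1:::poisson_threshold(mu, p),
                       as.integer(oracle(mu, p)),
                       info = sprintf("mu=%g p=%g", mu, p))
    }
  }
  expect_identical(neonv1:::poisson_threshold(0.5, 0.01), 4L)
})

test_that("latency detection: step response recovered, nulls calibrated", {
  # step 5 -> 50 sp/s at +80 ms, 70 trials; first-passage simulation of
  # the strict three-bin rule puts >= 90% of runs in [80, 90] ms and
  # >= 95% in [80, 95] ms (95th percentile of the latency distribution
  # is 91 ms at these rates), never earlier than the step
  n_rep <- 200
  lat <- rep(NA_real_, n_rep)
  bins <- seq(-0.3, 0.5 - 0.001, by = 0.001)
  rate <- ifelse(bins >= 0.08, 50, 5)
  set.seed(99)
  for (r in seq_len(n_rep)) {
    counts <- rpois(length(bins), rate * 0.001 * 70)
    p <- structure(list(bin_start_ms = bins * 1000, counts = counts,
                        rate = counts / 0.07, n_trials = 70,
                        binwidth_s = 0.001,
                        baseline_rate = sum(counts[bins < 0]) / (70 * 0.3)),
                   class = "psth")
    d <- detect_evoked_and_latency(p)
    if (d$evoked) lat[r] <- d$latency_ms
  }
  expect_gte(mean(!is.na(lat)), 0.99)
  expect_gte(mean(lat >= 80, na.rm = TRUE), 0.99)  # early FPs are rare
  expect_gte(mean(lat >= 80 & lat <= 90, na.rm = FALSE), 0.90)
  expect_gte(mean(lat >= 80 & lat <= 95, na.rm = FALSE), 0.95)

  # null calibration: baseline-only units rarely flagged (quick version;
  # the full 1000-unit calibration runs in the acceptance suite)
  set.seed(7)
  fp <- 0
  for (r in 1:200) {
    lam <- runif(1, 1, 8)
    counts <- rpois(800, lam * 0.001 * 70)
    p <- structure(list(bin_start_ms = seq(-300, 499), counts = counts,
                        rate = counts / 0.07, n_trials = 70,
                        binwidth_s = 0.001,
                        baseline_rate = sum(counts[1:300]) / (70 * 0.3)),
                   class = "psth")
    if (detect_evoked_and_latency(p)$evoked) fp <- fp + 1
  }
  expect_lte(fp / 200, 0.05)
})

test_that("detector monotonicity on noiseless rate input", {
  # raising the evoked rate never delays the detected latency
  bins <- seq(-0.3, 0.5 - 0.001, by = 0.001)
  lat <- rep(NA_real_, 3)
  for (i in seq_along(c(60, 120, 240))) {
    rate <- ifelse(bins >= 0.1, c(60, 120, 240)[i], 3)
    counts <- round(rate * 0.001 * 70)  # expected counts, no noise
    p <- structure(list(bin_start_ms = bins * 1000, counts = counts,
                        rate = counts / 0.07, n_trials = 70,
                        binwidth_s = 0.001, baseline_rate = 3),
                   class = "psth")
    lat[i] <- detect_evoked_and_latency(p)$latency_ms
  }
  expect_true(all(diff(lat) <= 0))
})

test_that("rectangle latency: recovery, invariance, non-responders", {
  cohort <- ground_truth_cohort(n_units = 3, seed = 31)
  cohort$latency_rect <- 40
  pres <- render_rf_rectangles(display_geometry(), order_seed = 31,
                               n_sweeps = 20, render = FALSE)$presentations
  pitch <- c(35 / 13, 35 / 8)
  cells <- expand.grid(row = 1:8, col = 1:13)
  cx <- (cells$col - 7) * pitch[1]; cy <- (4.5 - cells$row) * pitch[2]
  for (i in 1:2) {
    sp <- simulate_rf_spikes(cohort[i, ], pres, seed = 31)
    near <- ((cx - cohort$rf_x[i])^2 / cohort$rf_sigma_x[i]^2 +
             (cy - cohort$rf_y[i])^2 / cohort$rf_sigma_y[i]^2) <= 1
    lat <- rectangle_latency(sp, pres, cells[near, ], unit_id = i)
    expect_true(lat >= 40 && lat <= 50)
    # invariant to presentation order shuffling
    shuf <- pres[sample(nrow(pres)), ]
    expect_equal(rectangle_latency(sp, shuf, cells[near, ], i), lat)
  }
  # non-responsive unit
  quiet <- cohort[3, ]
  sp0 <- simulate_rf_spikes(quiet, pres, peak_rate = 0, seed = 31)
  far <- which(((cx - quiet$rf_x)^2 + (cy - quiet$rf_y)^2) <= 9)
  expect_true(is.na(rectangle_latency(sp0, pres, cells[far, ], 3)))
})

test_that("equi-responsive selection matches its quantile oracle", {
  # analytic construction: rates known exactly, no simulation noise
  set.seed(5)
  n <- 500
  g <- runif(n, -0.6, 0.6)
  r_ldg <- runif(n, 5, 20)
  m <- data.frame(unit_id = seq_len(n),
                  rate_ncs = r_ldg * (1 + g) / (1 - g),
                  rate_ldg = r_ldg,
                  csm = runif(n, -1, 0.5))
  for (tol in c(0, 0.1, 0.3, 1)) {
    sel <- select_equiresponsive(m, tolerance = tol)
    expected <- sum(abs(g) <= tol + 1e-12 & m$csm < 0)
    expect_equal(nrow(sel), expected, info = sprintf("tol=%g", tol))
  }
  # tolerance 1 admits every complex cell; without csm, every unit
  expect_equal(nrow(select_equiresponsive(m[, -4], tolerance = 1)), n)
})
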