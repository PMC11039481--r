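# Receptive-field estimation, overlap geometry, retinotopic reversals.

gauss_map <- function(rows, cols, x, y, cx, cy, sx, sy, amp = 10) {
  outer(y, x, function(Y, X)
    amp * exp(-((X - cx)^2 / (2 * sx^2) + (Y - cy)^2 / (2 * sy^2))))
}

test_that("rf_response_map: peak location, null maps, integral oracle", {
  cohort <- ground_truth_cohort(n_units = 2, seed = 19)
  cohort$rf_x[1] <- 2.7; cohort$rf_y[1] <- 4.4  # near cell (3, 8)
  pres <- render_rf_rectangles(display_geometry(), order_seed = 19,
                               n_sweeps = 20, render = FALSE)$presentations
  sp <- simulate_rf_spikes(cohort[1, ], pres, seed = 19)
  map <- rf_response_map(sp, pres, 1)
  pk <- which(map == max(map), arr.ind = TRUE)[1, ]
  # expected cell: col = 2.7/(35/13) + 7 = 8, row = 4.5 - 4.4/(35/8) = 3.5
  expect_lte(abs(pk[1] - 3.5), 1.5)
  expect_lte(abs(pk[2] - 8), 1.5)
  # unresponsive unit -> map ~ 0
  sp0 <- simulate_rf_spikes(cohort[2, ], pres, peak_rate = 0, seed = 19)
  map0 <- rf_response_map(sp0, pres, 2)
  expect_lt(max(abs(map0)), 6)
  expect_lt(abs(mean(map0)), 1)
  # integral oracle: sum(map) * cell_area ~ amp * 2 pi sx sy
  cell_area <- (35 / 13) * (35 / 8)
  # effective rate in the 100 ms window: 50 ms sustained + 25 ms doubled
  # onset = 60 * 0.075 / 0.1
  amp <- 60 * 0.75
  analytic <- amp * 2 * pi * cohort$rf_sigma_x[1] * cohort$rf_sigma_y[1]
  expect_equal(sum(map) * cell_area, analytic, tolerance = 0.35)
  # zero presentations for a cell -> error
  expect_error(rf_response_map(sp, pres[pres$row != 3, ], 1), "zero")
})

test_that("fit_rf: recovery, scale invariance, degenerate maps", {
  x <- seq(-16, 16, length.out = 33); y <- seq(12, -12, length.out = 25)
  m <- gauss_map(25, 33, x, y, cx = 3.5, cy = -2, sx = 3, sy = 3)
  rf <- fit_rf(m, x = x, y = y)
  expect_false(rf$no_rf)
  expect_lt(abs(rf$center[1] - 3.5), 0.1)
  expect_lt(abs(rf$center[2] + 2), 0.1)
  expect_lt(abs(rf$sigma[1] - rf$sigma[2]) / rf$sigma[1], 0.05)
  expect_equal(unname(rf$fwhm[["a"]] / rf$sigma[["sx"]]), sqrt(2 * log(2)),
               tolerance = 1e-6)
  # invariance to uniform scaling of the map
  rf10 <- fit_rf(m * 10, x = x, y = y)
  expect_equal(rf10$center, rf$center, tolerance = 1e-3)
  expect_equal(rf10$sigma, rf$sigma, tolerance = 1e-2)
  # flat map -> no RF
  expect_true(fit_rf(matrix(5, 8, 13))$no_rf)
  expect_true(fit_rf(matrix(0, 8, 13))$no_rf)
})

test_that("overlap_ratio: bounds, Monte-Carlo oracle, monotonicity", {
  lay <- inducer_layout_grid()   # nearest patch disk radius 4.5 deg
  mk_rf <- function(cx, cy, s) {
    structure(list(center = c(x = cx, y = cy), sigma = c(sx = s, sy = s),
                   rotation = 0, amplitude = 1,
                   fwhm = c(a = sqrt(2 * log(2)) * s,
                            b = sqrt(2 * log(2)) * s, rotation = 0),
                   fit_residual = 0, no_rf = FALSE),
              class = "receptive_field")
  }
  # fully inside: small ellipse at a patch centre
  expect_equal(overlap_ratio(mk_rf(0, 0, 1), lay), 1)
  # disjoint: far from every patch
  expect_equal(overlap_ratio(mk_rf(0, 0, 0.5) |>
    (\(r) { r$center <- c(x = 5.8, y = 5.8); r })(), lay), 0)
  # half-offset circle-circle case vs 1e6-point Monte-Carlo
  s <- 3 / sqrt(2 * log(2))      # FWHM radius exactly 3 deg
  rf <- mk_rf(4.5, 0, s)          # ellipse centre on the disk edge
  got <- overlap_ratio(rf, lay, resolution = 40)
  set.seed(21)
  px <- runif(1e6, 4.5 - 3, 4.5 + 3); py <- runif(1e6, -3, 3)
  in_ell <- (px - 4.5)^2 + py^2 <= 9
  mc <- sum(in_ell & (px^2 + py^2 <= 4.5^2)) / sum(in_ell)
  expect_lt(abs(got - mc), 0.01)
  # monotone non-decreasing as the centre approaches the patch centre
  # (within the basin of the origin patch, which owns |x| < ~5.8)
  d <- seq(5.5, 0, by = -0.5)
  ov <- sapply(d, function(di) overlap_ratio(mk_rf(di, 0, 1.5), lay))
  expect_true(all(diff(ov) >= -1e-3))
  expect_true(all(ov >= 0 & ov <= 1))
})

test_that("rf_inducer_distance", {
  lay <- inducer_layout_grid()
  rf <- structure(list(center = c(x = 35 / 3, y = 0), no_rf = FALSE),
                  class = "receptive_field")
  expect_equal(rf_inducer_distance(rf, lay), 0)
  # grid centroid between four patches: half the spacing diagonal
  rf2 <- structure(list(center = c(x = 35 / 6, y = 35 / 6), no_rf = FALSE),
                   class = "receptive_field")
  expect_equal(rf_inducer_distance(rf2, lay), sqrt(2) * 35 / 6,
               tolerance = 1e-9)
})

test_that("retinotopic reversal detection", {
  expect_equal(detect_retinotopic_reversals(c(1, 2, 3, 2, 1),
                                            smooth_window = 1), 3L)
  expect_identical(detect_retinotopic_reversals(1:8), integer(0))
  expect_error(detect_retinotopic_reversals(c(1, 2)), "at least 3")
  # noisy two-area track: reversal within +/-1 channel of ground truth
  set.seed(23)
  truth <- 12
  x <- c(seq(0, 22, length.out = truth), seq(20, 2, length.out = 10)) +
    rnorm(22, 0, 0.6)
  rev <- detect_retinotopic_reversals(x, smooth_window = 3)
  expect_true(any(abs(rev - truth) <= 1))
})

test_that("non-overlapping predicate reproduces ground-truth labels", {
  # cohort geometry is known exactly: build analytic RF objects and
  # check the (overlap < 1% and no DBC response) predicate
  lay <- inducer_layout_grid()
  set.seed(25)
  n <- 40
  cx <- runif(n, -12, 12); cy <- runif(n, -12, 12)
  s <- runif(n, 1, 2)
  k <- sqrt(2 * log(2))
  labels_pred <- logical(n); labels_true <- logical(n)
  for (i in seq_len(n)) {
    rf <- structure(list(center = c(x = cx[i], y = cy[i]),
                         sigma = c(sx = s[i], sy = s[i]), rotation = 0,
                         amplitude = 1,
                         fwhm = c(a = k * s[i], b = k * s[i], rotation = 0),
                         fit_residual = 0, no_rf = FALSE),
                    class = "receptive_field")
    ov <- overlap_ratio(rf, lay, resolution = 30)
    labels_pred[i] <- ov < 0.01            # DBC never drives responses here
    d <- rf_inducer_distance(rf, lay)
    labels_true[i] <- d > 4.5 + k * s[i]   # ellipse clear of the disk
  }
  # the geometric predicate must agree wherever the truth is clear-cut
  expect_true(all(labels_pred[labels_true]))
})
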