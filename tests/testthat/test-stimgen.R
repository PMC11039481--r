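# Stimulus rendering: geometry, value-set closure, the NCS/DBC temporal
# identity, NCS/LDG antiphase, and trial-table construction.

geo10 <- display_geometry(pixels_per_degree = 10, screen_deg = c(35, 35))
lay <- inducer_layout_grid()

stacks <- local({
  g <- grating_spec(direction = 90)
  list(ncs = render_ncs(geo10, lay, g, duration = 0.6),
       dbc = render_dbc(geo10, lay, g, duration = 0.6),
       ldg = render_ldg(geo10, lay, g, duration = 0.6))
})

test_that("frame count, timing and value-set closure", {
  expect_equal(dim(stacks$ncs$frames)[3], 36)  # 0.6 s at 60 Hz
  g <- grating_spec()
  st <- render_ncs(display_geometry(2, screen_deg = c(35, 35)), lay, g,
                   duration = 1)
  expect_equal(dim(st$frames)[3], 60)
  for (s in stacks) {
    expect_setequal(unique(as.vector(s$frames)), c(0, 0.5, 1))
  }
  expect_error(render_ncs(geo10, lay, g, duration = 0.001),
               "shorter than one frame")
})

test_that("NCS/DBC temporal-difference identity and static blockers", {
  for (k in 2:6) {
    expect_identical(stacks$ncs$frames[, , k] - stacks$ncs$frames[, , k - 1],
                     stacks$dbc$frames[, , k] - stacks$dbc$frames[, , k - 1])
  }
  d0 <- stacks$dbc$frames[, , 1] - stacks$ncs$frames[, , 1]
  expect_true(all(d0 >= 0))           # blockers only add white
  n_blk <- sapply(1:6, function(k)
    sum(stacks$dbc$frames[, , k] != stacks$ncs$frames[, , k]))
  expect_true(all(n_blk > 0))
  expect_equal(length(unique(n_blk)), 1)  # constant over time
  # blockers never intersect gray segments
  expect_true(all(stacks$ncs$frames[, , 1][d0 > 0] == 0))
  bad <- inducer_layout_grid(thickness = 0.1, blocker_thickness = 1.4)
  expect_error(render_dbc(geo10, bad, grating_spec(), 0.1), "blocker")
})

test_that("gray-segment duty cycle is 0.5 over one temporal cycle", {
  # pixel-count oracle: fraction of annulus pixels turned gray, averaged
  # over the 30 frames of one 2 Hz cycle
  fr <- sapply(1:30, function(k) {
    f <- stacks$ncs$frames[, , k]
    on_annulus <- f != 0
    sum(f[on_annulus] == 0.5) / sum(on_annulus)
  })
  expect_equal(mean(fr), 0.5, tolerance = 0.02)
})

test_that("NCS and LDG gray patterns are spatially antiphase", {
  for (dir in c(0, 90)) {
    g <- grating_spec(direction = dir)
    ncs <- render_ncs(geo10, lay, g, duration = 1 / 60)
    ldg <- render_ldg(geo10, lay, g, duration = 1 / 60)
    d <- wrap_deg(gray_pattern_phase(ncs) - gray_pattern_phase(ldg))
    # one pixel at 10 px/deg corresponds to 0.05 * 0.1 * 360 = 1.8 deg
    expect_equal(d, 180, tolerance = 2)
  }
  expect_gt(mean(stacks$ldg$frames[, , 1]), mean(stacks$ncs$frames[, , 1]))
})

test_that("drift: phase advances TF/SF/fps deg per frame and wraps at 1/TF", {
  # 2 Hz / 0.05 cpd / 60 Hz = 0.667 deg/frame -> 12 deg of spatial phase
  p1 <- gray_pattern_phase(stacks$ldg, 1)
  p2 <- gray_pattern_phase(stacks$ldg, 2)
  expect_equal(abs(circ_diff_deg(p2, p1)), 12, tolerance = 1)
  # periodicity: frames one full cycle (30 frames) apart are identical
  expect_identical(stacks$ncs$frames[, , 1], stacks$ncs$frames[, , 31])
  expect_identical(stacks$ldg$frames[, , 3], stacks$ldg$frames[, , 33])
})

test_that("honeycomb spacing yields a 39 deg inscribed illusory area", {
  hc <- inducer_layout_honeycomb()
  # distance-transform oracle at the centroid of three adjacent patches:
  # min distance from the centroid to any inducer circle edge, doubled
  ctr <- hc$centers
  d0 <- sqrt(rowSums(ctr^2))
  base <- ctr[which.min(d0), ]
  d <- sqrt((ctr[, 1] - base[1])^2 + (ctr[, 2] - base[2])^2)
  nb <- order(d)[2:3]
  centroid <- colMeans(rbind(base, ctr[nb[1], ], ctr[nb[2], ]))
  gap <- min(sqrt((ctr[, 1] - centroid[1])^2 +
                  (ctr[, 2] - centroid[2])^2)) - max(hc$diameters) / 2
  expect_equal(2 * gap, 39, tolerance = 0.1)
})

test_that("RF-rectangle sweeps: grid coverage, timing, determinism", {
  geo <- display_geometry(1, screen_deg = c(26, 16))
  r1 <- render_rf_rectangles(geo, order_seed = 7, render = FALSE)
  expect_equal(nrow(r1$presentations), 104)   # 8 x 13 locations
  expect_equal(nrow(unique(r1$presentations[, c("row", "col")])), 104)
  r2 <- render_rf_rectangles(geo, order_seed = 7, render = FALSE)
  expect_identical(r1$presentations, r2$presentations)
  r3 <- render_rf_rectangles(geo, order_seed = 8, render = FALSE)
  expect_false(identical(r1$presentations$row, r3$presentations$row))
  # 100 ms on / 100 ms off at 60 Hz -> 6 frames on, 6 off per presentation
  rr <- render_rf_rectangles(geo, grid_shape = c(2, 2), order_seed = 1)
  expect_equal(dim(rr$stack$frames)[3], 4 * 12)
  dark <- apply(rr$stack$frames, 3, function(f) any(f == geo$black))
  expect_equal(sum(dark), 4 * 6)
  expect_error(render_rf_rectangles(geo, rect_deg = 100), "larger")
})

test_that("size-tuning set: sizes, durations, area scaling", {
  geo <- display_geometry(2, screen_deg = c(50, 50))
  st <- render_size_tuning(geo)
  expect_length(st, 20)  # 10 sizes x 2 directions
  expect_equal(sort(unique(sapply(st, attr, "size_deg"))),
               c(2.5, seq(5, 45, by = 5)))
  expect_equal(dim(st[[1]]$frames)[3], 40)  # 666.7 ms at 60 Hz
  area <- function(s) sum(s$frames[, , 1] != geo$gray)
  i10 <- which(sapply(st, attr, "size_deg") == 10 &
               sapply(st, attr, "direction") == 0)
  i20 <- which(sapply(st, attr, "size_deg") == 20 &
               sapply(st, attr, "direction") == 0)
  expect_equal(area(st[[i20]]) / area(st[[i10]]), 4, tolerance = 0.05)
})

test_that("condition table: 24 conditions, counts, determinism", {
  tab <- condition_table(order_seed = 5)
  expect_equal(nrow(tab), 1680)
  cond <- table(tab$condition, tab$direction)
  expect_equal(dim(cond), c(3L, 8L))
  expect_true(all(cond == 70))
  expect_identical(tab, condition_table(order_seed = 5))
  expect_false(identical(tab$condition, condition_table(order_seed = 6)$condition))
  # trials do not overlap
  expect_true(all(diff(tab$onset_s) >= 1))
  lt <- condition_table(trials_per_condition = 2, light = TRUE)
  expect_equal(nrow(lt), 96)
  expect_equal(sum(lt$light), 48)
})
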