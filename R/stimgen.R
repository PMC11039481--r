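# Stimulus generation: neon-color-spreading (NCS) illusory gratings, the
# diffusion-blocked control (DBC), luminance-defined gratings (LDG),
# receptive-field mapping rectangles and size-tuning patches.
#
# Geometry convention: degrees of visual angle, origin at screen centre,
# x rightward, y upward; pixels are sampled at their centres and rasterised
# by a centre-in-region test. Frame k covers [k/fps, (k+1)/fps) and the
# grating phase is evaluated at the frame start.

#' Display geometry and luminance levels
#'
#' Describes the (virtual) display on which stimuli are rasterised. The
#' luminance values are arbitrary units in \[0, 1\]; stimuli use only the
#' three levels `black < gray < white`.
#'
#' @param pixels_per_degree rasterisation resolution (px/deg).
#' @param frame_rate display refresh rate (Hz).
#' @param screen_deg width and height of the screen (deg).
#' @param black,gray,white the three luminance levels.
#' @return an object of class `display_geometry`.
#' @export
display_geometry <- function(pixels_per_degree = 10, frame_rate = 60,
                             screen_deg = c(35, 35),
                             black = 0, gray = 0.5, white = 1) {
  if (pixels_per_degree <= 0) stopf("pixels_per_degree must be > 0")
  if (frame_rate <= 0) stopf("frame_rate must be > 0")
  if (!(black < gray && gray < white)) stopf("need black < gray < white")
  structure(list(ppd = pixels_per_degree, fps = frame_rate,
                 screen_deg = rep(screen_deg, length.out = 2),
                 black = black, gray = gray, white = white),
            class = "display_geometry")
}

#' Drifting-grating parameters
#'
#' @param spatial_frequency cycles per degree.
#' @param temporal_frequency drift rate (Hz).
#' @param direction drift direction in degrees; experimental conditions use
#'   the 8-point grid 0, 45, ..., 315.
#' @param phase0 spatial phase at t = 0 (deg).
#' @return an object of class `grating_spec`.
#' @export
grating_spec <- function(spatial_frequency = 0.05, temporal_frequency = 2,
                         direction = 0, phase0 = 0) {
  if (spatial_frequency <= 0) stopf("spatial_frequency must be > 0")
  if (temporal_frequency < 0) stopf("temporal_frequency must be >= 0")
  structure(list(sf = spatial_frequency, tf = temporal_frequency,
                 direction = wrap_deg(direction), phase0 = phase0),
            class = "grating_spec")
}

#' Inducer layout: 3x3 grid of concentric-circle patches
#'
#' Nine patches of concentric circles arranged on a three-by-three virtual
#' grid over a black square. Defaults follow the grid stimulus: circle
#' diameters 3/6/9 deg at 0.1 deg stroke, blockers (DBC) 0.4 deg.
#'
#' @param square_deg side of the black square carrying the stimulus (deg).
#' @param diameters circle diameters within each patch (deg, concentric).
#' @param thickness stroke width of the inducer circles (deg).
#' @param blocker_thickness stroke width of the DBC blocker rings (deg).
#' @return an object of class `inducer_layout`.
#' @export
inducer_layout_grid <- function(square_deg = 35, diameters = c(3, 6, 9),
                                thickness = 0.1, blocker_thickness = 0.4) {
  if (thickness <= 0 || blocker_thickness <= 0) stopf("thickness must be > 0")
  s <- square_deg / 3
  cx <- rep(c(-s, 0, s), times = 3)
  cy <- rep(c(-s, 0, s), each = 3)
  structure(list(arrangement = "grid3x3",
                 centers = cbind(x = cx, y = cy),
                 diameters = sort(diameters),
                 thickness = thickness,
                 blocker_thickness = blocker_thickness,
                 square_deg = square_deg),
            class = "inducer_layout")
}

#' Inducer layout: honeycomb (full-screen variant)
#'
#' Patches of concentric circles on a hexagonal lattice. The default
#' spacing places the largest empty circle inscribed between three mutually
#' adjacent patches at 39 deg diameter: with outermost patch radius r and
#' lattice spacing s, the inscribed-circle diameter is 2 (s / sqrt(3) - r).
#'
#' @param screen_deg extent covered by the lattice (deg).
#' @param diameters circle diameters within each patch (deg).
#' @param thickness inducer stroke width (deg).
#' @param blocker_thickness DBC blocker stroke width (deg).
#' @param spacing_deg centre-to-centre lattice spacing (deg); default gives
#'   the 39 deg inscribed illusory area.
#' @return an object of class `inducer_layout`.
#' @export
inducer_layout_honeycomb <- function(screen_deg = c(120, 90),
                                     diameters = c(8, 16, 24),
                                     thickness = 0.4,
                                     blocker_thickness = 0.8,
                                     spacing_deg = NULL) {
  if (thickness <= 0 || blocker_thickness <= 0) stopf("thickness must be > 0")
  r_out <- max(diameters) / 2
  if (is.null(spacing_deg)) spacing_deg <- sqrt(3) * (39 / 2 + r_out)
  screen_deg <- rep(screen_deg, length.out = 2)
  s <- spacing_deg
  # hexagonal lattice: rows s*sqrt(3)/2 apart, odd rows offset by s/2
  ny <- ceiling(screen_deg[2] / (s * sqrt(3) / 2)) + 1
  nx <- ceiling(screen_deg[1] / s) + 1
  pts <- list()
  for (j in -ny:ny) {
    y <- j * s * sqrt(3) / 2
    off <- if (j %% 2 == 0) 0 else s / 2
    for (i in -nx:nx) {
      x <- i * s + off
      if (abs(x) <= screen_deg[1] / 2 + r_out &&
          abs(y) <= screen_deg[2] / 2 + r_out)
        pts[[length(pts) + 1L]] <- c(x, y)
    }
  }
  centers <- do.call(rbind, pts)
  colnames(centers) <- c("x", "y")
  structure(list(arrangement = "honeycomb",
                 centers = centers,
                 diameters = sort(diameters),
                 thickness = thickness,
                 blocker_thickness = blocker_thickness,
                 square_deg = max(screen_deg),
                 spacing_deg = spacing_deg),
            class = "inducer_layout")
}

# pixel-centre coordinate grids (deg); x rightward, y upward
pixel_grid <- function(geometry) {
  W <- round(geometry$screen_deg[1] * geometry$ppd)
  H <- round(geometry$screen_deg[2] * geometry$ppd)
  x <- (seq_len(W) - (W + 1) / 2) / geometry$ppd
  y <- ((H + 1) / 2 - seq_len(H)) / geometry$ppd
  list(x = matrix(x, H, W, byrow = TRUE), y = matrix(y, H, W), W = W, H = H)
}

# logical H x W mask of the inducer annuli (and optionally blocker rings)
annulus_mask <- function(grid, layout, what = c("inducer", "blocker")) {
  what <- match.arg(what)
  th <- layout$thickness
  bt <- layout$blocker_thickness
  mask <- matrix(FALSE, nrow(grid$x), ncol(grid$x))
  for (p in seq_len(nrow(layout$centers))) {
    d <- sqrt((grid$x - layout$centers[p, 1])^2 +
              (grid$y - layout$centers[p, 2])^2)
    for (r in layout$diameters / 2) {
      if (what == "inducer") {
        mask <- mask | (abs(d - r) <= th / 2)
      } else {
        mask <- mask | (d >= r - th / 2 - bt & d < r - th / 2) |
                       (d > r + th / 2 & d <= r + th / 2 + bt)
      }
    }
  }
  mask
}

# validity of DBC geometry: radial bands (inducer + blockers) of the
# concentric circles must not overlap
validate_blockers <- function(layout) {
  half <- layout$thickness / 2 + layout$blocker_thickness
  r <- layout$diameters / 2
  lo <- r - half
  hi <- r + half
  if (any(lo <= 0)) stopf("blocker ring crosses the patch centre")
  if (length(r) > 1 && any(hi[-length(r)] >= lo[-1]))
    stopf("blocker rings overlap a neighbouring inducer circle")
  invisible(TRUE)
}

# square-wave drift phase: fraction in [0,1); "dark" half-cycle is
# frac >= 0.5. u is the coordinate along the drift axis.
drift_fraction <- function(grid, grating, t) {
  th <- deg2rad(grating$direction)
  u <- grid$x * cos(th) + grid$y * sin(th)
  (grating$sf * u - grating$tf * t + grating$phase0 / 360) %% 1
}

new_frame_stack <- function(frames, geometry, grating, layout, label) {
  structure(list(frames = frames,
                 frame_times = (seq_len(dim(frames)[3]) - 1) / geometry$fps,
                 condition_label = label, geometry = geometry,
                 grating = grating, layout = layout),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack %s: %d x %d px, %d frames @ %g Hz>\n",
              x$condition_label, d[1], d[2], d[3], x$geometry$fps))
  invisible(x)
}

n_frames <- function(geometry, duration) {
  n <- round(duration * geometry$fps)
  if (n < 1) stopf("duration shorter than one frame")
  n
}

# region carrying the stimulus (the black square of the grid layout, or
# the full screen for honeycomb)
stimulus_region <- function(grid, layout) {
  if (identical(layout$arrangement, "grid3x3")) {
    abs(grid$x) <= layout$square_deg / 2 & abs(grid$y) <= layout$square_deg / 2
  } else {
    matrix(TRUE, nrow(grid$x), ncol(grid$x))
  }
}

#' Render a neon-color-spreading (NCS) stimulus
#'
#' White concentric-circle inducers on a black background; wherever the
#' dark half-cycle of a virtual square-wave drifting grating covers an
#' inducer pixel, that pixel is replaced by gray. The gray segments induce
#' an illusory "darker than black" drifting grating.
#'
#' @param geometry a [display_geometry()].
#' @param layout an inducer layout ([inducer_layout_grid()] or
#'   [inducer_layout_honeycomb()]).
#' @param grating a [grating_spec()].
#' @param duration stimulus duration (s); at least one frame.
#' @return a `frame_stack` whose pixel values are restricted to
#'   `{black, gray, white}`.
#' @export
render_ncs <- function(geometry, layout, grating, duration = 1) {
  grid <- pixel_grid(geometry)
  ann <- annulus_mask(grid, layout, "inducer")
  nt <- n_frames(geometry, duration)
  base <- matrix(geometry$black, grid$H, grid$W)
  base[ann] <- geometry$white
  frames <- array(geometry$black, c(grid$H, grid$W, nt))
  any_gray <- FALSE
  for (k in seq_len(nt)) {
    f <- base
    dark <- drift_fraction(grid, grating, (k - 1) / geometry$fps) >= 0.5
    seg <- ann & dark
    f[seg] <- geometry$gray
    if (any(seg)) any_gray <- TRUE
    frames[, , k] <- f
  }
  if (!any_gray)
    warnf("grating never intersects the inducers (zero-area gray segments)")
  new_frame_stack(frames, geometry, grating, layout, "NCS")
}

#' Render the diffusion-blocked control (DBC)
#'
#' Identical pixel-wise temporal changes to the matched NCS stimulus, plus
#' static white blocker rings immediately inside and outside every inducer
#' circle. The blockers constrain the illusory filling-in.
#'
#' @inheritParams render_ncs
#' @return a `frame_stack`.
#' @export
render_dbc <- function(geometry, layout, grating, duration = 1) {
  validate_blockers(layout)
  stack <- render_ncs(geometry, layout, grating, duration)
  grid <- pixel_grid(geometry)
  blk <- annulus_mask(grid, layout, "blocker")
  for (k in seq_len(dim(stack$frames)[3])) {
    f <- stack$frames[, , k]
    f[blk] <- stack$geometry$white
    stack$frames[, , k] <- f
  }
  stack$condition_label <- "DBC"
  stack
}

#' Render the luminance-defined grating (LDG)
#'
#' A physical gray square-wave grating drifting over the black background
#' and the white inducers, with the same spatial/temporal frequency and
#' direction as the virtual grating of the NCS stimulus. The gray bars
#' occupy the bright half-cycle, so the LDG bars are spatially antiphase
#' (180 deg) to the NCS gray segments.
#'
#' @inheritParams render_ncs
#' @return a `frame_stack`.
#' @export
render_ldg <- function(geometry, layout, grating, duration = 1) {
  grid <- pixel_grid(geometry)
  ann <- annulus_mask(grid, layout, "inducer")
  region <- stimulus_region(grid, layout)
  nt <- n_frames(geometry, duration)
  base <- matrix(geometry$black, grid$H, grid$W)
  base[ann] <- geometry$white
  frames <- array(geometry$black, c(grid$H, grid$W, nt))
  for (k in seq_len(nt)) {
    f <- base
    bright <- drift_fraction(grid, grating, (k - 1) / geometry$fps) < 0.5
    f[region & bright] <- geometry$gray
    frames[, , k] <- f
  }
  new_frame_stack(frames, geometry, grating, layout, "LDG")
}

#' Render receptive-field mapping rectangles
#'
#' Black rectangles flashed on a gray background over a rows x cols grid of
#' locations in pseudo-random order, 100 ms on / 100 ms off by default.
#'
#' @param geometry a [display_geometry()].
#' @param grid_shape c(rows, cols) of the location grid (default 8 x 13).
#' @param rect_deg rectangle width/height (deg); default the grid pitch.
#' @param on_ms,off_ms flash and blank durations (ms).
#' @param order_seed RNG seed for the pseudo-random location order.
#' @param n_sweeps number of passes over the grid.
#' @param render logical; if `FALSE` only the presentation table is built.
#' @return a list with elements `stack` (a `frame_stack` or `NULL`) and
#'   `presentations` (data.frame: presentation, row, col, onset_s,
#'   offset_s).
#' @export
render_rf_rectangles <- function(geometry, grid_shape = c(8, 13),
                                 rect_deg = NULL, on_ms = 100, off_ms = 100,
                                 order_seed = 1, n_sweeps = 1,
                                 render = TRUE) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  pitch <- geometry$screen_deg / c(cols, rows)   # x-pitch, y-pitch
  if (is.null(rect_deg)) rect_deg <- min(pitch)
  if (rect_deg > min(geometry$screen_deg))
    stopf("rectangle larger than the screen")
  cells <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  order <- with_seed(order_seed, {
    unlist(lapply(seq_len(n_sweeps), function(s) sample.int(nrow(cells))))
  })
  period <- (on_ms + off_ms) / 1000
  pres <- data.frame(presentation = seq_along(order),
                     row = cells$row[order], col = cells$col[order],
                     onset_s = (seq_along(order) - 1) * period,
                     offset_s = (seq_along(order) - 1) * period + on_ms / 1000)
  stack <- NULL
  if (render) {
    grid <- pixel_grid(geometry)
    on_frames <- round(on_ms / 1000 * geometry$fps)
    off_frames <- round(off_ms / 1000 * geometry$fps)
    nt <- length(order) * (on_frames + off_frames)
    frames <- array(geometry$gray, c(grid$H, grid$W, nt))
    cx <- (cells$col - (cols + 1) / 2) * pitch[1]
    cy <- ((rows + 1) / 2 - cells$row) * pitch[2]
    k <- 1L
    for (i in seq_along(order)) {
      f <- matrix(geometry$gray, grid$H, grid$W)
      inside <- abs(grid$x - cx[order[i]]) <= rect_deg / 2 &
                abs(grid$y - cy[order[i]]) <= rect_deg / 2
      f[inside] <- geometry$black
      for (j in seq_len(on_frames)) { frames[, , k] <- f; k <- k + 1L }
      k <- k + off_frames
    }
    stack <- new_frame_stack(frames, geometry, NULL, NULL, "RECT")
  }
  list(stack = stack, presentations = pres)
}

#' Render size-tuning grating patches
#'
#' Circular patches of square-wave drifting grating (default SF 0.05
#' cyc/deg, TF 3 Hz) of increasing diameter, centred on the estimated RF
#' centre, for rightward (0 deg) and upward (90 deg) drift; 666.7 ms each.
#'
#' @param geometry a [display_geometry()].
#' @param sizes patch diameters (deg); default 2.5 then 5..45 by 5.
#' @param grating a [grating_spec()]; its direction field is ignored.
#' @param center patch centre (deg).
#' @param duration stimulus duration (s).
#' @return a list of `frame_stack`s, one per (size, direction), with
#'   attributes `size_deg` and `direction` on each element.
#' @export
render_size_tuning <- function(geometry, sizes = c(2.5, seq(5, 45, by = 5)),
                               grating = grating_spec(0.05, 3),
                               center = c(0, 0), duration = 2 / 3) {
  if (any(sizes <= 0)) stopf("sizes must be positive")
  grid <- pixel_grid(geometry)
  nt <- n_frames(geometry, duration)
  out <- list()
  for (dir in c(0, 90)) {
    g <- grating_spec(grating$sf, grating$tf, dir, grating$phase0)
    for (s in sizes) {
      inside <- (grid$x - center[1])^2 + (grid$y - center[2])^2 <= (s / 2)^2
      frames <- array(geometry$gray, c(grid$H, grid$W, nt))
      for (k in seq_len(nt)) {
        f <- matrix(geometry$gray, grid$H, grid$W)
        dark <- drift_fraction(grid, g, (k - 1) / geometry$fps) >= 0.5
        f[inside & dark] <- geometry$black
        f[inside & !dark] <- geometry$white
        frames[, , k] <- f
      }
      st <- new_frame_stack(frames, geometry, g, NULL, "SIZE")
      attr(st, "size_deg") <- s
      attr(st, "direction") <- dir
      out[[length(out) + 1L]] <- st
    }
  }
  out
}

#' Build a pseudo-randomised trial table
#'
#' Crosses stimulus types with drift directions (24 conditions for the
#' default NCS/DBC/LDG x 8 directions design), replicates each condition
#' `trials_per_condition` times (70 in the experiments) and shuffles the
#' order reproducibly.
#'
#' @param stimulus_types character vector, e.g. c("NCS", "DBC", "LDG").
#' @param directions drift directions (deg).
#' @param trials_per_condition replicates per condition.
#' @param order_seed RNG seed for the shuffle.
#' @param duration_s,iti_s stimulus duration and inter-trial interval (s).
#' @param light if `TRUE`, every condition is additionally crossed with an
#'   optogenetic light-on factor.
#' @param t0 onset of the first trial (s); leaves room for the pre-onset
#'   baseline window.
#' @return data.frame: trial_id, condition, direction, light, onset_s,
#'   offset_s.
#' @export
condition_table <- function(stimulus_types = c("NCS", "DBC", "LDG"),
                            directions = seq(0, 315, by = 45),
                            trials_per_condition = 70, order_seed = 1,
                            duration_s = 1, iti_s = 0.5, light = FALSE,
                            t0 = 0.5) {
  cond <- expand.grid(condition = stimulus_types, direction = directions,
                      light = if (light) c(FALSE, TRUE) else FALSE,
                      stringsAsFactors = FALSE)
  tab <- cond[rep(seq_len(nrow(cond)), each = trials_per_condition), ]
  ord <- with_seed(order_seed, sample.int(nrow(tab)))
  tab <- tab[ord, ]
  tab$trial_id <- seq_len(nrow(tab))
  tab$onset_s <- t0 + (tab$trial_id - 1) * (duration_s + iti_s)
  tab$offset_s <- tab$onset_s + duration_s
  rownames(tab) <- NULL
  tab[, c("trial_id", "condition", "direction", "light",
          "onset_s", "offset_s")]
}

#' Spatial phase of the gray-pixel pattern along the drift axis
#'
#' Projects the binarised gray-pixel indicator of one frame onto the drift
#' axis and evaluates the discrete Fourier component at the grating's
#' fundamental spatial frequency. The indicator is centred on its support
#' (the inducer annuli for NCS/DBC, the stimulus region for LDG) before
#' projection, which removes the DC leakage of the finite aperture;
#' coordinates are centred, so a symmetric aperture contributes no phase
#' of its own.
#'
#' @param stack a `frame_stack` rendered with a gray level.
#' @param frame frame index (1-based).
#' @return phase in degrees in \[0, 360).
#' @export
gray_pattern_phase <- function(stack, frame = 1) {
  geo <- stack$geometry
  grid <- pixel_grid(geo)
  ind <- abs(stack$frames[, , frame] - geo$gray) < 1e-9
  support <- if (stack$condition_label %in% c("NCS", "DBC"))
    annulus_mask(grid, stack$layout, "inducer")
  else
    stimulus_region(grid, stack$layout)
  th <- deg2rad(stack$grating$direction)
  u <- grid$x * cos(th) + grid$y * sin(th)
  z <- sum((ind - 0.5 * support) * exp(-2i * pi * stack$grating$sf * u))
  wrap_deg(rad2deg(Arg(z)))
}

#' Write a frame stack to plain-text files
#'
#' One CSV file per frame (`frame_0001.csv`, ...) plus a JSON stimulus
#' config, in lieu of a multi-page TIFF.
#'
#' @param stack a `frame_stack`.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory path.
#' @export
write_frame_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- dim(stack$frames)[3]
  for (k in seq_len(nt)) {
    utils::write.table(stack$frames[, , k],
                       file.path(dir, sprintf("frame_%04d.csv", k)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  cfg <- list(condition = stack$condition_label,
              frame_rate = stack$geometry$fps,
              pixels_per_degree = stack$geometry$ppd,
              n_frames = nt,
              grating = stack$grating[c("sf", "tf", "direction", "phase0")])
  jsonlite::write_json(cfg, file.path(dir, "stimulus.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
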