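#' Space-time stimulus movies
#'
#' A `stimulus_movie` stores luminance over space and time together with its
#' geometry. One-dimensional movies (used by the outer-retina circuit
#' simulator, [run_opl_simulation()]) hold a `space x time` matrix; 2-D movies
#' (used by the linear receptive-field population, [simulate_rf_population()])
#' hold a `y x x x time` array. Luminance is in arbitrary units with
#' `background` at rest; bar stimuli use background 0 and bar amplitude equal
#' to the contrast value, naturalistic movies use the 8-bit 0-255 scale.
#'
#' @param frames numeric matrix (`space x time`) or 3-d array (`y x x x time`).
#' @param dx micrometres per spatial sample.
#' @param dt milliseconds per frame.
#' @param background resting luminance value.
#' @param mask_regions list of numeric `c(start, end)` extents in um
#'   (half-open, `[start, end)`) where luminance is clamped to background.
#' @param condition_label one of `"flash_full"`, `"flash_masked"`,
#'   `"motion_full"`, `"motion_emerging"`, `"motion_exiting"`,
#'   `"apparent_motion"`, `"natural_movie"`.
#' @param meta named list of extra metadata (onset times, emergence site, ...).
#' @return an object of class `stimulus_movie`.
#' @export
stimulus_movie <- function(frames, dx, dt, background = 0,
                           mask_regions = list(),
                           condition_label = "flash_full",
                           meta = list()) {
  stopifnot(is.numeric(frames), dx > 0, dt > 0, all(is.finite(frames)))
  nd <- length(dim(frames))
  if (is.null(dim(frames)) || !(nd %in% c(2L, 3L)))
    stop("frames must be a space x time matrix or a y x x x time array")
  extent <- if (nd == 2L) nrow(frames) * dx else dim(frames)[2] * dx
  for (r in mask_regions) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0 || r[2] > extent)
      stop("mask region outside spatial bounds")
  }
  structure(list(frames = frames, dx = dx, dt = dt, background = background,
                 mask_regions = mask_regions,
                 condition_label = condition_label, meta = meta),
            class = "stimulus_movie")
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$frames)
  sp <- if (length(d) == 2L) sprintf("%d samples (1-D)", d[1])
        else sprintf("%d x %d samples (2-D)", d[1], d[2])
  cat(sprintf("<stimulus_movie: %s>\n", x$condition_label))
  cat(sprintf("  space: %s @ %g um/sample; time: %d frames @ %g ms\n",
              sp, x$dx, d[length(d)], x$dt))
  cat(sprintf("  background %g; %d mask region(s)\n",
              x$background, length(x$mask_regions)))
  invisible(x)
}

n_frames <- function(movie) {
  d <- dim(movie$frames)
  d[length(d)]
}

movie_duration <- function(movie) n_frames(movie) * movie$dt

space_axis <- function(movie) {
  d <- dim(movie$frames)
  n <- if (length(d) == 2L) d[1] else d[2]
  (seq_len(n) - 1) * movie$dx
}

#' Bar stimulus specification
#'
#' Parameters of flashed or moving bar stimuli, mirroring the display
#' protocols: full-display static flashes, 1-mm bars moving at 0.5 mm/s, and
#' 25-um apparent-motion bars.
#'
#' @param bar_length bar extent along the motion axis, um.
#' @param bar_width bar extent orthogonal to motion, um (2-D movies only).
#' @param speed drift speed, mm/s (0 for static flashes).
#' @param direction `"right"` or `"left"`.
#' @param contrast Michelson-style amplitude in `[-1, 1]`; the movie's bar
#'   luminance equals `contrast` above background.
#' @param flash_duration flash duration, ms.
#' @return an object of class `bar_spec`.
#' @export
bar_spec <- function(bar_length = 800, bar_width = 800, speed = 0,
                     direction = c("right", "left"), contrast = 1,
                     flash_duration = 2000) {
  direction <- match.arg(direction)
  stopifnot(speed >= 0, abs(contrast) <= 1, bar_length > 0)
  structure(list(bar_length = bar_length, bar_width = bar_width,
                 speed = speed, direction = direction, contrast = contrast,
                 flash_duration = flash_duration), class = "bar_spec")
}

#' Stimulus geometry
#'
#' @param extent_um spatial extent of the display/array, um.
#' @param dx um per spatial sample.
#' @param dt ms per frame.
#' @param duration_ms total movie duration, ms.
#' @param pre_ms pre-stimulus baseline before onset, ms.
#' @return a plain list used by the stimulus constructors.
#' @export
stim_geometry <- function(extent_um = 1500, dx = 10, dt = 1,
                          duration_ms = 4500, pre_ms = 200) {
  stopifnot(extent_um > 0, dx > 0, dt > 0, duration_ms > 0, pre_ms >= 0)
  list(extent_um = extent_um, dx = dx, dt = dt,
       duration_ms = duration_ms, pre_ms = pre_ms)
}

#' Static flashed bar
#'
#' A stationary bar flashed for `spec$flash_duration` ms starting at `onset`.
#' The default spec covers the entire display for 2 s, the full-field flash of
#' the stimulus battery.
#'
#' @param spec a [bar_spec()]; `speed` is ignored.
#' @param geometry a [stim_geometry()].
#' @param onset flash onset, ms (default `geometry$pre_ms`).
#' @param center bar centre position, um (default display centre).
#' @return a 1-D [stimulus_movie()], label `"flash_full"`.
#' @export
make_static_flash <- function(spec = bar_spec(), geometry = stim_geometry(),
                              onset = geometry$pre_ms, center = NULL) {
  stopifnot(spec$flash_duration > 0)
  if (spec$bar_length > geometry$extent_um)
    stop("bar larger than display geometry")
  nx <- round(geometry$extent_um / geometry$dx)
  nt <- round(geometry$duration_ms / geometry$dt)
  if (is.null(center)) center <- geometry$extent_um / 2
  x <- (seq_len(nx) - 1) * geometry$dx
  inside <- x >= center - spec$bar_length / 2 & x < center + spec$bar_length / 2
  t_ms <- (seq_len(nt) - 1) * geometry$dt
  on <- t_ms >= onset & t_ms < onset + spec$flash_duration
  frames <- matrix(0, nx, nt)
  frames[inside, on] <- spec$contrast
  stimulus_movie(frames, geometry$dx, geometry$dt,
                 condition_label = "flash_full",
                 meta = list(onset = onset, spec = spec, center = center))
}

#' Moving bar
#'
#' A bar of length `spec$bar_length` entering the display from one side at
#' `onset` and drifting at `spec$speed` mm/s. The leading edge advances
#' `speed * dt` um per frame; every spatial sample is covered for
#' `bar_length / speed` ms (2 s for the default 1-mm bar at 0.5 mm/s).
#'
#' @inheritParams make_static_flash
#' @return a 1-D [stimulus_movie()], label `"motion_full"`.
#' @export
make_moving_bar <- function(spec = bar_spec(bar_length = 1000, speed = 0.5),
                            geometry = stim_geometry(),
                            onset = geometry$pre_ms) {
  stopifnot(spec$speed > 0)
  nx <- round(geometry$extent_um / geometry$dx)
  nt <- round(geometry$duration_ms / geometry$dt)
  x <- (seq_len(nx) - 1) * geometry$dx
  t_ms <- (seq_len(nt) - 1) * geometry$dt
  v <- spec$speed  # mm/s == um/ms
  frames <- matrix(0, nx, nt)
  for (k in seq_len(nt)) {
    tt <- t_ms[k] - onset
    if (tt < 0) next
    if (spec$direction == "right") {
      lead <- v * tt  # leading edge position from left border
      inside <- x < lead & x >= lead - spec$bar_length
    } else {
      # exact lattice mirror of the rightward bar
      xm <- geometry$extent_um - geometry$dx
      lead <- xm - v * tt
      inside <- x > lead & x <= lead + spec$bar_length
    }
    frames[inside, k] <- spec$contrast
  }
  stimulus_movie(frames, geometry$dx, geometry$dt,
                 condition_label = "motion_full",
                 meta = list(onset = onset, spec = spec))
}

#' Occlude part of a stimulus movie
#'
#' Clamps luminance to background inside `region` (um, half-open
#' `[start, end)`) at all times and records the mask. For moving-bar movies
#' the condition label is re-derived: motion away from the masked side becomes
#' `"motion_emerging"`, motion into it `"motion_exiting"`; flashes become
#' `"flash_masked"`.
#'
#' @param movie a 1-D [stimulus_movie()].
#' @param region numeric `c(start, end)` in um.
#' @return the masked [stimulus_movie()].
#' @export
apply_mask <- function(movie, region) {
  stopifnot(inherits(movie, "stimulus_movie"))
  if (length(dim(movie$frames)) != 2L)
    stop("apply_mask supports 1-D movies; natural movies carry their own mask")
  extent <- nrow(movie$frames) * movie$dx
  if (region[1] >= region[2]) {
    warning("empty mask region; movie unchanged")
    return(movie)
  }
  if (region[1] < 0 || region[2] > extent)
    stop("mask region outside movie bounds")
  x <- space_axis(movie)
  inside <- x >= region[1] & x < region[2]
  movie$frames[inside, ] <- movie$background
  movie$mask_regions <- c(movie$mask_regions, list(region))
  lab <- movie$condition_label
  if (lab %in% c("flash_full", "flash_masked")) {
    movie$condition_label <- "flash_masked"
  } else if (grepl("^motion", lab)) {
    dir <- movie$meta$spec$direction
    left_mask <- region[1] <= 0 + 1e-9
    right_mask <- region[2] >= extent - 1e-9
    away <- (left_mask && identical(dir, "right")) ||
            (right_mask && identical(dir, "left"))
    movie$condition_label <- if (away) "motion_emerging" else "motion_exiting"
  }
  movie
}

# The seven fixed pseudorandom presentation orders for apparent-motion bars.
# Generated once from a named seed so they behave as precomputed patterns.
apparent_motion_orders <- function() {
  orders <- withr_seed(20140114, {
    lapply(seq_len(7), function(i) sample.int(14L))
  })
  orders
}

# run expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Apparent-motion bar sequence
#'
#' Flashes 25 x 350 um bars for 50 ms each in 14 positions tiling a 350-um
#' span at 25-um pitch. Presentation order is sequential (left/right, creating
#' apparent motion) or one of seven fixed pseudorandom permutations.
#'
#' @param order `"sequential_right"`, `"sequential_left"`, or `"shuffle"`.
#' @param k shuffle index in 1..7 (used when `order = "shuffle"`).
#' @param geometry a [stim_geometry()]; the 350-um tile is centred in the
#'   display. `geometry$duration_ms` is ignored: the movie spans the baseline
#'   plus 14 x 50 ms.
#' @param contrast bar amplitude.
#' @return a 1-D [stimulus_movie()], label `"apparent_motion"`; `meta$order`
#'   holds the position sequence.
#' @export
make_apparent_motion <- function(order = c("sequential_right",
                                           "sequential_left", "shuffle"),
                                 k = 1,
                                 geometry = stim_geometry(extent_um = 350,
                                                          dx = 25, dt = 1,
                                                          duration_ms = 900),
                                 contrast = 1) {
  order <- match.arg(order)
  pitch <- 25; n_pos <- 14L; flash_ms <- 50
  span <- pitch * n_pos
  if (geometry$extent_um < span) stop("display smaller than the 350-um tile")
  seq_pos <- switch(order,
    sequential_right = seq_len(n_pos),
    sequential_left  = rev(seq_len(n_pos)),
    shuffle = {
      if (!(k %in% 1:7)) stop("shuffle index k must be in 1..7")
      apparent_motion_orders()[[k]]
    })
  nx <- round(geometry$extent_um / geometry$dx)
  x <- (seq_len(nx) - 1) * geometry$dx
  x0 <- (geometry$extent_um - span) / 2
  nt <- round((geometry$pre_ms + n_pos * flash_ms) / geometry$dt)
  t_ms <- (seq_len(nt) - 1) * geometry$dt
  frames <- matrix(0, nx, nt)
  for (i in seq_len(n_pos)) {
    p <- seq_pos[i]
    lo <- x0 + (p - 1) * pitch
    inside <- x >= lo & x < lo + pitch
    on <- t_ms >= geometry$pre_ms + (i - 1) * flash_ms &
          t_ms < geometry$pre_ms + i * flash_ms
    frames[inside, on] <- contrast
  }
  stimulus_movie(frames, geometry$dx, geometry$dt,
                 condition_label = "apparent_motion",
                 meta = list(order = seq_pos, pitch = pitch,
                             flash_ms = flash_ms, onset = geometry$pre_ms))
}

# smooth padded white noise with a separable gaussian kernel (sd in
# samples) via two small matrix products; padding keeps the field
# statistically stationary up to the edges. kernel matrices are cached.
.kernel_cache <- new.env(parent = emptyenv())

smooth_gmat <- function(n, sd_samples, half) {
  key <- paste(n, sd_samples, half)
  g <- .kernel_cache[[key]]
  if (is.null(g)) {
    g <- outer(seq_len(n), seq_len(n + 2 * half) - half,
               function(a, b) stats::dnorm(a - b, sd = sd_samples))
    g <- g / rowSums(g)
    .kernel_cache[[key]] <- g
  }
  g
}

smooth_noise_once <- function(ny, nx, sd_samples) {
  half <- max(1L, ceiling(3 * sd_samples))
  z <- matrix(stats::rnorm((ny + 2 * half) * (nx + 2 * half)),
              ny + 2 * half, nx + 2 * half)
  zs <- smooth_gmat(ny, sd_samples, half) %*% z %*%
    t(smooth_gmat(nx, sd_samples, half))
  zs / stats::sd(zs)
}

# multi-scale naturalistic texture: independent gaussian-smoothed noise at
# octave-spaced scales with per-scale amplitude proportional to the scale (a
# red, roughly 1/f^2 power spectrum, the canonical natural-image statistic:
# most luminance variance lives in the largest structures), given a
# right-skewed lognormal-like luminance marginal (natural 8-bit frames are
# strongly right-skewed: sky and specular patches form a bright tail),
# standardized to exact mean/sd and clipped to the 8-bit range
smooth_noise_field <- function(ny, nx, scales_px, mean_target, sd_target,
                               skew = 0.8, weights = scales_px) {
  z <- 0
  for (i in seq_along(scales_px))
    z <- z + weights[i] * smooth_noise_once(ny, nx, scales_px[i])
  z <- (z - mean(z)) / stats::sd(z)
  if (skew > 0) {
    z <- exp(skew * z)
    z <- (z - mean(z)) / stats::sd(z)
  }
  pmin(pmax(mean_target + sd_target * z, 0), 255)
}

#' Synthetic naturalistic movie with an emerging object
#'
#' Emulates movies of a predator appearing in a textured natural scene: a
#' spatially correlated random background scaled to mean 128 and SD 30
#' (8-bit luminance), a textured stimulus disc whose mean is 2 SD above the
#' background (188), moving horizontally at `speed` mm/s, and (optionally) a
#' static occluding mask with an irregular silhouette boundary drawn at
#' background statistics. With the mask present the stimulus is hidden until
#' it crosses the silhouette and appears abruptly (novel emergence); without
#' the mask the identical trajectory is seen as continuous motion.
#'
#' @param n_px frame size in pixels (square), default 100.
#' @param dx um per pixel, default 10 (a 1000 x 1000 um scene).
#' @param dt ms per frame, default 20 (one pixel of travel per frame at
#'   0.5 mm/s).
#' @param duration_ms movie length, ms.
#' @param pre_ms background-only baseline before the stimulus enters, ms.
#' @param speed background translation speed, mm/s.
#' @param stim_speed object speed, mm/s (default 1; predators move relative
#'   to the flow).
#' @param stim_diameter_um diameter of the textured stimulus disc, um.
#' @param mask logical; draw the occluder.
#' @param mask_boundary_um mean x-position of the mask silhouette, um.
#' @param boundary_jitter_um SD of the smooth per-row silhouette jitter, um.
#' @param bg_mean,bg_sd background luminance statistics.
#' @param scales_px Gaussian smoothing scales (SD in pixels, octave-spaced)
#'   of the multi-scale texture used for background/mask/stimulus; equal
#'   variance per scale gives a natural-scene-like 1/f amplitude spectrum.
#' @param stim_fill fraction of the disc envelope filled by the silhouette
#'   (default 0.5; 1 gives a solid disc).
#' @param stim_fill_scale_px correlation scale of the silhouette's patchy
#'   fill, pixels.
#' @param bg_translate if `TRUE` (default) the background streams at `speed`
#'   behind the static occluder, as in head-motion footage of natural scenes;
#'   `FALSE` freezes the background.
#' @param seed integer seed; the same seed yields a bit-identical movie.
#' @param stim_seed optional separate seed for the stimulus texture. In
#'   background-permutation ensembles the moving object is one fixed
#'   "predator" whose texture must not change from trial to trial while the
#'   background and mask silhouette are redrawn; pass a fixed `stim_seed` for
#'   that design. `NULL` (default) draws the stimulus from the main seed's
#'   stream.
#' @return a 2-D [stimulus_movie()] with label `"natural_movie"`. `meta`
#'   carries `emergence_site` (um, `c(x, y)` of first stimulus appearance),
#'   `appearance_time` (matrix, ms at which the visible stimulus first covers
#'   each pixel; `Inf` where it never does), `mask_boundary_um`, and the
#'   trajectory parameters.
#' @export
make_synthetic_natural_movie <- function(n_px = 100, dx = 10, dt = 20,
                                         duration_ms = 1600, pre_ms = 200,
                                         speed = 0.5, stim_speed = 1,
                                         stim_diameter_um = 300,
                                         mask = TRUE,
                                         mask_boundary_um = 500,
                                         boundary_jitter_um = 30,
                                         bg_mean = 128, bg_sd = 30,
                                         scales_px = c(2, 5, 12, 30),
                                         stim_fill = 0.5,
                                         stim_fill_scale_px = 3,
                                         bg_translate = TRUE,
                                         seed = 1, stim_seed = NULL) {
  set.seed(seed)
  nt <- round(duration_ms / dt)
  shift_px <- if (bg_translate) as.integer(round(speed * dt / dx)) else 0L
  nxw <- n_px + shift_px * (nt - 1)
  # drawn first so a translating-background movie from the same seed shares
  # this exact field (paired conditions)
  wide <- smooth_noise_field(n_px, nxw, scales_px, bg_mean, bg_sd)
  # occluder texture & silhouette (per-row boundary, smoothed random walk)
  mask_tex <- smooth_noise_field(n_px, n_px, scales_px, bg_mean, bg_sd)
  jit <- stats::filter(stats::rnorm(n_px), rep(1 / 9, 9), sides = 2,
                       circular = TRUE)
  jit <- as.numeric(jit) / stats::sd(jit) * boundary_jitter_um
  jit <- jit - mean(jit)
  # the silhouette is flat where the object emerges, so the emergence time
  # and site are set by mask_boundary_um exactly
  y_c <- n_px %/% 2 + 1L            # trajectory row (pixel index)
  r_rows <- abs(seq_len(n_px) - y_c) * dx <= stim_diameter_um / 2 + dx
  jit[r_rows] <- 0
  boundary_um <- mask_boundary_um + jit              # per row (y)
  # stimulus: an irregular predator-like silhouette inside a disc envelope,
  # textured with pixel mean 2 SD above the background mean; a patchy fill
  # (wings, limbs, gaps) keeps the object from fully tiling an RF center
  r_px <- stim_diameter_um / 2 / dx
  dd <- ceiling(2 * r_px) + 3
  stim_scales <- scales_px[scales_px <= dd]
  draw_stim <- function() {
    tex <- smooth_noise_field(dd, dd, stim_scales, bg_mean + 2 * bg_sd,
                              bg_sd)
    fill <- smooth_noise_once(dd, dd, max(2, round(stim_fill_scale_px)))
    list(tex = tex, fill = fill >= stats::quantile(fill, 1 - stim_fill))
  }
  stim <- if (is.null(stim_seed)) draw_stim()
          else withr_seed(stim_seed, draw_stim())
  stim_tex <- stim$tex
  cy0 <- (dd + 1) / 2
  in_disc <- (outer(seq_len(dd) - cy0, seq_len(dd) - cy0,
                    function(a, b) sqrt(a^2 + b^2)) <= r_px) & stim$fill
  x_um <- (seq_len(n_px) - 1) * dx
  mask_px <- if (mask) {
    outer(boundary_um, x_um, function(b, x) x < b)  # ny x nx logical
  } else matrix(FALSE, n_px, n_px)
  # trajectory: disc centre starts so the disc is fully inside the frame
  x_start <- stim_diameter_um / 2   # um
  frames <- array(0, dim = c(n_px, n_px, nt))
  appearance <- matrix(Inf, n_px, n_px)
  first_app <- NULL
  for (k in seq_len(nt)) {
    tt <- (k - 1) * dt
    f <- wide[, (k - 1) * shift_px + seq_len(n_px)]
    if (tt >= pre_ms) {
      xc_um <- x_start + stim_speed * (tt - pre_ms)
      xc_px <- 1 + xc_um / dx
      xs <- round(xc_px - cy0) + seq_len(dd)
      ys <- (y_c - round(cy0) ) + seq_len(dd)
      ok_x <- xs >= 1 & xs <= n_px
      ok_y <- ys >= 1 & ys <= n_px
      sub <- in_disc[ok_y, ok_x, drop = FALSE]
      f_block <- f[ys[ok_y], xs[ok_x], drop = FALSE]
      t_block <- stim_tex[ok_y, ok_x, drop = FALSE]
      f_block[sub] <- t_block[sub]
      f[ys[ok_y], xs[ok_x]] <- f_block
      # occluder drawn on top
      if (mask) f[mask_px] <- mask_tex[mask_px]
      vis <- matrix(FALSE, n_px, n_px)
      vis[ys[ok_y], xs[ok_x]] <- sub
      vis <- vis & !mask_px
      newly <- vis & !is.finite(appearance)
      if (any(newly)) {
        appearance[newly] <- tt
        if (is.null(first_app)) {
          w <- which(newly, arr.ind = TRUE)
          # emergence site: leftmost newly visible column, centroid row
          j <- min(w[, 2])
          first_app <- c(x = (j - 1) * dx,
                         y = (mean(w[w[, 2] == j, 1]) - 1) * dx)
        }
      }
    } else if (mask) {
      f[mask_px] <- mask_tex[mask_px]
    }
    frames[, , k] <- f
  }
  stimulus_movie(frames, dx, dt, background = bg_mean,
                 condition_label = "natural_movie",
                 meta = list(emergence_site = first_app,
                             appearance_time = appearance,
                             mask = mask,
                             mask_boundary_um = mask_boundary_um,
                             boundary_um = boundary_um,
                             pre_ms = pre_ms, speed = speed,
                             stim_speed = stim_speed,
                             stim_diameter_um = stim_diameter_um,
                             bg_translate = bg_translate,
                             wide_field = wide, shift_px = shift_px,
                             mask_px = mask_px, mask_tex = mask_tex,
                             seed = seed))
}

#' Translating naturalistic background (continuous global motion)
#'
#' The mask-absent counterpart of [make_synthetic_natural_movie()] in the
#' novel-object analyses: no object and no occluder, just the textured
#' background translating horizontally at `speed` mm/s — the optic-flow-like
#' input produced by continuous motion of the whole scene. A wide background
#' field is drawn once and a `n_px`-wide window slides across it.
#'
#' @inheritParams make_synthetic_natural_movie
#' @return a 2-D [stimulus_movie()] with label `"natural_movie"`; `meta`
#'   carries the full `wide_field` and the per-frame `shift_px`, so the
#'   illumination of the translated scene can be computed once on the wide
#'   field and read out by translation.
#' @export
make_translating_background <- function(n_px = 100, dx = 10, dt = 20,
                                        duration_ms = 1600, speed = 0.5,
                                        bg_mean = 128, bg_sd = 30,
                                        scales_px = c(2, 5, 12, 30),
                                        seed = 1) {
  set.seed(seed)
  nt <- round(duration_ms / dt)
  shift_px <- speed * dt / dx
  if (abs(shift_px - round(shift_px)) > 1e-9)
    stop("speed, dt, dx must give a whole-pixel shift per frame")
  shift_px <- as.integer(round(shift_px))
  nxw <- n_px + shift_px * (nt - 1)
  wide <- smooth_noise_field(n_px, nxw, scales_px, bg_mean, bg_sd)
  frames <- array(0, dim = c(n_px, n_px, nt))
  for (k in seq_len(nt))
    frames[, , k] <- wide[, (k - 1) * shift_px + seq_len(n_px)]
  stimulus_movie(frames, dx, dt, background = bg_mean,
                 condition_label = "natural_movie",
                 meta = list(wide_field = wide, shift_px = shift_px,
                             speed = speed, seed = seed, translating = TRUE))
}

#' Write / read a stimulus movie as multi-page TIFF plus JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages (one page per frame); the
#' sidecar (`<path>.json`) records geometry, background, masks and label.
#'
#' @param movie a [stimulus_movie()].
#' @param path output TIFF path.
#' @return `path`, invisibly (writer); the reconstructed movie (reader).
#' @export
write_stimulus_movie <- function(movie, path) {
  d <- dim(movie$frames)
  nt <- d[length(d)]
  # TIFF stores [0, 1]; luminance is affinely packed and the range recorded
  lo <- min(movie$frames); hi <- max(movie$frames)
  scl <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(nt), function(k) {
    f <- if (length(d) == 2L) matrix(movie$frames[, k], d[1], 1)
         else movie$frames[, , k]
    (f - lo) / scl
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  side <- list(dx = movie$dx, dt = movie$dt, background = movie$background,
               mask_regions = movie$mask_regions,
               condition_label = movie$condition_label,
               range_lo = lo, range_scale = scl,
               space_dims = if (length(d) == 2L) 1L else 2L)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stimulus_movie
#' @export
read_stimulus_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  masks <- lapply(seq_len(NROW(side$mask_regions)), function(i)
    as.numeric(side$mask_regions[i, ]))
  if (side$space_dims == 1L) {
    frames <- vapply(pages, function(p) as.numeric(p[, 1]),
                     numeric(nrow(pages[[1]])))
  } else {
    frames <- array(unlist(pages),
                    dim = c(dim(pages[[1]]), length(pages)))
  }
  frames <- frames * side$range_scale + side$range_lo
  stimulus_movie(frames, side$dx, side$dt, background = side$background,
                 mask_regions = masks, condition_label = side$condition_label)
}
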