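#' Kinetic response template
#'
#' Canonical glutamate-release waveform used by the synthetic imaging
#' generator: a sigmoidal rising phase followed by exponential relaxation
#' toward a sustained plateau during the stimulus, and exponential decay to
#' baseline after stimulus offset. A `sustain_frac` near 0 gives a transient
#' response (high transiency index), near 1 a sustained plateau (TI near 0).
#'
#' @param t_ms evaluation times, ms.
#' @param onset response onset, ms.
#' @param rise_t50 time from onset to the sigmoid midpoint, ms.
#' @param rise_slope sigmoid slope parameter, ms.
#' @param decay_tau decay time constant, ms.
#' @param amplitude peak dF/F.
#' @param sustain_frac plateau level as a fraction of the peak, in `[0, 1)`.
#' @param stim_dur stimulus duration, ms.
#' @return dF/F at `t_ms`.
#' @export
template_response <- function(t_ms, onset = 0, rise_t50 = 100,
                              rise_slope = 15, decay_tau = 300,
                              amplitude = 1, sustain_frac = 0.2,
                              stim_dur = 2000) {
  t_peak <- onset + rise_t50 + 4 * rise_slope
  t_off <- onset + stim_dur
  sig <- 1 / (1 + exp(-(t_ms - onset - rise_t50) / rise_slope))
  dec <- sustain_frac + (1 - sustain_frac) *
    exp(-pmax(0, pmin(t_ms, t_off) - t_peak) / decay_tau)
  env <- sig * dec
  off <- t_ms > t_off
  if (any(off)) {
    sig_o <- 1 / (1 + exp(-(t_off - onset - rise_t50) / rise_slope))
    dec_o <- sustain_frac + (1 - sustain_frac) *
      exp(-max(0, t_off - t_peak) / decay_tau)
    env[off] <- sig_o * dec_o * exp(-(t_ms[off] - t_off) / decay_tau)
  }
  amplitude * env
}

#' Generate functional cluster templates
#'
#' Draws `k` kinetic templates whose rise times, decay constants, plateau
#' fractions and amplitudes are spread across the given ranges (evenly spaced
#' anchor points plus seeded jitter), guaranteeing at least one transient
#' (low plateau) and one sustained (high plateau) member. Motion conditions
#' are rendered with per-template multiplicative modifiers for the peak and
#' the rise time, so motion and stationary kinetics differ by a controlled
#' ground truth.
#'
#' @param k number of templates (>= 2).
#' @param seed integer seed.
#' @param rise_range,decay_range,amp_range,sustain_range,delay_range
#'   parameter ranges (`delay_range`: onset latency, ms).
#' @param polarity `"ON"` or `"OFF"` recycled over templates.
#' @return list of `cluster_template` objects (plain lists with a `ti_target`
#'   computed from the rendered noiseless waveform).
#' @export
make_cluster_templates <- function(k, seed = 1,
                                   rise_range = c(40, 320),
                                   decay_range = c(80, 700),
                                   amp_range = c(0.5, 1.5),
                                   sustain_range = c(0.02, 0.9),
                                   delay_range = c(0, 150),
                                   polarity = "ON") {
  stopifnot(k >= 2)
  if (diff(rise_range) <= 0 || diff(decay_range) <= 0 ||
      diff(sustain_range) <= 0)
    stop("degenerate parameter ranges")
  draw_once <- function() {
    spread <- function(rng) {
      anchors <- seq(rng[1], rng[2], length.out = k)
      jitter <- stats::runif(k, -1, 1) * diff(rng) / (4 * k)
      pmin(pmax(anchors + jitter, rng[1]), rng[2])
    }
    rise <- spread(rise_range)
    decay <- sample(spread(decay_range))
    amp <- sample(seq(amp_range[1], amp_range[2], length.out = k))
    sustain <- spread(sustain_range)
    delay <- sample(seq(delay_range[1], delay_range[2], length.out = k))
    slope <- sample(spread(c(8, 55)))
    pol <- rep_len(polarity, k)
    lapply(seq_len(k), function(i) {
      tm <- list(id = i, polarity = pol[i], rise_t50 = rise[i],
                 rise_slope = slope[i], decay_tau = decay[i],
                 amplitude = amp[i], sustain_frac = sustain[i],
                 onset_delay = delay[i],
                 motion_peak_mult = stats::runif(1, 0.6, 1.0),
                 motion_rise_mult = stats::runif(1, 1.5, 3.0))
      t_ms <- seq(0, 2000, by = 10)
      w <- template_response(t_ms, 0, tm$rise_t50, tm$rise_slope,
                             tm$decay_tau, tm$amplitude, tm$sustain_frac,
                             2000)
      tm$ti_target <- transiency_index(w)
      class(tm) <- "cluster_template"
      tm
    })
  }
  # functional types must be distinguishable within the 1-s analysis
  # window used for clustering: keep the most separated of several draws
  sep_of <- function(tms) {
    t_ms <- seq(0, 1000, by = 10)
    w <- vapply(tms, function(x)
      template_response(t_ms, x$onset_delay, x$rise_t50, x$rise_slope,
                        x$decay_tau, x$amplitude, x$sustain_frac, 2000),
      numeric(length(t_ms)))
    cc <- stats::cor(w)
    -max(cc[upper.tri(cc)])
  }
  withr_seed(seed, {
    best <- NULL; best_sep <- -Inf
    for (i in seq_len(60)) {
      cand <- draw_once()
      s <- sep_of(cand)
      if (s > best_sep) { best <- cand; best_sep <- s }
      if (-best_sep <= 0.85) break
    }
    best
  })
}

#' Stimulus-condition battery for imaging experiments
#'
#' The standard condition set presented during synthetic imaging: full-field
#' flash, masked flash, full-field motion in both directions, emerging and
#' exiting motion, and (optionally) sequential and shuffled apparent motion.
#' Each condition occupies one time segment; motion segments carry the bar
#' speed so response onsets can be shifted by RF position.
#'
#' @param seg_ms segment length, ms.
#' @param pre_ms pre-stimulus baseline within each segment, ms.
#' @param stim_dur stimulus (flash) duration, ms.
#' @param speed bar speed for motion conditions, mm/s.
#' @param include_apparent include the apparent-motion conditions.
#' @return data.frame with one row per condition: `condition`, `type`
#'   (`flash`/`motion`), `direction`, `masked`, `start_ms`, `onset_ms`
#'   (stimulus onset within the segment), `dur_ms`, `speed`.
#' @export
make_condition_battery <- function(seg_ms = 4000, pre_ms = 500,
                                   stim_dur = 2000, speed = 0.5,
                                   include_apparent = FALSE) {
  conds <- data.frame(
    condition = c("flash_full", "flash_masked", "motion_right",
                  "motion_left", "motion_emerging", "motion_exiting"),
    type = c("flash", "flash", "motion", "motion", "motion", "motion"),
    direction = c(NA, NA, "right", "left", "right", "left"),
    masked = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  if (include_apparent) {
    conds <- rbind(conds, data.frame(
      condition = c("apparent_sequential", "apparent_shuffled"),
      type = "apparent", direction = c("right", NA),
      masked = FALSE))
  }
  n <- nrow(conds)
  conds$start_ms <- (seq_len(n) - 1) * seg_ms
  conds$onset_ms <- pre_ms
  conds$dur_ms <- stim_dur
  conds$seg_ms <- seg_ms
  conds$speed <- speed
  conds
}

#' Non-overlapping ROI patch layout
#'
#' Places `n_rois` square pixel patches on a regular grid inside the imaging
#' field and assigns each one a template (round-robin) and an RF position
#' taken from the patch center.
#'
#' @param n_rois number of patches.
#' @param n_templates number of available templates.
#' @param field_px field size, pixels (square).
#' @param patch_px patch side, pixels.
#' @param um_per_px microns per pixel.
#' @param seed seed for the template-to-patch shuffle.
#' @return data.frame with patch corners, template id, and `rf_x_um`.
#' @export
make_roi_layout <- function(n_rois, n_templates, field_px = 32, patch_px = 4,
                            um_per_px = 1.28, seed = 1) {
  per_row <- (field_px - 2) %/% (patch_px + 2)
  if (per_row^2 < n_rois) stop("field too small for the requested patches")
  slots <- expand.grid(gx = seq_len(per_row), gy = seq_len(per_row))
  slots <- slots[seq_len(n_rois), ]
  # odd offsets keep patches aligned with 2x2 preprocessing blocks
  x0 <- (slots$gx - 1) * (patch_px + 2) + 3
  y0 <- (slots$gy - 1) * (patch_px + 2) + 3
  tmpl <- withr_seed(seed, {
    sample(rep_len(seq_len(n_templates), n_rois))
  })
  data.frame(roi = seq_len(n_rois), template = tmpl,
             x0 = x0, y0 = y0, w = patch_px, h = patch_px,
             rf_x_um = (x0 + patch_px / 2 - field_px / 2) * um_per_px)
}

#' Render a synthetic iGluSnFR-style imaging movie
#'
#' Builds a pixels-by-time raw-fluorescence movie for a condition battery:
#' each pixel inside an ROI patch follows its template's waveform (onset
#' shifted by RF position for motion conditions at `speed` mm/s; motion peak
#' and rise modified by the template's motion multipliers; masked motion
#' conditions use the emerging/exiting modifier conventions), background
#' pixels are silent, and seeded Gaussian noise of SD `noise_sd` (dF/F units)
#' is added everywhere. Raw fluorescence is `f0 * (1 + dFF)`.
#'
#' Emerging motion is rendered as a faster, larger response (stationary-like
#' kinetics); exiting motion as established motion, matching the ground-truth
#' convention that novelty responses resemble flashes.
#'
#' @param templates list from [make_cluster_templates()].
#' @param layout data.frame from [make_roi_layout()].
#' @param battery data.frame from [make_condition_battery()].
#' @param field_px field size, px.
#' @param um_per_px microns per pixel.
#' @param dt_ms frame interval, ms (default 20, i.e. 50 Hz).
#' @param noise_sd pixel noise SD in dF/F units.
#' @param roi_jitter within-type kinetic heterogeneity: each ROI's rise time,
#'   decay constant and plateau fraction are scaled by seeded multiplicative
#'   factors of SD `roi_jitter` (functional types are families of similar,
#'   not identical, cells; this also keeps the across-experiment distance
#'   geometry non-degenerate).
#' @param f0 baseline fluorescence (a.u.).
#' @param n_repeats number of stacked protocol repeats.
#' @param seed integer seed.
#' @return list with `movie` (an `imaging_movie`: raw fluorescence array
#'   `ny x nx x t` with attributes `dt_ms`, `um_per_px`, `segments`,
#'   `n_repeats`) and `manifest` (ground truth: pixel-to-template label
#'   image, layout, templates, noise, seed).
#' @export
render_imaging_movie <- function(templates, layout,
                                 battery = make_condition_battery(),
                                 field_px = 32, um_per_px = 1.28,
                                 dt_ms = 20, noise_sd = 0.05,
                                 roi_jitter = 0.02, f0 = 100,
                                 n_repeats = 1, seed = 1) {
  # patches must not overlap
  occ <- matrix(0L, field_px, field_px)
  for (i in seq_len(nrow(layout))) {
    ys <- layout$y0[i] + seq_len(layout$h[i]) - 1
    xs <- layout$x0[i] + seq_len(layout$w[i]) - 1
    if (any(occ[ys, xs] != 0L)) stop("overlapping ROI patches")
    occ[ys, xs] <- layout$roi[i]
  }
  label_px <- matrix(0L, field_px, field_px)
  tmpl_px <- matrix(0L, field_px, field_px)
  for (i in seq_len(nrow(layout))) {
    ys <- layout$y0[i] + seq_len(layout$h[i]) - 1
    xs <- layout$x0[i] + seq_len(layout$w[i]) - 1
    label_px[ys, xs] <- layout$roi[i]
    tmpl_px[ys, xs] <- layout$template[i]
  }
  total_ms <- max(battery$start_ms + battery$seg_ms)
  nt <- round(total_ms / dt_ms)
  t_ms <- (seq_len(nt) - 1) * dt_ms
  field_um <- field_px * um_per_px
  dff_roi <- matrix(0, nrow(layout), nt)
  jit <- withr_seed(seed * 7 + 1, matrix(stats::rnorm(nrow(layout) * 3,
                                                      1, roi_jitter),
                                         nrow(layout), 3))
  jit[] <- pmax(jit, 0.5)
  for (i in seq_len(nrow(layout))) {
    tm <- templates[[layout$template[i]]]
    tm$rise_t50 <- tm$rise_t50 * jit[i, 1]
    tm$decay_tau <- tm$decay_tau * jit[i, 2]
    tm$sustain_frac <- min(tm$sustain_frac * jit[i, 3], 0.95)
    tr <- numeric(nt)
    for (j in seq_len(nrow(battery))) {
      b <- battery[j, ]
      seg <- t_ms >= b$start_ms & t_ms < b$start_ms + b$seg_ms
      onset <- b$start_ms + b$onset_ms + tm$onset_delay
      amp <- tm$amplitude; rise <- tm$rise_t50
      if (b$type == "motion") {
        # bar enters the field edge at onset and sweeps across it
        offset_um <- if (identical(b$direction, "left"))
          field_um / 2 - layout$rf_x_um[i]
        else layout$rf_x_um[i] + field_um / 2
        onset <- onset + offset_um / b$speed
        novel <- isTRUE(b$masked) && b$condition == "motion_emerging"
        if (!novel) {
          amp <- amp * tm$motion_peak_mult
          rise <- rise * tm$motion_rise_mult
        }
      }
      tr[seg] <- tr[seg] +
        template_response(t_ms[seg], onset, rise, tm$rise_slope,
                          tm$decay_tau, amp, tm$sustain_frac, b$dur_ms)
    }
    dff_roi[i, ] <- tr
  }
  set.seed(seed)
  rep_list <- lapply(seq_len(n_repeats), function(r) {
    arr <- array(0, dim = c(field_px, field_px, nt))
    noise <- array(stats::rnorm(field_px * field_px * nt, sd = noise_sd),
                   dim = dim(arr))
    for (i in seq_len(nrow(layout))) {
      ys <- layout$y0[i] + seq_len(layout$h[i]) - 1
      xs <- layout$x0[i] + seq_len(layout$w[i]) - 1
      arr[ys, xs, ] <- rep(dff_roi[i, ], each = length(ys) * length(xs))
    }
    f0 * (1 + arr + noise)
  })
  movie <- structure(list(data = rep_list, dt_ms = dt_ms,
                          um_per_px = um_per_px, segments = battery,
                          n_repeats = n_repeats, kind = "raw"),
                     class = "imaging_movie")
  manifest <- list(label_px = label_px, template_px = tmpl_px,
                   layout = layout, templates = templates,
                   roi_jitter = jit, noise_sd = noise_sd, f0 = f0,
                   dt_ms = dt_ms,
                   um_per_px = um_per_px, seed = seed, battery = battery)
  list(movie = movie, manifest = manifest)
}

#' @export
print.imaging_movie <- function(x, ...) {
  d <- dim(if (is.list(x$data)) x$data[[1]] else x$data)
  cat(sprintf("<imaging_movie (%s): %d x %d px x %d frames @ %g ms, %d repeat(s)>\n",
              x$kind, d[1], d[2], d[3], x$dt_ms,
              if (is.list(x$data)) length(x$data) else 1L))
  invisible(x)
}
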