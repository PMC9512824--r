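#' Discretize peak responses to integer bins
#'
#' Rounds peak amplitudes to the nearest integer (half away from zero);
#' negative values clamp to 0, matching the convention that rectified peak
#' responses span 0 to about 200 a.u.
#'
#' @param peaks numeric peak amplitudes.
#' @return integer bins.
#' @export
discretize_peaks <- function(peaks) {
  stopifnot(all(is.finite(peaks)))
  as.integer(floor(pmax(peaks, 0) + 0.5))
}

#' Plug-in entropy
#'
#' Maximum-likelihood (plug-in) entropy `-sum p log2 p` over the observed
#' symbol frequencies, without bias correction.
#'
#' @param symbols vector of discrete symbols (any atomic type).
#' @return entropy in bits.
#' @export
entropy_bits <- function(symbols) {
  if (length(symbols) == 0L) stop("empty sample")
  p <- table(symbols) / length(symbols)
  -sum(p * log2(p))
}

#' Plug-in mutual information between condition and response
#'
#' `I = H(VS) - H(VS | R)` estimated from the joint contingency of discrete
#' responses and condition labels, with empirical condition priors.
#' Responses are discretized with [discretize_peaks()] unless already
#' integer-valued.
#'
#' @param conditions condition label per trial (e.g. mask present/absent).
#' @param responses response per trial (peak amplitudes or integer bins).
#' @return mutual information in bits (0, with a warning, if only one
#'   condition is present).
#' @export
mutual_information <- function(conditions, responses) {
  stopifnot(length(conditions) == length(responses))
  if (length(unique(conditions)) < 2L) {
    warning("single condition present; MI = 0")
    return(0)
  }
  r <- if (is.numeric(responses) && !all(responses == round(responses)))
    discretize_peaks(responses) else responses
  n <- length(r)
  joint <- table(conditions, r) / n
  h_vs <- entropy_bits(conditions)
  h_joint <- -sum(joint[joint > 0] * log2(joint[joint > 0]))
  h_r <- entropy_bits(r)
  # H(VS|R) = H(VS,R) - H(R)
  h_vs - (h_joint - h_r)
}

#' Select cells near the stimulus-emergence site
#'
#' @param positions data.frame with `x`, `y` (um) or matrix of positions.
#' @param emergence_site numeric `c(x, y)`, um.
#' @param radius inclusion radius, um (default 100; strict `<`).
#' @return integer indices of the selected cells (error if none).
#' @export
select_emergence_cells <- function(positions, emergence_site, radius = 100) {
  if (is.data.frame(positions)) {
    x <- positions$x; y <- positions$y
  } else {
    x <- positions[, 1]; y <- positions[, 2]
  }
  d <- sqrt((x - emergence_site[1])^2 + (y - emergence_site[2])^2)
  idx <- which(d < radius)
  if (!length(idx)) stop("no cells within radius of the emergence site")
  idx
}

# analytic per-cell response-window start: the time the (visible) stimulus
# disc first reaches within `reach` of the cell. In the masked condition the
# window cannot start before the emergence time.
window_starts <- function(cells_x, cells_y, movie_meta, reach, masked) {
  v <- movie_meta$stim_speed         # um/ms
  pre <- movie_meta$pre_ms
  r <- movie_meta$stim_diameter_um / 2
  x0 <- r                            # disc centre start
  y_traj <- movie_meta$traj_y_um
  dy <- cells_y - y_traj
  rr2 <- (r + reach)^2 - dy^2
  t_reach <- ifelse(rr2 >= 0,
                    pre + (cells_x - sqrt(pmax(rr2, 0)) - x0) / v,
                    Inf)
  t_reach <- pmax(t_reach, pre)
  if (masked) {
    t_e <- pre + (movie_meta$mask_boundary_um - r - x0) / v
    t_reach <- pmax(t_reach, t_e)
  }
  t_reach
}

#' Paired mask-on/mask-off response ensemble under naturalistic movies
#'
#' The core driver for novel-object information analyses. Each trial draws a
#' fresh naturalistic background (and mask silhouette) and renders three
#' conditions of the same scene: `masked` — the background streams at
#' 0.5 mm/s behind a static occluder, from behind which a textured object
#' (the "predator") emerges and crosses the scene; `flow` — the identical
#' streaming background with no occluder and no object (the input produced by
#' continuous motion of the whole scene, the mask-absent condition of the
#' information analysis); and `unmasked` — the identical object trajectory
#' with the occluder removed (the reference for the emerging-motion
#' enhancement profile, where the object arrives as established motion). All
#' three share one wide background field per trial; only the background,
#' silhouette (and, by default, object instance) are redrawn across trials.
#' The linear center-surround population is simulated on the pixel lattice
#' and per-cell peak responses are taken in a 500-ms window starting when the
#' (visible) object first reaches the cell (the same window times are applied
#' to the object-free flow condition), for every requested surround factor at
#' once (center and surround activations are shared across factors).
#'
#' Peaks are kept in full for cells near the stimulus-emergence site (the
#' input to [mutual_information()]); for cells along the motion axis only
#' running mean/SD of the masked-unmasked difference are accumulated (the
#' input to [enhancement_vs_distance()]).
#'
#' @param n_trials number of paired background permutations.
#' @param factors surround/center intensity ratios to evaluate.
#' @param params a [linear_rf_params()]; `factor_surround` is ignored in
#'   favour of `factors`.
#' @param radius_um emergence-cell inclusion radius, um (strict `<`).
#' @param window_ms response-window length, ms.
#' @param profile_halfband_um half-height of the row band used for the
#'   distance profile, um.
#' @param movie_args extra arguments passed to
#'   [make_synthetic_natural_movie()].
#' @param seed integer seed; trial b uses seed `seed * 1e4 + b` for its
#'   scene draw.
#' @param fixed_stimulus if `TRUE`, one object texture is drawn once and
#'   reused across all trials (a single predator image); if `FALSE`
#'   (default), each trial draws its own object instance from the same
#'   2-SD-above-background distribution, emulating stimuli taken from
#'   different predator frames.
#' @param progress print a progress line every 100 trials.
#' @return an object of class `novelty_ensemble`: list with `peaks` (array
#'   `cells x trials x factors x condition`, conditions
#'   `masked`/`flow`/`unmasked`),
#'   `cells` (data.frame with positions and distance to the emergence site),
#'   `profile` (per-cell running sums by factor and condition),
#'   `emergence_site`, `factors`, and the generator settings.
#' @export
novelty_ensemble <- function(n_trials = 1000, factors = c(0, 0.5),
                             params = linear_rf_params(),
                             radius_um = 100, window_ms = 500,
                             profile_halfband_um = 30,
                             movie_args = list(), seed = 1,
                             fixed_stimulus = FALSE,
                             progress = FALSE) {
  ma <- utils::modifyList(list(n_px = 100, dx = 10, dt = 20,
                               duration_ms = 1600, pre_ms = 200, speed = 0.5,
                               stim_speed = 1,
                               stim_diameter_um = 300,
                               mask_boundary_um = 500,
                               boundary_jitter_um = 30,
                               bg_mean = 128, bg_sd = 30,
                               scales_px = c(2, 5, 12, 30)),
                          movie_args)
  n_px <- ma$n_px; dx <- ma$dx
  y_traj <- (n_px %/% 2) * dx   # trajectory row (0-based um)
  site <- c(x = ma$mask_boundary_um, y = y_traj)
  # pixel lattice positions, column-major over [y, x]
  pos <- expand.grid(y = (seq_len(n_px) - 1) * dx,
                     x = (seq_len(n_px) - 1) * dx)
  dist_site <- sqrt((pos$x - site[1])^2 + (pos$y - site[2])^2)
  reach <- params$center_halfwidth
  emer_idx <- which(dist_site < radius_um & pos$x >= site[1])
  band_idx <- which(abs(pos$y - y_traj) <= profile_halfband_um &
                      pos$x >= site[1])
  keep <- sort(unique(c(emer_idx, band_idx)))
  meta0 <- list(stim_speed = ma$stim_speed, pre_ms = ma$pre_ms,
                stim_diameter_um = ma$stim_diameter_um,
                mask_boundary_um = ma$mask_boundary_um, traj_y_um = y_traj)
  # drop cells whose full response window does not fit in the movie
  lo_m <- window_starts(pos$x[keep], pos$y[keep], meta0, reach, TRUE)
  feasible <- is.finite(lo_m) & lo_m + window_ms <= ma$duration_ms
  keep <- keep[feasible]
  cells <- data.frame(idx = keep, x = pos$x[keep], y = pos$y[keep],
                      dist_site = dist_site[keep],
                      is_emergence = keep %in% emer_idx,
                      in_band = keep %in% band_idx)
  nm <- length(keep); nfac <- length(factors)
  lo <- window_starts(cells$x, cells$y, meta0, reach, TRUE)
  w_mask <- list(lo = as.integer(round(lo)),
                 hi = as.integer(round(lo + window_ms)))
  n_emer <- sum(cells$is_emergence)
  conds <- c("masked", "flow", "unmasked")
  peaks <- array(NA_real_, dim = c(n_emer, n_trials, nfac, 3),
                 dimnames = list(NULL, NULL, paste0("f", factors), conds))
  prof_sum <- prof_sumsq <- array(0, dim = c(nm, nfac, 3),
                                  dimnames = list(NULL, NULL, conds))
  swr <- params$surround_weight_ratio
  peaks_of <- function(ic, is_, w) {
    pk <- cpp_lrf_peaks(ic, is_, params$tau_center, params$tau_surround,
                        as.integer(round(ma$dt)), factors * swr,
                        ic[, 1], is_[, 1], w$lo, w$hi)
    pmax(pk, 0)   # rectified peaks
  }
  # both conditions of a pair share one wide translating background field;
  # the mask-present scene differs from the pure flow only inside the
  # occluder and object regions, so its illumination is the translated
  # wide-field illumination plus a small per-frame difference convolution
  nt_frames <- round(ma$duration_ms / ma$dt)
  cell_iy <- round(cells$y / dx) + 1L
  cell_ix <- round(cells$x / dx) + 1L
  mode <- params$halfwidth_mode
  m1c <- lattice_mass_1d(params$center_halfwidth, dx, mode)
  m1s <- lattice_mass_1d(params$surround_halfwidth, dx, mode)
  win_w <- function(hw, m1) {
    xo <- (seq_len(n_px) - 1) * dx
    outer(xo, xo, function(a, b) spatial_weight(a - b, hw, mode)) / m1
  }
  Wc <- win_w(params$center_halfwidth, m1c)
  Ws <- win_w(params$surround_halfwidth, m1s)
  run_trial <- function(m_on, m_open) {
    wf <- m_on$meta$wide_field
    sh <- m_on$meta$shift_px
    one <- function(hw, W) {
      iw <- illum_field(wf, dx, ma$bg_mean, hw, mode)
      flow <- matrix(0, nm, nt_frames)
      on <- matrix(0, nm, nt_frames)
      open <- matrix(0, nm, nt_frames)
      corr_of <- function(frame, base_win) {
        dif <- frame - base_win
        nz <- which(dif != 0, arr.ind = TRUE)
        if (nrow(nz) == 0) return(0)
        r <- range(nz[, 1]); cc <- range(nz[, 2])
        rows <- r[1]:r[2]; cols <- cc[1]:cc[2]
        corr <- W[, rows, drop = FALSE] %*%
          dif[rows, cols, drop = FALSE] %*% t(W[, cols, drop = FALSE])
        corr[cbind(cell_iy, cell_ix)]
      }
      for (k in seq_len(nt_frames)) {
        base <- iw[cbind(cell_iy, cell_ix + (k - 1L) * sh)]
        base_win <- wf[, (k - 1L) * sh + seq_len(n_px), drop = FALSE]
        flow[, k] <- base
        on[, k] <- base + corr_of(m_on$frames[, , k], base_win)
        open[, k] <- base + corr_of(m_open$frames[, , k], base_win)
      }
      list(on = on, flow = flow, open = open)
    }
    ic <- one(params$center_halfwidth, Wc)
    is_ <- one(params$surround_halfwidth, Ws)
    list(on = peaks_of(ic$on, is_$on, w_mask),
         flow = peaks_of(ic$flow, is_$flow, w_mask),
         open = peaks_of(ic$open, is_$open, w_mask))
  }
  stim_seed <- if (fixed_stimulus) seed * 10000 else NULL
  for (b in seq_len(n_trials)) {
    s <- seed * 10000 + b
    m_on <- do.call(make_synthetic_natural_movie,
                    c(ma, list(mask = TRUE, seed = s),
                      if (!is.null(stim_seed)) list(stim_seed = stim_seed)))
    m_open <- do.call(make_synthetic_natural_movie,
                      c(ma, list(mask = FALSE, seed = s),
                        if (!is.null(stim_seed)) list(stim_seed = stim_seed)))
    pr <- run_trial(m_on, m_open)
    pks <- list(pr$on, pr$flow, pr$open)
    for (ci in 1:3) {
      peaks[, b, , ci] <- pks[[ci]][cells$is_emergence, , drop = FALSE]
      prof_sum[, , ci] <- prof_sum[, , ci] + pks[[ci]]
      prof_sumsq[, , ci] <- prof_sumsq[, , ci] + pks[[ci]]^2
    }
    if (progress && b %% 100 == 0)
      message(sprintf("trial %d / %d", b, n_trials))
  }
  structure(list(peaks = peaks, cells = cells, factors = factors,
                 emergence_site = site, n_trials = n_trials,
                 prof_sum = prof_sum, prof_sumsq = prof_sumsq,
                 window_ms = window_ms, radius_um = radius_um,
                 movie_args = ma, params = params, seed = seed,
                 fixed_stimulus = fixed_stimulus),
            class = "novelty_ensemble")
}

#' @export
print.novelty_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<novelty_ensemble: %d paired trials, %d emergence",
                     " cells, factors %s>\n"),
              x$n_trials, sum(x$cells$is_emergence),
              paste(x$factors, collapse = ", ")))
  invisible(x)
}

#' Per-cell novel-object mutual information
#'
#' For one surround factor, computes for every emergence cell the plug-in
#' mutual information between mask condition (present/absent) and the
#' integer-discretized peak response, across the ensemble's paired trials.
#'
#' @param ensemble a [novelty_ensemble()].
#' @param factor surround factor (must be one of `ensemble$factors`).
#' @return list with `per_cell` (bits per cell), `mean`, `sd` (across cells),
#'   and `n_cells`.
#' @export
novelty_mi <- function(ensemble, factor = 0.5) {
  fi <- match(factor, ensemble$factors)
  if (is.na(fi)) stop("factor not in ensemble")
  pk <- ensemble$peaks[, , fi, , drop = FALSE]
  n_cells <- dim(pk)[1]; n_trials <- dim(pk)[2]
  cond <- rep(c("masked", "flow"), each = n_trials)
  per_cell <- vapply(seq_len(n_cells), function(i) {
    resp <- discretize_peaks(c(pk[i, , 1, "masked"], pk[i, , 1, "flow"]))
    mutual_information(cond, resp)
  }, numeric(1))
  list(per_cell = per_cell, mean = mean(per_cell), sd = stats::sd(per_cell),
       n_cells = n_cells)
}

#' Mutual information versus surround strength
#'
#' The surround-intensity sweep: novel-object MI as a function of the
#' surround/center factor, with across-cell SD, and the location of the peak.
#'
#' @param ensemble a [novelty_ensemble()] whose `factors` span the sweep; if
#'   `NULL` one is generated from the remaining arguments.
#' @param factors factor grid (used only when generating).
#' @param n_trials,seed,... passed to [novelty_ensemble()] when generating.
#' @return list with `curve` (data.frame `factor, mi, sd`), and `peak_factor`
#'   (argmax of the mean MI).
#' @export
mi_surround_sweep <- function(ensemble = NULL,
                              factors = seq(0, 1, by = 0.1),
                              n_trials = 200, seed = 1, ...) {
  if (is.null(ensemble))
    ensemble <- novelty_ensemble(n_trials = n_trials, factors = factors,
                                 seed = seed, ...)
  res <- lapply(ensemble$factors, function(f) novelty_mi(ensemble, f))
  curve <- data.frame(factor = ensemble$factors,
                      mi = vapply(res, `[[`, numeric(1), "mean"),
                      sd = vapply(res, `[[`, numeric(1), "sd"))
  list(curve = curve, peak_factor = curve$factor[which.max(curve$mi)],
       ensemble = ensemble)
}

#' Emerging-motion enhancement versus distance from the mask
#'
#' Mean (and across-trial SD, from running moments) change in peak RF
#' activation, mask present minus absent, as a function of cell distance from
#' the mask boundary along the motion axis, and the width over which the mean
#' change exceeds half of its maximum.
#'
#' @param ensemble a [novelty_ensemble()].
#' @param factor surround factor to profile.
#' @return list with `profile` (data.frame `distance_um, mean_change,
#'   sd_change, n_cells`) and `half_max_width_um`.
#' @export
enhancement_vs_distance <- function(ensemble, factor = 0.5) {
  fi <- match(factor, ensemble$factors)
  if (is.na(fi)) stop("factor not in ensemble")
  cells <- ensemble$cells
  band <- cells$in_band
  n <- ensemble$n_trials
  mu_on <- ensemble$prof_sum[band, fi, "masked"] / n
  mu_off <- ensemble$prof_sum[band, fi, "unmasked"] / n
  var_on <- ensemble$prof_sumsq[band, fi, "masked"] / n - mu_on^2
  var_off <- ensemble$prof_sumsq[band, fi, "unmasked"] / n - mu_off^2
  ch <- mu_on - mu_off
  d <- cells$x[band] - ensemble$emergence_site[1]
  agg <- stats::aggregate(
    data.frame(mean_change = ch,
               sd_change = sqrt(pmax(var_on + var_off, 0))),
    by = list(distance_um = d), FUN = mean)
  nc <- as.integer(table(d)[as.character(agg$distance_um)])
  agg$n_cells <- nc
  pk <- max(agg$mean_change)
  width <- if (pk > 0) {
    above <- agg$mean_change >= pk / 2
    # contiguous run containing the maximum
    i0 <- which.max(agg$mean_change)
    lo <- i0; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- i0; while (hi < nrow(agg) && above[hi + 1]) hi <- hi + 1
    agg$distance_um[hi] - agg$distance_um[lo] +
      diff(agg$distance_um[1:2])
  } else NA_real_
  list(profile = agg, half_max_width_um = width)
}

#' Permutation null for novel-object MI
#'
#' Shuffles the condition labels of one cell's trial responses to estimate
#' the null distribution of the plug-in MI (whose finite-sample bias is
#' positive), returning the null mean and the fraction of permutations at or
#' above the observed value.
#'
#' @param conditions,responses as for [mutual_information()].
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return list with `observed`, `null_mean`, `p_value`.
#' @export
mi_permutation_test <- function(conditions, responses, n_perm = 1000,
                                seed = 1) {
  obs <- mutual_information(conditions, responses)
  null <- withr_seed(seed, vapply(seq_len(n_perm), function(i)
    mutual_information(sample(conditions), responses), numeric(1)))
  list(observed = obs, null_mean = mean(null),
       p_value = (sum(null >= obs) + 1) / (n_perm + 1))
}
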