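#' Transiency index
#'
#' Summarises whether a response is a brief peak or a sustained plateau from
#' the peak and mean within the stimulation window. The default form is
#' `TI = 1 - mean/peak`, which is 0 for a rectangular plateau and approaches 1
#' for a single-sample impulse; `form = "peak_over_mean"` returns the raw
#' ratio `peak/mean` (>= 1) instead. Invariant to positive rescaling.
#'
#' @param trace numeric response trace.
#' @param window integer indices of the stimulation window (default: whole
#'   trace).
#' @param form `"one_minus_mean_over_peak"` (default) or `"peak_over_mean"`.
#' @return TI, or `NA` (with a warning) if the in-window peak is not positive.
#' @export
transiency_index <- function(trace, window = seq_along(trace),
                             form = c("one_minus_mean_over_peak",
                                      "peak_over_mean")) {
  form <- match.arg(form)
  v <- trace[window]
  pk <- max(v)
  if (!is.finite(pk) || pk <= 0) {
    warning("non-positive peak; transiency index undefined")
    return(NA_real_)
  }
  m <- mean(v)
  if (form == "one_minus_mean_over_peak") 1 - m / pk else pk / m
}

#' Static edge enhancement
#'
#' Relative increase of the peak response near a mask-stimulus boundary over
#' the full-field response: `r_edge / r_ff - 1`.
#'
#' @param r_edge peak response to the masked (edge) static flash.
#' @param r_ff peak response to the full-field static flash (> 0).
#' @return enhancement fraction (negative = suppression).
#' @export
edge_enhancement <- function(r_edge, r_ff) {
  if (any(r_ff <= 0)) stop("full-field peak must be positive")
  r_edge / r_ff - 1
}

#' Emerging-object enhancement
#'
#' Relative increase of the peak response to motion away from an occluding
#' mask (emergence) over motion toward it: `r_from_edge / r_to_edge - 1`.
#'
#' @param r_from_edge peak response to motion from the mask edge.
#' @param r_to_edge peak response to motion toward the mask edge (> 0).
#' @return enhancement fraction.
#' @export
emerging_enhancement <- function(r_from_edge, r_to_edge) {
  if (any(r_to_edge <= 0)) stop("to-edge peak must be positive")
  r_from_edge / r_to_edge - 1
}

#' Direction selectivity index
#'
#' Normalised magnitude of the vector sum of direction-tagged response peaks:
#' `DSI = |sum_i R_i exp(i theta_i)| / sum_i R_i`. 0 indicates no directional
#' preference; 1, response to a single direction only.
#'
#' @param peaks non-negative peak responses, one per probed direction.
#' @param directions stimulus directions, degrees.
#' @return DSI in `[0, 1]`, or `NA` (with a warning) if all peaks are zero.
#' @export
dsi <- function(peaks, directions) {
  stopifnot(length(peaks) == length(directions), length(peaks) >= 2,
            all(peaks >= 0))
  tot <- sum(peaks)
  if (tot <= 0) {
    warning("all peaks zero; DSI undefined")
    return(NA_real_)
  }
  th <- directions * pi / 180
  vx <- sum(peaks * cos(th)); vy <- sum(peaks * sin(th))
  sqrt(vx^2 + vy^2) / tot
}

#' Receptive-field position from opposed motion trials
#'
#' Horizontal RF position estimated as half the difference between the 50%
#' rise times of responses to leftward and rightward bar motion, multiplied by
#' stimulus speed. An RF at the display center responds to both at the same
#' time; a rightward-moving bar reaches an RF right of center later than a
#' leftward-moving bar does.
#'
#' @param t50_right,t50_left 50% rise times (ms) of the responses to rightward
#'   and leftward motion.
#' @param speed bar speed, mm/s.
#' @return signed offset from the display center, um (positive = rightward),
#'   or `NA` if either rise time is missing.
#' @export
rf_position <- function(t50_right, t50_left, speed = 0.5) {
  if (is.na(t50_right) || is.na(t50_left)) return(NA_real_)
  (t50_right - t50_left) / 2 * speed
}

#' Classify a response location relative to visual edges
#'
#' `full_field` if the RF center is at least 100 um from the nearest edge,
#' `near_edge` if some edge is closer than 50 um, `intermediate` otherwise
#' (excluded from both analyses).
#'
#' @param rf_pos RF center position, um.
#' @param edges positions of visual edges (mask boundaries and display
#'   borders), um.
#' @param far_um,near_um the 100-um / 50-um thresholds.
#' @return one of `"full_field"`, `"near_edge"`, `"intermediate"`.
#' @export
classify_location <- function(rf_pos, edges, far_um = 100, near_um = 50) {
  d <- min(abs(rf_pos - edges))
  if (d >= far_um) "full_field"
  else if (d < near_um) "near_edge"
  else "intermediate"
}

#' Model-free 50% rise time
#'
#' Linear-interpolated time at which the trace first crosses half of its peak
#' within the window.
#'
#' @param trace numeric trace.
#' @param dt ms per sample.
#' @param window indices of the stimulus window.
#' @return crossing time, ms from trace start, or `NA`.
#' @export
rise_t50 <- function(trace, dt = 1, window = seq_along(trace)) {
  v <- trace[window]
  pk_i <- which.max(v)
  pk <- v[pk_i]
  if (!is.finite(pk) || pk <= 0) return(NA_real_)
  half <- pk / 2
  pre <- v[seq_len(pk_i)]
  idx <- which(pre >= half)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (i == 1) return((window[1] - 1) * dt)
  frac <- (half - pre[i - 1]) / (pre[i] - pre[i - 1])
  ((window[i - 1] - 1) + frac) * dt
}

#' Fit response kinetics
#'
#' Fits a four-parameter logistic to the rising phase (baseline, amplitude,
#' midpoint, slope) and a single exponential to the decay phase of a response,
#' and reports model-free 50% rise time and time-to-peak. The sigmoid
#' parameterisation is `b + A / (1 + exp(-(t - m)/s))`; the decay is
#' `c + A exp(-(t - t_peak)/tau)`.
#'
#' @param trace numeric trace.
#' @param dt ms per sample.
#' @param window indices of the stimulus window.
#' @return an object of class `kinetics_fit`: list with `rise_t50`,
#'   `time_to_peak`, `sigmoid` (named coefficients or NULL), `decay_tau`,
#'   `fit_ok`.
#' @export
fit_kinetics <- function(trace, dt = 1, window = seq_along(trace)) {
  v <- trace[window]
  n <- length(v)
  out <- list(rise_t50 = NA_real_, time_to_peak = NA_real_, sigmoid = NULL,
              decay_tau = NA_real_, fit_ok = FALSE)
  class(out) <- "kinetics_fit"
  pk_i <- which.max(v)
  pk <- v[pk_i]
  rng <- diff(range(v))
  if (!is.finite(pk) || pk <= 0 || rng < 1e-12 || pk_i <= 2 || pk_i >= n - 2)
    return(out)  # flat or monotone: peak at a window edge
  out$rise_t50 <- rise_t50(trace, dt, window)
  out$time_to_peak <- (window[pk_i] - 1) * dt
  t_ms <- (window - 1) * dt
  rise <- data.frame(t = t_ms[seq_len(pk_i)], y = v[seq_len(pk_i)])
  dec <- data.frame(t = t_ms[pk_i:n], y = v[pk_i:n])
  sig <- tryCatch({
    st <- list(b = min(rise$y), A = pk - min(rise$y),
               m = out$rise_t50, s = max(dt, out$time_to_peak / 10))
    fit <- minpack.lm::nlsLM(y ~ b + A / (1 + exp(-(t - m) / s)),
                             data = rise, start = st,
                             control = minpack.lm::nls.lm.control(maxiter =
                                                                    200))
    stats::coef(fit)
  }, error = function(e) NULL)
  expf <- tryCatch({
    tail_mean <- mean(dec$y[max(1, nrow(dec) - 4):nrow(dec)])
    st <- list(c0 = tail_mean, A = pk - tail_mean,
               tau = max(dt, (max(dec$t) - min(dec$t)) / 3))
    fit <- minpack.lm::nlsLM(y ~ c0 + A * exp(-(t - min(t)) / tau),
                             data = dec, start = st,
                             lower = c(-Inf, 0, dt / 10),
                             control = minpack.lm::nls.lm.control(maxiter =
                                                                    200))
    stats::coef(fit)
  }, error = function(e) NULL)
  out$sigmoid <- sig
  if (!is.null(expf)) out$decay_tau <- unname(expf["tau"])
  out$fit_ok <- !is.null(sig) && !is.null(expf)
  out
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit: ok = %s>\n", x$fit_ok))
  cat(sprintf("  rise t50 %.1f ms, time-to-peak %.1f ms, decay tau %.1f ms\n",
              x$rise_t50, x$time_to_peak, x$decay_tau))
  invisible(x)
}

#' Log-ratio summary with Bonferroni correction
#'
#' Thin reporting helper for comparing response-ratio metrics across groups:
#' one-sample t tests on log-transformed ratios against a null ratio of 1,
#' with Bonferroni-adjusted p values.
#'
#' @param ratios named list of numeric ratio vectors (one per group).
#' @return data.frame with group, n, geometric mean ratio, and raw/adjusted p.
#' @export
ratio_tests <- function(ratios) {
  res <- lapply(names(ratios), function(nm) {
    x <- log(ratios[[nm]])
    x <- x[is.finite(x)]
    tt <- stats::t.test(x)
    data.frame(group = nm, n = length(x), gm_ratio = exp(mean(x)),
               p = tt$p.value)
  })
  res <- do.call(rbind, res)
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  res
}
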