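#' Linear center-surround receptive-field parameters
#'
#' Parameters of the linear spatiotemporal receptive-field (RF) model: each
#' unit integrates the stimulus under a center and a surround Gaussian and
#' low-pass filters each component with its own single-exponential time
#' constant. The full response is
#' `RF_full = RF_center - factor_surround * surround_weight_ratio *
#' RF_surround` (see `surround_weight_ratio`).
#'
#' @param center_halfwidth,surround_halfwidth Gaussian half-widths, um
#'   (defaults 50 and 200). Interpreted per `halfwidth_mode`.
#' @param tau_center,tau_surround component time constants, ms (defaults
#'   20 and 100), in units of the 1-ms simulation step.
#' @param factor_surround surround intensity relative to the center
#'   (>= 0; 0 gives a center-only unit).
#' @param surround_weight_ratio integrated surround-to-center weight at
#'   `factor_surround = 1` (default 2). Both Gaussians are normalised to unit
#'   mass on the lattice and the surround is then scaled by this ratio, so
#'   the difference-of-Gaussians balances (zero response to spatially uniform
#'   scenes) at `factor_surround = 1 / surround_weight_ratio` — factor 0.5
#'   under the default. The balance point governs how strongly extended
#'   scenes (global flow, established motion) are suppressed relative to
#'   newly appearing objects.
#' @param halfwidth_mode `"hwhm"` (default: the stated width is the
#'   half-width at half-maximum, so the weight is 0.5 at
#'   `distance = halfwidth`) or `"fwhm"` (the stated width is the full width
#'   at half maximum).
#' @return an object of class `linear_rf_params`.
#' @export
linear_rf_params <- function(center_halfwidth = 50, surround_halfwidth = 200,
                             tau_center = 20, tau_surround = 100,
                             factor_surround = 0.5,
                             surround_weight_ratio = 2,
                             halfwidth_mode = c("hwhm", "fwhm")) {
  halfwidth_mode <- match.arg(halfwidth_mode)
  stopifnot(center_halfwidth > 0, surround_halfwidth > 0,
            tau_center > 0, tau_surround > 0, factor_surround >= 0,
            surround_weight_ratio > 0)
  structure(list(center_halfwidth = center_halfwidth,
                 surround_halfwidth = surround_halfwidth,
                 tau_center = tau_center, tau_surround = tau_surround,
                 factor_surround = factor_surround,
                 surround_weight_ratio = surround_weight_ratio,
                 halfwidth_mode = halfwidth_mode),
            class = "linear_rf_params")
}

#' Gaussian spatial weight
#'
#' Radial Gaussian RF profile. Under the default HWHM interpretation the
#' weight is exactly 0.5 at `distance = halfwidth`; under `"fwhm"` it is 0.5
#' at `distance = halfwidth / 2`. Negative distances use their absolute value.
#'
#' @param distance distance from the RF center, um (vectorised).
#' @param halfwidth Gaussian width parameter, um.
#' @param mode `"hwhm"` or `"fwhm"`.
#' @return weights in `(0, 1]`.
#' @export
spatial_weight <- function(distance, halfwidth, mode = c("hwhm", "fwhm")) {
  mode <- match.arg(mode)
  stopifnot(halfwidth > 0)
  d <- abs(distance)
  if (mode == "hwhm") exp(-log(2) * (d / halfwidth)^2)
  else exp(-4 * log(2) * d^2 / halfwidth^2)
}

# 1-d lattice mass of the gaussian weight at spacing dx (sums to ~machine
# precision given the 6-sigma reach); 2-d kernels are separable so their
# mass is the product of the per-axis masses
lattice_mass_1d <- function(halfwidth, dx, mode) {
  sigma <- if (mode == "hwhm") halfwidth / sqrt(2 * log(2))
           else halfwidth / (2 * sqrt(2 * log(2)))
  reach <- ceiling(6 * sigma / dx)
  sum(spatial_weight((-reach:reach) * dx, halfwidth, mode))
}

#' Population grid
#'
#' Square grid of RF unit positions covering `extent` um with the given
#' spacing (default 1000 x 1000 um at 10 um).
#'
#' @param extent numeric of length 1 or 2, um.
#' @param spacing um between units.
#' @return list with `units` (data.frame `id, x, y`), `extent`, `spacing`.
#' @export
population_grid <- function(extent = c(1000, 1000), spacing = 10) {
  stopifnot(spacing > 0)
  if (length(extent) == 1L) extent <- c(extent, extent)
  xs <- seq(0, extent[1], by = spacing)
  ys <- seq(0, extent[2], by = spacing)
  units <- expand.grid(x = xs, y = ys)
  units <- data.frame(id = seq_len(nrow(units)), x = units$x, y = units$y)
  list(units = units, extent = extent, spacing = spacing)
}

#' Per-frame RF illumination
#'
#' Weighted sum of stimulus luminance under one RF component's Gaussian,
#' evaluated per frame. Kernels are normalised to unit mass on the movie's
#' pixel lattice, so a uniform full-field luminance L gives illumination L for
#' any component. Pixels beyond the movie extent contribute the background
#' value. Direct summation; intended for single units and small movies (the
#' population simulators use an equivalent separable fast path).
#'
#' @param movie a [stimulus_movie()] (1-D or 2-D).
#' @param position unit position: x (1-D) or `c(x, y)` (2-D), um.
#' @param params a [linear_rf_params()].
#' @param component `"center"` or `"surround"`.
#' @return numeric vector, one illumination value per frame.
#' @export
rf_illumination <- function(movie, position, params = linear_rf_params(),
                            component = c("center", "surround")) {
  component <- match.arg(component)
  hw <- if (component == "center") params$center_halfwidth
        else params$surround_halfwidth
  mode <- params$halfwidth_mode
  d <- dim(movie$frames)
  dx <- movie$dx
  m1 <- lattice_mass_1d(hw, dx, mode)
  if (length(d) == 2L) {
    x <- space_axis(movie)
    if (position < 0 || position > max(x)) {
      warning("unit outside movie extent; returning zero series")
      return(numeric(d[2]))
    }
    w <- spatial_weight(x - position, hw, mode) / m1
    inside <- sum(w)
    as.numeric(crossprod(w, movie$frames)) + (1 - inside) * movie$background
  } else {
    xs <- (seq_len(d[2]) - 1) * dx
    ys <- (seq_len(d[1]) - 1) * dx
    wx <- spatial_weight(xs - position[1], hw, mode) / m1
    wy <- spatial_weight(ys - position[2], hw, mode) / m1
    inside <- sum(wx) * sum(wy)
    nt <- d[3]
    out <- numeric(nt)
    for (k in seq_len(nt))
      out[k] <- as.numeric(wy %*% movie$frames[, , k] %*% wx)
    out + (1 - inside) * movie$background
  }
}

#' Single-exponential RF update
#'
#' One 1-ms step of the RF activation: the activation moves toward the current
#' illumination by `1/tau` of the difference,
#' `RF_t = (illum - RF_{t-1}) / tau + RF_{t-1}`.
#'
#' @param prev activation at the previous step (vectorised).
#' @param illum illumination at this step.
#' @param tau time constant in steps (>= 1).
#' @return the updated activation.
#' @export
step_rf <- function(prev, illum, tau) {
  stopifnot(tau >= 1)
  (illum - prev) / tau + prev
}

# illumination of every lattice position of a static luminance field under a
# gaussian component (unit lattice mass, background padding to 4 sigma)
illum_field <- function(field, dx, background, halfwidth, mode) {
  ny <- nrow(field); nx <- ncol(field)
  sigma <- if (mode == "hwhm") halfwidth / sqrt(2 * log(2))
           else halfwidth / (2 * sqrt(2 * log(2)))
  pad <- ceiling(4 * sigma / dx)
  m1 <- lattice_mass_1d(halfwidth, dx, mode)
  wmat <- function(n_out) {
    xo <- (seq_len(n_out) - 1) * dx
    xi <- (seq_len(n_out + 2 * pad) - 1 - pad) * dx
    outer(xo, xi, function(a, b) spatial_weight(a - b, halfwidth, mode)) / m1
  }
  p <- matrix(background, ny + 2 * pad, nx + 2 * pad)
  p[pad + seq_len(ny), pad + seq_len(nx)] <- field
  wmat(ny) %*% p %*% t(wmat(nx))
}

# illumination of every pixel position for every frame of a 2-d movie,
# via separable gaussian weight matrices with background padding.
# returns ny x nx x nt array. pad reaches 4 sigma beyond the frame.
illum_pixel_stack <- function(movie, halfwidth, mode) {
  d <- dim(movie$frames)
  ny <- d[1]; nx <- d[2]; nt <- d[3]
  dx <- movie$dx
  sigma <- if (mode == "hwhm") halfwidth / sqrt(2 * log(2))
           else halfwidth / (2 * sqrt(2 * log(2)))
  pad <- ceiling(4 * sigma / dx)
  m1 <- lattice_mass_1d(halfwidth, dx, mode)
  wmat <- function(n_out) {
    xo <- (seq_len(n_out) - 1) * dx
    xi <- (seq_len(n_out + 2 * pad) - 1 - pad) * dx
    outer(xo, xi, function(a, b) spatial_weight(a - b, halfwidth, mode)) / m1
  }
  Wy <- wmat(ny); Wx <- wmat(nx)
  padmat <- function(f) {
    p <- matrix(movie$background, ny + 2 * pad, nx + 2 * pad)
    p[pad + seq_len(ny), pad + seq_len(nx)] <- f
    p
  }
  out <- array(0, dim = c(ny, nx, nt))
  base <- Wy %*% padmat(movie$frames[, , 1]) %*% t(Wx)
  out[, , 1] <- base
  prev <- movie$frames[, , 1]
  for (k in 2:nt) {
    cur <- movie$frames[, , k]
    dif <- cur - prev
    nz <- which(dif != 0, arr.ind = TRUE)
    if (nrow(nz) > 0) {
      r <- range(nz[, 1]); cc <- range(nz[, 2])
      rows <- r[1]:r[2]; cols <- cc[1]:cc[2]
      base <- base + Wy[, pad + rows, drop = FALSE] %*%
        dif[rows, cols, drop = FALSE] %*% t(Wx[, pad + cols, drop = FALSE])
    }
    out[, , k] <- base
    prev <- cur
  }
  out
}

#' Simulate a population of linear center-surround units
#'
#' Runs the linear RF model over a stimulus movie: per-frame center and
#' surround illumination, single-exponential filtering of each component at a
#' 1-ms step, and the full response
#' `RF_full = RF_center - factor_surround * RF_surround`. All units share
#' `factor_surround`; with `factor_surround = 0` the full trace equals the
#' center trace (center-only mode).
#'
#' Traces are dense (`units x ms`); memory grows as
#' `3 * n_units * duration_ms` doubles, so use a coarser grid for long movies.
#'
#' @param movie a [stimulus_movie()] (1-D or 2-D). Frame duration `movie$dt`
#'   must be a whole number of 1-ms steps.
#' @param params a [linear_rf_params()].
#' @param grid a [population_grid()] (2-D movies) or numeric vector of unit
#'   x-positions (1-D movies).
#' @param init `"zero"` (states start at 0) or `"steady"` (states start at the
#'   first frame's illumination, i.e. adapted to the initial scene).
#' @return an object of class `trace_set`: list with `center`, `surround`,
#'   `full` (matrices `units x ms`), `units` (data.frame), `dt` (1 ms),
#'   `params`.
#' @export
simulate_rf_population <- function(movie, params = linear_rf_params(),
                                   grid = population_grid(),
                                   init = c("zero", "steady")) {
  init <- match.arg(init)
  spf <- round(movie$dt)
  if (abs(spf - movie$dt) > 1e-9 || spf < 1)
    stop("movie dt must be a whole number of milliseconds")
  d <- dim(movie$frames)
  two_d <- length(d) == 3L
  if (two_d) {
    units <- grid$units
    if (nrow(units) == 0L) stop("empty grid")
    # unit positions snapped to the pixel lattice for the separable fast path
    ix <- round(units$x / movie$dx) + 1L
    iy <- round(units$y / movie$dx) + 1L
    on_lattice <- all(abs(units$x / movie$dx - (ix - 1)) < 1e-9) &&
      all(abs(units$y / movie$dx - (iy - 1)) < 1e-9) &&
      all(ix >= 1 & ix <= d[2] & iy >= 1 & iy <= d[1])
    get_illum <- function(component) {
      hw <- if (component == "center") params$center_halfwidth
            else params$surround_halfwidth
      if (on_lattice) {
        stack <- illum_pixel_stack(movie, hw, params$halfwidth_mode)
        nt <- d[3]
        m <- matrix(0, nrow(units), nt)
        lin <- cbind(iy, ix)
        for (k in seq_len(nt)) m[, k] <- stack[, , k][lin]
        m
      } else {
        t(vapply(seq_len(nrow(units)), function(i) {
          rf_illumination(movie, c(units$x[i], units$y[i]), params, component)
        }, numeric(d[3])))
      }
    }
    illum_c <- get_illum("center")
    illum_s <- get_illum("surround")
  } else {
    xs <- as.numeric(if (is.list(grid)) grid$units$x else grid)
    if (length(xs) == 0L) stop("empty grid")
    units <- data.frame(id = seq_along(xs), x = xs, y = 0)
    illum_c <- t(vapply(xs, function(p)
      rf_illumination(movie, p, params, "center"), numeric(d[2])))
    illum_s <- t(vapply(xs, function(p)
      rf_illumination(movie, p, params, "surround"), numeric(d[2])))
  }
  init_c <- if (init == "steady") illum_c[, 1] else numeric(nrow(illum_c))
  init_s <- if (init == "steady") illum_s[, 1] else numeric(nrow(illum_s))
  center <- cpp_lrf_filter(illum_c, params$tau_center, spf, init_c)
  surround <- cpp_lrf_filter(illum_s, params$tau_surround, spf, init_s)
  full <- center -
    params$factor_surround * params$surround_weight_ratio * surround
  structure(list(center = center, surround = surround, full = full,
                 units = units, dt = 1, params = params),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set: %d units x %d ms (factor_surround = %g)>\n",
              nrow(x$full), ncol(x$full), x$params$factor_surround))
  invisible(x)
}

#' @export
plot.trace_set <- function(x, units = 1, component = "full", ...) {
  m <- x[[component]]
  t_ms <- seq_len(ncol(m)) - 1
  graphics::matplot(t_ms, t(m[units, , drop = FALSE]), type = "l", lty = 1,
                    xlab = "time (ms)", ylab = sprintf("%s activation (a.u.)",
                                                       component), ...)
  invisible(x)
}
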