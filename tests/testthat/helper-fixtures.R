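# shared fixtures: all synthetic, built in code at test time

# small 1-D movie with random luminance, background 0
random_movie_1d <- function(nx = 12, nt = 30, dx = 10, dt = 1, seed = 42) {
  set.seed(seed)
  stimulus_movie(matrix(runif(nx * nt), nx, nt), dx = dx, dt = dt)
}

# small 2-D movie with random luminance
random_movie_2d <- function(n = 8, nt = 6, dx = 10, dt = 1, seed = 42,
                            background = 0) {
  set.seed(seed)
  stimulus_movie(array(runif(n * n * nt), dim = c(n, n, nt)),
                 dx = dx, dt = dt, background = background)
}

# brute-force center/surround illumination: explicit double loop over pixels,
# independent of the package's vectorised implementation
brute_illumination <- function(movie, position, halfwidth, mode = "hwhm") {
  d <- dim(movie$frames)
  m1 <- sum(exp(-log(2) * ((seq(-1000, 1000) * movie$dx / halfwidth)^2)))
  if (mode == "fwhm")
    m1 <- sum(exp(-4 * log(2) * (seq(-1000, 1000) * movie$dx)^2 / halfwidth^2))
  out <- numeric(d[length(d)])
  for (k in seq_along(out)) {
    acc <- 0
    if (length(d) == 2L) {
      for (i in seq_len(d[1])) {
        dist <- (i - 1) * movie$dx - position
        w <- if (mode == "hwhm") exp(-log(2) * (dist / halfwidth)^2)
             else exp(-4 * log(2) * dist^2 / halfwidth^2)
        acc <- acc + w * movie$frames[i, k]
      }
      out[k] <- acc / m1
    } else {
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
        dy <- (i - 1) * movie$dx - position[2]
        dxx <- (j - 1) * movie$dx - position[1]
        dist2 <- dy^2 + dxx^2
        w <- if (mode == "hwhm") exp(-log(2) * dist2 / halfwidth^2)
             else exp(-4 * log(2) * dist2 / halfwidth^2)
        acc <- acc + w * movie$frames[i, j, k]
      }
      out[k] <- acc / m1^2
    }
  }
  out
}

# tiny circuit for fast opl tests
small_circuit <- function(...) circuit_params(n_cells = 40, ...)

small_battery <- function(params, duration_ms = 2200, ...) {
  opl_battery(params, duration_ms = duration_ms, bar_length = 300,
              mask_um = 100, ...)
}
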