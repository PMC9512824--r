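test_that("transiency index separates plateaus from impulses", {
  expect_equal(transiency_index(rep(2, 50)), 0)
  n <- 40
  imp <- c(rep(0, n - 1), 1)
  expect_equal(transiency_index(imp), 1 - 1 / n)
  # invariant to positive rescaling
  set.seed(2)
  tr <- abs(rnorm(100)) + 0.1
  expect_equal(transiency_index(tr), transiency_index(7.3 * tr))
  # literal peak-over-mean form available
  expect_equal(transiency_index(rep(2, 50), form = "peak_over_mean"), 1)
  expect_warning(ti <- transiency_index(rep(-1, 10)), "undefined")
  expect_true(is.na(ti))
})

test_that("enhancement ratios follow their definitions", {
  expect_equal(edge_enhancement(1, 1), 0)
  expect_equal(edge_enhancement(1.5, 1), 0.5)
  expect_equal(edge_enhancement(0.5, 1), -0.5)
  expect_error(edge_enhancement(1, 0), "positive")
  expect_equal(emerging_enhancement(1.3, 1), 0.3)
  # antisymmetry: swapping arguments maps e to 1/(1+e) - 1
  e <- emerging_enhancement(1.7, 1.1)
  expect_equal(emerging_enhancement(1.1, 1.7), 1 / (1 + e) - 1)
  # scale invariance of all ratio metrics
  expect_equal(emerging_enhancement(2.6, 2.2),
               emerging_enhancement(26, 22))
})

test_that("direction selectivity index is a normalised vector sum", {
  expect_equal(dsi(c(1, 0), c(0, 180)), 1)
  expect_equal(dsi(c(1, 1), c(0, 180)), 0)
  expect_equal(dsi(rep(1, 4), c(0, 90, 180, 270)), 0)
  expect_equal(dsi(c(1.9, 1.0), c(0, 180)), 0.9 / 2.9)
  # bounded and invariant to direction relabeling
  set.seed(3)
  for (i in 1:20) {
    pk <- runif(6); th <- runif(6, 0, 360)
    v <- dsi(pk, th)
    expect_true(v >= 0 && v <= 1 + 1e-12)
    perm <- sample(6)
    expect_equal(dsi(pk[perm], th[perm]), v)
  }
  expect_warning(v0 <- dsi(c(0, 0), c(0, 180)), "undefined")
  expect_true(is.na(v0))
})

test_that("RF position is recovered from opposed motion trials", {
  expect_equal(rf_position(1000, 1000), 0)
  expect_equal(rf_position(1400, 1000, speed = 0.5), 100)
  expect_true(is.na(rf_position(NA, 1000)))
  # antisymmetry under mirroring
  expect_equal(rf_position(1400, 1000), -rf_position(1000, 1400))
  # end-to-end: a linear RF unit shifted from display center is localised
  # to within 5 um from its 50% rise times
  geo <- stim_geometry(extent_um = 1000, dx = 10, dt = 1,
                       duration_ms = 4200, pre_ms = 0)
  p <- linear_rf_params(factor_surround = 0)
  offset <- 60
  pos <- 500 + offset
  mr <- make_moving_bar(bar_spec(bar_length = 1000, speed = 0.5), geo)
  ml <- make_moving_bar(bar_spec(bar_length = 1000, speed = 0.5,
                                 direction = "left"), geo)
  tr_r <- numeric(0); a <- 0
  ir <- rf_illumination(mr, pos, p, "center")
  il <- rf_illumination(ml, pos, p, "center")
  fr <- cpp_filter_ref <- function(illum, tau) {
    a <- 0
    out <- numeric(length(illum))
    for (k in seq_along(illum)) {
      a <- (illum[k] - a) / tau + a
      out[k] <- a
    }
    out
  }
  t50r <- rise_t50(fr(ir, 20))
  t50l <- rise_t50(fr(il, 20))
  expect_lt(abs(rf_position(t50r, t50l, 0.5) - offset), 5)
})

test_that("locations are classified by the 100/50 um edge rules", {
  edges <- c(0, 300, 1500)
  expect_equal(classify_location(420, edges), "full_field")
  expect_equal(classify_location(330, edges), "near_edge")
  expect_equal(classify_location(375, edges), "intermediate")
  expect_equal(classify_location(200, edges), "full_field")  # exactly 100
})

test_that("kinetics fits recover known sigmoid rise and exponential decay", {
  t_ms <- seq(0, 3000, by = 10)
  tr <- template_response(t_ms, onset = 200, rise_t50 = 150, rise_slope = 30,
                          decay_tau = 400, amplitude = 1.2,
                          sustain_frac = 0, stim_dur = 2800)
  fit <- fit_kinetics(tr, dt = 10)
  expect_true(fit$fit_ok)
  expect_lt(abs(fit$rise_t50 - 350) / 350, 0.02)  # onset + rise_t50
  expect_lt(abs(fit$decay_tau - 400) / 400, 0.10)
  # decay-constant recovery under noise, SNR 5..20
  set.seed(9)
  for (snr in c(5, 10, 20)) {
    taus <- vapply(1:8, function(i) {
      noisy <- tr + rnorm(length(tr), sd = 1.2 / snr)
      fit_kinetics(noisy, dt = 10)$decay_tau
    }, numeric(1))
    expect_lt(abs(median(taus) - 400) / 400, 0.10)
  }
  # degenerate traces are flagged
  expect_false(fit_kinetics(rep(0.3, 100))$fit_ok)
  expect_false(fit_kinetics(seq(0, 1, length.out = 50))$fit_ok)
})
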