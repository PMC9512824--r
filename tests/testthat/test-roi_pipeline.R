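# compact synthetic experiment used across pipeline tests
make_experiment <- function(k = 3, n_rois = 9, noise_sd = 0.05, seed = 1,
                            field_px = 32) {
  tm <- make_cluster_templates(k, seed = seed)
  lay <- make_roi_layout(n_rois, k, field_px = field_px, patch_px = 4,
                         um_per_px = 1.28, seed = seed)
  bat <- make_condition_battery(seg_ms = 3000, pre_ms = 400, stim_dur = 1500)
  render_imaging_movie(tm, lay, bat, field_px = field_px,
                       noise_sd = noise_sd, dt_ms = 20, seed = seed)
}

test_that("preprocessing bins, filters and rescales to dF/F", {
  ex <- make_experiment(noise_sd = 0)
  mv <- preprocess(ex$movie, bin = 2)
  d_raw <- dim(ex$movie$data[[1]])
  expect_equal(dim(mv$data)[1:2], d_raw[1:2] %/% 2)
  expect_equal(mv$um_per_px, ex$movie$um_per_px * 2)
  # constant movie comes out as zero dF/F
  const <- ex$movie
  const$data <- list(array(100, dim = d_raw))
  expect_lt(max(abs(preprocess(const)$data)), 1e-12)
  # a missing baseline is an error
  bad <- ex$movie
  bad$segments$onset_ms <- 0
  expect_error(preprocess(bad), "baseline")
})

test_that("the temporal low-pass matches its designed frequency response", {
  fs <- 200
  t_s <- seq(0, 5, by = 1 / fs)
  make_tone <- function(f_hz) sin(2 * pi * f_hz * t_s)
  arr <- array(100, dim = c(2, 2, length(t_s)))
  arr[1, 1, ] <- 100 * (1 + 0.2 * make_tone(5))
  arr[2, 2, ] <- 100 * (1 + 0.2 * make_tone(25))
  mv <- structure(list(data = list(arr), dt_ms = 1000 / fs, um_per_px = 1,
                       segments = data.frame(condition = "flash_full",
                                             start_ms = 0, onset_ms = 1000,
                                             seg_ms = 5000, dur_ms = 2000),
                       n_repeats = 1, kind = "raw"),
                  class = "imaging_movie")
  out <- preprocess(mv, bin = 1, lp_hz = 20)
  mid <- 200:800  # samples, away from the filter edges
  gain_of <- function(yx, f_hz) {
    y <- out$data[yx[1], yx[2], mid]
    sd(y) / sd(0.2 * make_tone(f_hz)[mid])
  }
  # oracle: squared Butterworth magnitude (filtfilt applies the filter twice)
  h2 <- function(f_hz, fc = 20, n = 2) (1 / sqrt(1 + (f_hz / fc)^(2 * n)))^2
  expect_equal(gain_of(c(1, 1), 5), h2(5), tolerance = 0.05)
  expect_equal(gain_of(c(2, 2), 25), h2(25), tolerance = 0.20)
  expect_lt(gain_of(c(2, 2), 25), 0.45)
  expect_gt(gain_of(c(1, 1), 5), 0.9)
})

test_that("pixel selection applies the 20% dF/F threshold", {
  ex <- make_experiment(noise_sd = 0.02)
  mv <- preprocess(ex$movie)
  px <- select_pixels(mv, 0.20)
  # selected pixels are inside labelled patches (after 2x2 binning the label
  # image shrinks accordingly)
  lab <- ex$manifest$label_px
  lab2 <- lab[seq(1, nrow(lab), 2), seq(1, ncol(lab), 2)]
  expect_true(all(lab2[px] > 0))
  expect_gt(length(px), 0)
  # zero threshold selects everything, an absurd threshold nothing
  expect_equal(length(select_pixels(mv, -1)),
               prod(dim(mv$data)[1:2]))
  expect_warning(none <- select_pixels(mv, 1e6), "no pixels")
  expect_equal(length(none), 0)
})

test_that("an all-zero movie yields no selected pixels", {
  ex <- make_experiment(noise_sd = 0)
  mv <- preprocess(ex$movie)
  mv$data[] <- 0
  expect_warning(px <- select_pixels(mv), "no pixels")
  expect_equal(length(px), 0)
})

test_that("primary clustering separates distinct waveforms into ROIs", {
  ex <- make_experiment(k = 2, n_rois = 4, noise_sd = 0.01, seed = 3)
  mv <- preprocess(ex$movie)
  px <- select_pixels(mv)
  rois <- primary_cluster(mv, px, threshold = 0.4)
  expect_gte(length(rois), 4)
  # every ROI's pixels map to a single ground-truth patch
  lab <- ex$manifest$label_px
  lab2 <- lab[seq(1, nrow(lab), 2), seq(1, ncol(lab), 2)]
  purity <- vapply(rois, function(r) {
    tab <- table(lab2[r$pixels])
    max(tab) / sum(tab)
  }, numeric(1))
  expect_true(all(purity == 1))
  # compact templates give compact ROIs
  expect_true(all(vapply(rois, `[[`, numeric(1), "extent_um") < 50))
})

test_that("farthest-point clustering is sane on constructed distances", {
  # three tight groups on a line
  x <- c(0, 0.1, 0.2, 5, 5.1, 10, 10.2)
  d <- dist(x)
  grp <- farthest_point_cluster(d, threshold = 1)
  expect_equal(length(unique(grp)), 3)
  expect_equal(grp[1], grp[2])
  expect_equal(grp[4], grp[5])
  expect_false(grp[1] == grp[6])
  # duplicating every item leaves the partition structure unchanged
  grp2 <- farthest_point_cluster(dist(rep(x, 2)), threshold = 1)
  expect_equal(grp2[seq_along(x)], grp2[seq_along(x) + length(x)])
})

test_that("curation drops high-variability ROIs with a strict threshold", {
  ex <- make_experiment(k = 2, n_rois = 4, noise_sd = 0, seed = 4)
  mv <- preprocess(ex$movie, bin = 1, lp_hz = 20)
  # construct two ROIs by hand: coherent and incoherent member pixels
  lab <- ex$manifest$label_px
  px_good <- which(lab == 1)
  d <- dim(mv$data)
  m <- matrix(mv$data, d[1] * d[2], d[3])
  roi_good <- structure(list(pixels = px_good,
                             trace = colMeans(m[px_good, , drop = FALSE])),
                        class = "roi")
  # incoherent ROI: scale half its pixels strongly so the across-pixel
  # coefficient of variation exceeds 1
  mv_bad <- mv
  half <- px_good[seq_len(length(px_good) %/% 2)]
  arr <- matrix(mv_bad$data, d[1] * d[2], d[3])
  arr[half, ] <- arr[half, , drop = FALSE] * -2
  mv_bad$data <- array(arr, dim = d)
  expect_equal(length(curate_rois(list(roi_good), mv, max_cov = 1)), 1L)
  kept <- curate_rois(list(roi_good), mv_bad, max_cov = 1)
  expect_equal(length(kept), 0L)
  # identical member pixels have zero variability
  expect_equal(curate_rois(list(roi_good), mv)[[1]]$cov, 0, tolerance = 1e-10)
})

test_that("the c-index is label-invariant and favours the true partition", {
  set.seed(5)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
  d <- dist(x)
  true_lab <- rep(1:2, each = 20)
  ci_true <- c_index(d, true_lab)
  ci_rand <- c_index(d, sample(true_lab))
  expect_lt(ci_true, ci_rand)
  perm <- c(2L, 1L)[true_lab]
  expect_equal(c_index(d, perm), ci_true)
  expect_true(is.na(c_index(d, seq_len(40))))  # no within pairs
})

test_that("secondary clustering recovers the template count and members", {
  skip_if_not_installed("mclust")
  ex <- make_experiment(k = 3, n_rois = 18, noise_sd = 0.08, seed = 38,
                        field_px = 64)
  res <- run_roi_pipeline(ex$movie, k_range = 3:14, threshold = 0.4)
  expect_equal(res$model$k, 3)
  truth <- vapply(res$rois, function(r) {
    lab <- ex$manifest$template_px
    lab2 <- lab[seq(1, nrow(lab), 2), seq(1, ncol(lab), 2)]
    as.integer(names(which.max(table(lab2[r$pixels]))))
  }, integer(1))
  ari <- mclust::adjustedRandIndex(res$model$assignments, truth)
  expect_gte(ari, 0.9)
  # summary covers every cluster with finite kinetics
  expect_equal(nrow(res$summary), 3)
  expect_true(all(is.finite(res$summary$ti)))
})

test_that("the pipeline is deterministic and recovers k in {5, 8}", {
  skip_if_not_installed("mclust")
  for (k in c(5, 8)) {
    ex <- make_experiment(k = k, n_rois = 6 * k, noise_sd = 0.08,
                          seed = 65 + k, field_px = if (k >= 8) 80 else 64)
    res <- run_roi_pipeline(ex$movie, k_range = 3:14, threshold = 0.4)
    expect_equal(res$model$k, k)
    lab <- ex$manifest$template_px
    lab2 <- lab[seq(1, nrow(lab), 2), seq(1, ncol(lab), 2)]
    truth <- vapply(res$rois, function(r)
      as.integer(names(which.max(table(lab2[r$pixels])))), integer(1))
    expect_gte(mclust::adjustedRandIndex(res$model$assignments, truth), 0.9)
    res2 <- run_roi_pipeline(ex$movie, k_range = 3:14, threshold = 0.4)
    expect_identical(res$model$assignments, res2$model$assignments)
    expect_identical(lapply(res$rois, `[[`, "pixels"),
                     lapply(res2$rois, `[[`, "pixels"))
  }
})

test_that("raising noise only ever removes curated ROIs", {
  counts <- vapply(c(0.02, 0.2, 0.6), function(ns) {
    ex <- make_experiment(k = 3, n_rois = 9, noise_sd = ns, seed = 7)
    mv <- preprocess(ex$movie)
    px <- select_pixels(mv)
    if (length(px) < 2) return(0L)
    rois <- primary_cluster(mv, px, threshold = 0.4)
    length(curate_rois(rois, mv))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})
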