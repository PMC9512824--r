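#' Preprocess a raw imaging movie
#'
#' Standard pixel preprocessing: averaging across repeated protocol
#' presentations, 2 x 2 spatial binning, zero-phase temporal low-pass
#' filtering (2nd-order Butterworth, 20 Hz by default), and conversion to
#' dF/F against the pre-stimulus baseline of each condition segment.
#'
#' @param movie an `imaging_movie` of kind `"raw"` (see
#'   [render_imaging_movie()]); `movie$data` is an array or list of repeat
#'   arrays.
#' @param bin spatial binning factor (default 2).
#' @param lp_hz low-pass cutoff, Hz (skipped with a warning at or above the
#'   Nyquist frequency).
#' @return an `imaging_movie` of kind `"dff"` with binned geometry.
#' @export
preprocess <- function(movie, bin = 2, lp_hz = 20) {
  stopifnot(inherits(movie, "imaging_movie"), movie$kind == "raw")
  reps <- if (is.list(movie$data)) movie$data else list(movie$data)
  arr <- Reduce(`+`, reps) / length(reps)
  d <- dim(arr)
  ny <- d[1] %/% bin; nx <- d[2] %/% bin; nt <- d[3]
  if (bin > 1) {
    binned <- array(0, dim = c(ny, nx, nt))
    for (by in seq_len(bin)) for (bx in seq_len(bin)) {
      binned <- binned + arr[seq(by, by + (ny - 1) * bin, by = bin),
                             seq(bx, bx + (nx - 1) * bin, by = bin), ,
                             drop = FALSE]
    }
    arr <- binned / bin^2
  }
  fs <- 1000 / movie$dt_ms
  if (lp_hz < fs / 2) {
    bf <- signal::butter(2, lp_hz / (fs / 2), type = "low")
    m <- matrix(arr, ny * nx, nt)
    for (i in seq_len(ny * nx)) {
      # filter fluctuations about the pixel mean: avoids the zero-state
      # edge transient on the large DC fluorescence offset
      mu <- mean(m[i, ])
      m[i, ] <- signal::filtfilt(bf, m[i, ] - mu) + mu
    }
    arr <- array(m, dim = c(ny, nx, nt))
  } else {
    warning("low-pass cutoff at or above Nyquist; filtering skipped")
  }
  segs <- movie$segments
  t_ms <- (seq_len(nt) - 1) * movie$dt_ms
  dff <- arr
  for (j in seq_len(nrow(segs))) {
    b <- segs[j, ]
    seg <- which(t_ms >= b$start_ms & t_ms < b$start_ms + b$seg_ms)
    base <- which(t_ms >= b$start_ms & t_ms < b$start_ms + b$onset_ms)
    if (!length(base)) stop("condition segment has no baseline frames")
    f0 <- apply(arr[, , base, drop = FALSE], c(1, 2), mean)
    if (any(f0 <= 0)) stop("non-positive baseline fluorescence")
    dff[, , seg] <- sweep(sweep(arr[, , seg, drop = FALSE], c(1, 2), f0,
                                `-`), c(1, 2), f0, `/`)
  }
  out <- movie
  out$data <- dff
  out$um_per_px <- movie$um_per_px * bin
  out$kind <- "dff"
  out$lp_hz <- if (lp_hz < fs / 2) lp_hz else NA_real_
  out
}

#' Select responsive pixels
#'
#' Pixels whose maximal dF/F across all conditions exceeds the threshold
#' (default 20%).
#'
#' @param movie a preprocessed (`"dff"`) `imaging_movie`.
#' @param threshold dF/F threshold.
#' @return integer vector of pixel indices (column-major over the `y, x`
#'   plane); empty, with a warning, if none qualify.
#' @export
select_pixels <- function(movie, threshold = 0.20) {
  stopifnot(movie$kind == "dff")
  d <- dim(movie$data)
  m <- matrix(movie$data, d[1] * d[2], d[3])
  mx <- apply(m, 1, max)
  idx <- which(mx > threshold)
  if (!length(idx)) warning("no pixels above threshold")
  idx
}

# per-pixel feature vectors: concatenated 1-s windows around stimulus
# entrance into the field, one per condition segment
pixel_features <- function(movie, pixels, win_before_ms = 200,
                           win_after_ms = 800) {
  d <- dim(movie$data)
  m <- matrix(movie$data, d[1] * d[2], d[3])[pixels, , drop = FALSE]
  t_ms <- (seq_len(d[3]) - 1) * movie$dt_ms
  segs <- movie$segments
  feats <- NULL
  for (j in seq_len(nrow(segs))) {
    b <- segs[j, ]
    entr <- b$start_ms + b$onset_ms
    w <- which(t_ms >= entr - win_before_ms & t_ms < entr + win_after_ms)
    feats <- cbind(feats, m[, w, drop = FALSE])
  }
  feats
}

# pairwise distance on feature rows: 1 - pearson correlation, or euclidean
feature_dist <- function(feats, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  if (metric == "correlation") {
    cc <- suppressWarnings(stats::cor(t(feats)))
    cc[!is.finite(cc)] <- 0
    as.dist(1 - cc)
  } else stats::dist(feats)
}

#' Farthest-point clustering
#'
#' Maximin-seeded partitioning of items by pairwise distance: the first seed
#' is the item farthest from all others on average; each further seed is the
#' item maximising its minimum distance to existing seeds; seeding stops when
#' that maximin distance falls below `threshold` (or `max_clusters` is
#' reached), and every item joins its nearest seed.
#'
#' @param d a `dist` or full distance matrix.
#' @param threshold stopping distance (same units as `d`).
#' @param max_clusters upper bound on the number of seeds.
#' @return integer cluster labels.
#' @export
farthest_point_cluster <- function(d, threshold = 0.5, max_clusters = 50) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n == 1L) return(1L)
  seeds <- which.max(rowMeans(dm))
  repeat {
    min_d <- apply(dm[, seeds, drop = FALSE], 1, min)
    cand <- which.max(min_d)
    if (min_d[cand] < threshold || length(seeds) >= max_clusters) break
    seeds <- c(seeds, cand)
  }
  unname(apply(dm[, seeds, drop = FALSE], 1, which.min))
}

# 4-connected components of a set of pixels on an ny x nx lattice
connected_components <- function(pixels, ny) {
  yx <- cbind(y = (pixels - 1) %% ny + 1, x = (pixels - 1) %/% ny + 1)
  n <- length(pixels)
  comp <- integer(n); cur <- 0L
  lookup <- new.env(hash = TRUE)
  for (i in seq_len(n))
    assign(paste(yx[i, 1], yx[i, 2]), i, envir = lookup)
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        key <- paste(yx[j, 1] + dd[1], yx[j, 2] + dd[2])
        k <- mget(key, envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(k) && comp[k] == 0L) {
          comp[k] <- cur
          queue <- c(queue, k)
        }
      }
    }
  }
  comp
}

#' Primary (within-field) pixel clustering into ROIs
#'
#' Groups responsive pixels by waveform similarity: per-pixel feature vectors
#' are the concatenated 1-s response windows around the time of stimulus
#' entrance into the imaging field (one window per condition), the pairwise
#' similarity matrix is 1 - Pearson correlation (Euclidean as option), groups
#' are found by [farthest_point_cluster()], and each group is split into
#' spatially 4-connected components which become ROIs.
#'
#' @param movie a preprocessed `imaging_movie`.
#' @param pixels pixel indices from [select_pixels()].
#' @param metric distance metric.
#' @param threshold farthest-point stopping distance.
#' @param max_clusters cap on waveform groups.
#' @param min_pixels minimum ROI size in pixels.
#' @param win_before_ms,win_after_ms entrance window, ms.
#' @return list of `roi` objects: `pixels`, `centroid_px`, `extent_um`
#'   (max pairwise member distance), `trace` (mean member dF/F), `group`
#'   (waveform group label).
#' @export
primary_cluster <- function(movie, pixels, metric = "correlation",
                            threshold = 0.5, max_clusters = 50,
                            min_pixels = 2, win_before_ms = 200,
                            win_after_ms = 800) {
  if (length(pixels) < 2L) stop("need at least 2 selected pixels")
  feats <- pixel_features(movie, pixels, win_before_ms, win_after_ms)
  d <- feature_dist(feats, metric)
  grp <- farthest_point_cluster(d, threshold, max_clusters)
  dims <- dim(movie$data)
  m <- matrix(movie$data, dims[1] * dims[2], dims[3])
  rois <- list()
  for (g in sort(unique(grp))) {
    px_g <- pixels[grp == g]
    comp <- connected_components(px_g, dims[1])
    for (cc in sort(unique(comp))) {
      px <- px_g[comp == cc]
      if (length(px) < min_pixels) next
      yx <- cbind((px - 1) %% dims[1] + 1, (px - 1) %/% dims[1] + 1)
      ext <- if (length(px) > 1)
        max(stats::dist(yx)) * movie$um_per_px else 0
      rois[[length(rois) + 1L]] <- structure(
        list(pixels = px, centroid_px = colMeans(yx), extent_um = ext,
             trace = colMeans(m[px, , drop = FALSE]), group = g),
        class = "roi")
    }
  }
  rois
}

# coefficient of variation of an ROI: mean over in-window timepoints of
# (across-pixel SD / |across-pixel mean|), over timepoints where the mean
# is distinguishable from zero
roi_cov <- function(roi, movie) {
  d <- dim(movie$data)
  m <- matrix(movie$data, d[1] * d[2], d[3])[roi$pixels, , drop = FALSE]
  t_ms <- (seq_len(d[3]) - 1) * movie$dt_ms
  segs <- movie$segments
  in_win <- rep(FALSE, d[3])
  for (j in seq_len(nrow(segs))) {
    b <- segs[j, ]
    in_win <- in_win | (t_ms >= b$start_ms + b$onset_ms &
                          t_ms < b$start_ms + b$onset_ms + b$dur_ms)
  }
  mu <- colMeans(m)[in_win]
  sdv <- apply(m[, in_win, drop = FALSE], 2, stats::sd)
  keep <- abs(mu) > 0.1 * max(abs(mu))
  if (!any(keep)) return(Inf)
  mean(sdv[keep] / abs(mu[keep]))
}

#' Curate ROIs by pixel variability
#'
#' Drops ROIs whose member-pixel coefficient of variation exceeds
#' `max_cov` (strict inequality: an ROI at exactly the threshold is kept).
#' The CoV is the mean over in-window timepoints of the across-pixel SD over
#' the absolute across-pixel mean.
#'
#' @param rois list from [primary_cluster()].
#' @param movie the preprocessed movie.
#' @param max_cov threshold (default 1).
#' @return the retained ROIs, each annotated with its `cov`.
#' @export
curate_rois <- function(rois, movie, max_cov = 1) {
  kept <- list()
  for (r in rois) {
    r$cov <- roi_cov(r, movie)
    if (r$cov <= max_cov) kept[[length(kept) + 1L]] <- r
  }
  kept
}

# mean silhouette width of a partition over a distance matrix
mean_silhouette <- function(d, labels) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) return(-1)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(dm[i, own & seq_len(n) != i])
    b <- min(vapply(ks[ks != labels[i]], function(g)
      mean(dm[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' c-index of a partition
#'
#' Internal cluster-validity criterion: with `S` the sum of within-cluster
#' pairwise distances over `n_w` pairs, and `S_min`/`S_max` the sums of the
#' `n_w` smallest/largest pairwise distances overall,
#' `C = (S - S_min) / (S_max - S_min)`; smaller is better.
#'
#' @param d a `dist` or distance matrix.
#' @param labels cluster assignment.
#' @return the c-index in `[0, 1]` (`NA` if no within pairs exist).
#' @export
c_index <- function(d, labels) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(length(labels) == n)
  iu <- which(upper.tri(dm))
  dv <- dm[iu]
  same <- outer(labels, labels, `==`)[iu]
  nw <- sum(same)
  if (nw == 0L || nw == length(dv)) return(NA_real_)
  s <- sum(dv[same])
  ds <- sort(dv)
  smin <- sum(ds[seq_len(nw)])
  smax <- sum(ds[seq(length(ds) - nw + 1, length(ds))])
  if (smax == smin) return(0)
  (s - smin) / (smax - smin)
}

#' Secondary (across-experiment) hierarchical clustering
#'
#' Groups curated ROIs into functional release types: agglomerative
#' clustering (average linkage by default) on the pairwise distance between
#' 1-s response waveforms to full-field static stimulation (positive-contrast
#' flashes for ON ROIs, negative for OFF; the caller pre-splits polarity),
#' with the cluster count chosen as the c-index minimum inside plausibility
#' bounds (counts outside `k_range` are rejected as biologically
#' implausible). Since the index falls to a flat plateau once clusters are
#' pure, near-ties with the minimum resolve to the smallest such count.
#'
#' @param waveforms matrix, one ROI waveform per row.
#' @param k_range candidate cluster counts (default 3:15).
#' @param metric `"correlation"` or `"euclidean"`.
#' @param linkage passed to [stats::hclust()] (default `"average"`).
#' @param polarity label stored with the model.
#' @return an object of class `cluster_model`: `assignments`, `k`,
#'   `means` (mean waveform per cluster), `cindex` (data.frame `k, cindex`),
#'   `hclust`, `polarity`.
#' @export
secondary_cluster <- function(waveforms, k_range = 3:15,
                              metric = "correlation", linkage = "average",
                              polarity = "ON") {
  if (!length(k_range)) stop("empty k_range")
  n <- nrow(waveforms)
  k_range <- k_range[k_range >= 1 & k_range <= n]
  if (!length(k_range)) stop("k_range incompatible with ROI count")
  d <- feature_dist(waveforms, metric)
  hc <- stats::hclust(d, method = linkage)
  ci <- vapply(k_range, function(k)
    c_index(d, stats::cutree(hc, k)), numeric(1))
  # the c-index falls steeply to a flat plateau once clusters are pure and
  # cannot distinguish cuts within the plateau (each cut's within pairs are
  # the globally smallest distances); plateau ties are resolved by the mean
  # silhouette width, which penalises both merged and over-split clusters
  tol <- 0.05 * (max(ci, na.rm = TRUE) - min(ci, na.rm = TRUE))
  plateau <- k_range[!is.na(ci) & ci <= min(ci, na.rm = TRUE) + tol]
  k_best <- if (length(plateau) > 1) {
    sil <- vapply(plateau, function(k)
      mean_silhouette(d, stats::cutree(hc, k)), numeric(1))
    plateau[which.max(sil)]
  } else plateau
  assign <- stats::cutree(hc, k_best)
  means <- t(vapply(sort(unique(assign)), function(g)
    colMeans(waveforms[assign == g, , drop = FALSE]),
    numeric(ncol(waveforms))))
  structure(list(assignments = assign, k = k_best, means = means,
                 cindex = data.frame(k = k_range, cindex = ci),
                 hclust = hc, polarity = polarity),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model (%s): %d ROIs in %d clusters>\n",
              x$polarity, length(x$assignments), x$k))
  invisible(x)
}

#' @export
plot.cluster_model <- function(x, ...) {
  graphics::plot(x$cindex$k, x$cindex$cindex, type = "b",
                 xlab = "cluster count k", ylab = "c-index", ...)
  graphics::abline(v = x$k, lty = 2)
  invisible(x)
}

#' Per-cluster summary
#'
#' Mean waveform, transiency index and kinetics per cluster and condition,
#' plus motion/stationary peak and rise-time ratios (flash vs full-field
#' motion), computed from the ROI traces of a fitted model.
#'
#' @param model a [secondary_cluster()] result.
#' @param rois the curated ROI list the model was fitted on (same order).
#' @param movie the preprocessed movie.
#' @return data.frame, one row per cluster.
#' @export
cluster_summary <- function(model, rois, movie) {
  segs <- movie$segments
  t_ms <- (seq_len(dim(movie$data)[3]) - 1) * movie$dt_ms
  seg_idx <- function(cond) {
    b <- segs[segs$condition == cond, ]
    if (!nrow(b)) return(NULL)
    which(t_ms >= b$start_ms & t_ms < b$start_ms + b$seg_ms)
  }
  win_idx <- function(cond) {
    b <- segs[segs$condition == cond, ]
    which(t_ms >= b$start_ms + b$onset_ms &
            t_ms < b$start_ms + b$seg_ms)
  }
  out <- lapply(sort(unique(model$assignments)), function(g) {
    tr <- colMeans(do.call(rbind, lapply(rois[model$assignments == g],
                                         `[[`, "trace")))
    wf <- win_idx("flash_full")
    ti <- transiency_index(tr, wf)
    kin_f <- fit_kinetics(tr, movie$dt_ms, wf)
    wm <- win_idx("motion_right")
    kin_m <- if (length(wm)) fit_kinetics(tr, movie$dt_ms, wm) else NULL
    pk_f <- max(tr[wf])
    pk_m <- if (length(wm)) max(tr[wm]) else NA_real_
    data.frame(cluster = g, n_rois = sum(model$assignments == g),
               ti = ti, rise_t50_flash = kin_f$rise_t50,
               decay_tau_flash = kin_f$decay_tau,
               rise_t50_motion = if (!is.null(kin_m)) kin_m$rise_t50
                                 else NA_real_,
               peak_flash = pk_f, peak_motion = pk_m,
               stationary_motion_ratio = pk_f / pk_m)
  })
  do.call(rbind, out)
}

#' Run the full imaging pipeline
#'
#' Convenience chain: [preprocess()] (if the movie is raw),
#' [select_pixels()], [primary_cluster()], [curate_rois()], and
#' [secondary_cluster()] on the flash-window waveforms of the curated ROIs.
#'
#' @param movie an `imaging_movie` (raw or dff).
#' @param threshold pixel-selection threshold.
#' @param k_range candidate cluster counts for the secondary stage.
#' @param ... passed to [primary_cluster()].
#' @return list with `movie` (preprocessed), `pixels`, `rois` (curated),
#'   `model`, `summary`.
#' @export
run_roi_pipeline <- function(movie, threshold = 0.20, k_range = 3:15, ...) {
  if (movie$kind == "raw") movie <- preprocess(movie)
  px <- select_pixels(movie, threshold)
  rois <- primary_cluster(movie, px, ...)
  rois <- curate_rois(rois, movie)
  if (length(rois) < 2L) stop("fewer than 2 curated ROIs")
  segs <- movie$segments
  t_ms <- (seq_len(dim(movie$data)[3]) - 1) * movie$dt_ms
  b <- segs[segs$condition == "flash_full", ]
  w <- which(t_ms >= b$start_ms + b$onset_ms - 200 &
               t_ms < b$start_ms + b$onset_ms + 800)
  wave <- t(vapply(rois, function(r) r$trace[w], numeric(length(w))))
  model <- secondary_cluster(wave, k_range = k_range)
  list(movie = movie, pixels = px, rois = rois, model = model,
       summary = cluster_summary(model, rois, movie))
}
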