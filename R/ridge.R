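#' Ridge-tracing configuration
#'
#' Parameters for [trace_region()]. A region of roughly 0.5-1 ppm containing
#' the peaks of interest is smoothed with a separable Gaussian, local maxima
#' are picked per timepoint, and the picked points are clustered into ridges
#' in (ppm, time, intensity) space by weighted single-linkage agglomeration.
#'
#' @param region closed ppm interval to trace.
#' @param sigma_ppm Gaussian smoothing sigma along the ppm axis, ppm.
#' @param sigma_time Gaussian smoothing sigma along the time axis, hours.
#' @param weights length-3 numeric `(w_ppm, w_time, w_intensity)` applied to
#'   the min-max scaled clustering coordinates; non-negative, not all zero.
#' @param n_clusters number of ridges to cut the linkage tree into
#'   (the usual, manually chosen setting). Exactly one of `n_clusters` /
#'   `linkage_cut` must be given.
#' @param linkage_cut alternative automated cut: a normalized linkage
#'   distance at which to cut the tree.
#' @param peak_floor minimum smoothed intensity for a picked maximum;
#'   the permissive default 0 lets some noise through, which clustering and
#'   visual QC are expected to absorb.
#' @param map_window_indices total width (axis points) of the window used to
#'   remap smoothed ridge positions onto the raw data; default 10, validated
#'   to lie in \[1, 60\].
#' @return A list of class `trace_config`.
#' @export
trace_config <- function(region, sigma_ppm, sigma_time,
                         weights = c(1, 1, 0.3), n_clusters = NULL,
                         linkage_cut = NULL, peak_floor = 0,
                         map_window_indices = 10L) {
  region <- as_interval(region)
  assert_that(is_number(sigma_ppm) && sigma_ppm > 0, "sigma_ppm must be > 0")
  assert_that(is_number(sigma_time) && sigma_time > 0, "sigma_time must be > 0")
  assert_that(is.numeric(weights) && length(weights) == 3 &&
                all(weights >= 0) && any(weights > 0),
              "weights must be three non-negative numbers, not all zero")
  assert_that(xor(is.null(n_clusters), is.null(linkage_cut)),
              "give exactly one of n_clusters or linkage_cut")
  if (!is.null(n_clusters))
    assert_that(is_number(n_clusters) && n_clusters >= 1,
                "n_clusters must be >= 1")
  if (!is.null(linkage_cut))
    assert_that(is_number(linkage_cut) && linkage_cut > 0,
                "linkage_cut must be > 0")
  assert_that(is_number(peak_floor) && peak_floor >= 0,
              "peak_floor must be >= 0")
  assert_that(is_number(map_window_indices) && map_window_indices >= 1 &&
                map_window_indices <= 60,
              "map_window_indices must be in [1, 60]")
  structure(list(region = region, sigma_ppm = sigma_ppm,
                 sigma_time = sigma_time, weights = as.numeric(weights),
                 n_clusters = n_clusters, linkage_cut = linkage_cut,
                 peak_floor = peak_floor,
                 map_window_indices = as.integer(map_window_indices)),
            class = "trace_config")
}

#' Traced peak ridge
#'
#' A ridge is one peak followed through time: at most one point per
#' timepoint, times strictly increasing, interior temporal gaps filled by
#' linearly interpolated positions (flagged). Built by [trace_region()] /
#' [ridges_from_clusters()].
#'
#' @param id ridge identifier.
#' @param points data.frame with columns `time_index`, `time_h`,
#'   `ppm_index`, `ppm`, `smoothed_intensity`, `raw_intensity`,
#'   `interpolated`.
#' @param annotation compound name, or `"unknown"`.
#' @param cluster_label integer label from clustering.
#' @param qc character vector of QC flags.
#' @return An object of class `ridge`.
#' @export
new_ridge <- function(id, points, annotation = "unknown",
                      cluster_label = NA_integer_, qc = character()) {
  needed <- c("time_index", "time_h", "ppm_index", "ppm",
              "smoothed_intensity", "raw_intensity", "interpolated")
  missing_cols <- setdiff(needed, names(points))
  for (cc in missing_cols) points[[cc]] <- NA
  points <- points[order(points$time_index), needed]
  assert_that(!anyDuplicated(points$time_index),
              "a ridge may have at most one point per timepoint")
  rownames(points) <- NULL
  structure(list(id = as.character(id), points = points,
                 annotation = annotation, cluster_label = cluster_label,
                 qc = qc),
            class = "ridge")
}

#' @export
print.ridge <- function(x, ...) {
  cat(sprintf("<ridge %s> %d points (%d interpolated), %s, ppm %.4f..%.4f\n",
              x$id, nrow(x$points), sum(x$points$interpolated),
              x$annotation, min(x$points$ppm), max(x$points$ppm)))
  invisible(x)
}

# 1-D Gaussian kernel sampled on the grid spacing `step`, truncated at
# 4 sigma, unit sum. Collapses to a delta when sigma << step.
gaussian_kernel <- function(sigma, step) {
  r <- max(0L, as.integer(ceiling(4 * sigma / step)))
  k <- exp(-((-r:r) * step)^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve each row of `mat` with `kernel` (odd length), edge replication
convolve_rows <- function(mat, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(mat * kernel)
  P <- ncol(mat)
  pad <- cbind(mat[, rep(1L, r), drop = FALSE], mat,
               mat[, rep(P, r), drop = FALSE])
  out <- matrix(0, nrow(mat), P)
  for (j in seq_along(kernel))
    out <- out + kernel[j] * pad[, j:(j + P - 1L), drop = FALSE]
  out
}

#' Smooth a spectral region with a separable 2-D Gaussian
#'
#' Convolves the region's intensity matrix with a Gaussian along the ppm
#' axis and then along the time axis. Kernels are sampled on the grid
#' spacing (the median spacing for a possibly non-uniform time axis),
#' truncated at 4 sigma and normalised to unit sum; boundaries use edge
#' replication, so a constant matrix is unchanged.
#'
#' @param series a [spectrum_series].
#' @param region closed ppm interval to smooth.
#' @param sigma_ppm Gaussian sigma along ppm, in ppm.
#' @param sigma_time Gaussian sigma along time, in hours.
#' @return A [spectrum_series] restricted to `region` containing the
#'   smoothed intensities.
#' @export
gaussian_smooth_2d <- function(series, region, sigma_ppm, sigma_time) {
  cols <- ppm_columns(series, region)
  if (length(cols) == 0)
    stop_civm("region does not overlap the ppm axis", "civmtrace_empty_error")
  assert_that(is_number(sigma_ppm) && sigma_ppm > 0, "sigma_ppm must be > 0")
  assert_that(is_number(sigma_time) && sigma_time > 0, "sigma_time must be > 0")
  mat <- series$intensities[, cols, drop = FALSE]
  ppm_step <- if (length(cols) > 1) abs(stats::median(diff(series$ppm[cols]))) else 1
  t_step <- if (n_times(series) > 1) stats::median(diff(series$times_h)) else 1
  mat <- convolve_rows(mat, gaussian_kernel(sigma_ppm, ppm_step))
  mat <- t(convolve_rows(t(mat), gaussian_kernel(sigma_time, t_step)))
  out <- spectrum_series(mat, series$ppm[cols], series$times_h,
                         meta = series$meta)
  add_history(out, sprintf("gaussian_smooth_2d([%g, %g], s_ppm=%g, s_t=%g)",
                           min(region), max(region), sigma_ppm, sigma_time))
}

#' Pick per-timepoint local maxima of a smoothed region
#'
#' Returns, for each timepoint, the interior strict local maxima along the
#' ppm dimension whose smoothed intensity is at least `peak_floor`. The two
#' edge columns of the region are never picked.
#'
#' @param smoothed a smoothed [spectrum_series] (output of
#'   [gaussian_smooth_2d()]).
#' @param peak_floor minimum smoothed intensity; default 0.
#' @return data.frame of candidate ridge points with columns `time_index`,
#'   `time_h`, `ppm_index`, `ppm`, `smoothed_intensity` (possibly 0 rows).
#' @export
pick_local_maxima <- function(smoothed, peak_floor = 0) {
  mat <- smoothed$intensities
  P <- ncol(mat)
  assert_that(P >= 3, "need at least 3 ppm points to find interior maxima")
  res <- vector("list", nrow(mat))
  for (t in seq_len(nrow(mat))) {
    y <- mat[t, ]
    i <- which(y[2:(P - 1)] > y[1:(P - 2)] & y[2:(P - 1)] > y[3:P]) + 1L
    i <- i[y[i] >= peak_floor]
    if (length(i))
      res[[t]] <- data.frame(time_index = t, time_h = smoothed$times_h[t],
                             ppm_index = i, ppm = smoothed$ppm[i],
                             smoothed_intensity = y[i])
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(time_index = integer(), time_h = numeric(),
                      ppm_index = integer(), ppm = numeric(),
                      smoothed_intensity = numeric())
  rownames(out) <- NULL
  out
}

# min-max scale a vector to [0, 1]; constant vectors map to 0
minmax01 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0, length(x))
}

#' Cluster picked peak points into ridges
#'
#' Each clustering dimension (ppm, time, smoothed intensity) is min-max
#' scaled to \[0, 1\] over the point set and multiplied by its weight; points
#' are then merged by single-linkage agglomeration on Euclidean distances in
#' the scaled space, and the tree is cut either into `n_clusters` groups or
#' at linkage distance `linkage_cut`.
#'
#' @param points data.frame from [pick_local_maxima()].
#' @param weights length-3 `(w_ppm, w_time, w_intensity)` weight vector.
#' @param n_clusters desired number of clusters (exactly one of
#'   `n_clusters` / `linkage_cut`).
#' @param linkage_cut linkage-distance cut height.
#' @return Integer vector of cluster labels (contiguous, numbered by first
#'   appearance in `points` order).
#' @export
cluster_peak_points <- function(points, weights = c(1, 1, 0.3),
                                n_clusters = NULL, linkage_cut = NULL) {
  assert_that(nrow(points) >= 1, "no points to cluster",
              "civmtrace_empty_error")
  assert_that(xor(is.null(n_clusters), is.null(linkage_cut)),
              "give exactly one of n_clusters or linkage_cut")
  n <- nrow(points)
  if (!is.null(n_clusters)) {
    assert_that(n_clusters >= 1 && n_clusters == as.integer(n_clusters),
                "n_clusters must be a positive integer")
    if (n_clusters > n)
      stop_civm(sprintf("n_clusters (%d) exceeds number of points (%d)",
                        n_clusters, n), "civmtrace_cluster_error")
  }
  if (n == 1L) return(1L)
  coords <- cbind(minmax01(points$ppm) * weights[1],
                  minmax01(points$time_h) * weights[2],
                  minmax01(points$smoothed_intensity) * weights[3])
  tree <- stats::hclust(stats::dist(coords), method = "single")
  raw <- if (!is.null(n_clusters)) stats::cutree(tree, k = n_clusters)
         else stats::cutree(tree, h = linkage_cut)
  match(raw, unique(raw))
}

#' Build ridges from clustered points
#'
#' Per cluster: when several points share a timepoint, the one with the
#' highest smoothed intensity is retained (ties broken toward higher ppm);
#' points are ordered by time; every interior missing timepoint is filled
#' with an interpolated point whose ppm is linear in time between the two
#' nearest retained points. No extrapolation happens before the first or
#' after the last retained point. Interpolated points carry no smoothed
#' intensity of their own.
#'
#' @param points data.frame from [pick_local_maxima()].
#' @param labels integer labels from [cluster_peak_points()].
#' @param times_h optional full time axis (hours) indexed by `time_index`,
#'   used to place interpolated points; without it their times are
#'   interpolated linearly in `time_index`.
#' @param ppm_axis optional full ppm axis used to assign the nearest
#'   `ppm_index` to interpolated points.
#' @return List of [new_ridge] objects, one per non-empty cluster, in label
#'   order.
#' @export
ridges_from_clusters <- function(points, labels, times_h = NULL,
                                 ppm_axis = NULL) {
  assert_that(nrow(points) == length(labels),
              "labels must align with points", "civmtrace_dim_error")
  out <- list()
  for (lb in sort(unique(labels))) {
    p <- points[labels == lb, , drop = FALSE]
    if (nrow(p) == 0) next
    # dedup: highest smoothed intensity per timepoint, ties -> higher ppm
    p <- p[order(p$time_index, -p$smoothed_intensity, -p$ppm), , drop = FALSE]
    p <- p[!duplicated(p$time_index), , drop = FALSE]
    p$raw_intensity <- NA_real_
    p$interpolated <- FALSE
    ti <- p$time_index
    gaps <- setdiff(seq(min(ti), max(ti)), ti)
    if (length(gaps)) {
      g_time <- if (!is.null(times_h)) times_h[gaps]
                else stats::approx(ti, p$time_h, xout = gaps)$y
      g_ppm <- stats::approx(p$time_h, p$ppm, xout = g_time)$y
      g_idx <- if (!is.null(ppm_axis))
        vapply(g_ppm, function(pp) which.min(abs(ppm_axis - pp)), integer(1))
      else rep(NA_integer_, length(gaps))
      p <- rbind(p, data.frame(
        time_index = gaps, time_h = g_time, ppm_index = g_idx, ppm = g_ppm,
        smoothed_intensity = NA_real_, raw_intensity = NA_real_,
        interpolated = TRUE))
    }
    out[[length(out) + 1L]] <- new_ridge(
      id = sprintf("R%02d", lb), points = p, cluster_label = lb)
  }
  out
}

#' Map a ridge traced on smoothed data back onto the raw data
#'
#' For every ridge point (interpolated ones included), searches the raw
#' series within `window_indices` total width — i.e. +/- floor(window/2)
#' axis points, clipped to the axis (and to `region` when given) — around
#' the smoothed peak position, and records the maximum raw intensity and its
#' refined ppm location. With `window_indices = 1` the raw value at the
#' smoothed position itself is taken.
#'
#' @param ridge a [new_ridge] object.
#' @param raw a raw (unsmoothed) [spectrum_series].
#' @param window_indices total window width in axis points, default 10.
#' @param region optional closed ppm interval to clip the search to.
#' @return The ridge with `raw_intensity`, `ppm` and `ppm_index` refined
#'   against the raw data (`ppm_index` now indexes the raw axis).
#' @export
map_ridge_to_raw <- function(ridge, raw, window_indices = 10L, region = NULL) {
  assert_that(inherits(ridge, "ridge"), "ridge must be a ridge object")
  assert_that(is_number(window_indices) && window_indices >= 1,
              "window_indices must be >= 1")
  half <- as.integer(window_indices) %/% 2L
  P <- n_points(raw)
  bounds <- if (!is.null(region)) range(ppm_columns(raw, region))
            else c(1L, P)
  p <- ridge$points
  for (i in seq_len(nrow(p))) {
    centre <- which.min(abs(raw$ppm - p$ppm[i]))
    lo <- max(bounds[1], centre - half)
    hi <- min(bounds[2], centre + half)
    y <- raw$intensities[p$time_index[i], lo:hi]
    j <- lo + which.max(y) - 1L
    p$raw_intensity[i] <- raw$intensities[p$time_index[i], j]
    p$ppm[i] <- raw$ppm[j]
    p$ppm_index[i] <- j
  }
  ridge$points <- p
  ridge
}

#' Trace all ridges in a spectral region
#'
#' The full semi-automated tracing procedure: Gaussian smoothing of the
#' region, per-timepoint peak picking, weighted single-linkage clustering of
#' the picked points, per-time deduplication and gap interpolation, and
#' remapping of each ridge onto the unsmoothed data. The configuration is
#' attached to the result for audit. Visual inspection is represented by
#' [qc_ridges()], which flags (never deletes) rejected ridges.
#'
#' @param series a preprocessed [spectrum_series].
#' @param cfg a [trace_config].
#' @return List of [new_ridge] objects (possibly empty), with attribute
#'   `config`.
#' @export
trace_region <- function(series, cfg) {
  assert_that(inherits(cfg, "trace_config"), "cfg must be a trace_config")
  sm <- gaussian_smooth_2d(series, cfg$region, cfg$sigma_ppm, cfg$sigma_time)
  pts <- pick_local_maxima(sm, cfg$peak_floor)
  if (nrow(pts) == 0) return(structure(list(), config = cfg))
  labels <- cluster_peak_points(pts, cfg$weights, cfg$n_clusters,
                                cfg$linkage_cut)
  ridges <- ridges_from_clusters(pts, labels, times_h = series$times_h,
                                 ppm_axis = sm$ppm)
  ridges <- lapply(ridges, map_ridge_to_raw, raw = series,
                   window_indices = cfg$map_window_indices,
                   region = cfg$region)
  structure(ridges, config = cfg)
}

#' Flag ridges after visual inspection
#'
#' Applies an accept/reject decision list by ridge id. Rejected ridges get a
#' `"manually rejected"` QC flag; they are kept in the list so the decision
#' is auditable.
#'
#' @param ridges list of ridges from [trace_region()].
#' @param reject character vector of ridge ids to reject.
#' @return The ridge list with QC flags applied.
#' @export
qc_ridges <- function(ridges, reject = character()) {
  lapply(ridges, function(r) {
    if (r$id %in% reject) r$qc <- union(r$qc, "manually rejected")
    r
  })
}
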