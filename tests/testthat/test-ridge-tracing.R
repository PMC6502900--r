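test_that("gaussian_smooth_2d preserves constants, mass, and the small-sigma limit", {
  ppm <- seq(2, 1, length.out = 41)
  times <- seq_len(11) / 10
  const <- spectrum_series(matrix(3, 11, 41), ppm, times)
  sm <- gaussian_smooth_2d(const, c(1, 2), sigma_ppm = 0.05, sigma_time = 0.2)
  expect_equal(sm$intensities, const$intensities, tolerance = 1e-12)

  # centred impulse: matches a dense 2-D convolution oracle, conserves mass
  mat <- matrix(0, 11, 41); mat[6, 21] <- 1
  imp <- spectrum_series(mat, ppm, times)
  sm <- gaussian_smooth_2d(imp, c(1, 2), sigma_ppm = 0.02, sigma_time = 0.1)
  expect_equal(sum(sm$intensities), 1, tolerance = 1e-6)
  oracle <- dense_gauss_2d(mat, 0.02, 0.1,
                           abs(median(diff(imp$ppm))), median(diff(times)))
  expect_equal(sm$intensities, oracle, tolerance = 1e-9)

  # sigma far below one grid step: identity within tolerance
  rnd <- spectrum_series(matrix(rnorm(11 * 41), 11, 41), ppm, times)
  tinysig <- gaussian_smooth_2d(rnd, c(1, 2),
                                sigma_ppm = 0.1 * abs(diff(ppm)[1]),
                                sigma_time = 0.01)
  expect_equal(tinysig$intensities, rnd$intensities, tolerance = 1e-8)

  expect_error(gaussian_smooth_2d(rnd, c(5, 6), 0.01, 0.1),
               class = "civmtrace_empty_error")
})

test_that("pick_local_maxima finds interior strict maxima above the floor", {
  sim <- tiny_series(list(const_peak("p", 2, 5)), n_points = 1000L)
  sm <- gaussian_smooth_2d(sim$series, c(1.5, 2.5), 0.01, 0.2)
  pts <- pick_local_maxima(sm, peak_floor = 0.5)
  expect_equal(nrow(pts), nrow(sm$intensities))  # exactly one per timepoint
  expect_true(all(abs(pts$ppm - 2) < 0.01))

  # floor above the global maximum: nothing picked
  expect_equal(nrow(pick_local_maxima(sm, peak_floor = 100)), 0L)

  # two well-separated peaks: two candidates per timepoint
  sim2 <- tiny_series(list(const_peak("a", 1.8, 5), const_peak("b", 2.2, 4)),
                      n_points = 1000L)
  sm2 <- gaussian_smooth_2d(sim2$series, c(1.5, 2.5), 0.01, 0.2)
  pts2 <- pick_local_maxima(sm2, peak_floor = 0.5)
  expect_equal(unname(table(pts2$time_index)),
               rep(2L, nrow(sm2$intensities)), ignore_attr = TRUE)
})

test_that("single-linkage clustering separates generating traces and matches the oracle", {
  # two drifting traces far apart relative to within-trace spacing
  t <- seq(0, 10, by = 0.5)
  pts <- data.frame(
    time_index = rep(seq_along(t), 2), time_h = rep(t, 2),
    ppm_index = 1L,
    ppm = c(2.0 + 0.001 * t, 3.0 - 0.001 * t),
    smoothed_intensity = c(5 + 0.1 * t, 4 - 0.1 * t))
  truth_id <- rep(1:2, each = length(t))
  labels <- cluster_peak_points(pts, weights = c(1, 1, 0.3), n_clusters = 2)
  expect_true(same_partition(labels, truth_id))

  # oracle equivalence on random instances
  set.seed(7)
  for (trial in 1:25) {
    n <- sample(5:120, 1)
    rp <- data.frame(time_index = 1L, time_h = runif(n, 0, 11),
                     ppm_index = 1L, ppm = runif(n, 0, 10),
                     smoothed_intensity = runif(n, 0, 5))
    w <- runif(3, 0.1, 2)
    k <- sample(1:min(6, n), 1)
    mine <- cluster_peak_points(rp, weights = w, n_clusters = k)
    scaled <- cbind((rp$ppm - min(rp$ppm)) / diff(range(rp$ppm)) * w[1],
                    (rp$time_h - min(rp$time_h)) / diff(range(rp$time_h)) * w[2],
                    (rp$smoothed_intensity - min(rp$smoothed_intensity)) /
                      diff(range(rp$smoothed_intensity)) * w[3])
    expect_true(same_partition(mine, oracle_single_linkage(scaled, k)))
  }
})

test_that("clustering handles weights, degenerate counts and errors", {
  pts <- data.frame(time_index = 1:4, time_h = 1:4, ppm_index = 1L,
                    ppm = c(1, 1.01, 3, 3.01),
                    smoothed_intensity = c(1, 2, 3, 4))
  expect_equal(cluster_peak_points(pts, n_clusters = 1), rep(1L, 4))
  # zero intensity weight: labels invariant to intensity rescaling
  l1 <- cluster_peak_points(pts, weights = c(1, 1, 0), n_clusters = 2)
  pts2 <- pts; pts2$smoothed_intensity <- pts$smoothed_intensity * 1e6
  l2 <- cluster_peak_points(pts2, weights = c(1, 1, 0), n_clusters = 2)
  expect_identical(l1, l2)
  expect_error(cluster_peak_points(pts, n_clusters = 5),
               class = "civmtrace_cluster_error")
  expect_error(cluster_peak_points(pts, n_clusters = 2, linkage_cut = 0.1))
  # a linkage-distance cut separates the two tight pairs
  lc <- cluster_peak_points(pts, weights = c(1, 0, 0), linkage_cut = 0.5)
  expect_true(same_partition(lc, c(1L, 1L, 2L, 2L)))
})

test_that("ridges_from_clusters dedups by intensity, interpolates gaps, never extrapolates", {
  pts <- data.frame(
    time_index = c(1L, 1L, 3L, 5L), time_h = c(1, 1, 3, 5),
    ppm_index = c(10L, 12L, 11L, 13L), ppm = c(1.00, 1.02, 1.00, 1.02),
    smoothed_intensity = c(5, 7, 6, 6))
  r <- ridges_from_clusters(pts, rep(1L, 4), times_h = 1:5)[[1]]
  p <- r$points
  # duplicate time 1: intensity 7 wins
  expect_equal(p$smoothed_intensity[p$time_index == 1], 7)
  # interior gaps at t=2 and t=4 interpolated linearly in time
  expect_true(all(c(2L, 4L) %in% p$time_index[p$interpolated]))
  expect_equal(p$ppm[p$time_index == 2], mean(c(1.02, 1.00)))
  expect_equal(p$ppm[p$time_index == 4], mean(c(1.00, 1.02)))
  # nothing before the first or after the last retained point
  expect_equal(range(p$time_index), c(1L, 5L))
  expect_equal(nrow(p), 5L)

  # tie at one timepoint: higher ppm wins
  tie <- data.frame(time_index = c(1L, 1L), time_h = c(1, 1),
                    ppm_index = c(1L, 2L), ppm = c(1.00, 1.05),
                    smoothed_intensity = c(5, 5))
  rt <- ridges_from_clusters(tie, c(1L, 1L))[[1]]
  expect_equal(rt$points$ppm, 1.05)
})

test_that("map_ridge_to_raw refines positions within the index window", {
  ppm <- seq(3, 1, length.out = 201)   # 0.01 ppm/index
  y <- peak_profile("lorentzian", 2.0, 0.05, 10, ppm)
  raw <- spectrum_series(rbind(y, y), ppm, c(0, 1))
  centre_idx <- which.min(abs(ppm - 2.0))
  # smoothed position deliberately 2 indices off the true maximum
  off <- data.frame(time_index = 1:2, time_h = c(0, 1),
                    ppm_index = centre_idx - 2L, ppm = ppm[centre_idx - 2L],
                    smoothed_intensity = 1, raw_intensity = NA,
                    interpolated = FALSE)
  r <- new_ridge("R", off)
  mapped <- map_ridge_to_raw(r, raw, window_indices = 10)
  expect_equal(mapped$points$ppm, rep(2.0, 2))
  expect_equal(mapped$points$raw_intensity, rep(10, 2))

  # window 1: raw value at the (nearest) smoothed position itself
  m1 <- map_ridge_to_raw(r, raw, window_indices = 1)
  expect_equal(m1$points$ppm, off$ppm)
  expect_equal(m1$points$raw_intensity, rep(y[centre_idx - 2L], 2))

  # mapping monotonicity: windowed max never below the unrefined value
  expect_true(all(mapped$points$raw_intensity >= m1$points$raw_intensity))
})

test_that("trace_region is deterministic and returns nothing on flat noise", {
  fx <- standard_fixtures()$two_drifting_peaks
  fx$n_points <- 4000L  # coarser axis keeps this a unit test
  sim <- simulate_series(fx)
  pre <- preprocess_pipeline(sim$series)
  cfg <- trace_config(region = c(2.6, 3.2), sigma_ppm = 0.003,
                      sigma_time = 0.3, n_clusters = 2)
  r1 <- trace_region(pre, cfg)
  r2 <- trace_region(preprocess_pipeline(simulate_series(fx)$series), cfg)
  expect_length(r1, 2L)
  expect_identical(r1, r2)

  # a signal-free region with the floor above the noise ceiling
  quiet <- trace_region(pre, trace_config(region = c(1.0, 1.6),
                                          sigma_ppm = 0.003, sigma_time = 0.3,
                                          linkage_cut = 0.05,
                                          peak_floor = 1))
  expect_length(quiet, 0L)
})
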