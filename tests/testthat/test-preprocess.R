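# A compact series used across the stage tests: DSS at 0 ppm plus one
# analyte peak, mis-referenced by a known offset where needed.
mk_series <- function(dss_amp = 1, analyte_amp = 10, dss_ppm = 0,
                      n = 6L, n_points = 600L) {
  ppm <- seq(4, -0.5, length.out = n_points)
  mat <- t(vapply(seq_len(n), function(t) {
    peak_profile("lorentzian", dss_ppm, 0.02, dss_amp, ppm) +
      peak_profile("lorentzian", 2.0, 0.02, analyte_amp, ppm)
  }, numeric(n_points)))
  spectrum_series(mat, ppm, seq_len(n) / 10)
}

test_that("reference_to_dss shifts the window maximum onto the axis point nearest 0", {
  ser <- mk_series(dss_ppm = 0.02)
  ref <- reference_to_dss(ser, 0.25)
  target <- which.min(abs(ref$ppm))
  cols <- which(ref$ppm >= -0.25 & ref$ppm <= 0.25)
  for (t in seq_len(nrow(ref$intensities))) {
    expect_equal(cols[which.max(ref$intensities[t, cols])], target)
  }
  # already-referenced input: zero shift, intensities untouched
  again <- reference_to_dss(ref, 0.25)
  expect_identical(again$intensities, ref$intensities)
})

test_that("reference_to_dss errors on signal-free windows and honours overrides", {
  flat <- spectrum_series(matrix(0, 2, 100), seq(1, -1, length.out = 100),
                          c(0, 1))
  expect_error(reference_to_dss(flat, 0.25), "timepoint 1",
               class = "civmtrace_reference_error")

  ser <- mk_series(dss_ppm = 0.02)
  man <- reference_to_dss(ser, 0.25, shift_override = rep(0L, 6))
  expect_identical(man$intensities, ser$intensities)
})

test_that("trim_ppm keeps exactly the closed interval", {
  ser <- mk_series()
  tr <- trim_ppm(ser, c(-0.2, 3))
  expect_true(all(tr$ppm >= -0.2 & tr$ppm <= 3))
  expect_equal(ncol(tr$intensities), length(tr$ppm))
  # keep spanning the full axis is the identity
  full <- trim_ppm(ser, range(ser$ppm))
  expect_identical(full$intensities, ser$intensities)
  expect_error(trim_ppm(ser, c(100, 101)), class = "civmtrace_empty_error")
})

test_that("zero_region zeroes exactly the closed region and is idempotent", {
  ser <- mk_series()
  z <- zero_region(ser, c(1.9, 2.1))
  cols <- which(z$ppm >= 1.9 & z$ppm <= 2.1)
  expect_true(all(z$intensities[, cols] == 0))
  expect_identical(z$intensities[, -cols], ser$intensities[, -cols])
  z2 <- zero_region(z, c(1.9, 2.1))
  expect_identical(z2$intensities, z$intensities)
  # region outside the axis is a no-op
  out <- zero_region(ser, c(50, 51))
  expect_identical(out$intensities, ser$intensities)
})

test_that("trim, zeroing and truncation commute", {
  ser <- mk_series()
  a <- trim_ppm(zero_region(ser, c(1.9, 2.1)), c(-0.2, 3))
  b <- zero_region(trim_ppm(ser, c(-0.2, 3)), c(1.9, 2.1))
  expect_identical(a$intensities, b$intensities)
  c1 <- truncate_time(zero_region(ser, c(1.9, 2.1)), 0.35)
  c2 <- zero_region(truncate_time(ser, 0.35), c(1.9, 2.1))
  expect_identical(c1$intensities, c2$intensities)
})

test_that("truncate_time retains the closed time bound", {
  ser <- mk_series(n = 8)  # times 0.1 .. 0.8 h
  tr <- truncate_time(ser, 0.55)
  expect_equal(max(tr$times_h), 0.5)
  ident <- truncate_time(ser, 2)
  expect_identical(ident$intensities, ser$intensities)
  expect_error(truncate_time(ser, 0.05), class = "civmtrace_empty_error")
})

test_that("normalize_to_reference makes the DSS-window maximum exactly 1 per spectrum", {
  ser <- mk_series(dss_amp = 2, analyte_amp = 10)
  nn <- normalize_to_reference(ser, 0.25)
  cols <- which(nn$ppm >= -0.25 & nn$ppm <= 0.25)
  expect_identical(unname(apply(nn$intensities[, cols], 1, max)),
                   rep(1, nrow(nn$intensities)))

  # scale invariance: multiplying one input spectrum leaves its output unchanged
  ser7 <- ser
  ser7$intensities[3, ] <- 7 * ser7$intensities[3, ]
  nn7 <- normalize_to_reference(ser7, 0.25)
  expect_equal(nn7$intensities[3, ], nn$intensities[3, ])

  # DSS heights {2, 4} with a constant analyte 10 -> analyte peaks {5, 2.5}
  ppm <- seq(4, -0.5, by = -0.005)  # 0 and 2 ppm exactly on grid
  mat <- rbind(
    peak_profile("lorentzian", 0, 0.02, 2, ppm) +
      peak_profile("lorentzian", 2, 0.02, 10, ppm),
    peak_profile("lorentzian", 0, 0.02, 4, ppm) +
      peak_profile("lorentzian", 2, 0.02, 10, ppm))
  two <- normalize_to_reference(spectrum_series(mat, ppm, c(0, 1)), 0.25)
  acols <- which(two$ppm >= 1.9 & two$ppm <= 2.1)
  expect_equal(max(two$intensities[1, acols]), 5, tolerance = 1e-3)
  expect_equal(max(two$intensities[2, acols]), 2.5, tolerance = 1e-3)
})

test_that("block_sum sums non-overlapping blocks, drops the tail and conserves signal", {
  ser <- mk_series(n = 7)
  bs <- block_sum(ser, 3)
  expect_equal(nrow(bs$intensities), 2L)  # floor(7/3)
  expect_equal(bs$times_h, c(mean(ser$times_h[1:3]), mean(ser$times_h[4:6])))
  expect_equal(sum(bs$intensities), sum(ser$intensities[1:6, ]))

  # constant unit spectra sum to the block size everywhere
  ones <- spectrum_series(matrix(1, 6, 64), seq(1, 0, length.out = 64),
                          1:6)
  expect_true(all(block_sum(ones, 3)$intensities == 3))

  ident <- block_sum(ser, 1)
  expect_identical(ident$intensities, ser$intensities)
  expect_error(block_sum(mk_series(n = 2), 3),
               class = "civmtrace_insufficient_data_error")
})

test_that("region_max_trajectory tracks a decaying peak's height", {
  decay <- synthetic_peak("d", center = list(type = "constant", ppm = 2),
                          amplitude = list(type = "exp_decay", A0 = 8,
                                           rate = 2),
                          fwhm = 0.02)
  sim <- tiny_series(list(decay), n_points = 4501L)  # 2.0 ppm on grid
  tr <- region_max_trajectory(sim$series, c(1.9, 2.1))
  truth <- sim$truth$peaks
  expect_equal(tr$intensity, truth$amplitude, tolerance = 1e-6)
  expect_equal(tr$time_h, truth$time_h)

  zeroed <- zero_region(sim$series, c(1.9, 2.1))
  expect_true(all(region_max_trajectory(zeroed, c(1.95, 2.05))$intensity == 0))

  two <- spectrum_series(matrix(c(1, 5), 2, 10), seq(1, 0, length.out = 10),
                         c(0, 1))
  expect_equal(region_max_trajectory(two, c(0, 1))$intensity, c(1, 5))
  expect_error(region_max_trajectory(two, c(7, 8)),
               class = "civmtrace_empty_error")
})

test_that("preprocess_pipeline composes the stages in the documented order", {
  sim <- tiny_series(list(const_peak("p", 2, 10)), duration_h = 2,
                     spacing_min = 6, noise_sd = 0)
  cfg <- preprocess_config(keep_ppm = c(-0.5, 3.5), water_ppm = c(2.5, 2.7),
                           max_time_h = 1.5, block = 3)
  out <- preprocess_pipeline(sim$series, cfg)
  expect_true(max(out$times_h) <= 1.5)
  wcols <- which(out$ppm >= 2.5 & out$ppm <= 2.7)
  expect_true(all(out$intensities[, wcols] == 0))
  dcols <- which(abs(out$ppm) <= 0.25)
  # each output spectrum is a sum of `block` individually normalised spectra
  expect_equal(unname(apply(out$intensities[, dcols], 1, max)),
               rep(3, nrow(out$intensities)))
  kept <- sum(sim$series$times_h <= 1.5)
  expect_equal(nrow(out$intensities), kept %/% 3)
  expect_length(out$meta$history, 7)  # simulate + 6 stages

  # normalisation does not commute with block summation when the reference
  # height varies between the spectra of a block
  ppm <- seq(4, -0.5, length.out = 600)
  dss_amps <- c(1, 2, 4, 1, 3, 2)
  mat <- t(vapply(seq_along(dss_amps), function(t)
    peak_profile("lorentzian", 0, 0.02, dss_amps[t], ppm) +
      peak_profile("lorentzian", 2, 0.02, 10, ppm), numeric(600)))
  vary <- spectrum_series(mat, ppm, seq_along(dss_amps) / 10)
  a <- block_sum(normalize_to_reference(vary, 0.25), 3)
  b <- normalize_to_reference(block_sum(vary, 3), 0.25)
  expect_gt(max(abs(a$intensities - b$intensities)), 1e-3)
})
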