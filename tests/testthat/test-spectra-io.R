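test_that("parse_acqus extracts scan counts, timestamps and optional fields", {
  rec <- parse_acqus(acqus_text(date = 1500000000, ns = 64, ds = 8))
  expect_s3_class(rec, "acquisition_record")
  expect_equal(rec$n_scans, 64)
  expect_equal(rec$n_dummy_scans, 8)
  expect_equal(rec$start_clock, 1500000000)
  expect_true(is.na(rec$pulse_width_us))

  # array parameters and derived quantities
  full <- acqus_text(extra = c(
    "##$TD= 42856", "##$SW_h= 11904.76",
    "##$P= (0..3)", "10 12.78 20 20",
    "##$D= (0..3)", "0 1.5 0 0",
    "##$O1= 2818.2", "##$SFO1= 600.13",
    "##$MASR= 6000", "##$PULPROG= <noesypr1d>"))
  rec <- parse_acqus(full)
  expect_equal(rec$acquisition_time_s, 42856 / (2 * 11904.76), tolerance = 1e-10)
  expect_equal(rec$pulse_width_us, 12.78)
  expect_equal(rec$recycle_delay_s, 1.5)
  expect_equal(rec$offset_ppm, 2818.2 / 600.13, tolerance = 1e-10)
  expect_equal(rec$spin_rate_hz, 6000)
  expect_equal(rec$label, "noesypr1d")
})

test_that("parse_acqus accepts degenerate but valid records and errors on missing keys", {
  rec <- parse_acqus(c("##$DATE= 1", "##$NS= 1", "##$DS= 0"))
  expect_equal(rec$n_scans, 1)
  expect_equal(rec$n_dummy_scans, 0)

  expect_error(parse_acqus("##$NS= 64"), "start_clock",
               class = "civmtrace_parse_error")
  expect_error(parse_acqus("##$DATE= 1500000000"), "n_scans",
               class = "civmtrace_parse_error")
})

test_that("assemble_series converts start clocks to hours and orders by time", {
  ppm <- seq(4, -0.5, length.out = 64)
  sp <- function(y0) list(ppm = ppm, intensity = rep(y0, 64))
  origin <- 1500000000
  recs <- lapply(c(0, 254, 508), function(off)
    acquisition_record(start_clock = origin + off, n_scans = 64))
  ser <- assemble_series(list(sp(1), sp(2), sp(3)), recs, origin)
  expect_equal(ser$times_h, c(0, 254, 508) / 3600, tolerance = 1e-12)

  # single spectrum at origin
  one <- assemble_series(list(sp(1)), recs[1], origin)
  expect_equal(one$times_h, 0)

  # any input permutation yields the same strictly increasing time axis
  perm <- c(3, 1, 2)
  ser2 <- assemble_series(list(sp(3), sp(1), sp(2)), recs[perm], origin)
  expect_identical(ser2$times_h, ser$times_h)
  expect_identical(ser2$intensities, ser$intensities)
  expect_true(all(diff(ser2$times_h) > 0))
})

test_that("assemble_series canonicalises ascending axes and rejects bad input", {
  asc <- seq(-0.5, 4, length.out = 64)
  origin <- 0
  recs <- list(acquisition_record(10, 1), acquisition_record(20, 1))
  y <- as.numeric(seq_len(64))
  ser <- assemble_series(list(list(ppm = asc, intensity = y),
                              list(ppm = rev(asc), intensity = rev(y))),
                         recs, origin)
  expect_true(all(diff(ser$ppm) < 0))
  # value attached to each ppm is preserved through reorientation
  expect_identical(ser$intensities[1, ], rev(y))
  expect_identical(ser$intensities[1, ], ser$intensities[2, ])

  expect_error(
    assemble_series(list(list(ppm = asc, intensity = y),
                         list(ppm = asc + 0.01, intensity = y)),
                    recs, origin),
    class = "civmtrace_axis_mismatch_error")
  expect_error(
    assemble_series(list(list(ppm = asc, intensity = y),
                         list(ppm = asc, intensity = y)),
                    list(acquisition_record(10, 1), acquisition_record(10, 1)),
                    origin),
    class = "civmtrace_duplicate_time_error")
})

test_that("series round-trips bitwise through the delimited interchange format", {
  sim <- tiny_series(list(const_peak("p", 2.0, 3)), noise_sd = 0.05)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_series_delim(sim$series, f)
  back <- read_series_delim(f)
  expect_identical(back$intensities, sim$series$intensities)
  expect_identical(back$ppm, sim$series$ppm)
  expect_identical(back$times_h, sim$series$times_h)
})

test_that("trajectory tables round-trip ridges and composites", {
  pts <- data.frame(time_index = 1:3, time_h = c(0, 0.1, 0.2),
                    ppm_index = c(5L, 6L, 7L), ppm = c(1.0, 1.01, 1.02),
                    smoothed_intensity = c(2, 3, NA),
                    raw_intensity = c(2.2, 3.1, 2.9),
                    interpolated = c(FALSE, FALSE, TRUE))
  r <- new_ridge("R01", pts, annotation = "citrate")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectories(list(r), f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 3L)  # one row per ridge point
  back <- read_trajectories(f)[[1]]
  expect_equal(back$points, r$points)
  expect_identical(back$annotation, "citrate")

  ct <- new_compound_trajectory("citrate", c("R01", "R02"), c(1, 2),
                                support = 1:3, times_h = c(0, 0.1),
                                value = c(5, 6), n_contributing = c(2L, 1L))
  write_trajectories(list(r, ct), f)
  both <- read_trajectories(f)
  expect_length(both, 2L)
  expect_equal(both[[2]]$value, c(5, 6))
  expect_equal(both[[2]]$n_contributing, c(2L, 1L))

  expect_error(write_trajectories(list(), f), class = "civmtrace_empty_error")
})

test_that("NMRPipe 1D spectra round-trip and FID input is rejected", {
  n <- 256L
  ppm <- seq(10, -0.5, length.out = n)
  y <- as.numeric(peak_profile("lorentzian", 4, 0.2, 7, ppm))
  f <- withr::local_tempfile(fileext = ".ft")
  write_nmrpipe_1d(ppm, y, f, obs_mhz = 600)
  back <- read_nmrpipe_1d(f)
  expect_equal(back$ppm, ppm, tolerance = 1e-6)
  # data stored as float32: single precision agreement
  expect_equal(back$intensity, y, tolerance = 1e-6)

  # flip the FT flag to simulate time-domain data
  con <- file(f, "r+b")
  seek(con, 220 * 4, rw = "write")
  writeBin(0, con, size = 4L, endian = "little")
  close(con)
  expect_error(read_nmrpipe_1d(f), "frequency-domain",
               class = "civmtrace_fid_error")
})
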