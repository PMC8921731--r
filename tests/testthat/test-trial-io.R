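make_sine_trial <- function(n = 900, rate = 300, freqs = c(50, 0.5)) {
  t <- (seq_len(n) - 1) / rate
  mk <- array(0, c(n, 1, 3))
  mk[, 1, 1] <- 5                        # constant channel
  mk[, 1, 2] <- sin(2 * pi * freqs[1] * t)
  mk[, 1, 3] <- sin(2 * pi * freqs[2] * t)
  marker_trial(mk, "a", rate)
}

test_that("marker trials validate their invariants", {
  d <- array(0, c(5, 2, 3))
  expect_s3_class(marker_trial(d, c("a", "b"), 100), "marker_trial")
  expect_error_class(marker_trial(d, c("a", "a"), 100), "invalid_input")
  expect_error_class(marker_trial(d, c("a", "b"), -1), "invalid_input")
  expect_error_class(
    marker_trial(d, c("a", "b"), 100, time = c(0, 1, 2, 3, 4)),
    "invalid_input")
  d2 <- d; d2[2, 1, 1] <- NA
  expect_error_class(marker_trial(d2, c("a", "b"), 100), "invalid_input")
  # NA is fine where flagged missing
  miss <- matrix(FALSE, 5, 2); miss[2, 1] <- TRUE
  expect_s3_class(marker_trial(d2, c("a", "b"), 100, missing = miss),
                  "marker_trial")
})

test_that("TRC writing and reading are inverse within float precision", {
  fx <- gait_fixture()
  tr <- fx$trial
  path <- tempfile(fileext = ".trc")
  write_trc(tr, path)
  tr2 <- read_trc(path)
  expect_identical(tr2$marker_names, tr$marker_names)
  expect_equal(tr2$rate, tr$rate)
  expect_lt(max(abs(tr2$data - tr$data)), 1e-6)
  # integer rates serialize with a decimal (e.g. "100.0")
  expect_match(readLines(path)[3], "^100\\.0\t")

  # missing samples become blanks and come back as flags
  miss <- tr$missing; miss[2:4, 5] <- TRUE
  trm <- marker_trial(tr$data, tr$marker_names, tr$rate, missing = miss)
  write_trc(trm, path)
  tr3 <- read_trc(path)
  expect_equal(sum(tr3$missing), 3L)
  expect_true(all(tr3$missing[2:4, 5]))

  expect_error_class(read_trc(tempfile(fileext = ".trc")), "format_error")
  bad <- tempfile(fileext = ".trc")
  writeLines(c("PathFileType\t4", "x", "not\tnumbers\there\tmm", "", "", ""),
             bad)
  expect_error_class(read_trc(bad), "format_error")
})

test_that("C3D writing and reading round-trip with unit normalization", {
  fx <- gait_fixture()
  tr <- fx$trial
  path <- tempfile(fileext = ".c3d")
  write_c3d(tr, path)
  tr2 <- read_c3d(path)
  expect_identical(tr2$marker_names, tr$marker_names)
  expect_equal(tr2$rate, tr$rate)
  expect_lt(max(abs(tr2$data - tr$data)), 1e-4)  # float32 storage

  # a file declaring meters is normalized to mm on read
  write_c3d(tr, path, units = "m")
  tr3 <- read_c3d(path)
  expect_lt(max(abs(tr3$data - tr$data)), 1e-3)

  # invalid samples (negative residual word) map to missing flags
  miss <- tr$missing; miss[c(3, 7, 9), 2] <- TRUE
  trm <- marker_trial(tr$data, tr$marker_names, tr$rate, missing = miss)
  write_c3d(trm, path)
  tr4 <- read_c3d(path)
  expect_equal(sum(tr4$missing), 3L)
  expect_true(all(tr4$missing[c(3, 7, 9), 2]))

  expect_error_class(read_c3d(tempfile(fileext = ".c3d")), "format_error")
  bad <- tempfile(fileext = ".c3d")
  writeBin(as.raw(rep(0, 100)), bad)
  expect_error_class(read_c3d(bad), "format_error")
})

test_that("trajectory CSV export has time plus xyz columns per marker", {
  fx <- gait_fixture()
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(fx$trial, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), n_frames(fx$trial))
  expect_equal(ncol(df), 1 + 3 * length(fx$trial$marker_names))
  expect_equal(df$th1_x, fx$trial$data[, "th1", 1], tolerance = 1e-9)
})

test_that("zero-phase Butterworth filtering matches the analytic response", {
  tr <- make_sine_trial()
  f <- lowpass_filter(tr, cutoff_hz = 5, order = 4)
  mid <- 200:700  # steady-state portion, away from the edges
  # DC gain is exactly 1
  expect_lt(max(abs(f$data[, 1, 1] - 5)), 1e-9)
  # 50 Hz is attenuated at least to the single-pass analytic magnitude
  # |H| = 1/sqrt(1 + (50/5)^8) ~ 1e-4 (the double pass squares it)
  expect_lt(max(abs(f$data[mid, 1, 2])), 1e-4)
  # 0.5 Hz passes within 1 %
  expect_gt(max(abs(f$data[mid, 1, 3])), 0.99)
  expect_lt(max(abs(f$data[mid, 1, 3])), 1.01)
  # length and rate unchanged
  expect_equal(n_frames(f), n_frames(tr))
  expect_equal(f$rate, tr$rate)

  expect_error_class(lowpass_filter(tr, cutoff_hz = 150), "invalid_parameter")
})

test_that("short gaps are interpolated and long gaps exclude the channel", {
  t <- (0:299) / 100
  mk <- array(rep(sin(2 * pi * t), 2 * 3), c(300, 2, 3))
  miss <- matrix(FALSE, 300, 2)
  miss[101:105, 1] <- TRUE        # 5-frame gap: interpolated
  miss[51:120, 2] <- TRUE         # 70-frame gap: excluded
  tr <- marker_trial(mk, c("ok", "bad"), 100, missing = miss)
  f <- lowpass_filter(tr, 5, 4)
  expect_false(any(f$missing[, "ok"]))
  expect_true(all(f$missing[, "bad"]))
  expect_identical(attr(f, "excluded_markers"), "bad")

  allmiss <- matrix(TRUE, 300, 1)
  tr2 <- marker_trial(array(0, c(300, 1, 3)), "x", 100, missing = allmiss)
  expect_error_class(lowpass_filter(tr2), "channel_error")
})

test_that("resampling decimates exactly and interpolates otherwise", {
  tr <- make_sine_trial(n = 300, rate = 300, freqs = c(1, 1))
  # same rate: identity
  expect_identical(resample_trial(tr, 300), tr)
  # 300 -> 100 Hz keeps every 3rd sample of 300 frames -> 100 frames
  r <- resample_trial(tr, 100)
  expect_equal(n_frames(r), 100L)
  expect_equal(r$data[, 1, 2], tr$data[seq(1, 300, 3), 1, 2])
  # samples match the closed form of the 1 Hz sinusoid
  expect_lt(max(abs(r$data[, 1, 3] - sin(2 * pi * 1 * r$time))), 1e-9)
  # non-integer ratio interpolates on a uniform grid
  r2 <- resample_trial(tr, 140)
  expect_equal(r2$rate, 140)
  expect_lt(max(abs(diff(r2$time) - 1 / 140)), 1e-12)
  expect_error_class(resample_trial(tr, 600), "invalid_parameter")
})

test_that("gait-cycle cropping keeps the half-open window and re-zeroes time", {
  fx <- gait_fixture()
  tr <- fx$trial
  full <- crop_cycle(tr, gait_cycle(0, n_frames(tr)))
  expect_equal(full$data, tr$data)
  expect_equal(full$time, tr$time)

  part <- crop_cycle(tr, gait_cycle(10, 20))
  expect_equal(n_frames(part), 10L)
  expect_equal(part$time[1], 0)
  expect_equal(part$data[1, , ], tr$data[11, , ])

  # a 1.39 s cycle at 100 Hz is 139 frames
  expect_equal(n_frames(tr), 139L)

  expect_error_class(gait_cycle(5, 5), "invalid_input")
  expect_error_class(crop_cycle(tr, gait_cycle(0, 1000)), "invalid_input")
})
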