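test_that("load_stream reads well-formed files and infers the rate", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_sensor_csv(f, t = c(0, 0.02, 0.04), ax = c(0, 0, 0),
                   ay = c(0, 0, 0), az = c(1, 1, 1))
  st <- load_stream(f, subject_id = "S1", side = "weak")
  expect_s3_class(st, "pdt_stream")
  expect_length(st$t, 3)
  expect_equal(st$rate_hz, 50)
  expect_equal(st$subject_id, "S1")
})

test_that("load_stream resolves subject and side from the file name", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "P07_weak.csv")
  write_sensor_csv(f, t = c(0, 0.02, 0.04), ax = 0, ay = 0, az = 1)
  st <- load_stream(f)
  expect_equal(st$subject_id, "P07")
  expect_equal(st$side, "weak")
})

test_that("load_stream converts m/s^2 dialects to g and mirrors left hands", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_sensor_csv(f, t = c(0, 0.02, 0.04), ax = 9.80665, ay = 0, az = 0)
  st <- load_stream(f, units = "ms2", side = "weak", subject_id = "S")
  expect_equal(st$ax, c(1, 1, 1))
  st_l <- load_stream(f, units = "ms2", hand = "left", side = "weak",
                      subject_id = "S")
  expect_equal(st_l$ax, c(-1, -1, -1))
})

test_that("malformed sensor files are rejected", {
  dir <- withr::local_tempdir()
  bad_cols <- file.path(dir, "a_weak.csv")
  utils::write.csv(data.frame(t = 0:2, x = 1), bad_cols, row.names = FALSE)
  expect_error(load_stream(bad_cols), class = "pdt_format_error")

  nonmono <- file.path(dir, "b_weak.csv")
  write_sensor_csv(nonmono, t = c(0.0, 0.02, 0.01), ax = 0, ay = 0, az = 1)
  expect_error(load_stream(nonmono), class = "pdt_data_error")

  empty <- file.path(dir, "c_weak.csv")
  writeLines("t,ax,ay,az", empty)
  expect_error(load_stream(empty), class = "pdt_data_error")

  expect_error(load_stream(file.path(dir, "nope.csv")),
               class = "pdt_format_error")
})

test_that("irregularly spaced input is resampled onto a uniform grid", {
  f <- withr::local_tempfile(fileext = ".csv")
  t_irr <- c(0, 0.018, 0.042, 0.060, 0.081, 0.100, 0.121, 0.139, 0.161)
  write_sensor_csv(f, t = t_irr, ax = 0, ay = t_irr, az = 1)
  st <- load_stream(f, side = "weak", subject_id = "S", rate_hz = 50)
  expect_equal(diff(st$t), rep(0.02, length(st$t) - 1), tolerance = 1e-12)
  expect_equal(st$ay, st$t, tolerance = 1e-9)  # linear signal survives
})

test_that("estimate_gravity returns unit vectors and passes a constant", {
  t <- seq(0, 5 - 0.02, by = 0.02)
  st <- pdt_stream(t, rep(0, length(t)), rep(0, length(t)),
                   rep(1, length(t)), side = "weak", subject_id = "S")
  g <- estimate_gravity(st, cutoff_hz = 1)
  expect_equal(sqrt(rowSums(g^2)), rep(1, length(t)), tolerance = 1e-9)
  expect_equal(max(abs(g[, 1])), 0, tolerance = 1e-6)
  expect_equal(max(abs(g[, 2])), 0, tolerance = 1e-6)
  expect_equal(g[, 3], rep(1, length(t)), tolerance = 1e-6)
})

test_that("a 10 Hz disturbance is rejected by the 1 Hz gravity filter", {
  rate <- 50
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  st <- pdt_stream(t, 0.1 * sin(2 * pi * 10 * t), rep(0, length(t)),
                   rep(1, length(t)), side = "weak", subject_id = "S")
  g <- estimate_gravity(st, cutoff_hz = 1)
  # order-2 Butterworth: |H(10 Hz)| = 1/sqrt(1 + (10/1)^4) ~ 0.01, so the
  # residual on X is ~0.001 g; allow 0.02 away from the edges
  mid <- t > 1 & t < 9
  expect_lt(max(abs(g[mid, 1])), 0.02)
  expect_lt(max(abs(g[mid, 3] - 1)), 0.02)
})

test_that("gravity estimation validates its parameters", {
  t <- seq(0, 1 - 0.02, by = 0.02)
  st <- pdt_stream(t, 0, 0, rep(1, length(t)), side = "weak",
                   subject_id = "S")
  expect_error(estimate_gravity(st, cutoff_hz = 30),
               class = "pdt_parameter_error")
  expect_error(estimate_gravity(st, cutoff_hz = 0.5),
               class = "pdt_data_error")  # shorter than warm-up
})

test_that("drift and pronation angles follow the tilt geometry", {
  expect_equal(drift_angle(c(0, 0, 1)), 0)
  expect_equal(drift_angle(c(0, 0.5, sqrt(3) / 2)), 30)
  expect_equal(drift_angle(c(0, 1, 0)), 90)
  expect_equal(pronation_angle(c(0, 0, 1)), 0)
  expect_equal(pronation_angle(c(1, 0, 0)), 90)
  expect_equal(pronation_angle(c(sqrt(0.5), 0, sqrt(0.5))), 45)
  expect_error(drift_angle(c(0, 0, 2)), class = "pdt_contract_error")
})

test_that("drift is odd in gy; pronation is odd in gx at fixed gz > 0", {
  for (v in c(0.1, 0.4, 0.8)) {
    gz <- sqrt(1 - v^2)
    expect_equal(drift_angle(c(0, v, gz)), -drift_angle(c(0, -v, gz)))
    expect_equal(pronation_angle(c(v, 0, gz)),
                 -pronation_angle(c(-v, 0, gz)))
  }
})

test_that("vertical forearm holds the last valid pronation value", {
  expect_warning(p <- pronation_angle(rbind(c(0, 1, 0))),
                 "pronation undefined")
  expect_true(is.na(p))
  expect_equal(fill_hold_last(c(10, 20, NA, NA, 30)), c(10, 20, 20, 20, 30))
  expect_equal(fill_hold_last(c(NA, 5, NA)), c(5, 5, 5))
})

test_that("stream_to_angles recovers a constant posture exactly", {
  t <- seq(0, 20 - 0.02, by = 0.02)
  st <- pdt_stream(t, 0, 0, rep(1, length(t)), side = "weak",
                   subject_id = "S")
  ang <- stream_to_angles(st)
  expect_equal(nrow(ang), length(t))
  expect_equal(max(abs(ang$drift_deg)), 0, tolerance = 1e-6)
  expect_equal(max(abs(ang$pron_deg)), 0, tolerance = 1e-6)
})

test_that("noise-free trajectories round-trip within 0.5 degrees RMS", {
  for (th in c(-60, 0, 70)) {
    for (ph in c(-150, 0, 150)) {
      truth <- make_slow_angles(th, ph)
      rec <- stream_to_angles(angles_to_accel(truth))
      rms <- sqrt(mean((rec$drift_deg - truth$drift_deg)^2 +
                       (rec$pron_deg - truth$pron_deg)^2))
      expect_lt(rms, 0.5)
    }
  }
})

test_that("white sensor noise of 0.05 g moves angles by under 2 deg RMS", {
  truth <- make_slow_angles(30, 60)
  clean <- stream_to_angles(angles_to_accel(truth))
  noisy <- stream_to_angles(angles_to_accel(truth, noise_sd = 0.05,
                                            seed = 11))
  rms_d <- sqrt(mean((noisy$drift_deg - clean$drift_deg)^2))
  rms_p <- sqrt(mean((noisy$pron_deg - clean$pron_deg)^2))
  expect_lt(rms_d, 2)
  expect_lt(rms_p, 2)
})

test_that("streams shorter than the filter warm-up are refused", {
  t <- seq(0, 0.5 - 0.02, by = 0.02)
  st <- pdt_stream(t, 0, 0, rep(1, length(t)), side = "weak",
                   subject_id = "S")
  expect_error(stream_to_angles(st), class = "pdt_data_error")
})
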