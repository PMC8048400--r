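test_that("acceleration converts to body-weight vGRF under both conventions", {
  one_g <- timeseries(rep(GRAVITY, 100), 500, units = "m/s^2")
  expect_equal(accel_to_vgrf(one_g, 60, "proper")$samples, rep(1, 100))
  standing <- timeseries(rep(0, 100), 500, units = "m/s^2")
  expect_equal(accel_to_vgrf(standing, 60, "kinematic")$samples, rep(1, 100))
  two_g <- timeseries(rep(2 * GRAVITY, 100), 500, units = "m/s^2")
  bw <- accel_to_vgrf(two_g, 60, "proper")
  expect_equal(bw$samples[1], 2)
  # un-normalized force: mass times acceleration
  expect_equal(bw$samples[1] * 60 * GRAVITY, 1177.2)
  expect_identical(bw$units, "BW")
  expect_error(accel_to_vgrf(one_g, 0, "proper"), "body_mass")
})

test_that("discrete variables reproduce rectangle and half-sine oracles", {
  # rectangle: constant 1 BW across a 0.2 s interval
  rect <- timeseries(rep(1, 501), 500, units = "BW")
  iv <- data.frame(start = 0.2, end = 0.4)
  rec <- discrete_variables(rect, iv)
  expect_equal(rec$peak_bw, 1)
  expect_equal(rec$impulse_bws, 0.2)
  expect_equal(rec$contact_time_s, 0.2)

  # half-sine with unit-mean impulse: peak pi/(2 f tc), impulse 1/f
  f <- 3.0; tc <- 0.19
  w <- step_waveform(f, tc, impact_amplitude = 0, rate = 500)
  ts <- timeseries(w$samples, 500, units = "BW")
  rec2 <- discrete_variables(ts, data.frame(start = 0, end = tc))
  expect_equal(rec2$peak_bw, pi / (2 * f * tc), tolerance = 1e-3)
  expect_equal(rec2$impulse_bws, 1 / f, tolerance = 1e-3)

  expect_identical(nrow(discrete_variables(ts, iv[0, ])), 0L)
  expect_error(discrete_variables(ts, data.frame(start = 5, end = 5.2)),
               "extent")
})

test_that("impulse is consistent with the mean-force x contact-time identity", {
  qt <- quiet_trial()
  rec <- discrete_variables(qt$proc$force_bw, qt$proc$intervals_force)
  # impulse / contact time = average stance vGRF; must sit between the
  # stance extremes and near the half-sine mean (2/pi of the peak)
  mean_bw <- rec$impulse_bws / rec$contact_time_s
  expect_true(all(mean_bw > 0 & mean_bw < rec$peak_bw))
  expect_equal(mean_bw / rec$peak_bw, rep(2 / pi, nrow(rec)),
               tolerance = 0.05)
})

test_that("condition summaries average complete steps inside the window", {
  recs <- data.frame(step = 1:30,
                     peak_bw = rep(c(2.5, 2.7), 15),
                     impulse_bws = rep(0.33, 30),
                     contact_time_s = rep(c(0.18, 0.20), 15))
  iv <- data.frame(start = seq(1, by = 1 / 3, length.out = 30))
  iv$end <- iv$start + 0.2
  sm <- summarize_condition(recs, iv, step_freq = 3.0, "S1", "female", 3.8,
                            "treadmill", window_from = 0, window_to = 12)
  expect_equal(sm$contact_time, 0.19)
  expect_equal(sm$peak_vgrf, 2.6)
  expect_identical(sm$n_steps, 30L)
  # restricting the window drops the excluded steps from the mean
  sm2 <- summarize_condition(recs, iv, 3.0, "S1", "female", 3.8,
                             "treadmill", window_from = 1, window_to = 2.1)
  expect_lt(sm2$n_steps, 30L)
  expect_error(summarize_condition(recs, iv, 3.0, "S1", "female", 3.8,
                                   "treadmill", 100, 110), "window")
})

test_that("treadmill summaries track simulator ground truth", {
  qt <- quiet_trial()
  sm <- qt$proc$summary
  gt <- qt$trial$ground_truth
  trd <- sm[sm$source == "treadmill", ]
  expect_equal(trd$peak_vgrf, mean(gt$steps$peak_vgrf), tolerance = 0.01)
  expect_equal(trd$vertical_impulse, gt$steps$impulse[1], tolerance = 0.01)
  # contact time: threshold truncation shortens, 30 Hz smoothing widens;
  # net within 2 samples of the true stance duration
  expect_lt(abs(trd$contact_time - gt$contact_time),
            2 / qt$proc$force_bw$rate + 1e-9)
  # per-step impulse balance on the raw force channel
  f_bw <- qt$trial$force$samples / (qt$trial$body_mass * GRAVITY)
  tt <- ts_times(qt$trial$force)
  dt <- 1 / qt$trial$force$rate
  for (k in c(1, 20, 60)) {
    idx <- which(tt >= gt$steps$contact_start[k] &
                   tt <= gt$steps$contact_end[k])
    y <- f_bw[idx]
    expect_equal(dt * (sum(y) - (y[1] + y[length(y)]) / 2),
                 1 / gt$step_frequency, tolerance = 1e-6)
  }
})

test_that("acceleration-source estimates carry a stable bias across seeds", {
  biases <- vapply(c(31, 32, 33), function(s) {
    cfg <- default_config(seed = s, trial_duration = 14)
    tr <- simulate_trial(subject_profile("S1", "female", 52), 3.8, cfg)
    p <- process_trial(tr, lag = cfg$clock_offset, cfg)
    p$contact_time[p$source == "acceleration"] /
      tr$ground_truth$contact_time
  }, numeric(1))
  expect_true(all(biases > 1))            # widened, never shrunk
  expect_lt(max(biases) - min(biases), 0.02)  # and stable across seeds
})
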