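test_that("step waveform satisfies impulse balance and the half-sine closed form", {
  # impulse balance holds by construction across parameter combinations
  for (f in c(2.8, 3.0, 3.1)) {
    for (amp in c(0, 0.4, 0.8)) {
      w <- step_waveform(f, 0.19, impact_amplitude = amp, rate = 1000)
      dx <- 1 / 1000
      integ <- dx * (sum(w$samples) - (w$samples[1] + w$samples[length(w$samples)]) / 2)
      expect_equal(integ, 1 / f, tolerance = 1e-9)
    }
  }
  # no impact bump: peak of unit-mean-impulse half-sine is pi/(2 f tc)
  w <- step_waveform(3.0, 0.19, impact_amplitude = 0, rate = 1000)
  expect_equal(max(w$samples), pi / (2 * 3.0 * 0.19), tolerance = 1e-3)
})

test_that("step waveform rejects a stance that leaves no flight phase", {
  expect_error(step_waveform(3.0, 0.40), "flight")
  expect_error(step_waveform(3.0, 1 / 3), "flight")
})

test_that("gait parameter defaults are deterministic and match the speed mapping", {
  zero <- c(step_frequency = 0, contact_time = 0, impact_amplitude = 0)
  p38 <- default_gait_parameters(3.8, "female", zero)
  expect_equal(p38$contact_time, 0.1985)
  p48 <- default_gait_parameters(4.8, "male", zero)
  expect_equal(p48$contact_time, 0.176)
  expect_equal(p48$step_frequency, 3.01)
  expect_identical(default_gait_parameters(4.1, "male", zero),
                   default_gait_parameters(4.1, "male", zero))
  expect_error(default_gait_parameters(2.0, "male", zero), "speed")
})

test_that("sensor model is consistent with Newton's second law", {
  qt <- quiet_trial()
  tr <- qt$trial
  m <- tr$body_mass
  # zero noise/artifact/tilt, proper convention: m * a reproduces force
  ta <- ts_times(tr$acceleration)
  tf <- ts_times(tr$force)
  f_at_ta <- approx(tf, tr$force$samples, xout = ta)$y
  err <- max(abs(m * tr$acceleration$samples - f_at_ta), na.rm = TRUE)
  expect_lt(err, 0.01 * max(tr$force$samples))
})

test_that("kinematic convention reads free fall as -g", {
  cfg <- quiet_config(signal_convention = "kinematic")
  sub <- subject_profile("S1", "female", 52)
  tr <- simulate_trial(sub, 3.8, cfg)
  gt <- tr$ground_truth$steps
  ta <- ts_times(tr$acceleration)
  # samples strictly inside flight (between consecutive stances)
  flight <- ta > gt$contact_end[5] + 0.02 & ta < gt$contact_start[6] - 0.02
  expect_equal(mean(tr$acceleration$samples[flight]), -GRAVITY,
               tolerance = 1e-6)
})

test_that("ground truth records the configured clock offset and ordered steps", {
  cfg <- quiet_config(clock_offset = 0.5)
  tr <- simulate_trial(subject_profile("S2", "male", 64), 4.1, cfg)
  gt <- tr$ground_truth
  expect_equal(gt$clock_offset, 0.5)
  expect_true(all(gt$steps$contact_end > gt$steps$contact_start))
  expect_true(all(diff(gt$steps$contact_start) > 0))
  # steps non-overlapping
  expect_true(all(gt$steps$contact_start[-1] >=
                    gt$steps$contact_end[-nrow(gt$steps)]))
  expect_error(simulate_trial(subject_profile("S2", "male", 64), 4.1,
                              quiet_config(trial_duration = 1)),
               "duration")
})

test_that("countermovement jump has the expected phases", {
  cfg <- quiet_config()
  sub <- subject_profile("S1", "female", 52)
  cmj <- simulate_cmj(sub, cfg)
  f <- cmj$force$samples
  bw <- 52 * GRAVITY
  # quiet standing within 0.1% of body weight
  expect_lt(max(abs(f[1:500] / bw - 1)), 0.001)
  # push-off peak of at least 2 BW
  expect_gte(max(f / bw), 2)
  # exactly one contiguous interval below 5% BW: the flight
  below <- rle(f < 0.05 * bw)
  expect_identical(sum(below$values), 1L)
  # flight acceleration reads 0 under the proper convention, zero noise
  ta <- ts_times(cmj$acceleration)
  tf <- ts_times(cmj$force)
  flight_t <- range(tf[f < 0.01 * bw])
  in_flight <- ta > flight_t[1] + 0.05 & ta < flight_t[2] - 0.05
  expect_equal(max(abs(cmj$acceleration$samples[in_flight])), 0,
               tolerance = 1e-9)
})

test_that("cohort layout follows the per-sex speed design", {
  sc <- small_cohort()
  coh <- sc$cohort
  expect_identical(length(coh$trials), 4L * 2L + 3L * 3L)
  speeds <- vapply(coh$trials, function(t) t$speed, numeric(1))
  sexes <- vapply(coh$trials, function(t) t$sex, character(1))
  expect_setequal(unique(speeds[sexes == "female"]), c(3.8, 4.9))
  expect_setequal(unique(speeds[sexes == "male"]), c(3.8, 4.1, 5.4))
  # every subject session is bracketed by two countermovement jumps
  expect_setequal(names(coh$cmj), coh$subjects$subject_id)
  expect_true(all(vapply(coh$cmj, function(x)
    all(c("pre", "post") %in% names(x)), logical(1))))
  expect_error(simulate_cohort(1, 0, sc$cfg), "2 subjects")
})

test_that("identical seeds reproduce the cohort bit for bit", {
  cfg <- default_config(seed = 77, trial_duration = 4)
  a <- simulate_cohort(2, 1, cfg)
  b <- simulate_cohort(2, 1, cfg)
  expect_identical(
    lapply(a$trials, function(t) t$acceleration$samples),
    lapply(b$trials, function(t) t$acceleration$samples))
  expect_identical(
    lapply(a$trials, function(t) t$force$samples),
    lapply(b$trials, function(t) t$force$samples))
  expect_identical(a$subjects, b$subjects)
  c2 <- simulate_cohort(2, 1, default_config(seed = 78, trial_duration = 4))
  expect_false(identical(a$trials[[1]]$acceleration$samples,
                         c2$trials[[1]]$acceleration$samples))
})

test_that("subject effects are drawn once and reused across conditions", {
  sc <- small_cohort()
  coh <- sc$cohort
  # for one male subject, true step frequency at each speed must differ by
  # exactly the deterministic speed term, i.e. share one subject offset
  male_id <- coh$subjects$subject_id[coh$subjects$sex == "male"][1]
  trs <- Filter(function(t) t$subject_id == male_id, coh$trials)
  offs <- vapply(trs, function(t)
    t$ground_truth$step_frequency - (3.0 + 0.05 * (t$speed - 4.6)),
    numeric(1))
  expect_equal(max(offs) - min(offs), 0, tolerance = 1e-12)
})
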