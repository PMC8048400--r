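# Shared fixtures for the suite. Everything is generated in code; the
# expensive full-cohort run is memoised so several files can share it.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# noise-free configuration: deterministic signal path
quiet_config <- function(seed = 3, ...) {
  default_config(seed = seed, noise_sd = 0, artifact_amplitude = 0,
                 clock_offset = 0, ...)
}

# one noise-free female trial at 3.8 m/s plus its processed channels
quiet_trial <- function() {
  memo("quiet_trial", {
    cfg <- quiet_config()
    sub <- subject_profile("S1", "female", 52)
    tr <- simulate_trial(sub, 3.8, cfg)
    list(cfg = cfg, sub = sub, trial = tr,
         proc = process_trial(tr, lag = 0, cfg, detail = TRUE))
  })
}

# small mixed cohort with default noise, short enough for fast tests
small_cohort <- function() {
  memo("small_cohort", {
    cfg <- default_config(seed = 21, trial_duration = 14)
    coh <- simulate_cohort(4, 3, cfg)
    list(cfg = cfg, cohort = coh, proc = process_cohort(coh, cfg))
  })
}

# the full study-scale run: default cohort, default noise model
full_run <- function(seed = 11) {
  memo(paste0("full_run_", seed), {
    cfg <- default_config(seed = seed)
    coh <- simulate_cohort(24, 13, cfg)
    proc <- process_cohort(coh, cfg)
    list(cfg = cfg, cohort = coh, proc = proc,
         report = run_experiment(proc$summaries, seed = seed, cfg))
  })
}

# synthetic feature rows from a known linear map (for model tests)
linear_feature_rows <- function(n, beta = c(intercept = 1.5, speed = 0.12,
                                            accel_estimate = 0.3,
                                            step_frequency = -0.25,
                                            body_mass = 0.002),
                                sigma = 0.08, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    subject_id = sprintf("S%02d", rep(seq_len(ceiling(n / 2)), each = 2))[1:n],
    speed = sample(c(3.8, 4.1, 4.9, 5.4), n, replace = TRUE),
    accel_estimate = stats::rnorm(n, 2.8, 0.2),
    step_frequency = stats::rnorm(n, 3.0, 0.15),
    body_mass = stats::rnorm(n, 55, 9))
  d$target <- beta[["intercept"]] + beta[["speed"]] * d$speed +
    beta[["accel_estimate"]] * d$accel_estimate +
    beta[["step_frequency"]] * d$step_frequency +
    beta[["body_mass"]] * d$body_mass +
    stats::rnorm(n, 0, sigma)
  d
}

# analytic above-threshold duration of a half-sine stance of peak P
above_threshold_duration <- function(peak, contact_time, threshold = 0.05) {
  contact_time - 2 * (contact_time / pi) * asin(threshold / peak)
}
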