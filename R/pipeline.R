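#' Process one trial into per-condition summaries
#'
#' The full single-trial processing chain: the force channel is
#' down-sampled to the accelerometer rate, normalized to body weights
#' and low-pass filtered (30 Hz zero-lag); the acceleration channel is
#' shifted by the estimated clock lag and low-pass filtered (10 Hz
#' zero-lag). Stance phases are detected independently on each channel
#' (5% BW / 0 m/s^2 thresholds), discrete variables extracted per step,
#' and steps inside the final analysis window averaged into one summary
#' row per source.
#'
#' @param trial a [trial_recording()].
#' @param lag clock lag in s (from [estimate_subject_lag()]); applied
#'   as `-lag` to the acceleration channel.
#' @param config a [default_config()].
#' @param detail if `TRUE`, also return the processed channels and
#'   intervals.
#' @return two-row data.frame (sources `"treadmill"`,
#'   `"acceleration"`) with the [summarize_condition()] columns plus
#'   `body_mass`; with `detail = TRUE` a list also carrying the
#'   intermediate signals.
#' @export
process_trial <- function(trial, lag = 0, config = default_config(),
                          detail = FALSE) {
  stopifnot(inherits(trial, "trial_recording"))
  m <- trial$body_mass

  f_ds <- downsample(trial$force, config$accel_rate)
  f_bw <- timeseries(f_ds$samples / (m * GRAVITY), f_ds$rate,
                     f_ds$start_time, units = "BW")
  f_bw <- zero_lag_butterworth(f_bw, config$force_filter)

  a_al <- apply_lag(trial$acceleration, lag)
  a_f  <- zero_lag_butterworth(a_al, config$accel_filter)
  a_bw <- accel_to_vgrf(a_f, m, config$signal_convention)

  t_end <- min(ts_end_time(f_bw), ts_end_time(a_f))
  w_from <- t_end - config$analysis_window_s

  iv_f <- detect_stance_force(f_bw, config$force_threshold_bw,
                              config$min_stance_s, config$min_flight_s)
  iv_a <- detect_stance_accel(a_f, config$accel_threshold,
                              config$min_stance_s, config$min_flight_s,
                              config$signal_convention)

  sf_f <- step_frequency(iv_f[iv_f$start >= w_from & iv_f$start <= t_end, ,
                              drop = FALSE],
                         config$analysis_window_s)
  sf_a <- step_frequency(iv_a[iv_a$start >= w_from & iv_a$start <= t_end, ,
                              drop = FALSE],
                         config$analysis_window_s)

  rec_f <- discrete_variables(f_bw, iv_f)
  rec_a <- discrete_variables(a_bw, iv_a)

  sm <- rbind(
    summarize_condition(rec_f, iv_f, sf_f, trial$subject_id, trial$sex,
                        trial$speed, "treadmill", w_from, t_end),
    summarize_condition(rec_a, iv_a, sf_a, trial$subject_id, trial$sex,
                        trial$speed, "acceleration", w_from, t_end))
  sm$body_mass <- m
  if (!detail) return(sm)
  list(summary = sm, force_bw = f_bw, accel_filtered = a_f,
       accel_vgrf = a_bw, intervals_force = iv_f, intervals_accel = iv_a,
       window = c(w_from, t_end))
}

#' Process a whole cohort
#'
#' Estimates each subject's clock lag from the countermovement-jump
#' pair bracketing their session, then runs [process_trial()] on every
#' condition.
#'
#' @param cohort a `"gait_cohort"` from [simulate_cohort()] (or an
#'   equivalent list with `subjects`, `trials`, `cmj`).
#' @param config a [default_config()].
#' @return list: `summaries` (one data.frame, two rows per trial) and
#'   `lags` (per-subject estimated lag and peak correlations).
#' @export
process_cohort <- function(cohort, config = default_config()) {
  lags <- list()
  for (i in seq_len(nrow(cohort$subjects))) {
    id <- cohort$subjects$subject_id[i]
    est <- estimate_subject_lag(cohort$cmj[[id]],
                                cohort$subjects$body_mass[i], config)
    lags[[i]] <- data.frame(
      subject_id = id, lag = est$lag,
      r_pre = est$per_jump$pre$peak_correlation,
      r_post = est$per_jump$post$peak_correlation)
  }
  lags <- do.call(rbind, lags)
  out <- vector("list", length(cohort$trials))
  for (j in seq_along(cohort$trials)) {
    tr <- cohort$trials[[j]]
    lag <- lags$lag[match(tr$subject_id, lags$subject_id)]
    out[[j]] <- process_trial(tr, lag, config)
  }
  list(summaries = do.call(rbind, out), lags = lags)
}
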