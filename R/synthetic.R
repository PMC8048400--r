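#' Subject profile for the gait simulator
#'
#' A simulated runner: identity, sex, body mass, and per-subject random
#' offsets (drawn once per subject and reused across all of that
#' subject's conditions) for step frequency, contact time and the
#' impact-bump amplitude. The offsets are what make conditions from the
#' same runner correlated, as they are in real cohorts.
#'
#' @param subject_id character scalar.
#' @param sex `"female"` or `"male"`.
#' @param body_mass body mass in kg, > 0.
#' @param effects named numeric vector with elements `step_frequency`
#'   (Hz), `contact_time` (s) and `impact_amplitude` (BW).
#' @return object of class `"subject_profile"`.
#' @export
subject_profile <- function(subject_id, sex, body_mass,
                            effects = c(step_frequency = 0,
                                        contact_time = 0,
                                        impact_amplitude = 0)) {
  sex <- match.arg(sex, c("female", "male"))
  if (body_mass <= 0) stop("body_mass must be > 0")
  needed <- c("step_frequency", "contact_time", "impact_amplitude")
  if (!all(needed %in% names(effects)))
    stop("effects must contain: ", paste(needed, collapse = ", "))
  structure(list(subject_id = as.character(subject_id), sex = sex,
                 body_mass = body_mass, effects = effects[needed]),
            class = "subject_profile")
}

#' Speed-dependent gait parameters
#'
#' Deterministic defaults mapping running speed to step frequency,
#' ground contact time and impact-bump amplitude, plus the subject's
#' random offsets. Contact time shortens and step frequency rises with
#' speed, consistent with treadmill running at 3.8-5.4 m/s.
#'
#' @param speed running speed in m/s, within 3.0-6.0.
#' @param sex `"female"` or `"male"` (validated; the default mapping is
#'   sex-neutral, sex differences enter through subject effects and the
#'   cohort's speed assignment).
#' @param effects per-subject offsets as in [subject_profile()].
#' @return list with `step_frequency` (Hz), `contact_time` (s),
#'   `impact_amplitude` (BW).
#' @examples
#' default_gait_parameters(3.8, "female")  # contact_time 0.1985 s
#' @export
default_gait_parameters <- function(speed, sex,
                                    effects = c(step_frequency = 0,
                                                contact_time = 0,
                                                impact_amplitude = 0)) {
  if (speed < 3.0 || speed > 6.0)
    stop("speed must be within 3.0-6.0 m/s")
  match.arg(sex, c("female", "male"))
  list(
    step_frequency   = 3.0 + 0.05 * (speed - 4.6) +
      unname(effects[["step_frequency"]]),
    contact_time     = 0.284 - 0.0225 * speed +
      unname(effects[["contact_time"]]),
    impact_amplitude = max(0, 0.4 + unname(effects[["impact_amplitude"]]))
  )
}

# Unscaled stance shape on relative time 0..contact_time: half-sine
# active bump of unit-impulse peak height plus a raised-cosine impact
# bump centred at 0.15*tc with full width 0.25*tc. Vectorised over t.
step_shape <- function(t, contact_time, step_frequency, impact_amplitude) {
  p0 <- pi / (2 * step_frequency * contact_time)  # unit-impulse half-sine peak
  inside <- t >= 0 & t <= contact_time
  w <- numeric(length(t))
  w[inside] <- p0 * sin(pi * t[inside] / contact_time)
  if (impact_amplitude > 0) {
    ctr <- 0.15 * contact_time
    wid <- 0.25 * contact_time
    nb <- abs(t - ctr) <= wid / 2 & inside
    w[nb] <- w[nb] +
      impact_amplitude * 0.5 * (1 + cos(2 * pi * (t[nb] - ctr) / wid))
  }
  w
}

trapz <- function(y, dx) dx * (sum(y) - (y[1L] + y[length(y)]) / 2)

#' Single-step vertical GRF waveform
#'
#' One stance phase of vertical ground reaction force in body weights:
#' a half-sine active bump plus an optional raised-cosine impact bump,
#' rescaled so the trapezoidal integral of the returned samples equals
#' exactly `1/step_frequency` BW.s — the impulse-balance constraint that
#' makes the average vGRF over a full step cycle one body weight.
#'
#' @param step_frequency steps per second, Hz (> 0).
#' @param contact_time stance duration in s; must be shorter than the
#'   step period (a flight phase must exist).
#' @param impact_amplitude impact-bump height in BW (0 disables it).
#' @param rate sampling rate in Hz.
#' @return list with `samples` (BW, at times `0, 1/rate, ...` covering
#'   the stance), `times`, and `scale` (the impulse-balance factor).
#' @examples
#' w <- step_waveform(3.0, 0.19, impact_amplitude = 0, rate = 1000)
#' max(w$samples)  # ~ pi / (2 * 3.0 * 0.19)
#' @export
step_waveform <- function(step_frequency, contact_time,
                          impact_amplitude = 0, rate = 1000) {
  if (step_frequency <= 0) stop("step_frequency must be > 0")
  if (contact_time <= 0) stop("contact_time must be > 0")
  if (contact_time >= 1 / step_frequency)
    stop("contact_time must be shorter than the step period (no flight phase)")
  tt <- seq(0, contact_time, by = 1 / rate)
  u <- step_shape(tt, contact_time, step_frequency, impact_amplitude)
  raw <- trapz(u, 1 / rate)
  scale <- (1 / step_frequency) / raw
  list(samples = u * scale, times = tt, scale = scale)
}

# Evaluate the scaled vGRF (BW) of a whole trial at arbitrary times.
# Steps share one (frequency, contact time, amplitude) but each has its
# own impulse-balance scale from the force-grid trapezoid.
trial_vgrf_fun <- function(starts, contact_time, step_frequency,
                           impact_amplitude, scales) {
  force(starts); force(scales)
  function(t) {
    out <- numeric(length(t))
    for (k in seq_along(starts)) {
      rel <- t - starts[k]
      inside <- rel >= 0 & rel <= contact_time
      if (any(inside))
        out[inside] <- step_shape(rel[inside], contact_time,
                                  step_frequency, impact_amplitude) * scales[k]
    }
    out
  }
}

# Sensor model: map a BW vGRF function to the accelerometer reading at
# times tt (in the sensor's own clock, offset s later than the force
# clock), with tilt scaling, soft-tissue artifact, and white noise.
sense_acceleration <- function(vgrf_bw_fun, tt, config) {
  a_true <- GRAVITY * vgrf_bw_fun(tt - config$clock_offset)
  if (config$signal_convention == "kinematic") a_true <- a_true - GRAVITY
  a <- a_true * cos(config$tilt_angle * pi / 180)
  if (config$artifact_amplitude > 0)
    a <- a + config$artifact_amplitude *
      sin(2 * pi * config$artifact_frequency * tt)
  if (config$noise_sd > 0)
    a <- a + stats::rnorm(length(tt), sd = config$noise_sd)
  a
}

#' Simulate one treadmill running trial
#'
#' Generates a paired recording: treadmill vertical GRF in newtons at
#' `config$force_rate` and sacral acceleration in m/s^2 at
#' `config$accel_rate`, derived from the same step waveform train via
#' Newton's second law. Under the `"proper"` convention the
#' accelerometer reads F/m (0 in flight); under `"kinematic"` it reads
#' F/m - g (-g in flight). The acceleration channel is tilt-scaled,
#' corrupted by a sinusoidal soft-tissue artifact and white noise, and
#' time-shifted by `config$clock_offset` relative to the force channel.
#'
#' @param subject a [subject_profile()].
#' @param speed running speed in m/s.
#' @param config a [default_config()].
#' @return a [trial_recording()] whose `ground_truth` is a list with
#'   `steps` (data.frame: `step`, `contact_start`, `contact_end`,
#'   `peak_vgrf` BW, `impulse` BW.s), `clock_offset`, `step_frequency`,
#'   `contact_time`, `impact_amplitude`.
#' @export
simulate_trial <- function(subject, speed, config = default_config()) {
  stopifnot(inherits(subject, "subject_profile"))
  if (config$trial_duration < 2) stop("trial duration must be at least 2 s")
  par <- default_gait_parameters(speed, subject$sex, subject$effects)
  f  <- par$step_frequency
  tc <- par$contact_time
  period <- 1 / f
  dur <- config$trial_duration
  # running is ongoing when the recording window closes: the step train
  # extends to the boundary and the final stance may be truncated there
  # (detectors discard edge-partial stances, as with real recordings)
  starts <- seq(0.02, dur, by = period)
  if (length(starts) < 1L) stop("trial too short for a single step")

  dtf <- 1 / config$force_rate
  tf  <- seq(0, dur - dtf, by = dtf)
  # per-step impulse-balance scale from the (virtual, full-stance)
  # force-grid trapezoid; samples beyond the recording end are not laid
  # down but keep truncated steps consistent with complete ones
  scales <- numeric(length(starts))
  peaks  <- numeric(length(starts))
  force_bw <- numeric(length(tf))
  for (k in seq_along(starts)) {
    tv <- seq(ceiling(starts[k] * config$force_rate - 1e-9) * dtf,
              starts[k] + tc, by = dtf)
    u <- step_shape(tv - starts[k], tc, f, par$impact_amplitude)
    scales[k] <- (1 / f) / trapz(u, dtf)
    vis <- tv <= dur - dtf + 1e-12
    force_bw[as.integer(round(tv[vis] * config$force_rate)) + 1L] <-
      u[vis] * scales[k]
    peaks[k] <- max(u) * scales[k]
  }
  vgrf_fun <- trial_vgrf_fun(starts, tc, f, par$impact_amplitude, scales)
  complete <- starts + tc <= dur - dtf
  if (!any(complete)) stop("trial too short for a complete step")

  ta <- seq(0, dur - 1 / config$accel_rate, by = 1 / config$accel_rate)
  accel <- sense_acceleration(vgrf_fun, ta, config)

  truth <- list(
    steps = data.frame(step = seq_len(sum(complete)),
                       contact_start = starts[complete],
                       contact_end = starts[complete] + tc,
                       peak_vgrf = peaks[complete],
                       impulse = 1 / f),
    clock_offset = config$clock_offset,
    step_frequency = f,
    contact_time = tc,
    impact_amplitude = par$impact_amplitude
  )
  trial_recording(subject$subject_id, subject$sex, subject$body_mass, speed,
                  force = timeseries(force_bw * subject$body_mass * GRAVITY,
                                     config$force_rate, units = "N"),
                  acceleration = timeseries(accel, config$accel_rate,
                                            units = "m/s^2"),
                  ground_truth = truth)
}

# Countermovement-jump vGRF profile in BW: quiet standing, unweighting
# dip, push-off peak, flight, landing spike, return to standing.
# Piecewise cosine-eased segments; vectorised over t (jump starts at t0).
cmj_bw_fun <- function(t0 = 3) {
  ease <- function(u) (1 - cos(pi * u)) / 2   # 0..1 smooth
  seg <- rbind(
    # t_rel_from, t_rel_to, from_BW, to_BW
    c(0.00, 0.30, 1.0, 0.4),   # unweighting dip
    c(0.30, 0.60, 0.4, 2.4),   # push-off rise (peak >= 2 BW)
    c(0.60, 0.75, 2.4, 0.0),   # take-off drop
    c(1.10, 1.175, 0.0, 3.0),  # landing spike up
    c(1.175, 1.40, 3.0, 1.0)   # settle
  )
  function(t) {
    rel <- t - t0
    w <- ifelse(rel < 0 | rel > 1.40, 1.0, NA_real_)
    w[rel >= 0.75 & rel < 1.10] <- 0.0      # flight
    for (i in seq_len(nrow(seg))) {
      sel <- !is.na(rel) & rel >= seg[i, 1] & rel < seg[i, 2]
      u <- (rel[sel] - seg[i, 1]) / (seg[i, 2] - seg[i, 1])
      w[sel] <- seg[i, 3] + (seg[i, 4] - seg[i, 3]) * ease(u)
    }
    w
  }
}

#' Simulate a countermovement jump recording
#'
#' One countermovement jump (CMJ) on the stationary force treadmill:
#' quiet standing at body weight, an unweighting dip, a push-off peak
#' above 2 BW, a flight interval at zero force, and a landing spike.
#' The acceleration channel uses the same sensor model (convention,
#' tilt, artifact, noise, clock offset) as [simulate_trial()], so a CMJ
#' pair can drive cross-correlation clock synchronization.
#'
#' @param subject a [subject_profile()] (supplies body mass).
#' @param config a [default_config()].
#' @param jump_time time of movement onset in s.
#' @param duration recording length in s (long enough to contain the
#'   jump in both clocks given the configured offset).
#' @return list with `force` (newtons) and `acceleration` (m/s^2)
#'   [timeseries()] channels.
#' @export
simulate_cmj <- function(subject, config = default_config(),
                         jump_time = 3, duration = 8) {
  stopifnot(inherits(subject, "subject_profile"))
  fun <- cmj_bw_fun(jump_time)
  dtf <- 1 / config$force_rate
  tf <- seq(0, duration - dtf, by = dtf)
  force_n <- fun(tf) * subject$body_mass * GRAVITY
  ta <- seq(0, duration - 1 / config$accel_rate, by = 1 / config$accel_rate)
  accel <- sense_acceleration(fun, ta, config)
  list(force = timeseries(force_n, config$force_rate, units = "N"),
       acceleration = timeseries(accel, config$accel_rate, units = "m/s^2"))
}

#' Simulate a full running cohort
#'
#' Generates the study design: every female subject runs at
#' `config$female_speeds` (default 3.8 and 4.9 m/s) and every male
#' subject at `config$male_speeds` (default 3.8, 4.1 and 5.4 m/s), each
#' condition a 30 s paired recording, with a countermovement jump
#' prepended and appended to each subject's session for clock
#' synchronization. Fully reproducible from `config$seed`.
#'
#' @param n_female,n_male subject counts; together at least 2.
#' @param config a [default_config()].
#' @return list of class `"gait_cohort"`:
#'   `subjects` (data.frame: `subject_id`, `sex`, `body_mass`),
#'   `trials` (list of [trial_recording()]),
#'   `cmj` (per-subject list with elements `pre` and `post`),
#'   `config`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(2, 1, default_config(seed = 7))
#' length(cohort$trials)  # 2*2 + 1*3 = 7
#' }
#' @export
simulate_cohort <- function(n_female, n_male, config = default_config()) {
  if (n_female + n_male < 2)
    stop("need at least 2 subjects to allow a subject-level split")
  set.seed(config$seed)
  ids <- c(if (n_female > 0) sprintf("F%02d", seq_len(n_female)),
           if (n_male > 0) sprintf("M%02d", seq_len(n_male)))
  sexes <- c(rep("female", n_female), rep("male", n_male))
  subjects <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    mass <- if (sexes[i] == "female") stats::rnorm(1, 51.5, 6)
            else stats::rnorm(1, 63.5, 6.5)
    mass <- max(mass, 35)
    eff <- c(step_frequency = stats::rnorm(1, 0, 0.10),
             contact_time = stats::rnorm(1, 0, 0.008),
             impact_amplitude = stats::rnorm(1, 0, 0.10))
    subjects[[i]] <- subject_profile(ids[i], sexes[i], mass, eff)
  }
  trials <- list()
  cmj <- list()
  for (sub in subjects) {
    cmj_pre <- simulate_cmj(sub, config)
    speeds <- if (sub$sex == "female") config$female_speeds
              else config$male_speeds
    for (sp in speeds)
      trials[[length(trials) + 1L]] <- simulate_trial(sub, sp, config)
    cmj_post <- simulate_cmj(sub, config)
    cmj[[sub$subject_id]] <- list(pre = cmj_pre, post = cmj_post)
  }
  structure(list(
    subjects = data.frame(
      subject_id = ids, sex = sexes,
      body_mass = vapply(subjects, function(s) s$body_mass, numeric(1))),
    trials = trials, cmj = cmj, config = config),
    class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d subjects (%d F, %d M), %d trials\n",
              nrow(x$subjects), sum(x$subjects$sex == "female"),
              sum(x$subjects$sex == "male"), length(x$trials)))
  invisible(x)
}
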