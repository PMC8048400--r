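#' Acceleration-based vGRF estimate
#'
#' Newton's second law: the vertical ground reaction force equals body
#' mass times vertical center-of-mass acceleration. In body-weight
#' units mass cancels: under the `"proper"` convention (accelerometer
#' reads ~F/m) the estimate is `a / g`; under `"kinematic"` (second
#' derivative of COM position) it is `(a + g) / g`. Negative values are
#' retained — clipping is left to downstream consumers.
#'
#' @param accel_filtered [timeseries()] in m/s^2, filtered per the
#'   pipeline.
#' @param body_mass kg, > 0 (not used for the BW scale itself but
#'   validated here because un-normalized force is `mass * a`).
#' @param convention `"proper"` or `"kinematic"`.
#' @return [timeseries()] in BW.
#' @examples
#' ts <- timeseries(rep(9.81, 100), rate = 500, units = "m/s^2")
#' accel_to_vgrf(ts, 60, "proper")$samples[1]  # 1 BW
#' @export
accel_to_vgrf <- function(accel_filtered, body_mass,
                          convention = c("proper", "kinematic")) {
  stopifnot(inherits(accel_filtered, "timeseries"))
  if (body_mass <= 0) stop("body_mass must be > 0")
  convention <- match.arg(convention)
  a <- accel_filtered$samples
  bw <- if (convention == "proper") a / GRAVITY else (a + GRAVITY) / GRAVITY
  timeseries(bw, accel_filtered$rate, accel_filtered$start_time, units = "BW")
}

#' Per-step discrete kinetic variables
#'
#' For each stance interval: peak vGRF (maximum sample), vertical
#' impulse (trapezoidal integral of vGRF over the interval) and contact
#' time (interval duration).
#'
#' @param vgrf [timeseries()] in BW on which the intervals were
#'   detected.
#' @param intervals stance data.frame (`start`, `end` in s).
#' @return data.frame with columns `step`, `peak_bw`, `impulse_bws`,
#'   `contact_time_s`; empty for an empty interval list.
#' @export
discrete_variables <- function(vgrf, intervals) {
  stopifnot(inherits(vgrf, "timeseries"))
  if (nrow(intervals) == 0L)
    return(data.frame(step = integer(), peak_bw = numeric(),
                      impulse_bws = numeric(), contact_time_s = numeric()))
  tt <- ts_times(vgrf)
  dt <- 1 / vgrf$rate
  t_min <- tt[1L]; t_max <- tt[length(tt)]
  out <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (s < t_min - 1e-9 || e > t_max + dt + 1e-9)
      stop("stance interval [", s, ", ", e, "] outside series extent")
    idx <- which(tt >= s - 1e-9 & tt <= e + 1e-9)
    y <- vgrf$samples[idx]
    out[[i]] <- data.frame(step = i, peak_bw = max(y),
                           impulse_bws = trapz(y, dt),
                           contact_time_s = e - s)
  }
  do.call(rbind, out)
}

#' Per-condition summary of discrete variables
#'
#' Arithmetic mean of the per-step variables over the steps that fall
#' entirely inside the final `analysis_window` seconds of the recording
#' — the steady-state tail of the trial.
#'
#' @param records per-step data.frame from [discrete_variables()].
#' @param intervals matching stance data.frame (restricts to the
#'   window).
#' @param step_freq step frequency in Hz for the window (see
#'   [step_frequency()]).
#' @param subject_id,sex,speed,source condition metadata; `source` is
#'   `"treadmill"` or `"acceleration"`.
#' @param window_from,window_to analysis window bounds in s.
#' @return one-row data.frame: `subject_id`, `sex`, `speed`, `source`,
#'   `peak_vgrf` (BW), `vertical_impulse` (BW.s), `contact_time` (s),
#'   `step_frequency` (Hz), `n_steps`.
#' @export
summarize_condition <- function(records, intervals, step_freq,
                                subject_id, sex, speed, source,
                                window_from, window_to) {
  keep <- intervals$start >= window_from - 1e-9 &
    intervals$end <= window_to + 1e-9
  if (!any(keep)) stop("no complete steps inside the analysis window")
  rec <- records[keep, , drop = FALSE]
  data.frame(subject_id = subject_id, sex = sex, speed = speed,
             source = source,
             peak_vgrf = mean(rec$peak_bw),
             vertical_impulse = mean(rec$impulse_bws),
             contact_time = mean(rec$contact_time_s),
             step_frequency = step_freq,
             n_steps = nrow(rec))
}
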