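#' Uniformly sampled time series channel
#'
#' The substrate of every signal-processing stage: an ordered vector of
#' samples at a fixed rate, with a start time and physical units. No
#' per-sample timestamps are stored; uniform sampling is an invariant.
#'
#' @param samples numeric vector, length >= 1, all finite.
#' @param rate sampling rate in Hz, > 0.
#' @param start_time time of the first sample in seconds.
#' @param units one of `"N"`, `"m/s^2"`, `"BW"`, `"BW.s"`, `"s"`.
#' @return object of class `"timeseries"`.
#' @examples
#' ts <- timeseries(sin(2 * pi * 2 * seq(0, 1, by = 0.002)), rate = 500,
#'                  units = "m/s^2")
#' ts_duration(ts)
#' @export
timeseries <- function(samples, rate, start_time = 0, units = "BW") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("time series must contain at least one sample")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("time series samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  units <- match.arg(units, c("N", "m/s^2", "BW", "BW.s", "s"))
  structure(list(samples = samples, rate = rate,
                 start_time = start_time, units = units),
            class = "timeseries")
}

#' @export
print.timeseries <- function(x, ...) {
  cat(sprintf("<timeseries> %d samples @ %g Hz [%s], t = %.3f..%.3f s\n",
              length(x$samples), x$rate, x$units,
              x$start_time, ts_end_time(x)))
  invisible(x)
}

#' @export
length.timeseries <- function(x) length(x$samples)

#' Sample times of a time series
#' @param ts a [timeseries()].
#' @return numeric vector of sample times in seconds.
#' @export
ts_times <- function(ts) {
  ts$start_time + (seq_along(ts$samples) - 1L) / ts$rate
}

#' @rdname ts_times
#' @export
ts_end_time <- function(ts) {
  ts$start_time + (length(ts$samples) - 1L) / ts$rate
}

#' @rdname ts_times
#' @export
ts_duration <- function(ts) (length(ts$samples) - 1L) / ts$rate

#' Extract a time window from a series
#'
#' Keeps the samples whose times fall in `[from, to]` (inclusive).
#'
#' @param ts a [timeseries()].
#' @param from,to window bounds in seconds.
#' @return a [timeseries()] covering the window.
#' @export
ts_window <- function(ts, from, to) {
  if (to <= from) stop("empty window: 'to' must exceed 'from'")
  tt <- ts_times(ts)
  keep <- which(tt >= from - 1e-9 & tt <= to + 1e-9)
  if (!length(keep)) stop("window contains no samples")
  timeseries(ts$samples[keep], ts$rate, start_time = tt[keep[1L]],
             units = ts$units)
}

#' One recorded subject-by-speed condition
#'
#' Bundles the treadmill force channel, the sacral acceleration channel
#' and the trial metadata for one running condition.
#'
#' @param subject_id character scalar.
#' @param sex `"female"` or `"male"`.
#' @param body_mass body mass in kg, > 0.
#' @param speed treadmill speed in m/s, > 0.
#' @param force [timeseries()] in newtons.
#' @param acceleration [timeseries()] in m/s^2.
#' @param ground_truth optional per-step truth table (see
#'   [simulate_trial()]).
#' @return object of class `"trial_recording"`.
#' @export
trial_recording <- function(subject_id, sex, body_mass, speed,
                            force, acceleration, ground_truth = NULL) {
  sex <- match.arg(sex, c("female", "male"))
  if (!is.numeric(body_mass) || body_mass <= 0) stop("body_mass must be > 0")
  if (!is.numeric(speed) || speed <= 0) stop("speed must be > 0")
  stopifnot(inherits(force, "timeseries"), inherits(acceleration, "timeseries"))
  structure(list(subject_id = as.character(subject_id), sex = sex,
                 body_mass = body_mass, speed = speed,
                 force = force, acceleration = acceleration,
                 ground_truth = ground_truth),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s (%s, %.1f kg) @ %.1f m/s\n",
              x$subject_id, x$sex, x$body_mass, x$speed))
  cat("  force:        "); print(x$force)
  cat("  acceleration: "); print(x$acceleration)
  invisible(x)
}
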