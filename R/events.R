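# Shared run logic: maximal runs of x > threshold, with debouncing
# (gaps shorter than min_flight merged, runs shorter than min_stance
# dropped) and edge-partial runs discarded. Returns a data.frame of
# sample-index runs (first, last) into x.
threshold_runs <- function(x, rate, threshold, min_stance, min_flight) {
  above <- x > threshold
  if (!any(above)) return(data.frame(first = integer(), last = integer()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  firsts <- ends - r$lengths + 1L
  runs <- data.frame(first = firsts[r$values], last = ends[r$values])
  # drop spurious short runs first (noise/artifact lobes), then bridge
  # brief dropouts within a stance, then re-check duration
  dur <- (runs$last - runs$first + 1L) / rate
  runs <- runs[dur >= min_stance, , drop = FALSE]
  if (nrow(runs) == 0L) return(runs)
  # merge runs separated by gaps shorter than min_flight
  if (nrow(runs) > 1L) {
    gap_s <- (runs$first[-1L] - runs$last[-nrow(runs)] - 1L) / rate
    merged <- list()
    cur <- runs[1L, ]
    for (i in seq_len(nrow(runs) - 1L)) {
      if (gap_s[i] < min_flight) {
        cur$last <- runs$last[i + 1L]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- runs[i + 1L, ]
      }
    }
    merged[[length(merged) + 1L]] <- cur
    runs <- do.call(rbind, merged)
  }
  # discard edge-partial runs (first/last sample above threshold)
  runs <- runs[runs$first > 1L & runs$last < length(x), , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

runs_to_intervals <- function(runs, series, source) {
  tt <- ts_times(series)
  dt <- 1 / series$rate
  if (nrow(runs) == 0L)
    return(data.frame(start = numeric(), end = numeric(),
                      source = character()))
  # contact duration: first-to-last above-threshold sample inclusive,
  # i.e. (number of samples) * sample period
  data.frame(start = tt[runs$first],
             end = tt[runs$first] + (runs$last - runs$first + 1L) * dt,
             source = source)
}

#' Detect stance phases from the force channel
#'
#' Maximal runs where the body-weight-normalized vGRF exceeds the
#' threshold (default 5% BW), debounced: sub-`min_flight` gaps are
#' bridged, sub-`min_stance` runs dropped, and runs touching either
#' window edge discarded so that per-step statistics use only complete
#' steps.
#'
#' @param vgrf [timeseries()] in BW, already filtered.
#' @param threshold stance threshold in BW.
#' @param min_stance minimum stance duration in s.
#' @param min_flight minimum flight (gap) duration in s.
#' @return data.frame with columns `start`, `end` (s; `end - start` is
#'   the inclusive above-threshold duration) and `source = "force"`;
#'   intervals are disjoint and time-ordered.
#' @export
detect_stance_force <- function(vgrf, threshold = 0.05,
                                min_stance = 0.05, min_flight = 0.02) {
  stopifnot(inherits(vgrf, "timeseries"))
  if (length(vgrf$samples) == 0L) stop("empty series")
  runs <- threshold_runs(vgrf$samples, vgrf$rate, threshold,
                         min_stance, min_flight)
  runs_to_intervals(runs, vgrf, "force")
}

#' Detect stance phases from filtered acceleration
#'
#' Same run logic as [detect_stance_force()] with a 0 m/s^2 threshold:
#' during running the sacral proper acceleration is positive through
#' stance and near zero (free fall) in flight, so the low-pass filtered
#' signal crosses 0 at stance boundaries. Under the `"kinematic"`
#' convention the signal reads `-g` in flight; gravity is added back
#' before thresholding so both conventions detect the same event.
#'
#' @param accel_filtered [timeseries()] in m/s^2, low-pass filtered
#'   (10 Hz, zero-lag) per the pipeline.
#' @param threshold detection threshold in m/s^2.
#' @param min_stance,min_flight debounce windows in s.
#' @param convention `"proper"` or `"kinematic"`.
#' @return data.frame as in [detect_stance_force()] with
#'   `source = "acceleration"`.
#' @export
detect_stance_accel <- function(accel_filtered, threshold = 0,
                                min_stance = 0.05, min_flight = 0.02,
                                convention = c("proper", "kinematic")) {
  stopifnot(inherits(accel_filtered, "timeseries"))
  if (length(accel_filtered$samples) == 0L) stop("empty series")
  convention <- match.arg(convention)
  x <- accel_filtered$samples
  if (convention == "kinematic") x <- x + GRAVITY
  runs <- threshold_runs(x, accel_filtered$rate, threshold,
                         min_stance, min_flight)
  runs_to_intervals(runs, accel_filtered, "acceleration")
}

#' Step frequency from detected stances
#'
#' Number of initial ground contacts (interval starts) per second over
#' the analysis window.
#'
#' @param intervals stance data.frame from a detector.
#' @param window window length in s, > 0.
#' @return step frequency in Hz; 0 with a warning when no intervals.
#' @examples
#' step_frequency(data.frame(start = seq(0, 9.9, length.out = 30),
#'                           end = seq(0.2, 10.1, length.out = 30)),
#'                window = 10)  # 3 Hz
#' @export
step_frequency <- function(intervals, window) {
  if (window <= 0) stop("window must be > 0")
  if (nrow(intervals) == 0L) {
    warning("no stance intervals: step frequency reported as 0 Hz")
    return(0)
  }
  nrow(intervals) / window
}
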