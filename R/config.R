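#' Standard gravitational acceleration (m/s^2)
#'
#' Used throughout to convert between force in newtons, acceleration in
#' m/s^2, and body-weight (BW) normalized units.
#' @export
GRAVITY <- 9.81

#' Default pipeline configuration
#'
#' Single source of truth for every stage parameter of the analysis
#' pipeline. Filter specifications, stance-detection thresholds, the
#' analysis window, model hyperparameters and the train/test split
#' fraction all default to the values used for treadmill running
#' analysis; simulator-only fields (noise, artifact, clock offset)
#' default to a realistic sacral-accelerometer noise model.
#'
#' @param seed integer seed controlling every stochastic stage.
#' @param ... named overrides for any configuration field.
#'
#' @return A named list with class `"gait_config"`:
#' \describe{
#'   \item{force_filter}{zero-lag low-pass spec for the force channel
#'     (30 Hz cutoff, nominal 4th order).}
#'   \item{accel_filter}{zero-lag low-pass spec for the acceleration
#'     channel (10 Hz cutoff, nominal 8th order).}
#'   \item{force_threshold_bw}{stance threshold on force, 0.05 BW.}
#'   \item{accel_threshold}{stance threshold on filtered acceleration,
#'     0 m/s^2.}
#'   \item{min_stance_s, min_flight_s}{debounce windows for stance
#'     detection (0.05 s / 0.02 s).}
#'   \item{analysis_window_s}{final window of each trial used for
#'     per-step statistics, 10 s.}
#'   \item{signal_convention}{`"proper"` (accelerometer reads ~F/m, 0 in
#'     flight) or `"kinematic"` (second derivative of COM position, -g in
#'     flight).}
#'   \item{n_trees, mtry_grid, cv_folds}{quantile regression forest
#'     hyperparameters (500 trees, mtry in 1..4, 5 subject-grouped
#'     folds).}
#'   \item{test_fraction}{subject-level held-out fraction, 0.24.}
#'   \item{alpha}{significance level for coefficient inference and the
#'     paired model comparison, 0.05.}
#'   \item{sync_window_s}{cross-correlation lag search half-window, 5 s.}
#'   \item{accel_rate, force_rate, trial_duration}{simulator sampling
#'     rates (500 / 1000 Hz) and trial length (30 s).}
#'   \item{noise_sd, artifact_amplitude, artifact_frequency,
#'     clock_offset, tilt_angle}{sensor model: white noise sd (m/s^2),
#'     soft-tissue artifact sinusoid amplitude (m/s^2) and frequency
#'     (Hz, above the 10 Hz analysis cutoff), inter-device clock offset
#'     (s), sensor tilt (degrees).}
#'   \item{female_speeds, male_speeds}{condition speeds (m/s) per sex.}
#' }
#' @examples
#' cfg <- default_config(seed = 1, noise_sd = 0)
#' cfg$force_filter$cutoff
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed               = as.integer(seed),
    # processing
    force_filter       = filter_spec(cutoff = 30, nominal_order = 4),
    accel_filter       = filter_spec(cutoff = 10, nominal_order = 8),
    force_threshold_bw = 0.05,
    accel_threshold    = 0,
    min_stance_s       = 0.05,
    min_flight_s       = 0.02,
    analysis_window_s  = 10,
    signal_convention  = "proper",
    sync_window_s      = 5,
    # models / evaluation
    n_trees            = 500L,
    mtry_grid          = 1:4,
    cv_folds           = 5L,
    test_fraction      = 0.24,
    alpha              = 0.05,
    # simulator
    accel_rate         = 500,
    force_rate         = 1000,
    trial_duration     = 30,
    noise_sd           = 0.8,
    artifact_amplitude = 3,
    artifact_frequency = 13,
    clock_offset       = 1.337,
    tilt_angle         = 0,
    female_speeds      = c(3.8, 4.9),
    male_speeds        = c(3.8, 4.1, 5.4)
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$force_rate > 0, cfg$accel_rate > 0)
  if (cfg$force_rate %% cfg$accel_rate != 0)
    stop("force_rate must be an integer multiple of accel_rate")
  cfg$signal_convention <- match.arg(cfg$signal_convention,
                                     c("proper", "kinematic"))
  structure(cfg, class = "gait_config")
}

#' @export
print.gait_config <- function(x, ...) {
  cat("<gait_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (inherits(v, "filter_spec")) {
      cat(sprintf("  %-20s low-pass %g Hz, nominal order %d\n",
                  nm, v$cutoff, v$nominal_order))
    } else {
      cat(sprintf("  %-20s %s\n", nm, paste(format(v), collapse = ", ")))
    }
  }
  invisible(x)
}
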