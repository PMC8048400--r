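#' Zero-lag low-pass filter specification
#'
#' Biomechanics convention: the stated "nominal" order is the effective
#' magnitude order after forward-backward application, so the underlying
#' Butterworth design has order `nominal_order / 2`.
#'
#' @param cutoff cutoff frequency in Hz.
#' @param nominal_order effective order, 4 or 8.
#' @return object of class `"filter_spec"`.
#' @export
filter_spec <- function(cutoff, nominal_order = 4) {
  if (!nominal_order %in% c(4, 8))
    stop("nominal_order must be 4 or 8")
  if (cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff, nominal_order = as.integer(nominal_order),
                 kind = "lowpass"),
            class = "filter_spec")
}

# Forward-backward filtering with odd-reflection edge padding (the
# padding signal::filtfilt lacks; without it DC gain collapses at the
# series ends). Padding length ~3 cutoff periods bounds the startup
# transient well below the pass band.
filtfilt_padded <- function(x, bf, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  pre  <- 2 * x[1L] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(pre, x, post)
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(npad + 1L):(npad + n)]
}

#' Zero-lag Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass of order `spec$nominal_order / 2`
#' forward then backward, yielding zero phase distortion and an
#' effective magnitude response of order `nominal_order`:
#' `|H(f)|^2 = 1 / (1 + (f/fc)^nominal_order)`. Edge transients are
#' controlled by odd-reflection padding. Output length, rate, start
#' time and units match the input.
#'
#' @param series a [timeseries()].
#' @param spec a [filter_spec()].
#' @return filtered [timeseries()].
#' @examples
#' ts <- timeseries(rep(2.5, 500), rate = 500, units = "BW")
#' all.equal(zero_lag_butterworth(ts, filter_spec(10, 8))$samples,
#'           ts$samples, tolerance = 1e-4)
#' @export
zero_lag_butterworth <- function(series, spec) {
  stopifnot(inherits(series, "timeseries"), inherits(spec, "filter_spec"))
  nyq <- series$rate / 2
  if (spec$cutoff >= nyq)
    stop("cutoff must be below the Nyquist frequency (", nyq, " Hz)")
  ord <- spec$nominal_order / 2
  if (length(series$samples) <= 3 * spec$nominal_order)
    stop("series too short to filter (need > 3 x filter order samples)")
  bf <- signal::butter(ord, spec$cutoff / nyq, type = "low")
  npad <- max(50L, as.integer(ceiling(3 * series$rate / spec$cutoff)))
  timeseries(filtfilt_padded(series$samples, bf, npad),
             series$rate, series$start_time, series$units)
}

#' Down-sample a series by an integer factor
#'
#' Anti-alias low-pass at `0.45 * target_rate` (zero-lag, nominal 8th
#' order) followed by decimation. The source rate must be an integer
#' multiple of the target rate.
#'
#' @param series a [timeseries()].
#' @param target_rate new rate in Hz.
#' @return decimated [timeseries()] starting at the same time.
#' @export
downsample <- function(series, target_rate) {
  stopifnot(inherits(series, "timeseries"))
  factor <- series$rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop("source rate must be an integer multiple of target_rate ",
         "(factor ", format(factor), ")")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(series)
  aa <- zero_lag_butterworth(series, filter_spec(0.45 * target_rate, 8))
  keep <- seq(1L, length(series$samples), by = factor)
  timeseries(aa$samples[keep], target_rate, series$start_time, series$units)
}

# Normalized cross-correlation of two equal-rate series over integer
# sample lags -max_lag..max_lag. r(k) is the Pearson correlation of
# x[(1+k):n] with y[1:(n-k)] (k >= 0; negative lags by symmetry),
# computed with an FFT numerator and cumulative-sum moments.
norm_xcorr <- function(x, y, max_lag, min_overlap) {
  n <- length(x)
  stopifnot(length(y) == n)
  nf <- stats::nextn(2L * n)
  X <- stats::fft(c(x, numeric(nf - n)))
  Y <- stats::fft(c(y, numeric(nf - n)))
  cc <- Re(stats::fft(X * Conj(Y), inverse = TRUE)) / nf
  one_side <- function(a, b, cc_pos) {
    ks <- 0:max_lag
    m <- n - ks
    ca <- cumsum(a); caa <- cumsum(a^2)
    cb <- cumsum(b); cbb <- cumsum(b^2)
    sa  <- ca[n] - c(0, ca)[ks + 1L]
    saa <- caa[n] - c(0, caa)[ks + 1L]
    sb  <- cb[m]
    sbb <- cbb[m]
    num <- cc_pos - sa * sb / m
    den <- sqrt(pmax(saa - sa^2 / m, 0) * pmax(sbb - sb^2 / m, 0))
    r <- ifelse(den > 0 & m >= min_overlap, num / den, NA_real_)
    r
  }
  r_pos <- one_side(x, y, cc[1L + 0:max_lag])            # lag k: x leads
  r_neg <- one_side(y, x, cc[c(1L, nf - 0:(max_lag - 1L))])[-1L]
  list(lags = c(-(max_lag:1), 0:max_lag), r = c(rev(r_neg), r_pos))
}

#' Estimate the clock lag between two channels
#'
#' Finds the lag maximizing the normalized cross-correlation between an
#' acceleration-derived vGRF estimate and the treadmill-measured vGRF,
#' evaluated over `+/- search_window` seconds. Both series must share a
#' rate and are mean-removed per overlap (Pearson normalization), so
#' the peak correlation lies in `[-1, 1]`. Applying `-lag` to the
#' acceleration channel aligns the two clocks. A peak correlation below
#' 0.5 triggers a low-confidence warning (not an error).
#'
#' @param accel_est_vgrf [timeseries()] in BW derived from acceleration.
#' @param measured_vgrf [timeseries()] in BW from the treadmill, same
#'   rate.
#' @param search_window lag search half-window in seconds.
#' @return list of class `"sync_result"`: `lag` (s), `peak_correlation`,
#'   `low_confidence` (logical).
#' @export
synchronize <- function(accel_est_vgrf, measured_vgrf, search_window = 5) {
  stopifnot(inherits(accel_est_vgrf, "timeseries"),
            inherits(measured_vgrf, "timeseries"))
  if (abs(accel_est_vgrf$rate - measured_vgrf$rate) > 1e-9)
    stop("series must share a sampling rate")
  rate <- measured_vgrf$rate
  n <- min(length(accel_est_vgrf$samples), length(measured_vgrf$samples))
  if (n / rate < 2) stop("need at least 2 s of overlap")
  x <- accel_est_vgrf$samples[seq_len(n)]
  y <- measured_vgrf$samples[seq_len(n)]
  max_lag <- min(n - as.integer(rate), as.integer(round(search_window * rate)))
  xc <- norm_xcorr(x, y, max_lag, min_overlap = as.integer(rate))
  if (all(is.na(xc$r))) stop("cross-correlation undefined (constant input?)")
  best <- which.max(xc$r)
  res <- structure(list(lag = xc$lags[best] / rate,
                        peak_correlation = xc$r[best],
                        low_confidence = xc$r[best] < 0.5),
                   class = "sync_result")
  if (res$low_confidence)
    warning("low-confidence synchronization: peak correlation ",
            sprintf("%.3f", res$peak_correlation), " < 0.5")
  res
}

#' Shift a channel to undo an estimated clock lag
#'
#' Removes `round(lag * rate)` samples so that events in the shifted
#' series line up with the reference clock: for a positive lag the
#' first samples are dropped, for a negative lag the last.
#'
#' @param series a [timeseries()].
#' @param lag lag in seconds as returned by [synchronize()].
#' @return shifted [timeseries()] (start time kept at the original
#'   start for positive lags; the series simply shortens by `|k|`
#'   samples).
#' @export
apply_lag <- function(series, lag) {
  k <- as.integer(round(lag * series$rate))
  n <- length(series$samples)
  if (abs(k) >= n - 1L) stop("lag exceeds series length")
  if (k == 0L) return(series)
  if (k > 0L) {
    timeseries(series$samples[(1L + k):n], series$rate,
               series$start_time, series$units)
  } else {
    timeseries(series$samples[1L:(n + k)], series$rate,
               series$start_time, series$units)
  }
}

#' Per-subject lag from a countermovement-jump pair
#'
#' Converts both CMJ recordings to body-weight vGRF in a common 10 Hz
#' band at the accelerometer rate (force: down-sampled, normalized,
#' filtered; acceleration: filtered, Newton's-second-law estimate) and
#' averages the two cross-correlation lags.
#'
#' @param cmj_pair list with `pre` and `post` CMJ recordings as from
#'   [simulate_cmj()].
#' @param body_mass subject mass in kg.
#' @param config a [default_config()].
#' @return list: `lag` (s, mean of the two jumps), `per_jump`
#'   (the two [synchronize()] results).
#' @export
estimate_subject_lag <- function(cmj_pair, body_mass,
                                 config = default_config()) {
  one <- function(cmj) {
    f_bw <- downsample(cmj$force, config$accel_rate)
    f_bw <- timeseries(f_bw$samples / (body_mass * GRAVITY), f_bw$rate,
                       f_bw$start_time, units = "BW")
    f_bw <- zero_lag_butterworth(f_bw, config$accel_filter)
    a_f <- zero_lag_butterworth(cmj$acceleration, config$accel_filter)
    a_bw <- accel_to_vgrf(a_f, body_mass, config$signal_convention)
    synchronize(a_bw, f_bw, config$sync_window_s)
  }
  res <- list(pre = one(cmj_pair$pre), post = one(cmj_pair$post))
  list(lag = mean(c(res$pre$lag, res$post$lag)), per_jump = res)
}
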