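#' Frame-wise displacement from rigid-body motion parameters
#'
#' Summarises head motion per frame as the sum of absolute backward
#' differences of the six rigid-body parameters, with the three rotations
#' converted to arc length on a sphere. The sphere radius is a knob because
#' the analyses span human (50 mm) and mouse (5 mm) head sizes.
#'
#' @param motion Data frame with columns `x`, `y`, `z` (translations, mm) and
#'   `pitch`, `roll`, `yaw` (rotations, radians), one row per frame.
#' @param sphere_radius Radius in mm used to convert rotations to arc length.
#' @return A tibble with columns `frame` and `fd` (mm); `fd[1]` is 0 by
#'   convention.
#' @export
compute_fd <- function(motion, sphere_radius = 50) {
  cols <- c("x", "y", "z", "pitch", "roll", "yaw")
  if (!is.data.frame(motion) || !all(cols %in% names(motion))) {
    stop("`motion` needs columns x, y, z, pitch, roll, yaw.", call. = FALSE)
  }
  if (nrow(motion) < 2) stop("Need at least 2 frames of motion parameters.", call. = FALSE)
  m <- as.matrix(motion[, cols])
  d <- abs(diff(m))
  d[, 4:6] <- d[, 4:6] * sphere_radius
  tibble::tibble(frame = seq_len(nrow(m)), fd = c(0, rowSums(d)))
}

#' Scrub high-motion frames from a time series
#'
#' Frames whose frame-wise displacement is strictly greater than the
#' threshold (default 0.35 mm) are censored. Censored frames are dropped,
#' not interpolated; downstream correlations operate on the retained frames
#' only. With `action = "na"` the frames are kept in place as `NA` so that
#' lagged analyses can do pair-wise deletion at the original frame grid.
#'
#' @param ts Time-series tibble.
#' @param fd Numeric vector of frame-wise displacements (mm), or the tibble
#'   returned by [compute_fd()].
#' @param threshold Censoring threshold in mm; frames with `fd > threshold`
#'   (strict) are removed.
#' @param action `"drop"` removes censored rows; `"na"` blanks their values.
#' @return A list with `series` (the scrubbed tibble), `mask` (a tibble with
#'   `frame`, `fd`, `keep`), and `threshold`.
#' @export
scrub <- function(ts, fd, threshold = 0.35, action = c("drop", "na")) {
  ts <- as_timeseries(ts)
  action <- match.arg(action)
  if (is.data.frame(fd)) fd <- fd$fd
  if (length(fd) != nrow(ts)) {
    stop("`fd` length must match the number of frames.", call. = FALSE)
  }
  keep <- fd <= threshold      # "larger than" is strict: fd == threshold kept
  if (!any(keep)) stop("All frames censored; series unusable.", call. = FALSE)
  mask <- tibble::tibble(frame = seq_len(nrow(ts)), fd = fd, keep = keep)
  series <- if (action == "drop") {
    ts[keep, ]
  } else {
    dplyr::mutate(ts, value = ifelse(keep, .data$value, NA_real_))
  }
  list(series = series, mask = mask, threshold = threshold)
}

# Least-squares polynomial detrend; order 0 = demean.
poly_detrend <- function(values, order) {
  if (order < 1) return(values - mean(values))
  t <- seq_along(values)
  unname(stats::residuals(stats::lm(values ~ stats::poly(t, order))))
}

# Zero-phase ideal (boxcar) bandpass via FFT: retain frequencies with
# band[1] <= f <= band[2]; DC and out-of-band bins are zeroed exactly.
fft_bandpass <- function(values, dt, band) {
  n <- length(values)
  f <- seq(0, n - 1) / (n * dt)
  f <- pmin(f, 1 / dt - f)            # two-sided grid folded to [0, Nyquist]
  keep <- f >= band[1] & f <= band[2]
  Re(stats::fft(stats::fft(values) * keep, inverse = TRUE)) / n
}

#' Clean an ROI time series for coupling analysis
#'
#' Applies, in order: optional truncation to the first `keep_first` frames,
#' polynomial detrending, zero-phase ideal bandpass filtering, and trimming
#' of frames at both ends to discard filter edge artifacts. The defaults
#' mirror a resting-state preparation: second-order detrend, 0.01-0.1 Hz
#' band, 5 frames trimmed from each end.
#'
#' @param ts Time-series tibble.
#' @param detrend_order Polynomial order removed by least squares (2 =
#'   quadratic trend).
#' @param band Passband `(low, high)` in Hz; must lie inside (0, Nyquist).
#' @param trim Frames discarded from `(head, tail)` after filtering.
#' @param keep_first If set, the series is truncated to its first
#'   `keep_first` frames before any other step.
#' @return The cleaned time-series tibble.
#' @export
preprocess <- function(ts, detrend_order = 2, band = c(0.01, 0.1),
                       trim = c(5, 5), keep_first = NULL) {
  ts <- as_timeseries(ts)
  if (!is.null(keep_first)) {
    keep_first <- min(keep_first, nrow(ts))
    ts <- ts[seq_len(keep_first), ]
  }
  n <- nrow(ts)
  if (n < sum(trim) + 2) stop("Series too short for the requested trim.", call. = FALSE)
  dt <- ts_dt(ts)
  nyq <- 1 / (2 * dt)
  if (band[1] <= 0 || band[2] <= band[1] || band[2] > nyq) {
    stop(sprintf("Band must satisfy 0 < low < high <= Nyquist (%.4g Hz).", nyq),
         call. = FALSE)
  }
  v <- ts$value
  if (!is.null(detrend_order)) v <- poly_detrend(v, detrend_order)
  v <- fft_bandpass(v, dt, band)
  out <- dplyr::mutate(ts, value = v)
  idx <- seq.int(trim[1] + 1, n - trim[2])
  out[idx, ]
}

#' Convert a signal to percent change from baseline
#'
#' @param ts Time-series tibble.
#' @param baseline Either `"mean"` (whole-series mean), an integer count of
#'   initial frames, or an integer vector of frame indices defining the
#'   baseline.
#' @return Time-series tibble with `value` in percent signal change:
#'   `100 * (value - baseline_mean) / baseline_mean`.
#' @export
percent_signal_change <- function(ts, baseline = "mean") {
  ts <- as_timeseries(ts)
  idx <- if (identical(baseline, "mean")) {
    seq_len(nrow(ts))
  } else if (length(baseline) == 1) {
    seq_len(baseline)
  } else {
    baseline
  }
  b <- mean(ts$value[idx])
  if (!is.finite(b) || b == 0) stop("Baseline mean is zero; cannot normalize.", call. = FALSE)
  dplyr::mutate(ts, value = 100 * (.data$value - b) / b)
}
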