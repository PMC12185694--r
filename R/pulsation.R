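#' Mean-normalized one-sided power spectrum
#'
#' Divides the series by its temporal mean, removes the mean (DC), and
#' returns the one-sided power spectrum. Powers are scaled so that their sum
#' equals the temporal variance of the normalized signal (population
#' convention, divisor n), i.e. Parseval's identity holds exactly: a pure
#' sinusoid of amplitude `a` at a grid frequency carries power `a^2/2`.
#'
#' @param ts Time-series tibble with positive temporal mean.
#' @return A tibble of class `nf_spectrum` with columns `freq` (Hz, up to
#'   Nyquist) and `power`; attributes `dt` and `variance`.
#' @export
normalize_and_spectrum <- function(ts) {
  ts <- as_timeseries(ts)
  dt <- ts_dt(ts)
  m <- mean(ts$value)
  if (!is.finite(m) || m <= 0) {
    stop("Temporal mean must be positive for mean normalization.", call. = FALSE)
  }
  x <- ts$value / m
  x <- x - mean(x)
  n <- length(x)
  X <- stats::fft(x)
  p2 <- Mod(X)^2 / n^2                 # two-sided, sums to var (divisor n)
  half <- floor(n / 2)
  idx <- seq_len(half + 1)             # bins 0 .. Nyquist
  power <- p2[idx]
  dup <- idx > 1 & (idx - 1) < n - (idx - 1)   # bins with a distinct conjugate
  power[dup] <- 2 * power[dup]
  out <- tibble::tibble(freq = (idx - 1) / (n * dt), power = power)
  structure(out, class = c("nf_spectrum", class(out)),
            dt = dt, variance = mean(x^2))
}

#' Fold a frequency across the Nyquist limit
#'
#' Frequencies above Nyquist alias into the observable band
#' `[0, 1/(2 dt)]` at `|f - round(f * dt) / dt|`. Used to locate where the
#' first cardiac harmonic lands when the heart rate exceeds half the
#' sampling rate.
#'
#' @param f Frequency in Hz (vectorized).
#' @param dt Sampling interval in seconds.
#' @return Folded frequency in Hz, within `[0, 1/(2 dt)]`.
#' @export
alias_fold <- function(f, dt) {
  stopifnot(all(f >= 0), dt > 0)
  abs(f - round(f * dt) / dt)
}

#' Detect the cardiac spectral peak
#'
#' Frequency of maximum power within a physiological search band (default
#' 2.5-5.8 Hz, i.e. 150-350 beats per minute). When an externally recorded
#' heart-rate prior is supplied, the search is restricted to prior +/- 1 Hz.
#'
#' @param spec An `nf_spectrum` tibble.
#' @param search_band `(low, high)` Hz search interval.
#' @param prior Optional prior heart rate in Hz.
#' @return Cardiac frequency in Hz.
#' @export
detect_cardiac_peak <- function(spec, search_band = c(2.5, 5.8), prior = NULL) {
  lo <- search_band[1]; hi <- search_band[2]
  if (!is.null(prior)) {
    lo <- max(lo, prior - 1); hi <- min(hi, prior + 1)
  }
  if (lo >= max(spec$freq)) stop("Search band lies outside the spectrum.", call. = FALSE)
  inband <- spec[spec$freq >= lo & spec$freq <= hi, ]
  if (nrow(inband) == 0) stop("Search band contains no frequency bins.", call. = FALSE)
  if (max(inband$power) <= 0 || diff(range(inband$power)) == 0) {
    stop("Flat spectrum in the search band; cardiac peak detection failed.",
         call. = FALSE)
  }
  inband$freq[which.max(inband$power)]
}

#' Arterial pulsation power in the cardiac band
#'
#' Applies a zero-phase ideal bandpass of total width `width` (default 2 Hz,
#' i.e. +/- 1 Hz) around the cardiac peak to the mean-normalized signal and
#' returns the temporal variance of the filtered signal as the pulsation
#' power. The aliased first harmonic (2x cardiac folded across Nyquist)
#' contributes whenever it falls naturally inside the band; its folded
#' location is recorded either way.
#'
#' @param ts Time-series tibble.
#' @param cardiac Cardiac frequency in Hz (e.g. from
#'   [detect_cardiac_peak()]).
#' @param width Band width in Hz; total width by default, half-width when
#'   `width_mode = "half"`.
#' @param width_mode `"total"` (band = cardiac +/- width/2) or `"half"`
#'   (band = cardiac +/- width).
#' @return One-row tibble of class `nf_pulsation`: `cardiac_freq`,
#'   `band_lo`, `band_hi`, `power` (variance of the filtered normalized
#'   signal), `temporal_sd` (SD of the full normalized signal),
#'   `harmonic_alias` (Hz), `harmonic_in_band` (logical).
#' @export
pulsation_power <- function(ts, cardiac, width = 2,
                            width_mode = c("total", "half")) {
  ts <- as_timeseries(ts)
  width_mode <- match.arg(width_mode)
  half <- if (width_mode == "total") width / 2 else width
  dt <- ts_dt(ts)
  nyq <- 1 / (2 * dt)
  lo <- max(cardiac - half, 0)
  hi <- min(cardiac + half, nyq)
  if (lo >= nyq || hi <= lo) stop("Cardiac band is empty below Nyquist.", call. = FALSE)

  m <- mean(ts$value)
  if (!is.finite(m) || m <= 0) stop("Temporal mean must be positive.", call. = FALSE)
  x <- ts$value / m
  x <- x - mean(x)
  filt <- fft_bandpass(x, dt, c(lo, hi))
  alias1 <- alias_fold(2 * cardiac, dt)
  tibble::tibble(
    cardiac_freq = cardiac,
    band_lo = lo, band_hi = hi,
    power = mean(filt^2),
    temporal_sd = sqrt(mean(x^2)),
    harmonic_alias = alias1,
    harmonic_in_band = alias1 >= lo & alias1 <= hi
  )
}

#' Temporal-SD fluctuation map
#'
#' Per-voxel standard deviation of the mean-normalized time course of a 4D
#' volume; high values co-localize with pulsatile structures such as
#' cerebral arteries. Voxels with non-positive temporal mean return `NA`.
#'
#' @param volume4d 4D numeric array `(x, y, z, t)`.
#' @return 3D array of temporal SDs (population convention, matching the
#'   spectral power scaling).
#' @export
temporal_sd_map <- function(volume4d) {
  dims <- dim(volume4d)
  stopifnot(length(dims) == 4, dims[4] >= 2)
  nvox <- prod(dims[1:3])
  mat <- matrix(volume4d, nrow = nvox, ncol = dims[4])
  mu <- rowMeans(mat)
  norm <- mat / mu
  sds <- sqrt(rowMeans((norm - rowMeans(norm))^2))
  sds[!is.finite(mu) | mu <= 0] <- NA_real_
  array(sds, dims[1:3])
}

#' @exportS3Method ggplot2::autoplot
autoplot.nf_spectrum <- function(object, ...) {
  ggplot2::ggplot(object[-1, ], ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power (a.u.²)") +
    ggplot2::theme_minimal()
}
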