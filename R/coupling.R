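#' Lagged cross-correlation between BOLD and CSF signals
#'
#' Computes the Pearson correlation of the two series at every integer lag
#' in `[-max_lag, +max_lag]`. At lag `l` the BOLD sample at time `t - l` is
#' paired with the CSF sample at time `t`, so a *negative* optimal lag means
#' the BOLD oscillation precedes the CSF inflow signal. Each lag's
#' correlation is a true Pearson coefficient of the overlapping segments
#' (their own means and SDs), so `|r| <= 1` at every lag. Pairs containing
#' `NA` (censored frames) are deleted lag-wise.
#'
#' @param bold,csf Time-series tibbles of equal length and sampling interval.
#' @param max_lag Maximum lag in frames (default 10).
#' @return A tibble of class `nf_xcorr` with columns `lag`, `r`, `n_pairs`.
#' @export
cross_correlate <- function(bold, csf, max_lag = 10) {
  bold <- as_timeseries(bold); csf <- as_timeseries(csf)
  if (nrow(bold) != nrow(csf)) stop("Series lengths differ.", call. = FALSE)
  n <- nrow(bold)
  if (n < 3 * max_lag) {
    stop(sprintf("Need at least 3*max_lag = %d frames.", 3 * max_lag), call. = FALSE)
  }
  b <- bold$value; c_ <- csf$value
  if (stats::sd(b, na.rm = TRUE) == 0 || stats::sd(c_, na.rm = TRUE) == 0) {
    stop("Constant input series; correlation undefined.", call. = FALSE)
  }
  res <- purrr::map_dfr(seq(-max_lag, max_lag), function(l) {
    # pair bold[i] with csf[i - l]
    i <- seq.int(max(1L, 1L + l), min(n, n + l))
    bi <- b[i]; ci <- c_[i - l]
    ok <- stats::complete.cases(bi, ci)
    r <- if (sum(ok) >= 3 && stats::sd(bi[ok]) > 0 && stats::sd(ci[ok]) > 0) {
      stats::cor(bi[ok], ci[ok])
    } else NA_real_
    tibble::tibble(lag = l, r = r, n_pairs = sum(ok))
  })
  structure(res, class = c("nf_xcorr", class(res)), dt = ts_dt(bold))
}

#' Coupling strength at a reference lag
#'
#' The coupling strength is the cross-correlation value read at a fixed
#' species-specific reference lag: -1 scan for human acquisitions (BOLD
#' leads CSF by one frame) and 0 for mouse. The lag is a parameter, never
#' hard-coded.
#'
#' @param cc An `nf_xcorr` tibble from [cross_correlate()].
#' @param reference_lag Reference lag in frames.
#' @return The correlation at `reference_lag` (dimensionless, in `[-1, 1]`).
#' @export
coupling_strength <- function(cc, reference_lag) {
  hit <- cc$r[cc$lag == reference_lag]
  if (length(hit) != 1) {
    stop(sprintf("Lag %d is outside the computed range.", reference_lag), call. = FALSE)
  }
  hit
}

#' Lag of strongest anticorrelation
#'
#' Returns the lag minimising the cross-correlation (most negative r, i.e.
#' strongest anticorrelation). Ties are broken toward the smallest absolute
#' lag, then toward the negative lag.
#'
#' @param cc An `nf_xcorr` tibble.
#' @return One-row tibble with `optimal_lag` (frames) and `optimal_r`.
#' @export
optimal_lag <- function(cc) {
  ok <- !is.na(cc$r)
  if (!any(ok)) stop("No valid correlations.", call. = FALSE)
  rmin <- min(cc$r[ok])
  cand <- cc$lag[ok][cc$r[ok] == rmin]
  pick <- cand[order(abs(cand), cand)][1]
  tibble::tibble(optimal_lag = pick, optimal_r = rmin)
}

#' Oscillation amplitude of a time series
#'
#' Amplitude is quantified as the temporal (sample) standard deviation of
#' the preprocessed series.
#'
#' @param ts Time-series tibble.
#' @return Sample SD of the values (same units as the series).
#' @export
oscillation_amplitude <- function(ts) {
  ts <- as_timeseries(ts)
  if (nrow(ts) < 2) stop("Need at least 2 frames.", call. = FALSE)
  stats::sd(ts$value, na.rm = TRUE)
}

#' One-call BOLD-CSF coupling summary
#'
#' Convenience wrapper: cross-correlates the two cleaned series and returns
#' the scalar coupling metrics in one row.
#'
#' @inheritParams cross_correlate
#' @param reference_lag Reference lag in frames (-1 human, 0 mouse).
#' @return One-row tibble: `strength`, `optimal_lag`, `optimal_r`,
#'   `amplitude` (temporal SD of the BOLD series).
#' @export
bold_csf_coupling <- function(bold, csf, max_lag = 10, reference_lag = -1) {
  cc <- cross_correlate(bold, csf, max_lag = max_lag)
  opt <- optimal_lag(cc)
  tibble::tibble(
    strength = coupling_strength(cc, reference_lag),
    optimal_lag = opt$optimal_lag,
    optimal_r = opt$optimal_r,
    amplitude = oscillation_amplitude(bold)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.nf_xcorr <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "Lag (frames; negative = BOLD earlier)",
                  y = "Pearson r") +
    ggplot2::theme_minimal()
}
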