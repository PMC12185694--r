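#' Build a uniformly sampled time-series tibble
#'
#' The unit object of the coupling and pulsation analyses: a regularly
#' sampled 1D signal stored as a two-column tibble (`time` in seconds,
#' `value` in arbitrary units or percent of baseline).
#'
#' @param values Numeric vector of samples.
#' @param dt Sampling interval in seconds (> 0).
#' @param t0 Time of the first sample in seconds.
#' @return A tibble with columns `time` and `value`.
#' @examples
#' ts_tibble(sin(2 * pi * 0.05 * seq(0, 100, by = 2)), dt = 2)
#' @export
ts_tibble <- function(values, dt, t0 = 0) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("`dt` must be a single positive number (seconds).", call. = FALSE)
  }
  tibble::tibble(time = t0 + dt * (seq_along(values) - 1), value = as.numeric(values))
}

#' Sampling interval of a time-series tibble
#'
#' @param ts A tibble with `time` and `value` columns.
#' @return The sampling interval in seconds (median of successive time
#'   differences, robust to dropped frames).
#' @export
ts_dt <- function(ts) {
  ts <- as_timeseries(ts)
  if (nrow(ts) < 2) stop("Need at least 2 frames to infer `dt`.", call. = FALSE)
  stats::median(diff(ts$time))
}

# Coerce to the canonical two-column form; numeric vectors are refused
# because dt would be unknown.
as_timeseries <- function(ts, arg = deparse(substitute(ts))) {
  if (!is.data.frame(ts) || !all(c("time", "value") %in% names(ts))) {
    stop(sprintf("`%s` must be a data frame with `time` and `value` columns.", arg),
         call. = FALSE)
  }
  tibble::as_tibble(ts[, c("time", "value")])
}

#' Read / write a time series as two-column TSV
#'
#' Plain tab-separated `time_s` / `value` files are the on-disk exchange
#' format for ROI time courses.
#'
#' @param path File path.
#' @return `read_series_tsv()` returns a tibble with `time` and `value`.
#' @export
read_series_tsv <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  names(x)[1:2] <- c("time", "value")
  tibble::as_tibble(x[, 1:2])
}

#' @param ts A time-series tibble.
#' @rdname read_series_tsv
#' @export
write_series_tsv <- function(ts, path) {
  ts <- as_timeseries(ts)
  out <- data.frame(time_s = ts$time, value = ts$value)
  tmp <- paste0(path, ".tmp")
  utils::write.table(out, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
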