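#' Normalize a dynamic Gd-enhanced signal to baseline
#'
#' Divides the raw intensity by the mean of the pre-injection baseline
#' frames and expresses the result as fractional signal change (0.2 = 20%
#' enhancement). Time is re-expressed in minutes relative to the injection
#' frame, so pre-injection frames carry negative times.
#'
#' @param raw Numeric vector of raw intensities, one per frame, or a tibble
#'   with a `value` column.
#' @param baseline_frames Number of initial baseline frames averaged
#'   (default 3).
#' @param injection_index Number of frames acquired before the injection;
#'   the first post-injection frame is `injection_index + 1`. Defaults to
#'   `baseline_frames`.
#' @param frame_dt Minutes per frame (default 3.33).
#' @return A tibble of class `gd_curve` with columns `frame`, `time`
#'   (minutes since injection) and `value` (fractional signal change).
#' @export
normalize_gd <- function(raw, baseline_frames = 3, injection_index = baseline_frames,
                         frame_dt = 3.33) {
  v <- if (is.data.frame(raw)) raw$value else as.numeric(raw)
  if (baseline_frames < 1 || baseline_frames > length(v)) {
    stop("Invalid `baseline_frames`.", call. = FALSE)
  }
  b <- mean(v[seq_len(baseline_frames)])
  if (!is.finite(b) || b <= 0) stop("Baseline mean must be positive.", call. = FALSE)
  out <- tibble::tibble(
    frame = seq_along(v),
    time = (seq_along(v) - 1 - injection_index) * frame_dt,
    value = v / b - 1
  )
  new_gd_curve(out, baseline_frames, injection_index, frame_dt)
}

new_gd_curve <- function(tbl, baseline_frames, injection_index, frame_dt) {
  structure(tbl, class = c("gd_curve", class(tibble::as_tibble(tbl))),
            baseline_frames = baseline_frames,
            injection_index = injection_index,
            frame_dt = frame_dt)
}

#' Assemble a Gd curve from already-normalized values
#'
#' For signals that are already in fractional-signal-change units (e.g. the
#' synthetic generator's output).
#'
#' @inheritParams normalize_gd
#' @param values Fractional signal change per frame.
#' @return A `gd_curve` tibble; see [normalize_gd()].
#' @export
gd_curve <- function(values, baseline_frames = 3, injection_index = baseline_frames,
                     frame_dt = 3.33) {
  tbl <- tibble::tibble(
    frame = seq_along(values),
    time = (seq_along(values) - 1 - injection_index) * frame_dt,
    value = as.numeric(values)
  )
  new_gd_curve(tbl, baseline_frames, injection_index, frame_dt)
}

post_injection <- function(curve) {
  curve[curve$time >= 0, , drop = FALSE]
}

# Levenberg-Marquardt over several starts; returns the converged fit with
# the lowest residual sum of squares, or NULL when every start fails.
lm_fit_best <- function(starts, lower, resid_fn) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL
    )
    if (is.null(fit) || !(fit$info %in% 1:4)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  best
}

#' Area under the enhancement curve
#'
#' Sum of the fractional signal change over post-injection frames; a proxy
#' for total tracer flux through the voxel or region. When `whole_brain_auc`
#' is supplied the AUC is divided by it, normalising away the
#' animal-to-animal variation in the amount of contrast delivered.
#'
#' @param curve A `gd_curve` tibble.
#' @param whole_brain_auc Optional whole-brain AUC used as the normaliser.
#' @return AUC (signal change x frames), or the dimensionless ratio when
#'   normalised.
#' @export
gd_auc <- function(curve, whole_brain_auc = NULL) {
  post <- post_injection(curve)
  a <- sum(post$value)
  if (!is.null(whole_brain_auc)) a <- a / whole_brain_auc
  a
}

#' Tracer arrival time
#'
#' The time of the first post-injection frame whose signal change strictly
#' exceeds 20% of the maximum post-injection signal change, reported at
#' frame resolution (no sub-frame interpolation).
#'
#' @param curve A `gd_curve` tibble.
#' @param threshold_frac Fraction of the maximum defining arrival
#'   (default 0.2).
#' @return Arrival time in minutes since injection.
#' @export
arrival_time <- function(curve, threshold_frac = 0.2) {
  post <- post_injection(curve)
  mx <- max(post$value)
  if (!is.finite(mx) || mx <= 0) {
    stop("No enhancement: maximum post-injection signal change is not positive.",
         call. = FALSE)
  }
  hit <- which(post$value > threshold_frac * mx)
  if (length(hit) == 0) stop("No frame exceeds the arrival threshold.", call. = FALSE)
  post$time[hit[1]]
}

#' Time-to-peak of the enhancement curve
#'
#' Time of the global post-injection maximum; ties (a plateau of equal
#' maxima) resolve to the earliest frame.
#'
#' @param curve A `gd_curve` tibble.
#' @return Time-to-peak in minutes since injection.
#' @export
time_to_peak <- function(curve) {
  post <- post_injection(curve)
  mx <- max(post$value)
  if (!is.finite(mx) || mx <= 0) {
    stop("No enhancement: maximum post-injection signal change is not positive.",
         call. = FALSE)
  }
  post$time[which.max(post$value)]
}

#' Tracer influx rate
#'
#' The rising slope of the enhancement curve between arrival time and
#' time-to-peak. Default is the least-squares slope over all frames in the
#' window (robust to noise); `method = "two_point"` uses the endpoints only.
#'
#' @param curve A `gd_curve` tibble.
#' @param arrival,ttp Window bounds in minutes; computed from the curve when
#'   omitted.
#' @param method `"regression"` (default) or `"two_point"`.
#' @return Influx rate in signal change per minute.
#' @export
influx_rate <- function(curve, arrival = NULL, ttp = NULL,
                        method = c("regression", "two_point")) {
  method <- match.arg(method)
  if (is.null(arrival)) arrival <- arrival_time(curve)
  if (is.null(ttp)) ttp <- time_to_peak(curve)
  if (arrival >= ttp) stop("Arrival must precede time-to-peak.", call. = FALSE)
  win <- curve[curve$time >= arrival & curve$time <= ttp, , drop = FALSE]
  if (nrow(win) < 2) stop("Fewer than 2 frames between arrival and peak.", call. = FALSE)
  if (method == "two_point") {
    (win$value[nrow(win)] - win$value[1]) / (win$time[nrow(win)] - win$time[1])
  } else {
    unname(stats::coef(stats::lm(value ~ time, data = win))[2])
  }
}

#' Exponential decay fit of the post-peak efflux
#'
#' Fits `A * exp(-(t - t_peak) / Decay) + C` to the post-peak frames by
#' nonlinear least squares (Levenberg-Marquardt). The clock starts at the
#' peak frame, which removes the degeneracy between `A` and the absolute
#' time origin. Initialization: `C0` = last value, `A0` = peak - last,
#' `Decay0` = time for the signal to fall halfway from peak to last (falling
#' back to half the post-peak span); `Decay` is constrained positive.
#'
#' @param curve A `gd_curve` tibble.
#' @param ttp Peak time in minutes; computed from the curve when omitted.
#' @return An object of class `nf_decay_fit`: list with `A`, `Decay`, `C`,
#'   `fit_rss`, `converged`, `n`, and the fitted model. Non-convergence
#'   after restarts is flagged via `converged = FALSE`, never a silent NaN.
#' @export
decay_fit <- function(curve, ttp = NULL) {
  if (is.null(ttp)) ttp <- time_to_peak(curve)
  post <- curve[curve$time >= ttp, , drop = FALSE]
  if (nrow(post) < 4) stop("Need at least 4 frames after the peak.", call. = FALSE)
  tt <- post$time - ttp
  y <- post$value

  c0 <- y[length(y)]
  a0 <- y[1] - c0
  half <- c0 + a0 / 2
  below <- which(y <= half)
  d0 <- if (length(below) > 0 && tt[below[1]] > 0) tt[below[1]] / log(2) else max(tt) / 2
  if (!is.finite(d0) || d0 <= 0) d0 <- max(tt) / 2

  starts <- list(
    c(A = a0, Decay = d0, C = c0),
    c(A = a0, Decay = max(tt) / 2, C = c0),
    c(A = a0, Decay = max(tt) / 10, C = 0)
  )
  fit <- lm_fit_best(starts, lower = c(-Inf, 1e-9, -Inf),
                     resid_fn = function(p) y - (p[1] * exp(-tt / p[2]) + p[3]))
  if (is.null(fit)) {
    return(structure(list(A = NA_real_, Decay = NA_real_, C = NA_real_,
                          fit_rss = NA_real_, converged = FALSE, n = length(y),
                          t_peak = ttp, model = NULL),
                     class = "nf_decay_fit"))
  }
  cf <- fit$par
  structure(list(A = unname(cf[1]), Decay = unname(cf[2]), C = unname(cf[3]),
                 fit_rss = fit$deviance,
                 converged = TRUE, n = length(y), t_peak = ttp, model = fit),
            class = "nf_decay_fit")
}

#' @export
print.nf_decay_fit <- function(x, ...) {
  cat("Exponential efflux fit: A*exp(-(t - t_peak)/Decay) + C\n")
  cat(sprintf("  A = %.4g  Decay = %.4g min  C = %.4g  (RSS %.4g, n = %d)\n",
              x$A, x$Decay, x$C, x$fit_rss, x$n))
  if (!x$converged) cat("  ** fit did not converge **\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nf_decay_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "Decay", "C"),
                 estimate = c(x$A, x$Decay, x$C))
}

#' @exportS3Method generics::glance
glance.nf_decay_fit <- function(x, ...) {
  tibble::tibble(fit_rss = x$fit_rss, n = x$n, converged = x$converged,
                 t_peak = x$t_peak)
}

#' Full kinetic-parameter extraction for one curve
#'
#' Computes all tracer-kinetic descriptors of an enhancement curve: AUC,
#' arrival time, time-to-peak, effective time-to-peak (TTP minus arrival),
#' influx rate and the exponential decay parameters.
#'
#' @param curve A `gd_curve` tibble.
#' @param whole_brain_auc Optional AUC normaliser; see [gd_auc()].
#' @return One-row tibble: `auc`, `arrival_time`, `ttp`, `effective_ttp`,
#'   `influx_rate`, `A`, `Decay`, `C`, `fit_rss`, `converged`.
#' @export
gd_kinetics <- function(curve, whole_brain_auc = NULL) {
  arr <- arrival_time(curve)
  ttp <- time_to_peak(curve)
  fit <- decay_fit(curve, ttp = ttp)
  tibble::tibble(
    auc = gd_auc(curve, whole_brain_auc),
    arrival_time = arr,
    ttp = ttp,
    effective_ttp = ttp - arr,
    influx_rate = influx_rate(curve, arrival = arr, ttp = ttp),
    A = fit$A, Decay = fit$Decay, C = fit$C,
    fit_rss = fit$fit_rss, converged = fit$converged
  )
}

#' Voxel-wise kinetic parameter maps
#'
#' Applies the per-curve kinetic extraction to every voxel inside a brain
#' mask of a 4D dynamic volume. The whole-brain AUC (sum over mask voxels'
#' post-injection signal change, averaged across voxels) normalises the AUC
#' map. Voxels where extraction fails (e.g. no enhancement) are flagged in
#' the QC map and carry `NA` in all parameter maps — never interpolated.
#'
#' @param volume4d 4D numeric array `(x, y, z, t)` of raw intensities.
#' @param brain_mask 3D logical/0-1 array on the same grid.
#' @param baseline_frames,injection_index,frame_dt See [normalize_gd()].
#' @return A list of 3D arrays: `auc` (whole-brain-normalised), `auc_raw`,
#'   `arrival_time`, `ttp`, `effective_ttp`, `influx_rate`, `decay`, `qc`
#'   (1 = extraction succeeded), plus `whole_brain_auc` (scalar).
#' @export
kinetic_maps <- function(volume4d, brain_mask, baseline_frames = 3,
                         injection_index = baseline_frames, frame_dt = 3.33) {
  dims <- dim(volume4d)
  stopifnot(length(dims) == 4, all(dim(brain_mask) == dims[1:3]))
  mask_idx <- which(brain_mask != 0)
  if (length(mask_idx) == 0) stop("Empty brain mask.", call. = FALSE)
  nvox <- prod(dims[1:3])
  mat <- matrix(volume4d, nrow = nvox, ncol = dims[4])[mask_idx, , drop = FALSE]

  curves <- lapply(seq_len(nrow(mat)), function(i) {
    tryCatch(normalize_gd(mat[i, ], baseline_frames, injection_index, frame_dt),
             error = function(e) NULL)
  })
  wb_auc <- mean(vapply(curves, function(cv) {
    if (is.null(cv)) NA_real_ else gd_auc(cv)
  }, numeric(1)), na.rm = TRUE)

  blank <- function() array(NA_real_, dims[1:3])
  maps <- list(auc = blank(), auc_raw = blank(), arrival_time = blank(),
               ttp = blank(), effective_ttp = blank(), influx_rate = blank(),
               decay = blank(), qc = array(0, dims[1:3]))
  for (k in seq_along(mask_idx)) {
    cv <- curves[[k]]
    res <- if (is.null(cv)) NULL else {
      tryCatch(gd_kinetics(cv, whole_brain_auc = wb_auc), error = function(e) NULL)
    }
    if (is.null(res) || !res$converged) next
    i <- mask_idx[k]
    maps$auc[i] <- res$auc
    maps$auc_raw[i] <- res$auc * wb_auc
    maps$arrival_time[i] <- res$arrival_time
    maps$ttp[i] <- res$ttp
    maps$effective_ttp[i] <- res$effective_ttp
    maps$influx_rate[i] <- res$influx_rate
    maps$decay[i] <- res$Decay
    maps$qc[i] <- 1
  }
  maps$whole_brain_auc <- wb_auc
  maps
}

#' @exportS3Method ggplot2::autoplot
autoplot.gd_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Time since injection (min)",
                  y = "Signal change (fraction of baseline)") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && isTRUE(fit$converged)) {
    post <- object[object$time >= fit$t_peak, ]
    pred <- tibble::tibble(
      time = post$time,
      value = fit$A * exp(-(post$time - fit$t_peak) / fit$Decay) + fit$C
    )
    p <- p + ggplot2::geom_line(data = pred, colour = "firebrick", linewidth = 0.8)
  }
  p
}
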