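#' Configuration for the synthetic-data generators
#'
#' One object carries every knob of the synthetic study: the coupled
#' BOLD/CSF oscillation, the tracer-kinetic curve, the pulsatile arterial
#' signal and the ASL dataset. Defaults emulate the study conditions the
#' analyses are designed for: human-like resting-state sampling (dt =
#' 2.68 s, 150 frames, vasomotion band 0.01-0.1 Hz, BOLD leading CSF by one
#' scan), a mouse heart rate of 4.58 Hz sampled at 70 ms so the first
#' cardiac harmonic aliases, and Gd kinetics on a 3.33 min frame grid.
#'
#' @param seed Integer master seed; each generator derives its own
#'   substream by a fixed offset so the streams are independent but fully
#'   reproducible.
#' @param n_subjects Number of subjects/units to simulate.
#' @param n_frames Frames per series (>= 2).
#' @param dt Seconds per frame (> 0).
#' @param band Passband `(low, high)` in Hz of the BOLD process; must lie
#'   below Nyquist.
#' @param true_lag Lag of the CSF signal relative to BOLD, in frames;
#'   negative = BOLD precedes CSF.
#' @param coupling_amp Amplitude of the (sign-inverted) coupling.
#' @param noise_sd SD of additive white noise, relative to the unit-SD
#'   BOLD process.
#' @param cardiac_freq Heart rate in Hz (default 4.58).
#' @param cardiac_amp,harmonic_amp,resp_amp Fractional modulation
#'   amplitudes of the cardiac line, its first harmonic and respiration.
#' @param resp_freq Respiration rate in Hz (default 1.5, i.e. 90
#'   breaths/min).
#' @param vasomotion_amp Amplitude of the slow vasomotion component.
#' @param vasomotion_freq Vasomotion frequency in Hz, inside 0.01-0.1.
#' @param kinetics Named list for the Gd curve: `baseline_frames`,
#'   `arrival` (min after injection at which the rise starts), `ttp` (min),
#'   `peak_amp` (fractional signal change at peak), `A`, `Decay` (min), `C`
#'   (efflux tail `A exp(-t/Decay) + C`), `frame_dt` (min/frame),
#'   `n_frames`, `rise` ("linear" or "sigmoid").
#' @param asl Named list: `cbf_true` (ml/100g/min), `t1t` (tissue T1, ms),
#'   `dims` (3D grid), `si_c` (control signal level, a.u.), plus the
#'   [asl_params()] constants `alpha`, `lambda`, `t1b`, `lt`, `pld`, `tr`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_subjects = 20L,
                       n_frames = 150L,
                       dt = 2.68,
                       band = c(0.01, 0.1),
                       true_lag = -1L,
                       coupling_amp = 1,
                       noise_sd = 0.3,
                       cardiac_freq = 4.58,
                       cardiac_amp = 0.05,
                       harmonic_amp = 0.02,
                       resp_freq = 1.5,
                       resp_amp = 0.03,
                       vasomotion_amp = 0.02,
                       vasomotion_freq = 0.05,
                       kinetics = list(),
                       asl = list()) {
  kin_def <- list(baseline_frames = 3L, arrival = 6.66, ttp = 39.96,
                  peak_amp = 0.8, A = 0.75, Decay = 40, C = 0.05,
                  frame_dt = 3.33, n_frames = 40L, rise = "linear")
  kinetics <- utils::modifyList(kin_def, kinetics)
  asl_def <- list(cbf_true = 100, t1t = 1700, dims = c(8L, 8L, 4L),
                  si_c = 1000, alpha = 0.75, lambda = 0.9, t1b = 2430,
                  lt = 3000, pld = 450, tr = 4414.68)
  asl <- utils::modifyList(asl_def, asl)

  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              n_frames = as.integer(n_frames), dt = dt, band = band,
              true_lag = as.integer(true_lag), coupling_amp = coupling_amp,
              noise_sd = noise_sd, cardiac_freq = cardiac_freq,
              cardiac_amp = cardiac_amp, harmonic_amp = harmonic_amp,
              resp_freq = resp_freq, resp_amp = resp_amp,
              vasomotion_amp = vasomotion_amp, vasomotion_freq = vasomotion_freq,
              kinetics = kinetics, asl = asl)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  nyq <- 1 / (2 * cfg$dt)
  if (cfg$n_frames < 2) stop("`n_frames` must be >= 2.", call. = FALSE)
  if (cfg$dt <= 0) stop("`dt` must be positive.", call. = FALSE)
  if (!(cfg$band[1] < cfg$band[2] && cfg$band[2] < nyq)) {
    stop(sprintf("Band must satisfy low < high < Nyquist (%.4g Hz).", nyq),
         call. = FALSE)
  }
  if (cfg$n_subjects < 1) stop("`n_subjects` must be >= 1.", call. = FALSE)
  if (cfg$kinetics$Decay <= 0) stop("`Decay` must be positive.", call. = FALSE)
  if (cfg$kinetics$baseline_frames < 1) stop("`baseline_frames` must be >= 1.", call. = FALSE)
  if (cfg$asl$cbf_true < 0) stop("`cbf_true` must be >= 0.", call. = FALSE)
  if (cfg$asl$t1t <= 0) stop("`t1t` must be positive.", call. = FALSE)
  invisible(cfg)
}

# Fixed substream offsets: one master seed, independent streams per
# generator. Subject index shifts within a stream.
SEED_OFFSETS <- c(coupled = 101L, motion = 211L, gd = 307L,
                  pulsatile = 401L, asl = 503L)

substream_seed <- function(cfg, stream, subject = 1L) {
  (cfg$seed + SEED_OFFSETS[[stream]] + 1000L * (subject - 1L)) %% .Machine$integer.max
}

# Band-limited unit-SD Gaussian process: white noise filtered in the
# frequency domain with an ideal boxcar band mask.
band_limited_noise <- function(n, dt, band) {
  x <- fft_bandpass(stats::rnorm(n), dt, band)
  s <- stats::sd(x)
  if (s == 0) stop("Band contains no frequency bins at this length.", call. = FALSE)
  x / s
}

#' Simulate a coupled BOLD/CSF signal pair
#'
#' BOLD is a band-limited unit-SD Gaussian process in `cfg$band`; the CSF
#' inflow signal is its sign-inverted, lag-shifted copy plus white noise:
#' `csf(t) = -coupling_amp * bold(t + true_lag) + noise_sd * e(t)`, so a
#' negative `true_lag` makes BOLD precede CSF (the physiological direction).
#' The lag is applied by integer circular shift on an extended series and
#' the wrapped segment is discarded, so the true lag is exact with no edge
#' transient.
#'
#' @param cfg A [sim_config()].
#' @param subject Subject index (selects an independent substream).
#' @return A list: `bold` and `csf` time-series tibbles of `cfg$n_frames`
#'   frames, and `truth` (one-row tibble of the generating parameters).
#' @export
gen_coupled_bold_csf <- function(cfg, subject = 1L) {
  validate_sim_config(cfg)
  if (abs(cfg$true_lag) > 10) stop("`true_lag` must be within +/-10 frames.", call. = FALSE)
  lag <- cfg$true_lag
  n <- cfg$n_frames
  n_ext <- n + abs(lag)
  withr::with_seed(substream_seed(cfg, "coupled", subject), {
    bold_ext <- band_limited_noise(n_ext, cfg$dt, cfg$band)
    shifted <- bold_ext[((seq_len(n_ext) - 1 + lag) %% n_ext) + 1]  # bold(t + lag)
    csf_ext <- -cfg$coupling_amp * shifted + cfg$noise_sd * stats::rnorm(n_ext)
    # discard the wrapped segment from both series
    idx <- if (lag < 0) seq.int(abs(lag) + 1, n_ext) else seq_len(n)
    bold <- bold_ext[idx]; csf <- csf_ext[idx]
  })
  list(
    bold = ts_tibble(bold, cfg$dt),
    csf = ts_tibble(csf, cfg$dt),
    truth = tibble::tibble(subject = subject, true_lag = lag,
                           coupling_amp = cfg$coupling_amp,
                           noise_sd = cfg$noise_sd, dt = cfg$dt,
                           n_frames = n, band_lo = cfg$band[1],
                           band_hi = cfg$band[2],
                           seed = substream_seed(cfg, "coupled", subject))
  )
}

#' Simulate a rigid-body motion trace
#'
#' Smooth low-amplitude sinusoidal drift on all six parameters plus
#' persistent translation steps of `spike_size` mm at the listed frames —
#' the fixture for frame-wise-displacement scrubbing tests.
#'
#' @param cfg A [sim_config()].
#' @param spike_frames Integer frames at which a translation step occurs.
#' @param spike_size Step size in mm.
#' @param drift_amp Amplitude of the smooth drift (mm for translations,
#'   radians for rotations); 0 gives a perfectly still head.
#' @return A tibble with columns `frame`, `x`, `y`, `z` (mm), `pitch`,
#'   `roll`, `yaw` (rad).
#' @export
gen_motion_trace <- function(cfg, spike_frames = integer(), spike_size = 0.5,
                             drift_amp = 0.02) {
  validate_sim_config(cfg)
  n <- cfg$n_frames
  if (length(spike_frames) > 0 &&
      (any(spike_frames < 1) || any(spike_frames > n))) {
    stop("`spike_frames` out of range.", call. = FALSE)
  }
  t <- seq_len(n)
  withr::with_seed(substream_seed(cfg, "motion"), {
    phases <- stats::runif(6, 0, 2 * pi)
  })
  drift <- function(k) drift_amp * sin(2 * pi * t / (n * 2) + phases[k])
  x <- drift(1); y <- drift(2); z <- drift(3)
  for (f in spike_frames) x[f:n] <- x[f:n] + spike_size
  tibble::tibble(frame = t, x = x, y = y, z = z,
                 pitch = drift(4) / 50, roll = drift(5) / 50, yaw = drift(6) / 50)
}

#' Simulate a Gd time-intensity curve
#'
#' Flat zero baseline before arrival, a rise (linear by default; logistic
#' behind the `rise = "sigmoid"` flag) from the arrival time to `peak_amp`
#' at the time-to-peak, then an exact exponential tail
#' `A exp(-(t - ttp)/Decay) + C`, plus additive Gaussian noise of SD
#' `noise_sd` (in signal-change units).
#'
#' @param cfg A [sim_config()]; the `kinetics` element sets the shape.
#' @param subject Subject index.
#' @param noise_sd Noise SD override; defaults to `cfg$noise_sd` scaled to
#'   signal-change units via `peak_amp` (an SNR-20-style default would be
#'   `peak_amp / 20`).
#' @return A list: `curve` (a [gd_curve()] tibble) and `truth` (one-row
#'   tibble of the generating parameters, including the injection index).
#' @export
gen_gd_curve <- function(cfg, subject = 1L, noise_sd = NULL) {
  validate_sim_config(cfg)
  k <- cfg$kinetics
  if (!(k$arrival < k$ttp)) stop("Need arrival < ttp.", call. = FALSE)
  if (k$Decay <= 0) stop("`Decay` must be positive.", call. = FALSE)
  injection_index <- k$baseline_frames
  n <- k$n_frames
  t <- (seq_len(n) - 1 - injection_index) * k$frame_dt   # min since injection
  v <- numeric(n)
  rising <- t > k$arrival & t < k$ttp
  if (identical(k$rise, "sigmoid")) {
    mid <- (k$arrival + k$ttp) / 2
    scl <- (k$ttp - k$arrival) / 10
    v[rising] <- k$peak_amp / (1 + exp(-(t[rising] - mid) / scl))
  } else {
    v[rising] <- k$peak_amp * (t[rising] - k$arrival) / (k$ttp - k$arrival)
  }
  tail <- t >= k$ttp
  v[tail] <- k$A * exp(-(t[tail] - k$ttp) / k$Decay) + k$C
  if (is.null(noise_sd)) noise_sd <- 0
  if (noise_sd > 0) {
    withr::with_seed(substream_seed(cfg, "gd", subject), {
      v <- v + stats::rnorm(n, sd = noise_sd)
    })
  }
  curve <- gd_curve(v, baseline_frames = k$baseline_frames,
                    injection_index = injection_index, frame_dt = k$frame_dt)
  list(curve = curve,
       truth = tibble::tibble(subject = subject,
                              arrival = k$arrival, ttp = k$ttp,
                              effective_ttp = k$ttp - k$arrival,
                              peak_amp = k$peak_amp, A = k$A, Decay = k$Decay,
                              C = k$C, noise_sd = noise_sd,
                              injection_index = injection_index,
                              frame_dt = k$frame_dt, rise = k$rise))
}

#' Simulate a pulsatile arterial signal
#'
#' Sum of sinusoids in continuous time — cardiac line, its first harmonic
#' (2x cardiac, which aliases naturally when sampled below its Nyquist),
#' respiration and a slow vasomotion component — sampled at `cfg$dt`, plus
#' white noise, around a unit temporal mean.
#'
#' @param cfg A [sim_config()].
#' @param subject Subject index.
#' @param noise_sd White-noise SD (fractional units); defaults to 0.005.
#' @return A list: `ts` (time-series tibble) and `truth` (components,
#'   amplitudes, and the folded location of each line at this `dt`).
#' @export
gen_pulsatile_signal <- function(cfg, subject = 1L, noise_sd = 0.005) {
  validate_sim_config(cfg)
  n <- cfg$n_frames
  t <- cfg$dt * (seq_len(n) - 1)
  withr::with_seed(substream_seed(cfg, "pulsatile", subject), {
    ph <- stats::runif(4, 0, 2 * pi)
    noise <- if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else numeric(n)
  })
  v <- 1 +
    cfg$cardiac_amp * sin(2 * pi * cfg$cardiac_freq * t + ph[1]) +
    cfg$harmonic_amp * sin(2 * pi * 2 * cfg$cardiac_freq * t + ph[2]) +
    cfg$resp_amp * sin(2 * pi * cfg$resp_freq * t + ph[3]) +
    cfg$vasomotion_amp * sin(2 * pi * cfg$vasomotion_freq * t + ph[4]) +
    noise
  truth <- tibble::tibble(
    component = c("cardiac", "harmonic", "respiration", "vasomotion"),
    freq = c(cfg$cardiac_freq, 2 * cfg$cardiac_freq, cfg$resp_freq,
             cfg$vasomotion_freq),
    amplitude = c(cfg$cardiac_amp, cfg$harmonic_amp, cfg$resp_amp,
                  cfg$vasomotion_amp),
    folded_freq = alias_fold(c(cfg$cardiac_freq, 2 * cfg$cardiac_freq,
                               cfg$resp_freq, cfg$vasomotion_freq), cfg$dt),
    variance = c(cfg$cardiac_amp, cfg$harmonic_amp, cfg$resp_amp,
                 cfg$vasomotion_amp)^2 / 2
  )
  list(ts = ts_tibble(v, cfg$dt), truth = truth)
}

#' Simulate a pCASL label/control dataset
#'
#' Sets every control voxel to a constant positive signal and computes the
#' label signal by algebraically inverting the CBF quantification formula
#' at `cfg$asl$cbf_true`, so quantification on the generated data recovers
#' the true CBF exactly. The per-voxel tissue T1 map is returned alongside.
#'
#' @param cfg A [sim_config()].
#' @param t1_jitter SD of multiplicative spatial variation applied to the
#'   T1 map (0 = uniform).
#' @return A list: `control`, `label`, `t1_map` (3D arrays), `params` (an
#'   [asl_params()] object) and `truth` (one-row tibble).
#' @export
gen_asl_dataset <- function(cfg, t1_jitter = 0) {
  validate_sim_config(cfg)
  a <- cfg$asl
  dims <- a$dims
  params <- asl_params(alpha = a$alpha, lambda = a$lambda, t1b = a$t1b,
                       lt = a$lt, pld = a$pld, tr = a$tr)
  t1_map <- array(a$t1t, dims)
  if (t1_jitter > 0) {
    withr::with_seed(substream_seed(cfg, "asl"), {
      t1_map <- t1_map * (1 + stats::rnorm(prod(dims), sd = t1_jitter))
    })
    t1_map[t1_map <= 0] <- a$t1t
  }
  control <- array(a$si_c, dims)
  label <- array(asl_label_from_cbf(a$cbf_true, control, t1_map, params), dims)
  list(control = control, label = label, t1_map = t1_map, params = params,
       truth = tibble::tibble(cbf_true = a$cbf_true, t1t = a$t1t,
                              si_c = a$si_c, alpha = a$alpha,
                              lambda = a$lambda, t1b = a$t1b, lt = a$lt,
                              pld = a$pld, tr = a$tr))
}
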