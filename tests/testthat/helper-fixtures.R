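# Shared fixtures built in code.

# A still head: all six motion parameters constant.
still_motion <- function(n, offset = 0) {
  tibble::tibble(x = rep(offset, n), y = offset, z = offset,
                 pitch = offset, roll = offset, yaw = offset)
}

# Sinusoid sampled over an integer number of cycles.
sinusoid_ts <- function(amp, freq, dt, n_cycles, phase = 0) {
  n <- round(n_cycles / (freq * dt))
  t <- dt * (0:(n - 1))
  ts_tibble(amp * sin(2 * pi * freq * t + phase), dt)
}

# Noiseless enhancement curve with a linear rise and exact exponential tail.
# Defaults keep arrival/ttp on the frame grid and the peak continuous with
# the tail (peak = A + C) so the post-peak frames lie exactly on the model.
make_gd_fixture <- function(arrival = 6.66, ttp = 33.3, A = 0.75,
                            decay = 40, C = 0.05, peak = A + C, n = 40,
                            frame_dt = 3.33, baseline_frames = 3) {
  cfg <- sim_config(kinetics = list(arrival = arrival, ttp = ttp,
                                    peak_amp = peak, A = A, Decay = decay,
                                    C = C, n_frames = n, frame_dt = frame_dt,
                                    baseline_frames = baseline_frames))
  gen_gd_curve(cfg)$curve
}

# Brute-force oracle for the 3-parameter exponential decay: grid over Decay
# with (A, C) solved exactly by linear least squares at each grid value
# (the model is linear in A and C once Decay is fixed).
grid_decay_oracle <- function(tt, y, d_grid) {
  best <- c(NA, NA, NA); best_rss <- Inf
  for (d in d_grid) {
    X <- cbind(exp(-tt / d), 1)
    cf <- qr.solve(X, y)
    rss <- sum((y - X %*% cf)^2)
    if (rss < best_rss) { best_rss <- rss; best <- c(cf[1], d, cf[2]) }
  }
  list(A = best[1], Decay = best[2], C = best[3], rss = best_rss)
}

# Brute-force oracle for the magnitude inversion-recovery model: grid over
# (b, T1) with s0 >= 0 profiled out exactly (the magnitude model is linear
# in s0: |s0 (1 - b e^{-TI/T1})| = s0 |1 - b e^{-TI/T1}|).
grid_t1_oracle <- function(tis, y, b_grid, t1_grid) {
  best <- c(NA, NA, NA); best_rss <- Inf
  for (b in b_grid) for (t1 in t1_grid) {
    g <- abs(1 - b * exp(-tis / t1))
    s0 <- max(sum(y * g) / sum(g^2), 0)
    rss <- sum((y - s0 * g)^2)
    if (rss < best_rss) { best_rss <- rss; best <- c(s0, b, t1) }
  }
  list(s0 = best[1], b = best[2], t1 = best[3], rss = best_rss)
}
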