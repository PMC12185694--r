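test_that("baseline normalization matches hand arithmetic", {
  cv <- normalize_gd(c(100, 100, 100, 120), baseline_frames = 3, frame_dt = 1)
  expect_equal(cv$value[4], 0.20)
  cv2 <- normalize_gd(c(90, 100, 110, 150), baseline_frames = 3, frame_dt = 1)
  expect_equal(cv2$value[4], 0.50)
  flat <- normalize_gd(rep(100, 6), baseline_frames = 3)
  expect_true(all(flat$value == 0))
  expect_error(normalize_gd(c(-1, -1, -1, 5)), "positive")
})

test_that("AUC sums post-injection frames and self-normalizes to 1", {
  cv <- gd_curve(c(0, 0, 0, rep(1, 10)), baseline_frames = 3,
                 injection_index = 3, frame_dt = 1)
  expect_equal(gd_auc(cv), 10)
  expect_equal(gd_auc(cv, whole_brain_auc = gd_auc(cv)), 1)
  zero <- gd_curve(c(0, 0, 0, rep(0, 10)), baseline_frames = 3)
  expect_equal(gd_auc(zero), 0)
  # a sum is permutation-invariant over post-injection frames ...
  perm <- gd_curve(c(0, 0, 0, sample(c(rep(1, 5), rep(2, 5)))),
                   baseline_frames = 3, frame_dt = 1)
  base <- gd_curve(c(0, 0, 0, rep(1, 5), rep(2, 5)),
                   baseline_frames = 3, frame_dt = 1)
  expect_equal(gd_auc(perm), gd_auc(base))
})

test_that("arrival time is the first frame strictly above 20% of max", {
  ramp <- gd_curve(seq(0, 1, by = 0.1), baseline_frames = 1,
                   injection_index = 0, frame_dt = 1)
  expect_equal(arrival_time(ramp), 3)        # first value > 0.2 is 0.3

  step <- gd_curve(c(0, 0, 0, 0, 1, 1), baseline_frames = 3,
                   injection_index = 3, frame_dt = 1)
  expect_equal(arrival_time(step), 1)

  # sub-threshold noise before the rise does not trigger arrival
  noisy <- gd_curve(c(0, 0, 0, 0.15, 0.1, 0.05, 0.6, 1, 0.9),
                    baseline_frames = 3, injection_index = 3, frame_dt = 1)
  expect_equal(arrival_time(noisy), 3)
  # ... but arrival and TTP are order-sensitive, unlike the AUC
  shuffled <- gd_curve(c(0, 0, 0, 1, 0.9, 0.6, 0.05, 0.1, 0.15),
                       baseline_frames = 3, injection_index = 3, frame_dt = 1)
  expect_false(isTRUE(all.equal(arrival_time(shuffled), arrival_time(noisy))))
})

test_that("time-to-peak takes the earliest maximal frame; effective TTP exact", {
  plateau <- gd_curve(c(0, 0, 0, 0.2, 1, 1, 1, 0.5), baseline_frames = 3,
                      injection_index = 3, frame_dt = 2)
  expect_equal(time_to_peak(plateau), 2)     # frames at t = 2, 4, 6 tie -> 2
  k <- gd_kinetics(make_gd_fixture())
  expect_identical(k$effective_ttp, k$ttp - k$arrival_time)
})

test_that("influx rate equals the least-squares slope over the window", {
  line <- gd_curve(c(0, 0, 0, 0, 0.2, 0.4, 0.6, 0.8, 1.0, 0.9),
                   baseline_frames = 3, injection_index = 3, frame_dt = 1)
  expect_equal(influx_rate(line), 0.2, tolerance = 1e-12)
  two <- gd_curve(c(0, 0, 0, 0, 0.2, 0.5, 1.0), baseline_frames = 3,
                  injection_index = 3, frame_dt = 2)
  # two-point slope between (t=2, 0.2) and (t=6, 1.0)
  expect_equal(influx_rate(two, arrival = 2, ttp = 6, method = "two_point"),
               0.2)
  expect_error(influx_rate(line, arrival = 5, ttp = 5), "precede")
})

test_that("decay fit recovers noiseless parameters and the C=0 log-linear oracle", {
  cv <- make_gd_fixture(A = 10, decay = 30, C = 2, n = 60)
  fit <- decay_fit(cv)
  expect_true(fit$converged)
  expect_equal(fit$A, 10, tolerance = 1e-6)
  expect_equal(fit$Decay, 30, tolerance = 1e-6)
  expect_equal(fit$C, 2, tolerance = 1e-6)
  expect_lt(fit$fit_rss, 1e-10)

  # C = 0: log-linear regression is a closed-form oracle
  cv0 <- make_gd_fixture(A = 5, decay = 25, C = 0, n = 60)
  fit0 <- decay_fit(cv0)
  post <- cv0[cv0$time >= time_to_peak(cv0), ]
  ll <- lm(log(value) ~ I(time - time_to_peak(cv0)), data = post)
  expect_equal(fit0$Decay, -1 / unname(coef(ll)[2]), tolerance = 1e-6)
  expect_equal(fit0$A, exp(unname(coef(ll)[1])), tolerance = 1e-6)

  expect_error(decay_fit(gd_curve(c(0, 0, 0, 1, 0.5), baseline_frames = 3)),
               "4 frames")
})

test_that("noisy decay fits agree with a brute-force grid oracle", {
  cfg <- sim_config(kinetics = list(A = 0.75, Decay = 40, C = 0.05))
  for (s in 1:10) {
    sim <- gen_gd_curve(cfg, subject = s, noise_sd = cfg$kinetics$peak_amp / 20)
    fit <- decay_fit(sim$curve)
    ttp <- time_to_peak(sim$curve)
    post <- sim$curve[sim$curve$time >= ttp, ]
    gr <- grid_decay_oracle(post$time - ttp, post$value,
                            d_grid = seq(20, 70, by = 2.5))
    expect_lte(abs(fit$Decay - gr$Decay), 2.5)
    expect_lte(fit$fit_rss, gr$rss + 1e-10)
  }
})

test_that("kinetic recovery on noisy curves meets the accuracy targets", {
  cfg <- sim_config()
  k <- cfg$kinetics
  res <- purrr::map_dfr(1:100, function(s) {
    sim <- gen_gd_curve(cfg, subject = s, noise_sd = k$peak_amp / 20)
    gd_kinetics(sim$curve)
  })
  expect_lt(median(abs(res$Decay - k$Decay) / k$Decay), 0.10)
  expect_lt(median(abs(res$ttp - k$ttp) / k$ttp), 0.05)
  # monotonicity: +50% true decay raises the estimate on shared noise seeds.
  # A 60-min decay constant needs the longer 50-volume acquisition to be
  # identifiable from the post-peak window.
  cfg_lo <- sim_config(kinetics = list(n_frames = 50L))
  cfg_hi <- sim_config(kinetics = list(n_frames = 50L, Decay = k$Decay * 1.5))
  up <- vapply(1:20, function(s) {
    lo <- decay_fit(gen_gd_curve(cfg_lo, subject = s,
                                 noise_sd = k$peak_amp / 20)$curve)$Decay
    hi <- decay_fit(gen_gd_curve(cfg_hi, subject = s,
                                 noise_sd = k$peak_amp / 20)$curve)$Decay
    hi > lo
  }, logical(1))
  expect_true(all(up))
})

test_that("tidy and glance expose the decay fit as tibbles", {
  fit <- decay_fit(make_gd_fixture())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("A", "Decay", "C"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, fit$n)
})

test_that("kinetic maps recover a uniform phantom and flag dead voxels", {
  cfg <- sim_config(kinetics = list(n_frames = 40))
  curve <- gen_gd_curve(cfg)$curve
  dims <- c(4, 4, 2)
  n_t <- nrow(curve)
  vol <- array(0, c(dims, n_t))
  raw <- 1000 * (1 + curve$value)
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (kk in 1:dims[3]) {
    vol[i, j, kk, ] <- raw
  }
  vol[1, 1, 1, ] <- 1000                     # no enhancement
  mask <- array(TRUE, dims)
  maps <- kinetic_maps(vol, mask, baseline_frames = 3, injection_index = 3,
                       frame_dt = cfg$kinetics$frame_dt)
  expect_equal(maps$qc[1, 1, 1], 0)
  expect_true(is.na(maps$decay[1, 1, 1]))
  ok <- maps$qc == 1
  expect_true(all(abs(maps$decay[ok] - cfg$kinetics$Decay) < 1e-4))
  expect_true(all(abs(maps$ttp[ok] - cfg$kinetics$ttp) < 1e-9))
  # two-region phantom: decay map is bimodal at the two true values
  cfg40 <- sim_config(kinetics = list(Decay = 20))
  c20 <- gen_gd_curve(cfg40)$curve
  for (i in 1:2) for (j in 1:4) for (kk in 1:2) {
    vol[i, j, kk, ] <- 1000 * (1 + c20$value)
  }
  maps2 <- kinetic_maps(vol, mask, baseline_frames = 3, injection_index = 3,
                        frame_dt = cfg$kinetics$frame_dt)
  vals <- round(maps2$decay[maps2$qc == 1], 2)
  expect_setequal(unique(vals), c(20, 40))
})
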