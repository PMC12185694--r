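test_that("auto_compare routes through the normality gate", {
  a <- c(1, 2, 3, 4, 5); b <- c(3, 4, 5, 6, 7)
  res <- auto_compare(a, b)
  expect_equal(res$test, "t")
  # closed-form pooled two-sample t
  sp2 <- (4 * var(a) + 4 * var(b)) / 8
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  p_oracle <- 2 * pt(-abs(t_oracle), 8)
  expect_equal(res$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(res$p, p_oracle, tolerance = 1e-10)

  same <- auto_compare(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1, tolerance = 1e-12)

  # heavy-tailed fixture fails Shapiro-Wilk -> rank-sum
  heavy <- c(0.1, 0.11, 0.12, 0.13, 0.14, 0.15, 0.16, 500, 900, 1500)
  expect_lt(shapiro.test(heavy)$p.value, 0.05)
  routed <- auto_compare(heavy, rnorm(10) + 1)
  expect_equal(routed$test, "rank-sum")

  one_tailed <- auto_compare(b, a, alternative = "greater")
  expect_equal(one_tailed$tails, 1L)
  expect_equal(one_tailed$p, pt(-abs(t_oracle), 8), tolerance = 1e-10)
  expect_error(auto_compare(c(1, 2), b), "n >= 3")
})

test_that("auto_compare holds its nominal type-I error", {
  withr::with_seed(2024, {
    rejections <- vapply(seq_len(2000), function(i) {
      auto_compare(rnorm(8), rnorm(8))$p < 0.05
    }, logical(1))
  })
  expect_gte(mean(rejections), 0.035)
  expect_lte(mean(rejections), 0.065)
})

test_that("correlate handles Pearson, Spearman and one-tailed directions", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(correlate(x, x * 2 + 1)$estimate, 1, tolerance = 1e-12)

  y <- exp(x)                                # monotone, nonlinear
  sp <- correlate(x, y, method = "spearman")
  expect_equal(sp$estimate, 1, tolerance = 1e-12)
  expect_lt(correlate(x, y)$estimate, 1)

  # Spearman rho equals Pearson on ranks (brute-force rank oracle)
  withr::with_seed(5, {
    u <- rnorm(12); v <- rnorm(12)
  })
  expect_equal(correlate(u, v, method = "spearman")$estimate,
               cor(rank(u), rank(v)), tolerance = 1e-12)

  two <- correlate(u, v)
  one <- correlate(u, v, alternative = if (two$estimate > 0) "greater" else "less")
  expect_equal(one$p, two$p / 2, tolerance = 1e-12)
  expect_error(correlate(u, rep(1, 12)), "Constant")
})

test_that("partial correlation controls covariates by residualization", {
  withr::with_seed(77, {
    z <- rnorm(200)
    x <- rnorm(200)
    y <- rnorm(200)
  })
  # covariate independent of both: partial ~ plain correlation
  plain <- correlate(x, y)$estimate
  part <- partial_correlation(x, y, z)$estimate
  expect_lt(abs(part - plain), 0.02)

  # y exactly equal to a covariate -> partial correlation 0
  expect_equal(partial_correlation(x, z, z)$estimate, 0, tolerance = 1e-10)

  # covariate identical to x -> degenerate
  expect_error(partial_correlation(x, y, x), "fully explained")
  expect_error(partial_correlation(x, y, cbind(z, z)), "Collinear")
})

test_that("Holm-Bonferroni matches the hand-executed step-down rule", {
  expect_equal(holm_bonferroni(0.03), 0.03)
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(rep(0.2, 4)), rep(min(4 * 0.2, 1), 4))
  expect_equal(holm_bonferroni(rep(0.4, 5)), rep(1, 5))

  withr::with_seed(10, {
    p <- runif(20)
  })
  adj <- holm_bonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("joint linear models report R2 and unique contributions", {
  withr::with_seed(42, {
    d <- tibble::tibble(p1 = rnorm(60), p2 = rnorm(60))
    d$out_exact <- 2 * d$p1 - 3 * d$p2
    d$out_noisy <- d$out_exact + rnorm(60)
  })
  tb <- suppressWarnings(joint_linear_models(d, "out_exact",
                                             list(joint = c("p1", "p2"))))
  expect_equal(tb$r_squared, 1, tolerance = 1e-10)

  # orthogonal predictors: joint R2 = sum of single R2
  d$q1 <- rep(c(-1, 1), 30)
  d$q2 <- rep(c(-1, -1, 1, 1), 15)      # orthogonal to q1 by construction
  expect_equal(sum(d$q1 * d$q2), 0)
  d$out2 <- d$q1 + 0.5 * d$q2 + rnorm(60, sd = 0.5)
  tb2 <- joint_linear_models(d, "out2",
                             list(m1 = "q1", m2 = "q2", joint = c("q1", "q2")))
  expect_equal(tb2$r_squared[3], tb2$r_squared[1] + tb2$r_squared[2],
               tolerance = 1e-10)
  # each predictor's unique contribution in the joint model
  terms <- tb2$terms[[3]]
  expect_equal(terms$delta_r2[terms$term == "q1"],
               tb2$r_squared[3] - tb2$r_squared[2], tolerance = 1e-12)

  d$dup <- d$p1
  expect_error(joint_linear_models(d, "out_noisy", list(bad = c("p1", "dup"))),
               "Rank-deficient")
})

test_that("voxelwise test finds an inserted effect and nothing under the null", {
  dims <- c(8, 8, 6)
  withr::with_seed(314, {
    null_a <- array(rnorm(prod(dims) * 8), c(dims, 8))
    null_b <- array(rnorm(prod(dims) * 8), c(dims, 8))
  })
  res0 <- voxelwise_test(null_a, null_b, extent = 10)
  expect_s3_class(res0, "nf_voxelstat")

  # identical groups -> t = 0 everywhere, no clusters
  res_same <- voxelwise_test(null_a, null_a, extent = 1)
  expect_equal(nrow(res_same$clusters), 0)

  # blob of Cohen's d = 3 in a 4x4x4 corner
  eff_a <- null_a
  eff_a[1:4, 1:4, 1:4, ] <- eff_a[1:4, 1:4, 1:4, ] + 3
  withr::with_seed(7, {
    res1 <- voxelwise_test(eff_a, null_b, n_perm = 100)
  })
  expect_gte(nrow(res1$clusters), 1)
  big <- which.max(res1$clusters$size)
  blob_labels <- res1$labels[1:4, 1:4, 1:4]
  expect_gte(mean(blob_labels == res1$clusters$cluster[big]), 0.9)

  # extent larger than any cluster -> empty result
  res2 <- voxelwise_test(eff_a, null_b, extent = prod(dims) + 1)
  expect_equal(nrow(res2$clusters), 0)
  expect_error(voxelwise_test(null_a, null_b[1:4, , , ]), "common grid|4D")
})

test_that("permutation cluster null keeps the false-positive rate near alpha", {
  dims <- c(6, 6, 4)
  n_sim <- 60
  withr::with_seed(2718, {
    hits <- vapply(seq_len(n_sim), function(i) {
      a <- array(rnorm(prod(dims) * 6), c(dims, 6))
      b <- array(rnorm(prod(dims) * 6), c(dims, 6))
      nrow(voxelwise_test(a, b, n_perm = 60)$clusters) > 0
    }, logical(1))
  })
  rate <- mean(hits)
  mc_se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lte(rate, 0.05 + 3 * mc_se)
})
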