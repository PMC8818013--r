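test_that("auxiliary indicator draws have the right support and mean", {
  expect_identical(draw_success_indicators(rep(0, 10)), rep(0L, 10))
  expect_identical(draw_success_indicators(rep(1, 10)), rep(1L, 10))
  expect_error(draw_success_indicators(c(0.2, 1.4)), "\\[0, 1\\]")
  m <- draw_success_indicators(rep(0.3, 1e5), seed = 51)
  expect_lt(abs(mean(m) - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))
  expect_identical(draw_success_indicators(rep(0.4, 5), seed = 1),
                   draw_success_indicators(rep(0.4, 5), seed = 1))
})

test_that("the z statistic is exact rational arithmetic", {
  expect_identical(z_statistic(2, 0, 1, 0, K = 2), 1)
  expect_identical(z_statistic(3, 3, 1, 1, K = 4), 0)
  expect_error(z_statistic(1, 0, 1, 0, K = 1), "K = 1")
  expect_error(z_statistic(3, 0, 1, 0, K = 2))
})

test_that("z has mean 0 at matched means and (L1-L2)^2 otherwise", {
  n <- 1e5; K <- 5
  set.seed(52)
  for (lams in list(c(0.4, 0.4), c(0.3, 0.6))) {
    Y1 <- rbinom(n, K, lams[1]); Y2 <- rbinom(n, K, lams[2])
    M1 <- rbinom(n, 1, Y1 / K); M2 <- rbinom(n, 1, Y2 / K)
    z <- z_statistic(Y1, Y2, M1, M2, K)
    expect_lt(abs(mean(z) - (lams[1] - lams[2])^2),
              3 * sd(z) / sqrt(n))
  }
})

test_that("overdispersion shifts the mean of z upward, increasing in eta", {
  n <- 4e4; K <- 5; lam <- 0.5
  set.seed(53)
  mz <- sapply(c(0.5, 2.0), function(eta) {
    phi <- phi_from_overdispersion(K, eta)
    Y1 <- rbinom(n, K, rbeta(n, phi * lam, phi * (1 - lam)))
    Y2 <- rbinom(n, K, rbeta(n, phi * lam, phi * (1 - lam)))
    M1 <- rbinom(n, 1, Y1 / K); M2 <- rbinom(n, 1, Y2 / K)
    mean(z_statistic(Y1, Y2, M1, M2, K))
  })
  expect_gt(mz[1], 0)
  expect_gt(mz[2], mz[1])
})

test_that("discrete matching: A-set selection and degenerate arithmetic", {
  # all covariates time-invariant: every pair is matched
  df <- data.frame(id = rep(1:12, each = 2), time = rep(1:2, 12),
                   Y = rep(c(0, 2, 1, 2), 6), x = rep(rnorm(12), each = 2))
  p <- panel_binomial(df, K = 2)
  tst <- overdispersion_test(p, variant = "discrete", seed = 54,
                             min_matched = 5)
  expect_s3_class(tst, "overdispersion_test")
  expect_identical(tst$n_effective, 12L)
  expect_true(tst$p.value >= 0 && tst$p.value <= 1)
  # hand-built matched z of (1, 0, -1) averages to t = 0
  res <- blogitfe:::disp_two_discrete(
    c(1, 0, -1),
    list(dX = matrix(0, 3, 1), t = rep(1L, 3)), min_matched = 2)
  expect_identical(res$tau, 0)
  expect_identical(res$statistic, 0)
  expect_equal(res$p.value, 1)
  # a singleton matched set has no variance
  expect_error(blogitfe:::disp_two_discrete(
    1, list(dX = matrix(0, 1, 1)), min_matched = 1), "variance")
  # warning below the minimum matched size
  expect_warning(overdispersion_test(p, variant = "discrete", seed = 54,
                                     min_matched = 50), "matched set")
})

test_that("kernel weights are a proper, permutation-equivariant average", {
  set.seed(55)
  delta <- rnorm(40)
  kw <- blogitfe:::kernel_weights(delta)
  expect_false(kw$degenerate)
  w <- kw$kw / sum(kw$kw)
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0))
  perm <- sample(40)
  expect_equal(blogitfe:::kernel_weights(delta[perm])$kw, kw$kw[perm])
  # all index differences zero: equal weights, tau = mean(z), no bias
  z <- rnorm(40)
  res <- blogitfe:::disp_two_kernel(z, rep(0, 40), rep(0, 40))
  expect_equal(res$tau, mean(z))
  expect_identical(res$bias, 0)
})

test_that("two-period kernel test runs end to end with an internal CML fit", {
  sim <- simulate_binomial_panel(dgp_config(N = 120, T = 2, K = 5),
                                 seed = 56)
  tst <- overdispersion_test(sim$panel, variant = "kernel", seed = 56)
  expect_identical(tst$variant, "kernel-two-period")
  expect_identical(tst$n_effective, 120L)
  expect_gte(tst$bias, 0)
  expect_gt(tst$variance, 0)
  # supplying beta_hat gives the same statistic as the internal fit
  bh <- coef(blogit(data = sim$panel, K = 5, method = "cml"))
  tst2 <- overdispersion_test(sim$panel, variant = "kernel",
                              beta_hat = bh, seed = 56)
  expect_equal(tst2$statistic, tst$statistic)
})

test_that("multi-period J: chi-square frame and the T = 2 identity", {
  sim <- simulate_binomial_panel(dgp_config(N = 200, T = 5, K = 3,
                                            x_law = "binary"), seed = 57)
  tst <- overdispersion_test(sim$panel, variant = "discrete", seed = 57)
  expect_identical(tst$variant, "discrete-multi")
  expect_identical(tst$df, 4L)
  expect_gte(tst$statistic, 0)
  expect_length(tst$n_effective, 4L)
  # with two waves the J statistic is exactly the squared t statistic
  sim2 <- simulate_binomial_panel(dgp_config(N = 150, T = 2, K = 3,
                                             x_law = "binary"), seed = 58)
  t2 <- overdispersion_test(sim2$panel, variant = "discrete", seed = 99)
  j2 <- overdispersion_test(sim2$panel, variant = "discrete", seed = 99,
                            multi = TRUE)
  expect_equal(j2$statistic, t2$statistic^2, tolerance = 1e-10)
  expect_equal(j2$p.value, t2$p.value, tolerance = 1e-9)
})

test_that("kernel multi-period J with full and diagonal S", {
  sim <- simulate_binomial_panel(dgp_config(N = 150, T = 4, K = 5),
                                 seed = 59)
  bh <- coef(blogit(data = sim$panel, K = 5, method = "cml"))
  full <- overdispersion_test(sim$panel, variant = "kernel",
                              beta_hat = bh, seed = 60)
  diag <- overdispersion_test(sim$panel, variant = "kernel",
                              beta_hat = bh, s_mode = "diagonal",
                              seed = 60)
  expect_identical(full$s_mode, "full")
  expect_identical(diag$s_mode, "diagonal")
  expect_gte(full$statistic, 0)
  expect_gte(diag$statistic, 0)
  expect_identical(full$df, 3L)
})

test_that("guards: K = 1, one wave, and m_draws averaging", {
  p1 <- panel_from_matrices(cbind(0:1, 1:0), cbind(0, 1), K = 1)
  expect_error(overdispersion_test(p1), "K >= 2")
  df <- data.frame(id = 1:5, time = 1, Y = rbinom(5, 2, 0.5), x = rnorm(5))
  expect_error(overdispersion_test(panel_binomial(df, K = 2)),
               "two waves")
  sim <- simulate_binomial_panel(dgp_config(N = 80, T = 2, K = 4,
                                            x_law = "binary"), seed = 61)
  tavg <- overdispersion_test(sim$panel, variant = "discrete", seed = 61,
                              m_draws = 20)
  expect_true(is.finite(tavg$statistic))
})
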