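test_that("non-informative units are dropped, with counts", {
  df <- data.frame(id = rep(1:3, each = 2), time = rep(1:2, 3),
                   Y = c(0, 0, 0, 2, 2, 2), x = rnorm(6))
  p <- panel_binomial(df, K = 2)
  out <- informative_subset(p)
  expect_setequal(out$dropped, c("1", "3"))   # totals 0 and K*T
  expect_equal(unique(out$panel$id), 2)

  allbad <- panel_binomial(data.frame(id = rep(1:2, each = 2),
                                      time = rep(1:2, 2),
                                      Y = c(0, 0, 2, 2), x = rnorm(4)),
                           K = 2)
  expect_error(informative_subset(allbad), "no informative units")
})

test_that("recursion matches the enumeration oracle on random instances", {
  set.seed(101)
  for (i in 1:100) {
    K <- sample(1:4, 1)
    T <- sample(2:4, 1)
    if (K * T > 12) next
    g <- random_group(K, T)
    expect_equal(group_cond_loglik(g$eta, g$Y, g$K),
                 brute_force_cond_loglik(g$eta, g$Y, g$K),
                 tolerance = 1e-10)
  }
})

test_that("hand-computable conditional probabilities are exact", {
  # beta = 0, K = 2, T = 2, Y = (1,1): 4 of the 6 weighted compositions
  expect_equal(group_cond_loglik(c(0, 0), c(1, 1), 2), log(4 / 6),
               tolerance = 1e-12)
  # K = 1 reduces to the binary conditional logit probability
  eta <- c(0.4, -0.9)
  expect_equal(brute_force_cond_loglik(eta, c(1, 0), 1),
               log(exp(eta[1]) / (exp(eta[1]) + exp(eta[2]))),
               tolerance = 1e-12)
  # boundary totals are a precondition violation
  expect_error(group_cond_loglik(c(0, 0), c(0, 0), 2), "non-informative")
  expect_error(brute_force_cond_loglik(c(0, 0), c(2, 2), 2),
               "non-informative")
  expect_error(brute_force_cond_loglik(rep(0, 40), rep(5, 40), 10,
                                       max_compositions = 100),
               "enumeration")
})

test_that("at beta = 0 the conditional law is multivariate hypergeometric", {
  # closed form: P(Y | S) = prod_t C(K, Y_t) / C(K*T, S) by Vandermonde
  set.seed(7)
  for (i in 1:20) {
    g <- random_group(sample(2:4, 1), sample(2:3, 1))
    lp <- group_cond_loglik(rep(0, length(g$Y)), g$Y, g$K)
    closed <- sum(lchoose(g$K, g$Y)) -
      lchoose(g$K * length(g$Y), sum(g$Y))
    expect_equal(lp, closed, tolerance = 1e-12)
  }
})

test_that("a unit-level constant in the index drops out (fixed effects)", {
  set.seed(8)
  for (i in 1:20) {
    g <- random_group(3, 3)
    expect_equal(group_cond_loglik(g$eta, g$Y, g$K),
                 group_cond_loglik(g$eta + rnorm(1, sd = 5), g$Y, g$K),
                 tolerance = 1e-10)
  }
})

test_that("analytic score agrees with finite differences", {
  set.seed(9)
  p <- random_small_panel(N = 25, T = 3, K = 3)
  p <- informative_subset(p)$panel
  for (b in c(-0.5, 0, 1.2)) {
    g <- cond_score(p, b)
    expect_length(g, 1L)
    eps <- 1e-6
    fd <- (cond_loglik(p, b + eps) - cond_loglik(p, b - eps)) / (2 * eps)
    expect_equal(g, fd, tolerance = 1e-5)
  }
  expect_error(cond_score(p, NaN), "finite")
  # antisymmetric design: equal counts across the two periods kill the
  # score at beta = 0, whatever the covariate gap
  ps <- panel_from_matrices(cbind(1, 1), cbind(0.7, -0.7), K = 2)
  expect_equal(cond_score(ps, 0), 0, tolerance = 1e-12)
})

test_that("expansion clones preserve sums and the ones-first layout", {
  df <- data.frame(id = 1, time = 1, Y = 3, x = 0.2)
  ex <- expand_to_bernoulli(panel_binomial(df, K = 5))
  expect_identical(ex$Y, c(1L, 1L, 1L, 0L, 0L))
  expect_identical(ex$K, 1L)
  set.seed(10)
  p <- random_small_panel(N = 12, T = 2, K = 4)
  ex <- expand_to_bernoulli(p)
  expect_equal(nrow(as.data.frame(ex)), 4 * length(p$Y))
  sums <- rowsum(ex$Y, paste(ex$id, sub("\\.\\d+$", "", ex$time)))
  orig <- rowsum(p$Y, paste(p$id, p$time))
  expect_equal(sums[order(rownames(sums)), 1],
               orig[order(rownames(orig)), 1])
  # K = 1 expansion is the identity up to period relabelling
  p1 <- random_small_panel(N = 5, T = 2, K = 1)
  expect_identical(expand_to_bernoulli(p1)$Y, p1$Y)
})

test_that("direct and expansion fits coincide; likelihoods differ by the constant", {
  set.seed(20)
  for (i in 1:10) {
    p <- random_small_panel(N = 25, T = sample(2:3, 1), K = sample(2:3, 1))
    fd <- blogit(data = p, K = p$K, method = "cml")
    fe <- blogit(data = p, K = p$K, method = "cml", via_expansion = TRUE)
    expect_equal(coef(fd), coef(fe), tolerance = 1e-6)
    flt <- informative_subset(p)$panel
    expect_equal(fd$loglik - fe$loglik, sum(lchoose(p$K, flt$Y)),
                 tolerance = 1e-8)
  }
})

test_that("permuting clone order within a cell leaves the fit unchanged", {
  set.seed(21)
  p <- random_small_panel(N = 20, T = 2, K = 3)
  ex <- expand_to_bernoulli(p)
  f1 <- blogit(data = ex, K = 1, method = "cml", gtol = 1e-12)
  # shuffle the 0/1 indicators within each original (unit, period) cell
  cell <- paste(ex$id, sub("\\.\\d+$", "", ex$time))
  ex2 <- ex
  for (cl in unique(cell)) {
    rows <- which(cell == cl)
    ex2$Y[rows] <- sample(ex$Y[rows])
  }
  f2 <- blogit(data = ex2, K = 1, method = "cml", gtol = 1e-12)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
})

test_that("K = 1 CML equals the two-period Chamberlain closed form", {
  set.seed(22)
  N <- 80
  x <- matrix(rnorm(2 * N), N, 2)
  alpha <- rnorm(N)
  Y <- matrix(rbinom(2 * N, 1, plogis(1.5 * x + alpha)), N, 2)
  p <- panel_from_matrices(Y, x, K = 1)
  fit <- blogit(data = p, K = 1, method = "cml")
  # movers-only closed form: P(0,1 -> 1,0 pattern) = plogis(b * (x1 - x2))
  movers <- rowSums(Y) == 1
  d1 <- Y[movers, 1]
  dx <- x[movers, 1] - x[movers, 2]
  nll <- function(b) -sum(d1 * plogis(b * dx, log.p = TRUE) +
                          (1 - d1) * plogis(-b * dx, log.p = TRUE))
  bhat <- optimize(nll, c(-10, 10))$minimum
  expect_equal(unname(coef(fit)), bhat, tolerance = 1e-5)
})

test_that("time-invariant and collinear covariates are rejected with names", {
  set.seed(23)
  N <- 10
  df <- data.frame(id = rep(1:N, each = 2), time = rep(1:2, N),
                   Y = rbinom(2 * N, 2, 0.5),
                   x = rnorm(2 * N), z = rep(rnorm(N), each = 2))
  p <- panel_binomial(df, K = 2, covariates = c("x", "z"))
  expect_error(blogit(data = p, K = 2, method = "cml"), "z")
  df$z <- 2 * df$x
  p2 <- panel_binomial(df, K = 2, covariates = c("x", "z"))
  expect_error(blogit(data = p2, K = 2, method = "cml"), "collinear")
})

test_that("the formula interface and methods behave like a standard fit", {
  set.seed(24)
  sim <- simulate_binomial_panel(dgp_config(N = 60, T = 3, K = 4), seed = 24)
  df <- as.data.frame(sim$panel)
  fit <- blogit(Y ~ x, data = df, id = "id", time = "time", K = 4)
  expect_s3_class(fit, "blogit")
  expect_named(coef(fit), "x")
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-6)
  expect_equal(dim(vcov(fit)), c(1, 1))
  expect_gt(vcov(fit)[1, 1], 0)
  s <- summary(fit)
  expect_true(all(c("Estimate", "Std. Error") %in%
                  colnames(s$coefficients)))
  ci <- confint(fit)
  expect_lt(ci[1, 1], coef(fit)[1])
  expect_gt(ci[1, 2], coef(fit)[1])
  expect_output(print(fit), "Blogit CML")
  expect_error(predict(fit, type = "response"), "fixed effects")
  expect_length(predict(fit, type = "link"), nobs(fit))
  expect_equal(nobs(fit), fit$n_units_used * 3)
})
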