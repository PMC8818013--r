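# Tests of the binomial (no-overdispersion) null for panel proportions.
# The building block compares, within a unit, the squared difference of
# counts across a pair of periods with the squared difference of auxiliary
# Bernoulli draws with the observed proportions as means: under the
# binomial null with matched expectations both have the same expectation,
# and their standardized difference z has mean zero.  No fixed-effect
# estimates are required.

#' Auxiliary Bernoulli success indicators
#'
#' One independent Bernoulli(y) draw per observed proportion y.  These
#' carry the "binomial benchmark" variance y(1-y) into the z statistic.
#'
#' @param y proportions in \[0, 1\].
#' @param seed optional integer seed for reproducibility.
#' @return 0/1 draws, same length as `y`.
#' @export
draw_success_indicators <- function(y, seed = NULL) {
  if (any(y < 0 | y > 1)) stop("'y' must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  rbinom(length(y), 1, y)
}

#' The pairwise dispersion statistic z
#'
#' \eqn{z = [(Y_1-Y_2)^2 - K(M_1-M_2)^2] / (K(K-1))}.  Under the binomial
#' null its expectation is \eqn{(\Lambda_1-\Lambda_2)^2}: zero whenever the
#' two periods share the same expected proportion.  Overdispersion inflates
#' the first square relative to the Bernoulli benchmark and pushes the mean
#' of z above zero.
#'
#' @param Y1,Y2 counts in 0..K for the two periods (vectorized).
#' @param M1,M2 auxiliary 0/1 draws (see [draw_success_indicators()]).
#' @param K trials per observation; must be >= 2 (the statistic is not
#'   defined for binary data).
#' @return numeric vector of z values.
#' @examples
#' z_statistic(2, 0, 1, 0, K = 2)  # (4 - 2)/2 = 1
#' @export
z_statistic <- function(Y1, Y2, M1, M2, K) {
  if (K < 2) stop("z is undefined for K = 1 (denominator K(K-1) = 0); ",
                  "the binomial and Bernoulli variances coincide")
  stopifnot(all(Y1 >= 0 & Y1 <= K), all(Y2 >= 0 & Y2 <= K),
            all(M1 %in% 0:1), all(M2 %in% 0:1))
  ((Y1 - Y2)^2 - K * (M1 - M2)^2) / (K * (K - 1))
}

# Consecutive-wave pairs of a panel.  Waves are the sorted unique period
# labels; a pair is formed when a unit observes two adjacent waves.
pair_table <- function(panel) {
  waves <- sort(unique(panel$time))
  wi <- match(panel$time, waves)
  ord <- order(panel$id, wi)
  id <- panel$id[ord]; w <- wi[ord]
  Y <- panel$Y[ord]; X <- panel$X[ord, , drop = FALSE]
  n <- length(Y)
  a <- seq_len(n - 1)
  ok <- id[a] == id[a + 1] & w[a + 1] == w[a] + 1
  a <- a[ok]
  list(unit = id[a], t = w[a],
       Y1 = Y[a], Y2 = Y[a + 1],
       y1 = Y[a] / panel$K, y2 = Y[a + 1] / panel$K,
       dX = X[a, , drop = FALSE] - X[a + 1, , drop = FALSE],
       row1 = a, row2 = a + 1, ord = ord, n_waves = length(waves))
}

#' Test the binomial dispersion assumption
#'
#' Tests H0: the counts are (conditionally on unit effects and covariates)
#' binomial, against over-/under-dispersion, using within-unit consecutive
#' period pairs.  Two variants:
#' \describe{
#'   \item{`"discrete"`}{restricts to the matched set A of pairs whose
#'     covariates are identical in both periods (so the expected
#'     proportions coincide and \eqn{E(z)=0} under H0); the statistic is
#'     the mean z over A, studentized by its sample standard deviation.}
#'   \item{`"kernel"`}{uses all pairs, weighting z by a Gaussian kernel in
#'     the estimated index difference \eqn{\hat\Delta_i =
#'     (x_{i1}-x_{i2})'\hat\beta} (bandwidth 0.9 n^{-1/5} after
#'     standardizing \eqn{\hat\Delta}), with plug-in bias and variance
#'     corrections from the local-constant regression asymptotics.}
#' }
#' With two waves, a two-sided normal z-test is returned.  With T > 2
#' waves, the T-1 per-pair moments are combined into a chi-square(T-1)
#' statistic \eqn{J = (\sqrt{n}\circ\bar g)'\hat S^{-1}(\sqrt{n}\circ\bar
#' g)}; for the discrete variant the default \eqn{\hat S} is diagonal
#' (pairwise covariances are poorly estimated on the small overlap sets
#' and distort the size), for the kernel variant the full matrix.
#'
#' The test is randomized through the auxiliary draws M; fix `seed` for
#' reproducibility.  `m_draws > 1` averages z over that many independent M
#' draws (an extension; the default single draw matches the construction
#' above).
#'
#' @param panel a [panel_binomial] with K >= 2 and at least two waves.
#' @param variant `"discrete"` (matched covariates) or `"kernel"`.
#' @param beta_hat slope estimates for the kernel variant; default: an
#'   internal Blogit CML fit (consistent under H0).
#' @param s_mode `"diagonal"` or `"full"` weighting matrix for the
#'   multi-period statistic; defaults as described above.
#' @param alpha nominal level (stored on the result; rejection =
#'   `p.value < alpha`).
#' @param seed optional seed for the M draws.
#' @param m_draws number of M draws averaged into z.
#' @param min_matched warn when the matched set is smaller than this.
#' @param multi force the multi-period statistic even with two waves
#'   (default: automatic).
#' @return an object of class `"overdispersion_test"`: statistic
#'   (standardized t, or J), raw `tau`, `bias`, `variance`, `df`,
#'   `p.value`, `n_effective`, `variant`, `s_mode`.
#' @export
overdispersion_test <- function(panel,
                                variant = c("discrete", "kernel"),
                                beta_hat = NULL, s_mode = NULL,
                                alpha = 0.05, seed = NULL, m_draws = 1L,
                                min_matched = 10L, multi = NULL) {
  stopifnot(inherits(panel, "panel_binomial"))
  variant <- match.arg(variant)
  K <- panel$K
  if (K < 2) stop("the dispersion test requires K >= 2")
  pt <- pair_table(panel)
  if (pt$n_waves < 2) stop("at least two waves are required")
  if (!length(pt$Y1)) stop("no consecutive-wave pairs in the panel")
  if (is.null(multi)) multi <- pt$n_waves > 2
  if (is.null(s_mode))
    s_mode <- if (variant == "discrete") "diagonal" else "full"
  s_mode <- match.arg(s_mode, c("diagonal", "full"))
  if (!is.null(seed)) set.seed(seed)
  # one M draw per observation (shared across the pairs that use it),
  # averaged over m_draws independent draws if requested
  y_all <- panel$Y[pt$ord] / K
  z <- 0
  for (r in seq_len(m_draws)) {
    M <- rbinom(length(y_all), 1, y_all)
    z <- z + z_statistic(pt$Y1, pt$Y2, M[pt$row1], M[pt$row2], K) / m_draws
  }
  if (variant == "kernel") {
    if (!ncol(pt$dX)) stop("kernel variant needs covariates")
    if (is.null(beta_hat)) {
      fit <- blogit(data = panel, K = K, method = "cml")
      beta_hat <- coef(fit)
    }
    delta <- drop(pt$dX %*% beta_hat)
    tau_fun <- (pt$y2 * (1 - pt$y2) * delta)^2
  }
  res <- if (!multi) {
    if (variant == "discrete")
      disp_two_discrete(z, pt, min_matched)
    else
      disp_two_kernel(z, delta, tau_fun)
  } else {
    if (variant == "discrete")
      disp_multi_discrete(z, pt, s_mode, min_matched)
    else
      disp_multi_kernel(z, delta, tau_fun, pt, s_mode)
  }
  res$variant <- paste0(variant, if (multi) "-multi" else "-two-period")
  res$alpha <- alpha
  res$reject <- res$p.value < alpha
  class(res) <- "overdispersion_test"
  res
}

disp_two_discrete <- function(z, pt, min_matched) {
  inA <- rowSums(abs(pt$dX) > 0) == 0
  nA <- sum(inA)
  if (nA <= 1) stop("matched set has ", nA, " pair(s); variance undefined")
  if (nA < min_matched)
    warning("matched set has only ", nA, " pairs; the normal ",
            "approximation may be poor")
  tau <- mean(z[inA])
  v <- var(z[inA])
  tstat <- tau / sqrt(v / nA)
  list(statistic = tstat, tau = tau, bias = 0, variance = v / nA,
       df = NA_integer_, p.value = 2 * pnorm(-abs(tstat)),
       n_effective = nA, s_mode = NA_character_)
}

kernel_weights <- function(delta) {
  n <- length(delta)
  s <- sd(delta)
  if (!is.finite(s) || s == 0) {
    # degenerate index differences: every pair equally informative
    list(kw = rep(dnorm(0), n), h = NA_real_, degenerate = TRUE)
  } else {
    h <- 0.9 * n^(-1 / 5)
    list(kw = dnorm(delta / s / h), h = h, degenerate = FALSE)
  }
}

disp_two_kernel <- function(z, delta, tau_fun) {
  n <- length(z)
  if (n < 2) stop("too few pairs for the kernel test")
  kwl <- kernel_weights(delta)
  kw <- kwl$kw
  w <- kw / sum(kw)
  tau <- sum(w * z)
  bias <- sum(w * tau_fun)
  sig2 <- sum(w * (z - tau_fun)^2)
  if (kwl$degenerate) {
    v <- sig2 / n
  } else {
    fhat <- sum(kw) / (n * kwl$h)
    v <- sig2 / fhat^2 * sum(kw^2) / (n^2 * kwl$h^2)
  }
  tstat <- (tau - bias) / sqrt(v)
  list(statistic = tstat, tau = tau, bias = bias, variance = v,
       df = NA_integer_, p.value = 2 * pnorm(-abs(tstat)),
       n_effective = n, s_mode = NA_character_)
}

# J = (sqrt(n) o gbar)' S^{-1} (sqrt(n) o gbar),  J ~ chi^2(T-1) under H0
j_statistic <- function(gbar, nvec, S, s_mode, df) {
  if (s_mode == "diagonal") S <- diag(diag(S), nrow = nrow(S))
  q <- sqrt(nvec) * gbar
  J <- tryCatch(drop(q %*% solve(S, q)), error = function(e) NULL)
  if (is.null(J) && s_mode == "full") {
    warning("singular moment covariance; falling back to diagonal S")
    s_mode <- "diagonal"
    J <- drop(q %*% solve(diag(diag(S), nrow = nrow(S)), q))
  }
  list(J = J, s_mode = s_mode, p = pchisq(J, df, lower.tail = FALSE))
}

disp_multi_discrete <- function(z, pt, s_mode, min_matched) {
  inA <- rowSums(abs(pt$dX) > 0) == 0
  tvals <- sort(unique(pt$t))
  df <- pt$n_waves - 1L
  gbar <- numeric(0); nvec <- integer(0)
  gl <- list()  # per moment: named vector of z by unit, matched pairs only
  for (t in tvals) {
    sel <- inA & pt$t == t
    if (sum(sel) <= 1)
      stop("matched set for wave pair (", t, ",", t + 1, ") has ",
           sum(sel), " pair(s)")
    gl[[as.character(t)]] <- setNames(z[sel], as.character(pt$unit[sel]))
    gbar <- c(gbar, mean(z[sel])); nvec <- c(nvec, sum(sel))
  }
  if (any(nvec < min_matched))
    warning("some matched sets have fewer than ", min_matched, " pairs")
  m <- length(gl)
  S <- matrix(0, m, m)
  for (i in seq_len(m)) S[i, i] <- var(gl[[i]])
  if (s_mode == "full") {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      common <- intersect(names(gl[[i]]), names(gl[[j]]))
      if (length(common) >= 2)
        S[i, j] <- S[j, i] <- cov(gl[[i]][common], gl[[j]][common])
    }
  }
  js <- j_statistic(gbar, nvec, S, s_mode, df)
  list(statistic = js$J, tau = gbar, bias = rep(0, m), variance = S,
       df = df, p.value = js$p, n_effective = nvec, s_mode = js$s_mode)
}

disp_multi_kernel <- function(z, delta, tau_fun, pt, s_mode) {
  tvals <- sort(unique(pt$t))
  df <- pt$n_waves - 1L
  m <- length(tvals)
  gbar <- numeric(m); nvec <- integer(m)
  gl <- vector("list", m)
  for (k in seq_len(m)) {
    sel <- pt$t == tvals[k]
    n <- sum(sel)
    if (n <= 1) stop("too few pairs for wave pair (", tvals[k], ",",
                     tvals[k] + 1, ")")
    kwl <- kernel_weights(delta[sel])
    g <- kwl$kw * (z[sel] - tau_fun[sel]) / mean(kwl$kw)
    gl[[k]] <- setNames(g, as.character(pt$unit[sel]))
    gbar[k] <- mean(g); nvec[k] <- n
  }
  S <- matrix(0, m, m)
  for (i in seq_len(m)) S[i, i] <- var(gl[[i]])
  if (s_mode == "full") {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      common <- intersect(names(gl[[i]]), names(gl[[j]]))
      if (length(common) >= 2)
        S[i, j] <- S[j, i] <- cov(gl[[i]][common], gl[[j]][common])
    }
  }
  js <- j_statistic(gbar, nvec, S, s_mode, df)
  list(statistic = js$J, tau = gbar, bias = rep(0, m), variance = S,
       df = df, p.value = js$p, n_effective = nvec, s_mode = js$s_mode)
}

#' @export
print.overdispersion_test <- function(x, ...) {
  cat("Binomial dispersion test (", x$variant, ")\n", sep = "")
  if (is.na(x$df)) {
    cat("t =", format(x$statistic), "  two-sided normal p =",
        format.pval(x$p.value), "\n")
    cat("tau =", format(x$tau), " bias =", format(x$bias),
        " |A| / n =", x$n_effective, "\n")
  } else {
    cat("J =", format(x$statistic), " df =", x$df, " (S: ", x$s_mode,
        ")  p =", format.pval(x$p.value), "\n")
    cat("moment sample sizes:", paste(x$n_effective, collapse = ", "),
        "\n")
  }
  cat("H0: binomial dispersion; reject at", x$alpha, ":",
      x$reject, "\n")
  invisible(x)
}
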