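# Data-generating processes: binomial panels and beta-binomial
# (overdispersed) panels with individual effects correlated with the
# covariate mean.

#' Beta precision implied by a variance-inflation degree
#'
#' The beta-binomial variance is \eqn{K\Lambda(1-\Lambda)(1 + (K-1)/(\phi+1))},
#' so a target inflation factor \eqn{1+\eta} pins down the beta precision
#' \eqn{\phi = (K-1)/\eta - 1}.  E.g. 10\% overdispersion at K = 2 gives
#' \eqn{\phi = 9}.  Feasibility requires \eqn{\eta < K - 1} (\eqn{\phi > 0}):
#' at K = 2 no inflation beyond 100\% can be generated.
#'
#' @param K number of trials (>= 2).
#' @param eta overdispersion degree (variance inflation minus 1), in
#'   (0, K-1).
#' @return the beta precision parameter \eqn{\phi}.
#' @examples
#' phi_from_overdispersion(2, 0.1)  # 9
#' @export
phi_from_overdispersion <- function(K, eta) {
  if (K < 2) stop("overdispersion requires K >= 2")
  if (eta <= 0) stop("'eta' must be positive (use the binomial DGP for 0)")
  if (eta >= K - 1)
    stop("infeasible: eta = ", eta, " requires phi = (K-1)/eta - 1 <= 0; ",
         "the beta-binomial cannot inflate the variance by more than a ",
         "factor K = ", K, " (this is why high-dispersion cells do not ",
         "exist at small K)")
  (K - 1) / eta - 1
}

#' Configuration of a simulated panel
#'
#' Collects the study design: N units, T periods, K trials, the logistic
#' index \eqn{\beta_0 + \beta_1 x_{it} + \alpha_i} with
#' \eqn{\alpha_i = \sqrt{T}\bar x_i + \varepsilon_i},
#' \eqn{\varepsilon_i \sim N(0,1)} (so \eqn{cor(\alpha_i, \bar x_i) = 0.5}),
#' the covariate law, and the overdispersion degree.
#'
#' @param N,T,K panel dimensions and trials per observation.
#' @param beta0,beta1 intercept and slope of the index (defaults 0 and 2).
#' @param x_law `"uniform"` (U\[-1,1\], continuous) or `"binary"`
#'   (Bernoulli(1/2) on \{0,1\}).
#' @param eta overdispersion degree; 0 selects the binomial branch,
#'   positive values the beta-binomial branch with
#'   [phi_from_overdispersion()].
#' @param beta_bounds lower bounds (b_u, b_v) on the two beta parameters
#'   below which an observation's beta draw is refused and the observation
#'   dropped (defaults 0.05 and 0.15, replicating common generator
#'   limits); only used by the beta-binomial branch.
#' @return a list of class `"dgp_config"`.
#' @export
dgp_config <- function(N, T, K, beta0 = 0, beta1 = 2,
                       x_law = c("uniform", "binary"), eta = 0,
                       beta_bounds = c(0.05, 0.15)) {
  x_law <- match.arg(x_law)
  stopifnot(N >= 1, T >= 1, K >= 1, eta >= 0, length(beta_bounds) == 2)
  if (eta > 0) phi_from_overdispersion(K, eta)  # validate feasibility
  structure(list(N = as.integer(N), T = as.integer(T), K = as.integer(K),
                 beta0 = beta0, beta1 = beta1, x_law = x_law, eta = eta,
                 beta_bounds = beta_bounds), class = "dgp_config")
}

draw_x <- function(config) {
  n <- config$N * config$T
  if (config$x_law == "uniform") matrix(runif(n, -1, 1), config$N, config$T)
  else matrix(rbinom(n, 1, 0.5), config$N, config$T)
}

build_panel <- function(config, x, Y, keep = NULL) {
  N <- config$N; T <- config$T
  df <- data.frame(id = rep(seq_len(N), times = T),
                   time = rep(seq_len(T), each = N),
                   Y = as.vector(Y), x = as.vector(x))
  if (!is.null(keep)) df <- df[as.vector(keep), , drop = FALSE]
  panel_binomial(df, K = config$K, covariates = "x")
}

#' Simulate a binomial panel with correlated fixed effects
#'
#' Draw order under one seed: covariates x, then the effect noise
#' \eqn{\varepsilon}, then the outcomes.  \eqn{\alpha_i = \sqrt{T}\bar x_i +
#' \varepsilon_i}, \eqn{p_{it} = \Lambda(\beta_0+\beta_1 x_{it}+\alpha_i)},
#' \eqn{Y_{it} \sim binomial(K, p_{it})}.
#'
#' @param config a [dgp_config()] (its `eta` must be 0).
#' @param seed integer seed; every draw is governed by it.
#' @return list with `panel` ([panel_binomial]), and the ground truth
#'   `alpha`, `p` (N x T), `x` (N x T), `n_dropped` (always 0 here).
#' @export
simulate_binomial_panel <- function(config, seed) {
  stopifnot(inherits(config, "dgp_config"), config$eta == 0)
  set.seed(seed)
  x <- draw_x(config)
  eps <- rnorm(config$N)
  alpha <- sqrt(config$T) * rowMeans(x) + eps
  p <- plogis(config$beta0 + config$beta1 * x + alpha)
  Y <- matrix(rbinom(length(p), config$K, p), config$N, config$T)
  list(panel = build_panel(config, x, Y), alpha = alpha, p = p, x = x,
       n_dropped = 0L)
}

#' Simulate a beta-binomial (overdispersed) panel
#'
#' As [simulate_binomial_panel()], but the success probability is itself
#' random: \eqn{\tilde p_{it} \sim beta(\phi\Lambda_{it},
#' \phi(1-\Lambda_{it}))} with \eqn{\phi} from
#' [phi_from_overdispersion()], inflating the conditional variance by
#' \eqn{1+\eta} while preserving the mean \eqn{K\Lambda_{it}}.
#' Observations whose beta parameters fall below the configured lower
#' bounds are dropped before drawing (mimicking common beta generators);
#' the count is reported, as dropping only shrinks the effective sample.
#' Draw order: x, \eqn{\varepsilon}, \eqn{\tilde p} (kept observations),
#' Y.
#'
#' @inheritParams simulate_binomial_panel
#' @return as [simulate_binomial_panel()], with `p_tilde` in place of `p`
#'   and `n_dropped` the number of discarded observations.
#' @export
simulate_betabinomial_panel <- function(config, seed) {
  stopifnot(inherits(config, "dgp_config"), config$eta > 0)
  phi <- phi_from_overdispersion(config$K, config$eta)
  set.seed(seed)
  x <- draw_x(config)
  eps <- rnorm(config$N)
  alpha <- sqrt(config$T) * rowMeans(x) + eps
  lam <- plogis(config$beta0 + config$beta1 * x + alpha)
  u <- phi * lam; v <- phi * (1 - lam)
  keep <- u >= config$beta_bounds[1] & v >= config$beta_bounds[2]
  if (!any(keep)) stop("all observations violate the beta parameter bounds")
  ptilde <- matrix(NA_real_, config$N, config$T)
  ptilde[keep] <- rbeta(sum(keep), u[keep], v[keep])
  Y <- matrix(NA_integer_, config$N, config$T)
  Y[keep] <- rbinom(sum(keep), config$K, ptilde[keep])
  list(panel = build_panel(config, x, Y, keep), alpha = alpha,
       p_tilde = ptilde, x = x, n_dropped = sum(!keep))
}

#' Simulate from a configuration (dispatch on dispersion)
#'
#' @inheritParams simulate_binomial_panel
#' @export
simulate_panel <- function(config, seed) {
  if (config$eta == 0) simulate_binomial_panel(config, seed)
  else simulate_betabinomial_panel(config, seed)
}
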