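# Small panels built in code for the unit tests.

# balanced panel from an N x T count matrix and covariate matrix/list
panel_from_matrices <- function(Y, x, K) {
  N <- nrow(Y); T <- ncol(Y)
  panel_binomial(
    data.frame(id = rep(seq_len(N), times = T),
               time = rep(seq_len(T), each = N),
               Y = as.vector(Y), x = as.vector(x)),
    K = K, covariates = "x")
}

# a random small informative instance for oracle cross-checks
random_group <- function(K, T) {
  eta <- rnorm(T)
  repeat {
    Y <- sample(0:K, T, replace = TRUE)
    if (sum(Y) > 0 && sum(Y) < K * T) break
  }
  list(eta = eta, Y = Y, K = K)
}

# random small panel guaranteed to contain informative units
random_small_panel <- function(N = 30, T = 3, K = 3, beta = 1) {
  x <- matrix(runif(N * T, -1, 1), N, T)
  alpha <- rnorm(N)
  p <- plogis(beta * x + alpha)
  Y <- matrix(rbinom(N * T, K, p), N, T)
  panel_from_matrices(Y, x, K)
}
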