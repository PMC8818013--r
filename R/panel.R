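#' Logistic conditional expectation function
#'
#' The inverse-logit map \eqn{\Lambda(\eta) = \exp(\eta)/(1+\exp(\eta))},
#' the conditional expectation of the proportion given the linear index
#' \eqn{\eta = x'\beta + \alpha}.  Computed overflow-safely.
#'
#' @param eta numeric vector of finite linear indices.
#' @return probabilities in (0, 1).
#' @examples
#' logistic_cef(0)        # 0.5
#' logistic_cef(c(-2, 2)) # symmetric around 0.5
#' @export
logistic_cef <- function(eta) {
  if (!is.numeric(eta) || any(!is.finite(eta)))
    stop("'eta' must be finite numeric")
  plogis(eta)
}

#' Construct a binomial proportion panel
#'
#' Validates and stores a long-format panel of grouped binomial outcomes:
#' for each unit i and period t a count \eqn{Y_{it} \in \{0,...,K\}} of
#' successes out of a known, constant number of trials K, plus covariates.
#' The response column may instead hold proportions \eqn{y = Y/K}; these are
#' converted by rounding K*y, and values off the grid \{0, 1/K, ..., 1\}
#' are rejected.
#'
#' @param data a data.frame in long format.
#' @param K positive integer, number of trials per observation.
#' @param id,time,response names of the unit identifier, period and outcome
#'   columns.
#' @param covariates character vector of covariate column names; default all
#'   remaining numeric columns.
#' @param proportion logical; is the response a proportion rather than a
#'   count?  Default `NULL` auto-detects (non-integer values present).
#' @return an object of class `"panel_binomial"`: a list with components
#'   `id`, `time`, `Y`, `X` (covariate matrix, no intercept), `K`.
#' @details Rows are sorted by (id, time).  Duplicated (id, time) pairs,
#'   missing values, and counts outside \[0, K\] are errors.  Unbalanced
#'   panels are allowed; units contribute whatever periods they have.
#' @export
panel_binomial <- function(data, K, id = "id", time = "time",
                           response = "Y", covariates = NULL,
                           proportion = NULL) {
  stopifnot(is.data.frame(data))
  if (length(K) != 1L || !is.finite(K) || K < 1 || K != round(K))
    stop("'K' must be a single positive integer")
  K <- as.integer(K)
  for (col in c(id, time, response))
    if (!col %in% names(data)) stop("column '", col, "' not found")
  if (is.null(covariates))
    covariates <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                          c(id, time, response, "K"))
  if (length(covariates))
    for (col in covariates)
      if (!col %in% names(data)) stop("covariate '", col, "' not found")
  r <- data[[response]]
  if (anyNA(data[c(id, time, response, covariates)]))
    stop("missing values are not allowed")
  if (!is.numeric(r)) stop("response must be numeric")
  if (is.null(proportion)) proportion <- any(r != round(r))
  if (proportion) {
    if (any(r < 0 | r > 1)) stop("proportions must lie in [0, 1]")
    Yr <- K * r
    if (any(abs(Yr - round(Yr)) > 1e-6))
      stop("proportions are off the grid {0, 1/K, ..., 1} for K = ", K)
    Y <- as.integer(round(Yr))
  } else {
    Y <- as.integer(r)
  }
  if (any(Y < 0 | Y > K)) stop("counts must lie in 0..K")
  key <- paste(data[[id]], data[[time]], sep = "\r")
  if (anyDuplicated(key)) stop("duplicated (id, time) pairs")
  ord <- order(data[[id]], data[[time]])
  X <- if (length(covariates))
    as.matrix(data[ord, covariates, drop = FALSE])
  else
    matrix(numeric(0), nrow = nrow(data), ncol = 0)
  storage.mode(X) <- "double"
  structure(list(id = data[[id]][ord], time = data[[time]][ord],
                 Y = Y[ord], X = X, K = K),
            class = "panel_binomial")
}

#' @export
print.panel_binomial <- function(x, ...) {
  cat("Binomial proportion panel: ", length(unique(x$id)), " units, ",
      length(x$Y), " observations, K = ", x$K, "\n", sep = "")
  cat("Covariates:", if (ncol(x$X)) paste(colnames(x$X), collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' @export
as.data.frame.panel_binomial <- function(x, ...) {
  data.frame(id = x$id, time = x$time, Y = x$Y, x$X,
             check.names = FALSE)
}

#' Read / write a panel from delimited text
#'
#' `read_panel()` reads a long-format CSV with a header (columns `id`,
#' `time`, `Y` or `y`, covariates) into a [panel_binomial] object;
#' `write_panel()` writes one back.  If `K` is missing, a constant column
#' named `K` in the file is used.
#'
#' @param file path to a CSV file.
#' @param K number of trials; may be omitted when the file has a constant
#'   `K` column.
#' @param ... passed on to [panel_binomial()].
#' @return `read_panel()` a `"panel_binomial"`; `write_panel()` the file
#'   path, invisibly.
#' @export
read_panel <- function(file, K = NULL, ...) {
  df <- read.csv(file, header = TRUE)
  if (is.null(K)) {
    if (!"K" %in% names(df))
      stop("'K' not supplied and no 'K' column in file")
    Kv <- unique(df$K)
    if (length(Kv) != 1L) stop("'K' column must be constant")
    K <- Kv
  }
  args <- list(data = df, K = K, ...)
  if (is.null(args$response))
    args$response <- if ("Y" %in% names(df)) "Y" else "y"
  do.call(panel_binomial, args)
}

#' @param panel a `"panel_binomial"` object.
#' @rdname read_panel
#' @export
write_panel <- function(panel, file) {
  write.csv(as.data.frame(panel), file, row.names = FALSE)
  invisible(file)
}

#' Binomial log-likelihood of a panel
#'
#' \eqn{\sum_{it} Y_{it}\log\Lambda_{it} + (K-Y_{it})\log(1-\Lambda_{it})},
#' with \eqn{\Lambda_{it} = \Lambda(x_{it}'\beta + \alpha_i)}.  The binomial
#' coefficient constant \eqn{\sum \log {K \choose Y_{it}}} is excluded by
#' default, which makes the value identical to the Bernoulli log-likelihood
#' of the K-fold expanded dataset; set `include_constant = TRUE` to report
#' the full binomial log-likelihood.
#'
#' @param panel a [panel_binomial] object.
#' @param beta coefficient vector (length `ncol(panel$X)`).
#' @param alpha unit intercepts: a single number recycled to all units, or a
#'   vector named by unit id.  Default 0 (intercept folded into `beta` via
#'   an intercept covariate, if any).
#' @param include_constant add the log binomial coefficients?
#' @return the log-likelihood; `-Inf` when a fitted probability of exactly
#'   0 or 1 conflicts with the observed count.
#' @export
binomial_loglik <- function(panel, beta, alpha = 0,
                            include_constant = FALSE) {
  stopifnot(inherits(panel, "panel_binomial"))
  if (length(beta) != ncol(panel$X))
    stop("length(beta) must equal the number of covariates")
  a <- if (length(alpha) == 1L) rep(alpha, length(panel$Y))
       else {
         if (is.null(names(alpha))) stop("'alpha' must be named by unit id")
         miss <- setdiff(unique(as.character(panel$id)), names(alpha))
         if (length(miss)) stop("'alpha' missing units: ",
                                paste(miss, collapse = ", "))
         alpha[as.character(panel$id)]
       }
  eta <- drop(panel$X %*% beta) + a
  lp <- plogis(eta, log.p = TRUE)      # log Lambda
  lq <- plogis(-eta, log.p = TRUE)     # log(1 - Lambda)
  Y <- panel$Y; K <- panel$K
  ll <- sum(ifelse(Y > 0, Y * lp, 0) + ifelse(Y < K, (K - Y) * lq, 0))
  if (include_constant) ll <- ll + sum(lchoose(K, Y))
  ll
}

#' Binomial benchmark standard deviation of a proportion
#'
#' Under the binomial model a proportion with mean \eqn{\Lambda} observed
#' as K trials has standard deviation \eqn{\sqrt{\Lambda(1-\Lambda)/K}}.
#' Comparing this benchmark with the observed marginal standard deviation
#' is a quick first look at overdispersion (the formal test is
#' [overdispersion_test()]).
#'
#' @param mean_level mean proportion in \[0, 1\].
#' @param K number of trials.
#' @return the implied standard deviation of y.
#' @examples
#' binomial_proportion_sd(0.56, 10)  # 0.157
#' @export
binomial_proportion_sd <- function(mean_level, K) {
  if (any(mean_level < 0 | mean_level > 1))
    stop("'mean_level' must lie in [0, 1]")
  sqrt(mean_level * (1 - mean_level) / K)
}

#' Semi-elasticity of the expected proportion
#'
#' For the logistic conditional expectation the proportional response of
#' \eqn{E(y)} to a covariate is \eqn{\partial \log E(y)/\partial x =
#' \beta(1-\Lambda)}.  Averaged over the sample, \eqn{\Lambda} is well
#' estimated by the sample mean of the outcome, so a coefficient is turned
#' into a population-average semi-elasticity by multiplying with
#' \eqn{1-\bar y} — a quantity available even though conditional ML never
#' estimates the fixed effects.
#'
#' @param object a coefficient vector, or a fitted [blogit] model.
#' @param mean_level the mean outcome level \eqn{\bar\Lambda \in [0,1]}; for
#'   a fitted model, defaults to the sample mean of y.
#' @param ... unused.
#' @return semi-elasticities, same shape as the coefficients.
#' @examples
#' semi_elasticity(-2.097, 0.55)  # about -0.94: a 90% lower expected level
#' @export
semi_elasticity <- function(object, mean_level, ...) {
  UseMethod("semi_elasticity")
}

#' @rdname semi_elasticity
#' @export
semi_elasticity.default <- function(object, mean_level, ...) {
  if (!is.numeric(mean_level) || any(mean_level < 0 | mean_level > 1))
    stop("'mean_level' must lie in [0, 1]")
  object * (1 - mean_level)
}

#' @rdname semi_elasticity
#' @export
semi_elasticity.blogit <- function(object, mean_level = NULL, ...) {
  if (is.null(mean_level)) mean_level <- object$ybar
  semi_elasticity.default(coef(object), mean_level)
}
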