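#' Fit a binomial logit model for panel proportions
#'
#' Fits the binomial logit model \eqn{E(y_{it}|x_{it},\alpha_i) =
#' \Lambda(x_{it}'\beta + \alpha_i)} for counts \eqn{Y_{it} = K y_{it}} by
#' one of three estimators:
#' \describe{
#'   \item{`"cml"`}{conditional maximum likelihood ("Blogit CML"): each
#'     unit's likelihood is conditioned on its total \eqn{\sum_t Y_{it}},
#'     eliminating the fixed effects \eqn{\alpha_i}.  Consistent for fixed
#'     T; no intercept or time-invariant covariates are identified.}
#'   \item{`"dv"`}{joint ML with a dummy intercept per unit ("Blogit DV"),
#'     fitted by a concentrated (profile) likelihood; subject to the
#'     incidental-parameters bias, which shrinks as T and K grow.}
#'   \item{`"pooled"`}{pooled binomial logit with a common intercept,
#'     ignoring the individual effects; inconsistent when effects are
#'     correlated with covariates.}
#' }
#' Units with all outcomes at the same boundary (total 0 or K*T) are
#' non-informative / perfectly predicted and dropped for `"cml"` and
#' `"dv"`.  Standard errors are cluster-robust at the unit level (sandwich
#' over per-unit scores, with a G/(G-1) small-sample factor).
#'
#' @param formula model formula, e.g. `Y ~ x1 + x2`.  The response is a
#'   success count in 0..K, or a proportion when `proportion = TRUE`.  The
#'   intercept is dropped automatically for `"cml"` and `"dv"`.
#' @param data a data.frame, or a [panel_binomial] object (then `formula`,
#'   `id`, `time`, `K` are taken from it and `formula` may be omitted).
#' @param id,time names of the unit and period columns in `data`.
#' @param K number of trials per observation.
#' @param method estimator, see above.
#' @param proportion is the response a proportion y rather than a count?
#'   `NULL` auto-detects.
#' @param via_expansion for `"cml"` only: fit through the K-fold Bernoulli
#'   data expansion (see [expand_to_bernoulli()]) instead of the direct
#'   grouped recursion.  Same estimate; mainly a cross-check.
#' @param gtol gradient-norm convergence tolerance.
#' @param maxit maximum quasi-Newton iterations.
#' @return an object of class `"blogit"` with components `coefficients`,
#'   `vcov`, `loglik`, `method`, `K`, `n_units_used`, `dropped`,
#'   `converged`, `iterations`, `gradient_norm`, `alpha` (DV only), `ybar`
#'   (sample mean of y on the estimation sample), `nobs`.
#' @examples
#' sim <- simulate_binomial_panel(dgp_config(N = 60, T = 4, K = 5), seed = 1)
#' fit <- blogit(Y ~ x, data = as.data.frame(sim$panel),
#'               id = "id", time = "time", K = 5)
#' summary(fit)
#' semi_elasticity(fit)
#' @export
blogit <- function(formula, data, id = "id", time = "time", K,
                   method = c("cml", "dv", "pooled"), proportion = NULL,
                   via_expansion = FALSE, gtol = 1e-8, maxit = 200L) {
  method <- match.arg(method)
  cl <- match.call()
  if (inherits(data, "panel_binomial")) {
    panel <- data
  } else {
    mf <- model.frame(formula, data)
    y <- model.response(mf)
    X <- model.matrix(attr(mf, "terms"), mf)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
    df <- data.frame(.id = data[[id]], .time = data[[time]], .Y = y,
                     check.names = FALSE)
    df <- cbind(df, as.data.frame(X, optional = TRUE))
    panel <- panel_binomial(df, K = K, id = ".id", time = ".time",
                            response = ".Y", covariates = colnames(X),
                            proportion = proportion)
  }
  core <- switch(method,
    cml = if (via_expansion) fit_cml_expansion(panel, gtol = gtol,
                                               maxit = maxit)
          else fit_cml_core(panel, gtol = gtol, maxit = maxit),
    dv = fit_dv_core(panel, gtol = gtol, maxit = maxit),
    pooled = fit_pooled_core(panel))
  est_panel <- core$panel
  structure(list(
    coefficients = core$beta, vcov = core$vcov, loglik = core$loglik,
    method = method, K = panel$K,
    n_units_used = core$n_units_used,
    dropped = core$dropped,
    n_units_dropped = length(core$dropped),
    converged = core$converged, iterations = core$iterations,
    gradient_norm = core$gradient_norm,
    alpha = core$alpha,
    ybar = mean(est_panel$Y) / est_panel$K,
    nobs = length(est_panel$Y),
    panel = est_panel, call = cl), class = "blogit")
}

#' @export
print.blogit <- function(x, ...) {
  lab <- c(cml = "Blogit CML (conditional maximum likelihood)",
           dv = "Blogit DV (individual dummy variables)",
           pooled = "Pooled binomial logit")[x$method]
  cat(lab, "\n", sep = "")
  cat("K =", x$K, "  units used:", x$n_units_used,
      "  dropped (boundary outcomes):", x$n_units_dropped, "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
coef.blogit <- function(object, ...) object$coefficients

#' @export
vcov.blogit <- function(object, ...) object$vcov

#' @export
logLik.blogit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$nobs, class = "logLik")
}

#' @export
nobs.blogit <- function(object, ...) object$nobs

#' @export
summary.blogit <- function(object, ...) {
  est <- object$coefficients
  se <- sqrt(diag(object$vcov))
  zval <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = zval,
               `Pr(>|z|)` = 2 * pnorm(-abs(zval)))
  structure(list(coefficients = tab, fit = object,
                 semi_elasticity = est * (1 - object$ybar)),
            class = "summary.blogit")
}

#' @export
print.summary.blogit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nCluster-robust (unit-level) standard errors.\n")
  cat("Conditional/loglik:", format(x$fit$loglik), "  converged:",
      x$fit$converged, "\n")
  cat("Semi-elasticities at mean outcome", round(x$fit$ybar, 3), ":\n")
  print(round(x$semi_elasticity, 4))
  invisible(x)
}

#' @export
confint.blogit <- function(object, parm, level = 0.95, ...) {
  est <- coef(object); se <- sqrt(diag(vcov(object)))
  if (missing(parm)) parm <- names(est)
  z <- qnorm(1 - (1 - level) / 2)
  out <- cbind(est[parm] - z * se[parm], est[parm] + z * se[parm])
  colnames(out) <- paste(format(100 * c((1 - level) / 2,
                                        1 - (1 - level) / 2)), "%")
  out
}

#' Predictions from a fitted binomial panel logit
#'
#' For `"dv"` and `"pooled"` fits, fitted expected proportions
#' \eqn{\hat\Lambda_{it}} (type `"response"`) or the linear predictor.  For
#' `"cml"` fits the individual effects are never estimated, so only the
#' covariate part of the index `x'beta` (type `"link"`) is available.
#'
#' @param object a `"blogit"` fit.
#' @param newdata optional data.frame with the model covariates; default:
#'   the estimation sample.
#' @param type `"link"` or `"response"`.
#' @param ... unused.
#' @export
predict.blogit <- function(object, newdata = NULL,
                           type = c("link", "response"), ...) {
  type <- match.arg(type)
  nm <- setdiff(names(coef(object)), "(Intercept)")
  X <- if (is.null(newdata)) object$panel$X[, nm, drop = FALSE]
       else as.matrix(newdata[, nm, drop = FALSE])
  eta <- drop(X %*% coef(object)[nm])
  if (object$method == "pooled")
    eta <- eta + coef(object)["(Intercept)"]
  if (object$method == "dv") {
    if (!is.null(newdata))
      stop("DV predictions require the estimation sample (unit effects)")
    eta <- eta + object$alpha[as.character(object$panel$id)]
  }
  if (type == "link") return(eta)
  if (object$method == "cml")
    stop("'response' predictions need the unestimated fixed effects; ",
         "use type = 'link' or the semi-elasticity")
  plogis(eta)
}

#' @export
residuals.blogit <- function(object, ...) {
  if (object$method == "cml")
    stop("response residuals need the unestimated fixed effects")
  object$panel$Y / object$K - predict(object, type = "response")
}

#' @export
fitted.blogit <- function(object, ...) predict(object, type = "response")
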