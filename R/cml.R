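# Conditional maximum likelihood machinery for the fixed-effects binomial
# logit.  Conditioning each unit on S_i = sum_t Y_it eliminates alpha_i; the
# conditional density denominator is the degree-S coefficient of the
# generating polynomial prod_t (1 + z e^{eta_t})^K, evaluated in log space
# by the compiled recursion in src/cml_core.cpp.

group_index <- function(id) {
  f <- factor(id, levels = unique(id))
  lens <- as.integer(table(f))
  starts <- c(0L, cumsum(lens)[-length(lens)])
  list(levels = levels(f), starts = starts, lens = lens)
}

#' Drop non-informative units
#'
#' Units whose total count is 0 or K*T_i have conditional probability 1
#' given their total: they carry no information about the slope parameters
#' and are removed before conditional estimation (for the dummy-variable
#' estimator the same units are perfectly predicted).
#'
#' @param panel a [panel_binomial] object.
#' @return list with the filtered `panel` and the `dropped` unit ids.
#' @export
informative_subset <- function(panel) {
  stopifnot(inherits(panel, "panel_binomial"))
  gi <- group_index(panel$id)
  S <- rowsum(panel$Y, factor(panel$id, levels = gi$levels))[, 1]
  Tn <- gi$lens
  bad <- S == 0 | S == panel$K * Tn
  dropped <- gi$levels[bad]
  if (all(bad))
    stop("no informative units: every unit's total is 0 or K*T ",
         "(all outcomes at the same boundary); the slope is not estimable")
  keep <- !(as.character(panel$id) %in% dropped)
  out <- panel
  out$id <- panel$id[keep]; out$time <- panel$time[keep]
  out$Y <- panel$Y[keep]; out$X <- panel$X[keep, , drop = FALSE]
  list(panel = out, dropped = dropped)
}

#' Conditional log-likelihood of one unit
#'
#' Log of the probability of the observed within-unit counts given their
#' total S: \eqn{\sum_t [Y_t \eta_t + \log{K \choose Y_t}] - \log D(S)},
#' where D(S) collects all count vectors with the same total.
#'
#' @param eta per-period linear indices \eqn{x_t'\beta}.
#' @param Y per-period counts.
#' @param K trials per period.
#' @return the conditional log-likelihood contribution (0 for T = 1).
#' @export
group_cond_loglik <- function(eta, Y, K) {
  stopifnot(length(eta) == length(Y), K >= 1, all(Y >= 0), all(Y <= K))
  S <- sum(Y)
  if (S == 0 || S == K * length(Y))
    stop("group total is 0 or K*T: non-informative, filter first")
  sum(Y * eta + lchoose(K, Y)) - cpp_cond_logdenom(eta, as.integer(K),
                                                   as.integer(S))
}

#' Brute-force conditional log-likelihood (enumeration oracle)
#'
#' Enumerates every count vector q with \eqn{0 \le q_t \le K} and
#' \eqn{\sum q_t = S} and sums the conditional density denominator
#' explicitly.  Reference implementation for testing the polynomial
#' recursion; refuses instances with more than `max_compositions` terms.
#'
#' @inheritParams group_cond_loglik
#' @param max_compositions enumeration guard.
#' @return the conditional log-likelihood contribution.
#' @export
brute_force_cond_loglik <- function(eta, Y, K, max_compositions = 1e6) {
  S <- sum(Y); Tt <- length(Y)
  if (S == 0 || S == K * Tt)
    stop("group total is 0 or K*T: non-informative")
  # count compositions by DP before enumerating
  cnt <- rep(0, S + 1); cnt[1] <- 1
  for (t in seq_len(Tt)) {
    new <- rep(0, S + 1)
    for (q in 0:min(K, S)) {
      idx <- seq_len(S + 1 - q)
      new[idx + q] <- new[idx + q] + cnt[idx]
    }
    cnt <- new
  }
  if (cnt[S + 1] > max_compositions)
    stop("enumeration too large (", cnt[S + 1], " compositions)")
  qs <- enumerate_compositions(S, Tt, K)
  logw <- vapply(qs, function(q) sum(lchoose(K, q) + q * eta), 0.0)
  m <- max(logw)
  logden <- m + log(sum(exp(logw - m)))
  sum(Y * eta + lchoose(K, Y)) - logden
}

enumerate_compositions <- function(S, Tt, K) {
  if (Tt == 1L) {
    if (S >= 0 && S <= K) return(list(S)) else return(list())
  }
  out <- list()
  for (q in max(0, S - K * (Tt - 1)):min(K, S))
    out <- c(out, lapply(enumerate_compositions(S - q, Tt - 1L, K),
                         function(rest) c(q, rest)))
  out
}

# shared: eta, group bookkeeping for a filtered panel at given beta
cml_eval <- function(panel, beta) {
  gi <- group_index(panel$id)
  eta <- if (ncol(panel$X)) drop(panel$X %*% beta) else rep(0, length(panel$Y))
  cpp_cml_eval(eta, panel$X, gi$starts, gi$lens, panel$Y,
               as.integer(panel$K))
}

#' Conditional score of the Blogit CML criterion
#'
#' \eqn{\sum_i [\sum_t Y_t x_t - E_c(\sum_t q_t x_t | S_i)]}, the gradient
#' of the conditional log-likelihood, with the conditional expectation
#' computed from the same generating-polynomial recursion.
#'
#' @param panel a [panel_binomial] object, already filtered to informative
#'   units (see [informative_subset()]).
#' @param beta coefficient vector.
#' @return score vector, one element per covariate.
#' @export
cond_score <- function(panel, beta) {
  stopifnot(inherits(panel, "panel_binomial"))
  if (any(!is.finite(beta))) stop("'beta' must be finite")
  drop(cml_eval(panel, beta)$score)
}

#' Conditional log-likelihood of a panel
#'
#' Sum of [group_cond_loglik()] over informative units.
#'
#' @inheritParams cond_score
#' @return total conditional log-likelihood.
#' @export
cond_loglik <- function(panel, beta) {
  stopifnot(inherits(panel, "panel_binomial"))
  cml_eval(panel, beta)$loglik
}

#' Expand grouped counts to Bernoulli rows
#'
#' Each observation with count Y out of K becomes K cloned rows with a 0/1
#' indicator (ones first) and unchanged covariates, so any conditional
#' (fixed-effects) binary logit routine can fit the binomial model: the
#' conditional Bernoulli likelihood of the expansion differs from the
#' grouped conditional likelihood only by the constant
#' \eqn{\sum_{it}\log{K \choose Y_{it}}}.
#'
#' @param panel a [panel_binomial] object.
#' @return a `"panel_binomial"` with K = 1, K times the rows, and a `clone`
#'   suffix appended to the period labels to keep (id, time) pairs unique.
#' @export
expand_to_bernoulli <- function(panel) {
  stopifnot(inherits(panel, "panel_binomial"))
  K <- panel$K
  n <- length(panel$Y)
  idx <- rep(seq_len(n), each = K)
  j <- rep(seq_len(K), times = n)
  d <- as.integer(j <= panel$Y[idx])  # ones first
  out <- panel
  out$id <- panel$id[idx]
  out$time <- paste(panel$time[idx], j, sep = ".")
  out$Y <- d
  out$X <- panel$X[idx, , drop = FALSE]
  out$K <- 1L
  out
}

# collinearity / time-invariance screen on the within-unit variation
check_within_variation <- function(panel) {
  if (!ncol(panel$X)) stop("no covariates to estimate")
  f <- factor(panel$id, levels = unique(panel$id))
  cnt <- as.integer(table(f))
  means <- rowsum(panel$X, f) / cnt
  Xd <- panel$X - means[as.integer(f), , drop = FALSE]
  wsd <- sqrt(colSums(Xd^2))
  ti <- wsd < 1e-10
  if (any(ti))
    stop("covariate(s) ", paste(colnames(panel$X)[ti], collapse = ", "),
         " are time-invariant within every unit and are absorbed by the ",
         "fixed effects; drop them or interact them with time-varying terms")
  if (qr(Xd)$rank < ncol(Xd))
    stop("within-unit covariate variation is collinear; the conditional ",
         "likelihood cannot separate the coefficients")
  invisible(Xd)
}

num_hessian <- function(gr, beta, eps = 1e-5) {
  p <- length(beta)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    bp <- beta; bm <- beta
    bp[j] <- bp[j] + eps; bm[j] <- bm[j] - eps
    H[, j] <- (gr(bp) - gr(bm)) / (2 * eps)
  }
  (H + t(H)) / 2
}

# core CML fit on a (not yet filtered) panel; returns the pieces blogit()
# assembles into the fit object
fit_cml_core <- function(panel, start = NULL, gtol = 1e-8, maxit = 200L) {
  flt <- informative_subset(panel)
  dat <- flt$panel
  check_within_variation(dat)
  p <- ncol(dat$X)
  if (is.null(start)) start <- rep(0, p)
  negll <- function(b) -cml_eval(dat, b)$loglik
  neggr <- function(b) -drop(cml_eval(dat, b)$score)
  opt <- optim(start, negll, neggr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  beta <- opt$par
  gr <- function(b) drop(cml_eval(dat, b)$score)
  # Newton polish to the gradient-norm tolerance
  it <- opt$counts[["function"]]
  g <- gr(beta)
  k <- 0L
  while (sqrt(sum(g^2)) > gtol && k < 25L) {
    H <- num_hessian(gr, beta)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta - step
    g <- gr(beta)
    k <- k + 1L
  }
  converged <- sqrt(sum(g^2)) <= max(gtol, 1e-6)
  if (!converged)
    warning("CML fit did not reach the gradient tolerance (|g| = ",
            format(sqrt(sum(g^2))), ")")
  ev <- cml_eval(dat, beta)
  H <- num_hessian(gr, beta)
  bread <- tryCatch(solve(-H), error = function(e)
    stop("singular Hessian at the optimum; check covariates ",
         paste(colnames(dat$X), collapse = ", ")))
  G <- nrow(ev$scores)
  meat <- crossprod(ev$scores)
  vcov <- bread %*% meat %*% bread * G / (G - 1)
  dimnames(vcov) <- list(colnames(dat$X), colnames(dat$X))
  list(beta = setNames(beta, colnames(dat$X)), vcov = vcov,
       loglik = ev$loglik, dropped = flt$dropped,
       n_units_used = G, converged = converged,
       iterations = it + k, gradient_norm = sqrt(sum(g^2)),
       panel = dat)
}

# expansion path: expand to Bernoulli clones, refit with the grouped CML
# machinery at K = 1 (each unit's K*T clones are one conditioning group)
fit_cml_expansion <- function(panel, max_rows = 2e6, ...) {
  if (length(panel$Y) * panel$K > max_rows)
    stop("expansion would create ", length(panel$Y) * panel$K,
         " rows; use the direct conditional fit instead")
  fit_cml_core(expand_to_bernoulli(panel), ...)
}
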