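# Comparison estimators: the binomial logit with individual dummy variables
# (subject to the incidental-parameters bias) and the pooled binomial logit
# (ignores the individual effects entirely).

# For fixed beta the unit intercepts separate: alpha_i solves the 1-D score
# sum_t (Y_it - K Lambda(eta_it + a)) = 0, strictly decreasing in a.
# Vectorized safeguarded Newton across units.
profile_alpha <- function(eta0, Y, f, K, tol = 1e-10, maxit = 100L) {
  S <- rowsum(Y, f)[, 1]
  Tn <- as.integer(table(f))
  # logit of shrunk unit mean, net of the average index, as a start
  a <- qlogis((S + 0.5) / (K * Tn + 1)) - rowsum(eta0, f)[, 1] / Tn
  g <- rep(Inf, length(a))
  for (it in seq_len(maxit)) {
    lam <- plogis(eta0 + a[as.integer(f)])
    g <- S - K * rowsum(lam, f)[, 1]
    if (max(abs(g)) < tol) break
    dg <- K * rowsum(lam * (1 - lam), f)[, 1]
    step <- g / pmax(dg, 1e-12)
    a <- a + pmin(pmax(step, -10), 10)
  }
  lam <- plogis(eta0 + a[as.integer(f)])
  g <- S - K * rowsum(lam, f)[, 1]
  for (i in which(abs(g) >= tol)) {  # safeguarded root fallback per unit
    rows <- which(as.integer(f) == i)
    fun <- function(aa) S[i] - K * sum(plogis(eta0[rows] + aa))
    lo <- -50; hi <- 50
    while (fun(lo) < 0 && lo > -1e4) lo <- lo * 2
    while (fun(hi) > 0 && hi < 1e4) hi <- hi * 2
    a[i] <- stats::uniroot(fun, c(lo, hi), tol = 1e-12)$root
  }
  a
}

fit_dv_core <- function(panel, gtol = 1e-8, maxit = 200L) {
  flt <- informative_subset(panel)  # perfectly predicted units
  dat <- flt$panel
  check_within_variation(dat)
  f <- factor(dat$id, levels = unique(dat$id))
  K <- dat$K; Y <- dat$Y; X <- dat$X
  p <- ncol(X)
  prof <- function(b) {
    eta0 <- drop(X %*% b)
    a <- profile_alpha(eta0, Y, f, K)
    eta <- eta0 + a[as.integer(f)]
    list(ll = sum(Y * plogis(eta, log.p = TRUE) +
                  (K - Y) * plogis(-eta, log.p = TRUE)),
         grad = drop(crossprod(X, Y - K * plogis(eta))),
         alpha = a, eta = eta)
  }
  opt <- optim(rep(0, p), function(b) -prof(b)$ll,
               function(b) -prof(b)$grad, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  beta <- opt$par
  gr <- function(b) prof(b)$grad
  g <- gr(beta); k <- 0L
  while (sqrt(sum(g^2)) > gtol && k < 25L) {
    H <- num_hessian(gr, beta)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta - step; g <- gr(beta); k <- k + 1L
  }
  converged <- sqrt(sum(g^2)) <= max(gtol, 1e-6)
  if (!converged) warning("DV fit did not reach the gradient tolerance")
  pr <- prof(beta)
  res <- Y - K * plogis(pr$eta)
  scores <- rowsum(X * res, f)
  H <- num_hessian(gr, beta)
  bread <- tryCatch(solve(-H), error = function(e)
    stop("singular Hessian in the dummy-variable fit; a covariate may be ",
         "constant within units"))
  G <- nlevels(f)
  vcov <- bread %*% crossprod(scores) %*% bread * G / (G - 1)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(beta = setNames(beta, colnames(X)), vcov = vcov,
       loglik = pr$ll, alpha = setNames(pr$alpha, levels(f)),
       dropped = flt$dropped, n_units_used = G,
       converged = converged, iterations = opt$counts[["function"]] + k,
       gradient_norm = sqrt(sum(g^2)), panel = dat)
}

fit_pooled_core <- function(panel) {
  dat <- panel
  Y <- dat$Y; K <- dat$K; X <- dat$X
  df <- data.frame(succ = Y, fail = K - Y)
  if (ncol(X)) df <- cbind(df, as.data.frame(X))
  form <- if (ncol(X))
    as.formula(paste("cbind(succ, fail) ~",
                     paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  else cbind(succ, fail) ~ 1
  gfit <- glm(form, family = binomial(), data = df)
  beta <- coef(gfit)
  names(beta) <- c("(Intercept)", colnames(X))
  Xf <- cbind(`(Intercept)` = 1, X)
  lam <- plogis(drop(Xf %*% beta))
  res <- Y - K * lam
  f <- factor(dat$id, levels = unique(dat$id))
  scores <- rowsum(Xf * res, f)
  W <- K * lam * (1 - lam)
  bread <- solve(crossprod(Xf * sqrt(W)))
  G <- nlevels(f)
  vcov <- bread %*% crossprod(scores) %*% bread * G / (G - 1)
  dimnames(vcov) <- list(names(beta), names(beta))
  list(beta = beta, vcov = vcov,
       loglik = sum(Y * plogis(drop(Xf %*% beta), log.p = TRUE) +
                    (K - Y) * plogis(-drop(Xf %*% beta), log.p = TRUE)),
       dropped = character(0), n_units_used = G,
       converged = gfit$converged, iterations = gfit$iter,
       gradient_norm = NA_real_, panel = dat)
}
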