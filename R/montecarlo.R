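# Monte Carlo harness: estimator-comparison cells, test size/power cells,
# and relative-bias curves over a dispersion grid.  Replication r of a cell
# uses seed `seed + r - 1` for everything in that replication (data first,
# then any auxiliary test draws continue the same stream), so a cell is
# bit-reproducible and independent of whatever other cells run.

rep_seed <- function(seed, r) as.integer((seed + r - 1) %% .Machine$integer.max)

#' Monte Carlo comparison of the three estimators on one design cell
#'
#' For each replication: simulate a panel from `config`, fit the requested
#' estimators, and record the slope estimate.  The conditional and
#' dummy-variable estimators drop boundary (non-informative / perfectly
#' predicted) units by construction; the pooled estimator uses the full
#' sample, as the individual effects it ignores are exactly what makes
#' boundary totals frequent.  Failures are caught and counted, never
#' silently ignored.
#'
#' @param config a [dgp_config()].
#' @param n_reps number of replications.
#' @param seed master seed; replication r uses `seed + r - 1`.
#' @param estimators subset of `c("cml", "dv", "pooled")`.
#' @return an object of class `"mc_summary"`: per-estimator `mean`, `sd`
#'   and failure count of the slope estimate, plus the cell description.
#' @export
run_estimator_cell <- function(config, n_reps, seed,
                               estimators = c("cml", "dv", "pooled")) {
  stopifnot(inherits(config, "dgp_config"))
  estimators <- match.arg(estimators, several.ok = TRUE)
  est <- matrix(NA_real_, n_reps, length(estimators),
                dimnames = list(NULL, estimators))
  for (r in seq_len(n_reps)) {
    sim <- simulate_panel(config, rep_seed(seed, r))
    for (m in estimators) {
      fit <- tryCatch(blogit(data = sim$panel, K = config$K, method = m),
                      error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit)) est[r, m] <- coef(fit)[["x"]]
    }
  }
  n_failed <- as.integer(colSums(is.na(est)))
  names(n_failed) <- estimators
  if (any(n_failed > 0.1 * n_reps))
    warning("more than 10% of fits failed for: ",
            paste(estimators[n_failed > 0.1 * n_reps], collapse = ", "))
  structure(list(config = config, n_reps = n_reps, seed = seed,
                 estimates = est,
                 mean = colMeans(est, na.rm = TRUE),
                 sd = apply(est, 2, sd, na.rm = TRUE),
                 mc_se = apply(est, 2, sd, na.rm = TRUE) /
                   sqrt(colSums(!is.na(est))),
                 n_failed = n_failed),
            class = "mc_summary")
}

#' Monte Carlo rejection rate of the dispersion test on one design cell
#'
#' Simulates `n_reps` panels from `config` and runs
#' [overdispersion_test()] on each; under `eta = 0` the rejection rate
#' estimates the size of the test, under `eta > 0` its power.
#'
#' @inheritParams run_estimator_cell
#' @param variant,s_mode,m_draws passed to [overdispersion_test()].
#' @param alpha nominal level.
#' @param use_true_beta kernel variant only: use the design slope
#'   `config$beta1` for the index differences instead of refitting the
#'   Blogit CML each replication (both are consistent under H0; refitting
#'   is the default and matches practice).
#' @return an `"mc_summary"` with the `rejection_rate`, the per-replication
#'   p-values, and the failure count.
#' @export
run_test_cell <- function(config, n_reps, seed,
                          variant = c("discrete", "kernel"),
                          alpha = 0.05, s_mode = NULL, m_draws = 1L,
                          use_true_beta = FALSE) {
  stopifnot(inherits(config, "dgp_config"))
  variant <- match.arg(variant)
  pv <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    sim <- simulate_panel(config, rep_seed(seed, r))
    bh <- if (variant == "kernel" && use_true_beta)
      setNames(config$beta1, "x") else NULL
    tst <- tryCatch(
      overdispersion_test(sim$panel, variant = variant, beta_hat = bh,
                          s_mode = s_mode, alpha = alpha,
                          m_draws = m_draws),
      error = function(e) NULL)
    if (!is.null(tst)) pv[r] <- tst$p.value
  }
  n_failed <- sum(is.na(pv))
  if (n_failed > 0.1 * n_reps)
    warning("more than 10% of test computations failed")
  structure(list(config = config, n_reps = n_reps, seed = seed,
                 variant = variant, alpha = alpha,
                 p_values = pv,
                 rejection_rate = mean(pv < alpha, na.rm = TRUE),
                 n_failed = n_failed),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cfg <- x$config
  cat("Monte Carlo cell: N=", cfg$N, " T=", cfg$T, " K=", cfg$K,
      " eta=", cfg$eta, " x:", cfg$x_law, "  reps=", x$n_reps, "\n",
      sep = "")
  if (!is.null(x$rejection_rate)) {
    cat("variant:", x$variant, " rejection rate at alpha=", x$alpha, ":",
        round(x$rejection_rate, 4), " (failed:", x$n_failed, ")\n")
  } else {
    tab <- rbind(mean = x$mean, sd = x$sd, mc_se = x$mc_se,
                 n_failed = x$n_failed)
    print(round(tab, 4))
  }
  invisible(x)
}

#' Relative bias of the slope over a dispersion grid
#'
#' Runs [run_estimator_cell()] on every feasible (eta, T, K) combination
#' and reports the relative bias `(mean estimate - beta1)/beta1` of each
#' estimator.  Cells where the requested inflation is infeasible
#' (`eta >= K - 1`) are skipped with a message.
#'
#' @param N cross-section size.
#' @param T_grid,K_grid,eta_grid design grids (`eta = 0` rows give the
#'   correctly specified binomial benchmark).
#' @param n_reps,seed as in [run_estimator_cell()].
#' @param estimators estimators to include.
#' @return a data.frame of class `"relative_bias"` with columns `eta`,
#'   `T`, `K`, `estimator`, `mean`, `sd`, `rel_bias`, `n_failed`.
#' @export
relative_bias_curves <- function(N, T_grid, K_grid, eta_grid, n_reps,
                                 seed, estimators = c("cml", "dv")) {
  rows <- list()
  for (K in K_grid) for (T in T_grid) for (eta in eta_grid) {
    if (eta > 0 && eta >= K - 1) {
      message("skipping infeasible cell K=", K, " eta=", eta)
      next
    }
    cfg <- dgp_config(N = N, T = T, K = K, eta = eta)
    cell <- run_estimator_cell(cfg, n_reps, seed, estimators = estimators)
    for (m in estimators)
      rows[[length(rows) + 1L]] <- data.frame(
        eta = eta, T = T, K = K, estimator = m,
        mean = cell$mean[[m]], sd = cell$sd[[m]],
        rel_bias = (cell$mean[[m]] - cfg$beta1) / cfg$beta1,
        n_failed = cell$n_failed[[m]])
  }
  structure(do.call(rbind, rows),
            class = c("relative_bias", "data.frame"))
}

#' @param x a `"relative_bias"` table.
#' @param ... unused.
#' @rdname relative_bias_curves
#' @export
plot.relative_bias <- function(x, ...) {
  cells <- unique(x[, c("T", "K")])
  ests <- unique(x$estimator)
  cols <- seq_along(ests)
  graphics::plot(range(x$eta), range(x$rel_bias), type = "n",
                 xlab = "overdispersion degree (eta)",
                 ylab = "relative bias of the slope", ...)
  lty <- 0
  for (i in seq_len(nrow(cells))) {
    lty <- lty + 1
    for (j in seq_along(ests)) {
      sub <- x[x$T == cells$T[i] & x$K == cells$K[i] &
               x$estimator == ests[j], ]
      graphics::lines(sub$eta, sub$rel_bias, col = cols[j], lty = lty)
    }
  }
  graphics::abline(h = 0, col = "grey")
  graphics::legend("topleft", bty = "n",
                   legend = c(ests, paste0("T=", cells$T, ",K=", cells$K)),
                   col = c(cols, rep("black", nrow(cells))),
                   lty = c(rep(1, length(ests)), seq_len(nrow(cells))))
  invisible(x)
}
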