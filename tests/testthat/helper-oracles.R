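# Independent oracles used to validate the implementation.

# Maximum violation of the subgradient (KKT) conditions of
#   (1/n) ||y - X b - a||^2 + lambda ||b||_1
# on the standardized scale; 0 at an exact minimizer.
kkt_violation <- function(X, y, lambda, beta, intercept) {
  n <- nrow(X)
  mx <- colMeans(X)
  Xc <- sweep(X, 2, mx)
  sx <- sqrt(colMeans(Xc^2))
  keep <- sx > 0
  Xs <- sweep(Xc[, keep, drop = FALSE], 2, sx[keep], "/")
  bs <- (beta * sx)[keep]
  r <- (y - mean(y)) - Xs %*% bs
  grad <- -2 / n * crossprod(Xs, r)
  v <- ifelse(bs != 0,
              abs(grad + lambda * sign(bs)),
              pmax(0, abs(grad) - lambda))
  max(c(0, v))
}

# independent closed-form lambda_max
oracle_lambda_max <- function(X, y) {
  n <- nrow(X)
  mx <- colMeans(X)
  Xc <- sweep(X, 2, mx)
  sx <- sqrt(colMeans(Xc^2))
  keep <- sx > 0
  if (!any(keep)) return(0)
  Xs <- sweep(Xc[, keep, drop = FALSE], 2, sx[keep], "/")
  max(abs(crossprod(Xs, y - mean(y)))) * 2 / n
}

oracle_lambda_path <- function(X, y, n_lams, eps = 1e-4) {
  lm <- oracle_lambda_max(X, y)
  if (lm <= 0) return(0)
  c(0, exp(seq(log(lm * eps), log(lm), length.out = n_lams - 1)))
}

# Explicit nested two-loop double cross-validation oracle, mirroring the
# four-step procedure with plain loops and its own interpolation, path
# construction and selection logic. Shares only the elementary solver.
oracle_double_cv <- function(g, p, delays, n_lams, eps = 1e-4) {
  al <- align_timepoints(g$times, p$y)
  tms <- as.numeric(unclass(al$grid))
  obs <- al$protein$values
  n <- length(tms)
  lag_design <- function(idx, tau) {
    Xq <- sapply(seq_len(nrow(g$X)), function(k)
      approx(g$times, g$X[k, ], xout = tms[idx] - tau, rule = 2)$y)
    matrix(Xq, nrow = length(idx))
  }
  out <- NULL
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    surface <- list()
    for (tau in delays) {
      Xtr <- lag_design(train, tau)
      path <- oracle_lambda_path(Xtr, obs[train], n_lams, eps)
      mses <- sapply(path, function(lam) {
        errs <- numeric(length(train))
        for (jj in seq_along(train)) {
          fit <- lasso_solve(Xtr[-jj, , drop = FALSE], obs[train][-jj],
                             lam, tol = 1e-12, maxit = 1000000L)
          pred <- fit$intercept + sum(fit$beta * Xtr[jj, ])
          errs[jj] <- (obs[train][jj] - pred)^2
        }
        mean(errs)
      })
      surface[[length(surface) + 1]] <- list(tau = tau, path = path,
                                             mses = mses)
    }
    # near-ties (1e-6 relative band) collapse; then smallest delay,
    # then largest penalty
    thr <- min(sapply(surface, function(z) min(z$mses)))
    thr <- thr * (1 + 1e-6) + 1e-12
    best_tau <- NA; best_lam <- NA
    for (z in surface) {
      ok <- which(z$mses <= thr)
      if (length(ok)) {
        best_tau <- z$tau
        best_lam <- z$path[max(ok)]
        break
      }
    }
    fit <- lasso_solve(lag_design(train, best_tau), obs[train], best_lam,
                       tol = 1e-12, maxit = 1000000L)
    pred <- fit$intercept + sum(fit$beta * lag_design(i, best_tau)[1, ])
    out <- rbind(out, data.frame(heldout_index = i, predicted = pred,
                                 tau_used = best_tau,
                                 lam_used = best_lam))
  }
  out
}
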