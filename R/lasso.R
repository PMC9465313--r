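# L1-penalized least squares on tiny designs.
#
# Objective (the one reported throughout the package):
#   (1/N) * || y - X beta - intercept ||_2^2 + lambda * || beta ||_1
# Predictors are centered and scaled to unit (population) variance inside
# the solver, the penalty applies on that standardized scale, and the
# coefficients are mapped back to the original scale; the intercept enters
# through centering.

standardize_design <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    stop("X and y must have the same number of observations")
  if (nrow(X) < 2)
    stop("need at least 2 observations")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("X and y must be finite (no NA/NaN/Inf)")
  mx <- colMeans(X)
  Xc <- sweep(X, 2, mx, "-")
  sx <- sqrt(colMeans(Xc^2))
  # near-constant columns are constant: never standardize round-off noise
  keep <- sx > 1e-12 * pmax(1, apply(abs(X), 2, max))
  Xs <- Xc
  if (any(keep)) Xs[, keep] <- sweep(Xc[, keep, drop = FALSE], 2,
                                     sx[keep], "/")
  Xs[, !keep] <- 0
  ybar <- mean(y)
  list(Xs = Xs, yc = y - ybar, mx = mx, sx = sx, keep = keep, ybar = ybar)
}

#' Solve the L1-penalized regression problem
#'
#' Minimizes `(1/N) ||y - X beta - intercept||^2 + lambda ||beta||_1` by
#' cyclic coordinate descent. Predictors are standardized internally
#' (population sd); coefficients are returned on the original scale.
#' Zero-variance predictors get a zero coefficient.
#'
#' @param X numeric design matrix, observations x predictors.
#' @param y numeric response vector.
#' @param lambda penalty weight (>= 0).
#' @param tol coordinate-descent convergence tolerance (max coefficient
#'   change on the standardized scale).
#' @param maxit maximum number of full coordinate sweeps.
#' @return list with `beta` (original scale, named if `X` has column
#'   names) and `intercept`.
#' @export
lasso_solve <- function(X, y, lambda, tol = 1e-10, maxit = 10000L) {
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda < 0)
    stop("lambda must be a single non-negative number")
  st <- standardize_design(X, y)
  p <- ncol(st$Xs)
  beta <- numeric(p)
  if (any(st$keep)) {
    bstd <- cpp_cd_lasso(st$Xs[, st$keep, drop = FALSE], st$yc, lambda,
                         numeric(sum(st$keep)), tol, as.integer(maxit))
    beta[st$keep] <- bstd / st$sx[st$keep]
  }
  names(beta) <- colnames(X)
  list(beta = beta, intercept = st$ybar - sum(beta * st$mx))
}

#' Smallest penalty that shrinks all coefficients to zero
#'
#' Closed form from the subgradient condition at beta = 0:
#' `lambda_max = (2/N) max_j |x_j' (y - mean(y))|` with standardized
#' predictors.
#'
#' @inheritParams lasso_solve
#' @return a single non-negative number (0 for zero-variance designs).
#' @export
lambda_max <- function(X, y) {
  st <- standardize_design(X, y)
  if (!any(st$keep)) return(0)
  n <- length(st$yc)
  max(abs(crossprod(st$Xs[, st$keep, drop = FALSE], st$yc))) * 2 / n
}

#' Penalty path for a design
#'
#' A log-spaced grid of `n_lams - 1` penalties from `lambda_max * eps` up to
#' `lambda_max`, with 0 prepended so the unpenalized solution is always on
#' the path (the grid of candidate penalties is grown until every
#' coefficient is zero). Returns the single-element path `0` for
#' zero-variance designs.
#'
#' @inheritParams lasso_solve
#' @param n_lams number of penalties on the path (>= 2).
#' @param eps ratio of the smallest positive penalty to `lambda_max`.
#' @return strictly increasing numeric vector; the largest element shrinks
#'   every coefficient to zero.
#' @export
lambda_path <- function(X, y, n_lams = 50L, eps = 1e-4) {
  if (!is.numeric(n_lams) || length(n_lams) != 1 || n_lams < 2)
    stop("n_lams must be >= 2")
  lm <- lambda_max(X, y)
  if (lm <= 0) return(0)
  c(0, exp(seq(log(lm * eps), log(lm), length.out = as.integer(n_lams) - 1L)))
}
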