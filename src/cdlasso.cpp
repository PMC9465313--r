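#include <RcppArmadillo.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <numeric>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Soft-threshold operator.
static inline double soft(double z, double g) {
  if (z > g)  return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for
//   min_b (1/n) * || y - X b ||_2^2 + lambda * || b ||_1
// on data that the caller has already centered/standardized.
// X is column-major n x p, r must equal y - X b on entry and is kept
// up to date; xtx[j] = sum_i X(i,j)^2.
static void cd_solve(const double* X, int n, int p, double lambda,
                     double* beta, double* r, const double* xtx,
                     double tol, int maxit) {
  const double thr = lambda * n / 2.0;
  for (int it = 0; it < maxit; ++it) {
    double maxdel = 0.0;
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) { beta[j] = 0.0; continue; }
      const double* xj = X + static_cast<size_t>(j) * n;
      double rho = 0.0;
      for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
      rho += xtx[j] * beta[j];
      const double bnew = soft(rho, thr) / xtx[j];
      const double d = bnew - beta[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
        beta[j] = bnew;
        const double ad = std::fabs(d);
        if (ad > maxdel) maxdel = ad;
      }
    }
    if (maxdel < tol) break;
  }
}

// Minimum-norm least-squares coefficients (the lambda = 0 special case;
// exact, deterministic, and fast where coordinate descent would crawl on
// near-collinear designs). Singular values below max_sv * 1e-10 are
// treated as zero.
static void lstsq_minnorm(const double* X, int n, int p, const double* y,
                          double* beta) {
  arma::mat A(const_cast<double*>(X), n, p, false, true);
  arma::vec b(const_cast<double*>(y), n, false, true);
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd_econ(U, s, V, A)) {
    std::fill(beta, beta + p, 0.0);
    return;
  }
  const double cut = (s.n_elem ? s.max() : 0.0) * 1e-10;
  arma::vec coef = U.t() * b;
  for (arma::uword k = 0; k < s.n_elem; ++k)
    coef[k] = (s[k] > cut) ? coef[k] / s[k] : 0.0;
  arma::vec out = V * coef;
  for (int j = 0; j < p; ++j) beta[j] = out[j];
}

// [[Rcpp::export]]
NumericVector cpp_cd_lasso(NumericMatrix Xs, NumericVector yc, double lambda,
                           NumericVector beta_init, double tol, int maxit) {
  const int n = Xs.nrow(), p = Xs.ncol();
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  if (lambda == 0.0) {
    lstsq_minnorm(REAL(Xs), n, p, REAL(yc), beta.data());
    return NumericVector(beta.begin(), beta.end());
  }
  std::vector<double> xtx(p), r(yc.begin(), yc.end());
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Xs(i, j) * Xs(i, j);
    xtx[j] = s;
    if (beta[j] != 0.0)
      for (int i = 0; i < n; ++i) r[i] -= Xs(i, j) * beta[j];
  }
  cd_solve(REAL(Xs), n, p, lambda, beta.data(), r.data(), xtx.data(),
           tol, maxit);
  return NumericVector(beta.begin(), beta.end());
}

// Leave-one-out CV squared error, averaged over folds, for every penalty in
// `lambdas`. Fold i trains on the design rows (X, y) without row i and is
// scored against yobs[i], predicting from the query row Xq(i,). Each
// training fold is centered and standardized afresh (population sd);
// columns constant within a fold are dropped for that fold. lambda = 0 is
// solved in closed form (minimum-norm least squares); positive penalties
// use cold-started coordinate descent so results match the reference
// solver. Results are returned in the input order of `lambdas`.
// [[Rcpp::export]]
NumericVector cpp_loocv_path(NumericMatrix X, NumericVector y,
                             NumericMatrix Xq, NumericVector yobs,
                             NumericVector lambdas, double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  if (n < 3) stop("leave-one-out CV needs at least 3 rows");
  if (Xq.nrow() != n || Xq.ncol() != p || yobs.size() != n)
    stop("query design must match the training design shape");

  std::vector<int> ord(L);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return lambdas[a] > lambdas[b];
  });

  std::vector<double> sums(L, 0.0);
  const int m = n - 1;
  std::vector<double> Xt(static_cast<size_t>(m) * p), yt(m), mu(p), sd(p),
      xtx(p), beta(p), r(m), xq(p);

  for (int hold = 0; hold < n; ++hold) {
    // training stats
    for (int j = 0; j < p; ++j) {
      double s = 0.0, amax = 0.0;
      for (int i = 0; i < n; ++i) if (i != hold) {
        s += X(i, j);
        const double a = std::fabs(X(i, j));
        if (a > amax) amax = a;
      }
      mu[j] = s / m;
      double v = 0.0;
      for (int i = 0; i < n; ++i) if (i != hold) {
        const double d = X(i, j) - mu[j];
        v += d * d;
      }
      sd[j] = std::sqrt(v / m);
      // a column of (near-)identical values is constant: round-off from
      // the mean must not be standardized into a fake predictor
      if (sd[j] <= 1e-12 * std::max(1.0, amax)) sd[j] = 0.0;
    }
    double ybar = 0.0;
    for (int i = 0; i < n; ++i) if (i != hold) ybar += y[i];
    ybar /= m;

    for (int j = 0; j < p; ++j) {
      double* col = Xt.data() + static_cast<size_t>(j) * m;
      int k = 0;
      if (sd[j] > 0.0) {
        for (int i = 0; i < n; ++i) if (i != hold)
          col[k++] = (X(i, j) - mu[j]) / sd[j];
        xq[j] = (Xq(hold, j) - mu[j]) / sd[j];
      } else {
        for (int i = 0; i < m; ++i) col[i] = 0.0;
        xq[j] = 0.0;
      }
      double s = 0.0;
      for (int i = 0; i < m; ++i) s += col[i] * col[i];
      xtx[j] = s;
    }
    {
      int k = 0;
      for (int i = 0; i < n; ++i) if (i != hold) yt[k++] = y[i] - ybar;
    }

    for (int li = 0; li < L; ++li) {
      const int pos = ord[li];
      if (lambdas[pos] == 0.0) {
        lstsq_minnorm(Xt.data(), m, p, yt.data(), beta.data());
      } else {
        std::fill(beta.begin(), beta.end(), 0.0);
        std::copy(yt.begin(), yt.end(), r.begin());
        cd_solve(Xt.data(), m, p, lambdas[pos], beta.data(), r.data(),
                 xtx.data(), tol, maxit);
      }
      double pred = ybar;
      for (int j = 0; j < p; ++j) pred += beta[j] * xq[j];
      const double e = yobs[hold] - pred;
      sums[pos] += e * e;
    }
  }

  NumericVector out(L);
  for (int li = 0; li < L; ++li) out[li] = sums[li] / n;
  return out;
}
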