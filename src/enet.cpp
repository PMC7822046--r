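#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the elastic net with penalty
//   (1/2n) ||y - X b||^2 + lambda * alpha * ||b||_1 + lambda * (1-alpha) * ||b||_2^2
// (note: no 1/2 on the quadratic term). Columns of X are assumed centred and
// scaled so that x_j'x_j / n = 1; y is assumed centred. Active-set strategy:
// converge on the current nonzero set, then one full sweep to check for
// violators, repeating until the full sweep changes nothing.

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static double sweep_set(const NumericMatrix& X, NumericVector& r,
                        NumericVector& beta, const std::vector<int>& idx,
                        double l1, double ridge, int n) {
  double max_change = 0.0;
  for (int k = 0; k < (int)idx.size(); ++k) {
    const int j = idx[k];
    double dot = 0.0;
    const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) dot += xj[i] * r[i];
    double z = dot / n + beta[j];
    double bj = soft_threshold(z, l1) / ridge;
    double diff = bj - beta[j];
    if (diff != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= xj[i] * diff;
      beta[j] = bj;
      double ad = std::abs(diff);
      if (ad > max_change) max_change = ad;
    }
  }
  return max_change;
}

// [[Rcpp::export]]
NumericVector enet_cd(const NumericMatrix& X, const NumericVector& y,
                      double lambda, double alpha,
                      double tol, int max_iter,
                      Nullable<NumericVector> beta_init = R_NilValue) {
  const int n = X.nrow();
  const int p = X.ncol();
  NumericVector beta(p);
  if (beta_init.isNotNull()) beta = clone(NumericVector(beta_init));
  NumericVector r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i];
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= X(i, j) * beta[j];
    }
  }
  const double l1 = lambda * alpha;
  const double ridge = 1.0 + 2.0 * lambda * (1.0 - alpha);
  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;
  int iter = 0;
  while (iter < max_iter) {
    // full sweep
    double change = sweep_set(X, r, beta, all, l1, ridge, n);
    ++iter;
    if (change < tol) break;
    // converge on the active set
    std::vector<int> active;
    active.reserve(64);
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
    while (iter < max_iter) {
      double ch = sweep_set(X, r, beta, active, l1, ridge, n);
      ++iter;
      if (ch < tol) break;
    }
  }
  return beta;
}

// Warm-started path over a descending lambda grid; returns p x L matrix.
// The path stops early once the fit saturates (nonzero count > max_nnz,
// where the solution stops being meaningfully sparse and coordinate descent
// degenerates); later columns repeat the last computed solution.
// [[Rcpp::export]]
NumericMatrix enet_path(const NumericMatrix& X, const NumericVector& y,
                        const NumericVector& lambdas, double alpha,
                        double tol, int max_iter, int max_nnz = -1) {
  const int p = X.ncol();
  const int L = lambdas.size();
  if (max_nnz < 0) max_nnz = p;
  NumericMatrix out(p, L);
  NumericVector beta(p);
  for (int l = 0; l < L; ++l) {
    beta = enet_cd(X, y, lambdas[l], alpha, tol, max_iter, beta);
    for (int j = 0; j < p; ++j) out(j, l) = beta[j];
    int nnz = 0;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) ++nnz;
    if (nnz > max_nnz) {
      for (int l2 = l + 1; l2 < L; ++l2)
        for (int j = 0; j < p; ++j) out(j, l2) = beta[j];
      break;
    }
  }
  return out;
}

// Bootstrap selection counts at a fixed lambda. idx holds 1-based resample
// row indices, one column per bootstrap replicate; each resample is
// restandardized (columns centred, unit population variance; zero-variance
// columns never selected) before fitting. Returns an integer vector of
// per-column selection counts with attribute-free layout: first p entries
// are counts, entry p is followed by B nonzero-set sizes.
// [[Rcpp::export]]
List enet_boot(const NumericMatrix& X, const NumericVector& y,
               const IntegerMatrix& idx, double lambda, double alpha,
               double tol, int max_iter) {
  const int p = X.ncol();
  const int m = idx.nrow();
  const int B = idx.ncol();
  IntegerVector counts(p);
  IntegerVector qsizes(B);
  NumericMatrix Xb(m, p);
  NumericVector yb(m);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < m; ++i) {
      const int row = idx(i, b) - 1;
      yb[i] = y[row];
      for (int j = 0; j < p; ++j) Xb(i, j) = X(row, j);
    }
    double ymean = 0.0;
    for (int i = 0; i < m; ++i) ymean += yb[i];
    ymean /= m;
    for (int i = 0; i < m; ++i) yb[i] -= ymean;
    std::vector<bool> keep(p, true);
    for (int j = 0; j < p; ++j) {
      double mu = 0.0;
      for (int i = 0; i < m; ++i) mu += Xb(i, j);
      mu /= m;
      double ss = 0.0;
      for (int i = 0; i < m; ++i) {
        Xb(i, j) -= mu;
        ss += Xb(i, j) * Xb(i, j);
      }
      double sd = std::sqrt(ss / m);
      if (sd <= 0.0) {
        keep[j] = false;
        for (int i = 0; i < m; ++i) Xb(i, j) = 0.0;
      } else {
        for (int i = 0; i < m; ++i) Xb(i, j) /= sd;
      }
    }
    NumericVector beta = enet_cd(Xb, yb, lambda, alpha, tol, max_iter);
    int q = 0;
    for (int j = 0; j < p; ++j) {
      if (keep[j] && beta[j] != 0.0) {
        ++counts[j];
        ++q;
      }
    }
    qsizes[b] = q;
  }
  return List::create(_["counts"] = counts, _["q"] = qsizes);
}
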