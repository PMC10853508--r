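#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Exact SMO solver for the soft-margin linear C-SVC dual:
//   min_a 1/2 a' Q a - e' a,  0 <= a_i <= C,  sum_i a_i y_i = 0,
// with Q_ij = y_i y_j K_ij. Maximal-violating-pair working-set selection,
// stopping when the KKT gap drops below `tol`. K is the (precomputed) Gram
// matrix of the training points; n is small (leave-one-out folds), so the
// dense O(n) selection scan per iteration is the fast regime.
static void smo_solve(const std::vector<double> &K, const std::vector<int> &y,
                      int n, double C, double tol, int maxit,
                      std::vector<double> &alpha, double &b) {
  alpha.assign(n, 0.0);
  std::vector<double> u(n, 0.0); // u_i = sum_j alpha_j y_j K_ij
  const double INF = std::numeric_limits<double>::infinity();
  int it = 0;
  for (; it < maxit; ++it) {
    double m = -INF, M = INF;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      const double v = (double)y[t] - u[t]; // = -E_t
      const bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0.0);
      const bool lo = (y[t] == -1 && alpha[t] < C) || (y[t] == 1 && alpha[t] > 0.0);
      if (up && v > m) { m = v; i = t; }
      if (lo && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < tol) break;
    const double Ei = u[i] - (double)y[i];
    const double Ej = u[j] - (double)y[j];
    double eta = K[(size_t)i * n + i] + K[(size_t)j * n + j] -
                 2.0 * K[(size_t)i * n + j];
    if (eta < 1e-12) eta = 1e-12;
    const double s = (double)(y[i] * y[j]);
    double L, H;
    if (s > 0.0) {
      const double g = alpha[i] + alpha[j];
      L = std::max(0.0, g - C); H = std::min(C, g);
    } else {
      const double d = alpha[j] - alpha[i];
      L = std::max(0.0, d); H = std::min(C, C + d);
    }
    double aj = alpha[j] + (double)y[j] * (Ei - Ej) / eta;
    if (aj < L) aj = L; else if (aj > H) aj = H;
    if (std::abs(aj - alpha[j]) < 1e-14) break; // box-bound stall
    double ai = alpha[i] + s * (alpha[j] - aj);
    // snap numerical dust to the box bounds so stale points leave the
    // working sets instead of stalling the violating-pair selection
    if (ai < 1e-12) ai = 0.0; else if (ai > C - 1e-12) ai = C;
    if (aj < 1e-12) aj = 0.0; else if (aj > C - 1e-12) aj = C;
    const double di = (ai - alpha[i]) * (double)y[i];
    const double dj = (aj - alpha[j]) * (double)y[j];
    for (int t = 0; t < n; ++t)
      u[t] += di * K[(size_t)i * n + t] + dj * K[(size_t)j * n + t];
    alpha[i] = ai; alpha[j] = aj;
  }
  // Bias from free support vectors (y_i (u_i + b) = 1), else KKT midpoint.
  double acc = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-10 && alpha[t] < C - 1e-10) {
      acc += (double)y[t] - u[t]; ++nfree;
    }
  if (nfree > 0) {
    b = acc / (double)nfree;
  } else {
    double m = -INF, M = INF;
    for (int t = 0; t < n; ++t) {
      const double v = (double)y[t] - u[t];
      const bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0.0);
      const bool lo = (y[t] == -1 && alpha[t] < C) || (y[t] == 1 && alpha[t] > 0.0);
      if (up && v > m) m = v;
      if (lo && v < M) M = v;
    }
    b = (m + M) / 2.0;
  }
}

// Pooled-variance two-sample t per column of X, groups given by y = -1 / +1
// (t > 0 when the y = -1 group mean is larger). Zero pooled variance gives
// t = 0 for a zero difference, +-1e300 otherwise.
static std::vector<double> pooled_t(const NumericMatrix &X,
                                    const std::vector<int> &y,
                                    const std::vector<int> &rows) {
  const int p = X.ncol();
  int n1 = 0, n2 = 0;
  for (int r : rows) (y[r] == -1 ? n1 : n2)++;
  std::vector<double> t(p);
  for (int c = 0; c < p; ++c) {
    double s1 = 0, s2 = 0, q1 = 0, q2 = 0;
    for (int r : rows) {
      const double v = X(r, c);
      if (y[r] == -1) { s1 += v; q1 += v * v; } else { s2 += v; q2 += v * v; }
    }
    const double m1 = s1 / n1, m2 = s2 / n2;
    const double ss1 = q1 - n1 * m1 * m1, ss2 = q2 - n2 * m2 * m2;
    const double sp2 = (ss1 + ss2) / (double)(n1 + n2 - 2);
    const double d = m1 - m2;
    const double se = std::sqrt(sp2 * (1.0 / n1 + 1.0 / n2));
    if (se > 0.0) t[c] = d / se;
    else t[c] = (d == 0.0) ? 0.0 : (d > 0.0 ? 1e300 : -1e300);
  }
  return t;
}

// Order features by decreasing |t|, ties broken by lower index.
static std::vector<int> t_order(const std::vector<double> &t) {
  std::vector<int> ord(t.size());
  for (size_t i = 0; i < t.size(); ++i) ord[i] = (int)i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return std::abs(t[a]) > std::abs(t[b]);
  });
  return ord;
}

// [[Rcpp::export(name = ".cpp_pooled_t")]]
NumericVector cpp_pooled_t(NumericMatrix X, IntegerVector y) {
  std::vector<int> yy(y.begin(), y.end());
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  std::vector<double> t = pooled_t(X, yy, rows);
  return wrap(t);
}

// [[Rcpp::export(name = ".cpp_svm_fit")]]
List cpp_svm_fit(NumericMatrix X, IntegerVector y, double C, double tol,
                 int maxit) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> yy(y.begin(), y.end());
  std::vector<double> K((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < p; ++c) s += X(i, c) * X(j, c);
      K[(size_t)i * n + j] = s; K[(size_t)j * n + i] = s;
    }
  std::vector<double> alpha;
  double b = 0.0;
  smo_solve(K, yy, n, C, tol, maxit, alpha, b);
  NumericVector w(p);
  for (int c = 0; c < p; ++c) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += alpha[i] * yy[i] * X(i, c);
    w[c] = s;
  }
  return List::create(_["weights"] = w, _["bias"] = b,
                      _["alpha"] = wrap(alpha));
}

// Leave-one-out decision scores over a grid of top-k feature-subset sizes.
// For each held-out row: rank features by |pooled t| on the training rows
// (nested = true) or once on all rows (nested = false), z-score features on
// the training rows, and fit the SVM on the top-k ranked features for every
// k in `ks`. The Gram matrix and test kernel vector grow incrementally as k
// walks up the ranked list, so the whole grid costs one Gram build per fold.
// Returns the n x length(ks) matrix of held-out decision scores and the
// per-fold feature ranking (1-based).
// [[Rcpp::export(name = ".cpp_loo_grid")]]
List cpp_loo_grid(NumericMatrix X, IntegerVector y, IntegerVector ks,
                  bool nested, double C, double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol(), nk = ks.size();
  std::vector<int> yy(y.begin(), y.end());

  // process ks in increasing order, remember original columns
  std::vector<int> kidx(nk);
  for (int i = 0; i < nk; ++i) kidx[i] = i;
  std::stable_sort(kidx.begin(), kidx.end(),
                   [&](int a, int b) { return ks[a] < ks[b]; });

  std::vector<int> pooled_ord;
  if (!nested) {
    std::vector<int> all(n);
    for (int i = 0; i < n; ++i) all[i] = i;
    pooled_ord = t_order(pooled_t(X, yy, all));
  }

  NumericMatrix scores(n, nk);
  IntegerMatrix orders(n, p);
  const int ntr = n - 1;
  std::vector<int> tr(ntr), ytr(ntr);
  std::vector<double> K((size_t)ntr * ntr), ktest(ntr), z(ntr), alpha;

  for (int f = 0; f < n; ++f) {
    int w = 0;
    for (int i = 0; i < n; ++i)
      if (i != f) { tr[w] = i; ytr[w] = yy[i]; ++w; }

    std::vector<int> ord = nested ? t_order(pooled_t(X, yy, tr)) : pooled_ord;
    for (int c = 0; c < p; ++c) orders(f, c) = ord[c] + 1;

    // training-fold standardization parameters, all features
    std::vector<double> mu(p), sd(p);
    for (int c = 0; c < p; ++c) {
      double s = 0.0, q = 0.0;
      for (int i = 0; i < ntr; ++i) s += X(tr[i], c);
      mu[c] = s / ntr;
      for (int i = 0; i < ntr; ++i) {
        const double d = X(tr[i], c) - mu[c];
        q += d * d;
      }
      sd[c] = std::sqrt(q / (ntr - 1));
      if (sd[c] <= 0.0) sd[c] = 1.0;
    }

    std::fill(K.begin(), K.end(), 0.0);
    std::fill(ktest.begin(), ktest.end(), 0.0);
    int dim = 0;
    double b = 0.0;
    for (int s = 0; s < nk; ++s) {
      const int k = ks[kidx[s]];
      while (dim < k) {
        const int c = ord[dim];
        for (int i = 0; i < ntr; ++i) z[i] = (X(tr[i], c) - mu[c]) / sd[c];
        const double zt = (X(f, c) - mu[c]) / sd[c];
        for (int i = 0; i < ntr; ++i) {
          ktest[i] += z[i] * zt;
          for (int j = i; j < ntr; ++j) {
            K[(size_t)i * ntr + j] += z[i] * z[j];
            if (j != i) K[(size_t)j * ntr + i] = K[(size_t)i * ntr + j];
          }
        }
        ++dim;
      }
      smo_solve(K, ytr, ntr, C, tol, maxit, alpha, b);
      double sc = b;
      for (int i = 0; i < ntr; ++i) sc += alpha[i] * ytr[i] * ktest[i];
      scores(f, kidx[s]) = sc;
    }
  }
  return List::create(_["scores"] = scores, _["orders"] = orders);
}

// Assemble one chromophore's channels x samples signal:
//   amp[c] * reg[t] + global[t] + rowCumsum(drift)[c,t] + noise[c,t]
// where global is AR(1) built from its innovations (marginal SD sdg,
// coefficient phi). drift/noise may be 0 x 0 when disabled. The random
// draws are made by the caller in R, keeping the RNG stream in one place.
// [[Rcpp::export(name = ".cpp_assemble_chrom")]]
NumericMatrix cpp_assemble_chrom(NumericVector amp, NumericVector reg,
                                 NumericVector ginnov, double sdg, double phi,
                                 NumericMatrix drift, NumericMatrix noise) {
  const int C = amp.size(), n = reg.size();
  NumericMatrix out(C, n);
  std::vector<double> g(n, 0.0);
  if (sdg > 0.0) {
    const double sdi = sdg * std::sqrt(1.0 - phi * phi);
    g[0] = sdg * ginnov[0];
    for (int t = 1; t < n; ++t) g[t] = phi * g[t - 1] + sdi * ginnov[t];
  }
  const bool hasDrift = drift.nrow() == C, hasNoise = noise.nrow() == C;
  for (int c = 0; c < C; ++c) {
    double dacc = 0.0;
    for (int t = 0; t < n; ++t) {
      double v = amp[c] * reg[t] + g[t];
      if (hasDrift) { dacc += drift(c, t); v += dacc; }
      if (hasNoise) v += noise(c, t);
      out(c, t) = v;
    }
  }
  return out;
}
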