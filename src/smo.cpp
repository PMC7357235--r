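#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// epsilon-insensitive SVR with an RBF kernel, solved by SMO on the standard
// 2n-variable dual (alpha for the +eps side, alpha* for the -eps side):
//   min 1/2 a' Q a + p' a,  0 <= a_t <= C,  sum_t y_t a_t = 0
// with y_t = +1 (t < n), -1 (t >= n), p_t = eps - y_i resp. eps + y_i and
// Q_st = y_s y_t K(s mod n, t mod n).  Pair selection is the maximal
// violating pair; the two-variable subproblem is solved analytically.

struct SmoResult {
  std::vector<double> beta;
  double bias;
  int iterations;
  bool converged;
};

// K: n x n kernel (column-major, symmetric); a: 2n warm-start alphas
// (modified in place)
static SmoResult smo_solve(const std::vector<double>& K,
                           const double* y, int n, double cost, double eps,
                           double tol, int max_iter,
                           std::vector<double>& a) {
  const int m = 2 * n;
  std::vector<double> G(m);
  // G_t = u_i + eps - y_i (t < n), -u_i + eps + y_i (t >= n),
  // u = K beta with beta_i = a_i - a_{n+i}
  {
    std::vector<double> beta(n);
    for (int i = 0; i < n; ++i) beta[i] = a[i] - a[n + i];
    for (int i = 0; i < n; ++i) {
      double u = 0.0;
      const double* Ki = &K[(size_t)i * n];
      for (int j = 0; j < n; ++j) u += Ki[j] * beta[j];
      G[i] = u + eps - y[i];
      G[n + i] = -u + eps + y[i];
    }
  }
  const auto lab = [n](int t) { return t < n ? 1.0 : -1.0; };

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    double Gmax = -INFINITY, Gmin = INFINITY;
    int ii = -1, jj = -1;
    for (int t = 0; t < m; ++t) {
      double yt = lab(t), v = -yt * G[t];
      bool up = (yt > 0) ? (a[t] < cost) : (a[t] > 0);
      bool low = (yt > 0) ? (a[t] > 0) : (a[t] < cost);
      if (up && v > Gmax) { Gmax = v; ii = t; }
      if (low && v < Gmin) { Gmin = v; jj = t; }
    }
    if (ii < 0 || jj < 0 || Gmax - Gmin < tol) break;

    const int i = ii, j = jj;
    const double yi = lab(i), yj = lab(j);
    const int ri = i % n, rj = j % n;
    double quad = K[(size_t)ri * n + ri] + K[(size_t)rj * n + rj] -
                  2.0 * K[(size_t)ri * n + rj];
    if (quad < 1e-12) quad = 1e-12;
    // move a_i += yi * t, a_j -= yj * t; descent along t > 0
    double b = yi * G[i] - yj * G[j];  // < 0 at a violating pair
    double t = -b / quad;
    double thi = (yi > 0) ? (cost - a[i]) : a[i];
    double tlo1 = (yi > 0) ? -a[i] : a[i] - cost;
    double thi2 = (yj > 0) ? a[j] : (cost - a[j]);
    double tlo2 = (yj > 0) ? a[j] - cost : -a[j];
    double hi = std::min(thi, thi2), lo = std::max(tlo1, tlo2);
    if (t > hi) t = hi;
    if (t < lo) t = lo;
    a[i] += yi * t;
    a[j] -= yj * t;
    // beta_ri changes by +t and beta_rj by -t, whatever the halves
    const double* Kri = &K[(size_t)ri * n];
    const double* Krj = &K[(size_t)rj * n];
    for (int s = 0; s < n; ++s) {
      double d = (Kri[s] - Krj[s]) * t;
      G[s] += d;
      G[n + s] -= d;
    }
  }

  SmoResult res;
  res.iterations = iter;
  res.converged = iter < max_iter;
  res.beta.resize(n);
  for (int i = 0; i < n; ++i) res.beta[i] = a[i] - a[n + i];
  // bias from the KKT estimate at free variables, else interval midpoint
  double bsum = 0.0;
  int nfree = 0;
  double ub = INFINITY, lb = -INFINITY;
  for (int t = 0; t < m; ++t) {
    double yt = lab(t), v = -yt * G[t];
    if (a[t] > 0 && a[t] < cost) {
      bsum += v;
      ++nfree;
    } else {
      // KKT: v over I_up bounds the bias from below, v over I_low from
      // above (b in [max_{I_up} v, min_{I_low} v] at optimality)
      bool up = (yt > 0) ? (a[t] < cost) : (a[t] > 0);
      bool low = (yt > 0) ? (a[t] > 0) : (a[t] < cost);
      if (up && v > lb) lb = v;
      if (low && v < ub) ub = v;
    }
  }
  if (nfree > 0) res.bias = bsum / nfree;
  else if (R_finite(ub) && R_finite(lb)) res.bias = (ub + lb) / 2.0;
  else if (R_finite(ub)) res.bias = ub;
  else if (R_finite(lb)) res.bias = lb;
  else res.bias = 0.0;
  return res;
}

static void rbf_kernel(const std::vector<double>& X, int n, int p,
                       double gamma, std::vector<double>& K) {
  K.assign((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        double d = X[(size_t)k * n + i] - X[(size_t)k * n + j];
        s += d * d;
      }
      double kv = std::exp(-gamma * s);
      K[(size_t)i * n + j] = kv;
      K[(size_t)j * n + i] = kv;
    }
  }
}

// [[Rcpp::export(name = ".smo_fit")]]
List smo_fit(NumericMatrix X, NumericVector y, double cost, double eps,
             double gamma, double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> Xv(X.begin(), X.end());
  std::vector<double> K;
  rbf_kernel(Xv, n, p, gamma, K);
  std::vector<double> a(2 * n, 0.0);
  SmoResult r = smo_solve(K, REAL(y), n, cost, eps, tol, max_iter, a);
  return List::create(_["beta"] = NumericVector(r.beta.begin(), r.beta.end()),
                      _["bias"] = r.bias, _["iterations"] = r.iterations,
                      _["converged"] = r.converged);
}

// [[Rcpp::export(name = ".rbf_predict")]]
NumericVector rbf_predict(NumericMatrix Xtrain, NumericVector beta,
                          double bias, double gamma, NumericMatrix Xnew) {
  const int n = Xtrain.nrow(), p = Xtrain.ncol(), q = Xnew.nrow();
  NumericVector out(q);
  for (int i = 0; i < q; ++i) {
    double s = bias;
    for (int j = 0; j < n; ++j) {
      if (beta[j] == 0.0) continue;
      double d2 = 0.0;
      for (int k = 0; k < p; ++k) {
        double d = Xnew(i, k) - Xtrain(j, k);
        d2 += d * d;
      }
      s += beta[j] * std::exp(-gamma * d2);
    }
    out[i] = s;
  }
  return out;
}

// Leave-one-out CV with warm-started folds: the full-data dual solution,
// with the held-out point's alphas removed (and the equality constraint
// repaired), seeds each fold's solver.  Standardization statistics
// (mean, population sd; constant columns -> unit scale) are recomputed
// from each fold's training rows.  Returns the out-of-fold predictions.
// [[Rcpp::export(name = ".smo_loocv")]]
List smo_loocv(NumericMatrix X, NumericVector y, double cost, double eps,
               double gamma, double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol();
  const double* xp = X.begin();
  const double* yp = REAL(y);

  // full-data standardization + solve (cold)
  std::vector<double> ctr(p), scl(p);
  std::vector<double> Xs((size_t)n * p);
  for (int k = 0; k < p; ++k) {
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double v = xp[(size_t)k * n + i];
      s += v;
      s2 += v * v;
    }
    double mu = s / n, var = s2 / n - mu * mu;
    if (var < 0) var = 0;
    double sd = std::sqrt(var);
    if (!(sd > 1e-12)) sd = 1.0;
    ctr[k] = mu;
    scl[k] = sd;
    for (int i = 0; i < n; ++i)
      Xs[(size_t)k * n + i] = (xp[(size_t)k * n + i] - mu) / sd;
  }
  std::vector<double> K;
  rbf_kernel(Xs, n, p, gamma, K);
  std::vector<double> a_full(2 * n, 0.0);
  SmoResult full = smo_solve(K, yp, n, cost, eps, tol, max_iter, a_full);
  if (!full.converged)
    return List::create(_["converged"] = false, _["fold"] = 0);

  NumericVector pred(n);
  long total_iter = full.iterations;
  const int nf = n - 1;
  std::vector<double> Xf((size_t)nf * p), yf(nf), Kf, af(2 * nf),
      xnew(p);
  for (int hold = 0; hold < n; ++hold) {
    // fold standardization from training rows
    for (int k = 0; k < p; ++k) {
      double s = 0.0, s2 = 0.0;
      for (int i = 0; i < n; ++i) {
        if (i == hold) continue;
        double v = xp[(size_t)k * n + i];
        s += v;
        s2 += v * v;
      }
      double mu = s / nf, var = s2 / nf - mu * mu;
      if (var < 0) var = 0;
      double sd = std::sqrt(var);
      if (!(sd > 1e-12)) sd = 1.0;
      int r = 0;
      for (int i = 0; i < n; ++i) {
        if (i == hold) continue;
        Xf[(size_t)k * nf + r] = (xp[(size_t)k * n + i] - mu) / sd;
        ++r;
      }
      xnew[k] = (xp[(size_t)k * n + hold] - mu) / sd;
    }
    int r = 0;
    for (int i = 0; i < n; ++i)
      if (i != hold) yf[r++] = yp[i];

    // warm start: drop the held-out alphas, then repair sum y_t a_t = 0
    r = 0;
    for (int i = 0; i < n; ++i) {
      if (i == hold) continue;
      af[r] = a_full[i];
      af[nf + r] = a_full[n + i];
      ++r;
    }
    double s = 0.0;
    for (int t = 0; t < nf; ++t) s += af[t] - af[nf + t];
    if (s > 0) {
      for (int t = 0; t < nf && s > 0; ++t) {
        double d = af[t] < s ? af[t] : s;
        af[t] -= d;
        s -= d;
      }
    } else if (s < 0) {
      double def = -s;
      for (int t = 0; t < nf && def > 0; ++t) {
        double d = af[nf + t] < def ? af[nf + t] : def;
        af[nf + t] -= d;
        def -= d;
      }
    }

    rbf_kernel(Xf, nf, p, gamma, Kf);
    SmoResult fr = smo_solve(Kf, yf.data(), nf, cost, eps, tol, max_iter,
                             af);
    if (!fr.converged)
      return List::create(_["converged"] = false, _["fold"] = hold + 1);
    total_iter += fr.iterations;

    double u = fr.bias;
    for (int j = 0; j < nf; ++j) {
      if (fr.beta[j] == 0.0) continue;
      double d2 = 0.0;
      for (int k = 0; k < p; ++k) {
        double d = xnew[k] - Xf[(size_t)k * nf + j];
        d2 += d * d;
      }
      u += fr.beta[j] * std::exp(-gamma * d2);
    }
    pred[hold] = u;
  }
  return List::create(_["converged"] = true, _["predicted"] = pred,
                      _["iterations"] = (double)total_iter);
}
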