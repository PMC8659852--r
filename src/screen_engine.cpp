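// Leave-one-out cross-validation engine for the feature-combination screen.
//
// The exhaustive screen evaluates every size-1/2/3 feature combination against a
// nine-member classifier bank (k-NN with k in {1,3,5}; linear soft-margin SVM and
// L2-penalised logistic regression with C in {0.1,1,10}) under LOOCV.  With ~66
// feature columns this is >1e6 classifier fits of ~20-sample folds, so the whole
// loop lives here.  All solvers are deterministic: k-NN breaks distance ties by
// the smallest training index, the SVM solves the standard C-SVM dual by SMO with
// a libsvm-style intercept rule, and the logistic solver is a damped Newton method.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// families encoded from R: 1 = knn (par = k), 2 = svm (par = C), 3 = logistic (par = C)

// ---------------------------------------------------------------------------
// small dense solver: A (d x d, row-major) x = b, Gaussian elimination with
// partial pivoting.  d <= 4 in practice.
static bool solve_dense(std::vector<double> A, std::vector<double> b,
                        std::vector<double>& x, int d) {
  for (int col = 0; col < d; ++col) {
    int piv = col;
    double best = std::fabs(A[col * d + col]);
    for (int r = col + 1; r < d; ++r) {
      double v = std::fabs(A[r * d + col]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-300) return false;
    if (piv != col) {
      for (int c = 0; c < d; ++c) std::swap(A[col * d + c], A[piv * d + c]);
      std::swap(b[col], b[piv]);
    }
    double diag = A[col * d + col];
    for (int r = col + 1; r < d; ++r) {
      double f = A[r * d + col] / diag;
      if (f == 0.0) continue;
      for (int c = col; c < d; ++c) A[r * d + c] -= f * A[col * d + c];
      b[r] -= f * b[col];
    }
  }
  x.assign(d, 0.0);
  for (int r = d - 1; r >= 0; --r) {
    double s = b[r];
    for (int c = r + 1; c < d; ++c) s -= A[r * d + c] * x[c];
    x[r] = s / A[r * d + r];
  }
  return true;
}

// ---------------------------------------------------------------------------
// C-SVM dual via SMO (Platt's working-set heuristic, deterministic scan order).
// K: n x n linear-kernel Gram matrix (row-major), y in {-1,+1}.
static void svm_smo(const std::vector<double>& K, const std::vector<int>& y,
                    int n, double C, std::vector<double>& alpha, double& b) {
  alpha.assign(n, 0.0);
  b = 0.0;
  const double tol = 1e-6, eps = 1e-12;
  // cached margin values F_i = sum_j alpha_j y_j K_ij (without the intercept),
  // updated incrementally after every alpha step
  std::vector<double> F(n, 0.0);

  auto take_step = [&](int i, int j) -> bool {
    if (i == j) return false;
    double Ei = F[i] + b - y[i];
    double Ej = F[j] + b - y[j];
    double ai_old = alpha[i], aj_old = alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (H - L < eps) return false;
    double eta = 2.0 * K[i * n + j] - K[i * n + i] - K[j * n + j];
    if (eta >= -1e-14) return false;
    double aj = aj_old - y[j] * (Ei - Ej) / eta;
    aj = std::min(H, std::max(L, aj));
    if (std::fabs(aj - aj_old) < 1e-10 * (aj + aj_old + 1e-10)) return false;
    double ai = ai_old + y[i] * y[j] * (aj_old - aj);
    alpha[i] = ai; alpha[j] = aj;
    double di = (ai - ai_old) * y[i], dj = (aj - aj_old) * y[j];
    for (int m = 0; m < n; ++m) F[m] += di * K[i * n + m] + dj * K[j * n + m];
    double b1 = b - Ei - di * K[i * n + i] - dj * K[i * n + j];
    double b2 = b - Ej - di * K[i * n + j] - dj * K[j * n + j];
    if (ai > eps && ai < C - eps) b = b1;
    else if (aj > eps && aj < C - eps) b = b2;
    else b = 0.5 * (b1 + b2);
    return true;
  };

  // maximal-violating-pair outer loop: with -y_i grad_i = y_i - F_i, optimality
  // holds when max over the "up" set minus min over the "down" set is < tol
  long iter = 0, max_iter = 50000;
  while (iter++ < max_iter) {
    int i_up = -1, j_low = -1;
    double m_up = -std::numeric_limits<double>::infinity();
    double m_low = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = y[t] - F[t];
      bool in_up = (y[t] > 0 && alpha[t] < C - eps) || (y[t] < 0 && alpha[t] > eps);
      bool in_low = (y[t] < 0 && alpha[t] < C - eps) || (y[t] > 0 && alpha[t] > eps);
      if (in_up && v > m_up) { m_up = v; i_up = t; }
      if (in_low && v < m_low) { m_low = v; j_low = t; }
    }
    if (i_up < 0 || j_low < 0 || m_up - m_low < tol) break;
    if (!take_step(i_up, j_low)) {
      // degenerate pair (duplicated points); try any productive partner
      bool moved = false;
      for (int j = 0; j < n && !moved; ++j) moved = take_step(i_up, j);
      if (!moved) break;
    }
  }
  // final intercept, libsvm-style: average over free SVs, else midpoint of the
  // feasible interval from the bound KKT conditions.
  double sum_free = 0.0; int n_free = 0;
  double lb = -std::numeric_limits<double>::infinity();
  double ub = std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i) {
    double fi = F[i];
    if (alpha[i] > eps && alpha[i] < C - eps) { sum_free += y[i] - fi; ++n_free; }
    else if (alpha[i] <= eps) {
      if (y[i] > 0) lb = std::max(lb, 1.0 - fi); else ub = std::min(ub, -1.0 - fi);
    } else { // alpha == C
      if (y[i] > 0) ub = std::min(ub, 1.0 - fi); else lb = std::max(lb, -1.0 - fi);
    }
  }
  if (n_free > 0) b = sum_free / n_free;
  else if (std::isfinite(lb) && std::isfinite(ub)) b = 0.5 * (lb + ub);
  else if (std::isfinite(lb)) b = lb;
  else if (std::isfinite(ub)) b = ub;
}

// ---------------------------------------------------------------------------
// L2-penalised logistic regression, sklearn/glmnet-compatible objective:
//   min_w,b  0.5 * ||w||^2 + C * sum_i log(1 + exp(-y_i (w'x_i + b)))
// (intercept unpenalised).  Damped Newton, start at 0.
static void logistic_newton(const std::vector<double>& X, const std::vector<int>& y,
                            int n, int p, double C, std::vector<double>& wb) {
  int d = p + 1; // w_1..w_p, b
  wb.assign(d, 0.0);
  auto obj = [&](const std::vector<double>& v) {
    double pen = 0.0;
    for (int j = 0; j < p; ++j) pen += v[j] * v[j];
    double loss = 0.0;
    for (int i = 0; i < n; ++i) {
      double f = v[p];
      for (int j = 0; j < p; ++j) f += v[j] * X[i * p + j];
      double m = -y[i] * f;
      loss += (m > 30.0) ? m : std::log1p(std::exp(m));
    }
    return 0.5 * pen + C * loss;
  };
  double cur = obj(wb);
  for (int it = 0; it < 100; ++it) {
    std::vector<double> g(d, 0.0), Hm(d * d, 0.0);
    for (int j = 0; j < p; ++j) { g[j] = wb[j]; Hm[j * d + j] = 1.0; }
    for (int i = 0; i < n; ++i) {
      double f = wb[p];
      for (int j = 0; j < p; ++j) f += wb[j] * X[i * p + j];
      double z = y[i] * f;
      double s = 1.0 / (1.0 + std::exp(z));      // sigma(-z)
      double wgt = s * (1.0 - s);                 // Hessian weight
      double gi = -C * y[i] * s;
      for (int j = 0; j < p; ++j) g[j] += gi * X[i * p + j];
      g[p] += gi;
      for (int a = 0; a < d; ++a) {
        double xa = (a < p) ? X[i * p + a] : 1.0;
        for (int bcol = a; bcol < d; ++bcol) {
          double xb = (bcol < p) ? X[i * p + bcol] : 1.0;
          Hm[a * d + bcol] += C * wgt * xa * xb;
        }
      }
    }
    for (int a = 0; a < d; ++a)
      for (int bcol = 0; bcol < a; ++bcol) Hm[a * d + bcol] = Hm[bcol * d + a];
    double gnorm = 0.0;
    for (int a = 0; a < d; ++a) gnorm += g[a] * g[a];
    if (std::sqrt(gnorm) < 1e-10) break;
    std::vector<double> step;
    if (!solve_dense(Hm, g, step, d)) break;
    double t = 1.0;
    bool ok = false;
    for (int h = 0; h < 30; ++h) {
      std::vector<double> trial(wb);
      for (int a = 0; a < d; ++a) trial[a] -= t * step[a];
      double v = obj(trial);
      if (v <= cur + 1e-14) { wb = trial; cur = v; ok = true; break; }
      t *= 0.5;
    }
    if (!ok) break;
  }
}

// ---------------------------------------------------------------------------
// k-NN vote on standardized features; distance ties -> smallest training index
// (stable sort on (distance, index)); returns predicted label in {-1,+1}.
static int knn_predict(const std::vector<double>& Xtr, const std::vector<int>& ytr,
                       int ntr, int p, const std::vector<double>& xte, int k) {
  std::vector<std::pair<double, int> > d(ntr);
  for (int i = 0; i < ntr; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) {
      double diff = Xtr[i * p + j] - xte[j];
      s += diff * diff;
    }
    d[i] = std::make_pair(s, i);
  }
  std::sort(d.begin(), d.end());
  int kk = std::min(k, ntr), vote = 0;
  for (int i = 0; i < kk; ++i) vote += ytr[d[i].second];
  if (vote > 0) return 1;
  if (vote < 0) return -1;
  return ytr[d[0].second]; // even-vote fallback: nearest neighbour decides
}

// ---------------------------------------------------------------------------
// One LOOCV pass of the whole bank on a feature subset.
// X: n x P full matrix (column-major from R), cols: 0-based subset, y: {-1,+1}.
// Missing values (NA) are imputed with training-fold means; features are
// z-scored with training-fold statistics (constant/all-missing -> zero column).
// preds: nbank x n predicted labels.
static void loocv_bank(const NumericMatrix& X, const std::vector<int>& y,
                       const std::vector<int>& cols,
                       const std::vector<int>& fam, const std::vector<double>& par,
                       std::vector<int>& preds) {
  const int n = X.nrow();
  const int p = (int)cols.size();
  const int nbank = (int)fam.size();
  preds.assign(nbank * n, 0);

  std::vector<double> Xtr(std::max(1, (n - 1) * p)), xte(p);
  std::vector<int> ytr(std::max(1, n - 1));

  for (int hold = 0; hold < n; ++hold) {
    int ntr = 0;
    // training-fold mean / sd per feature, NA-aware
    std::vector<double> mu(p, 0.0), sd(p, 0.0);
    for (int j = 0; j < p; ++j) {
      double s = 0.0, s2 = 0.0; int m = 0;
      for (int i = 0; i < n; ++i) {
        if (i == hold) continue;
        double v = X(i, cols[j]);
        if (ISNAN(v)) continue;
        s += v; s2 += v * v; ++m;
      }
      if (m > 0) {
        mu[j] = s / m;
        double var = (m > 1) ? (s2 - s * s / m) / (m - 1) : 0.0;
        sd[j] = (var > 0.0) ? std::sqrt(var) : 0.0;
      } else { mu[j] = 0.0; sd[j] = 0.0; }
    }
    ntr = 0;
    for (int i = 0; i < n; ++i) {
      if (i == hold) continue;
      for (int j = 0; j < p; ++j) {
        double v = X(i, cols[j]);
        if (ISNAN(v)) v = mu[j];
        Xtr[ntr * p + j] = (sd[j] > 0.0) ? (v - mu[j]) / sd[j] : 0.0;
      }
      ytr[ntr] = y[i];
      ++ntr;
    }
    for (int j = 0; j < p; ++j) {
      double v = X(hold, cols[j]);
      if (ISNAN(v)) v = mu[j];
      xte[j] = (sd[j] > 0.0) ? (v - mu[j]) / sd[j] : 0.0;
    }
    // single-class fold -> majority-class prediction for every bank member
    int npos = 0;
    for (int i = 0; i < ntr; ++i) if (ytr[i] > 0) ++npos;
    if (npos == 0 || npos == ntr) {
      int maj = (npos > ntr - npos) ? 1 : -1;
      for (int bidx = 0; bidx < nbank; ++bidx) preds[bidx * n + hold] = maj;
      continue;
    }

    // shared Gram matrix for the SVM members
    bool need_svm = false;
    for (int bidx = 0; bidx < nbank; ++bidx) if (fam[bidx] == 2) need_svm = true;
    std::vector<double> K;
    if (need_svm) {
      K.assign(ntr * ntr, 0.0);
      for (int i = 0; i < ntr; ++i)
        for (int j2 = i; j2 < ntr; ++j2) {
          double s = 0.0;
          for (int c = 0; c < p; ++c) s += Xtr[i * p + c] * Xtr[j2 * p + c];
          K[i * ntr + j2] = s; K[j2 * ntr + i] = s;
        }
    }
    for (int bidx = 0; bidx < nbank; ++bidx) {
      int pred = 0;
      if (fam[bidx] == 1) {
        pred = knn_predict(Xtr, ytr, ntr, p, xte, (int)par[bidx]);
      } else if (fam[bidx] == 2) {
        std::vector<double> alpha; double bint;
        svm_smo(K, ytr, ntr, par[bidx], alpha, bint);
        double f = bint;
        for (int i = 0; i < ntr; ++i) {
          if (alpha[i] <= 0.0) continue;
          double dot = 0.0;
          for (int c = 0; c < p; ++c) dot += Xtr[i * p + c] * xte[c];
          f += alpha[i] * ytr[i] * dot;
        }
        pred = (f > 0.0) ? 1 : -1;
      } else {
        std::vector<double> wb;
        logistic_newton(Xtr, ytr, ntr, p, par[bidx], wb);
        double f = wb[p];
        for (int c = 0; c < p; ++c) f += wb[c] * xte[c];
        pred = (f > 0.0) ? 1 : -1;
      }
      preds[bidx * n + hold] = pred;
    }
  }
}

// direct single-fit entry points (used by the test suite to compare the
// solvers against independent implementations)

// [[Rcpp::export]]
List cpp_svm_fit(NumericMatrix X, IntegerVector ypm, double C) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> y(ypm.begin(), ypm.end());
  std::vector<double> K(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < p; ++c) s += X(i, c) * X(j, c);
      K[i * n + j] = s; K[j * n + i] = s;
    }
  std::vector<double> alpha; double b;
  svm_smo(K, y, n, C, alpha, b);
  NumericVector w(p);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < p; ++c) w[c] += alpha[i] * y[i] * X(i, c);
  double obj = 0.0;
  for (int c = 0; c < p; ++c) obj += 0.5 * w[c] * w[c];
  for (int i = 0; i < n; ++i) {
    double f = b;
    for (int c = 0; c < p; ++c) f += w[c] * X(i, c);
    obj += C * std::max(0.0, 1.0 - y[i] * f);
  }
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["w"] = w, _["objective"] = obj);
}

// [[Rcpp::export]]
List cpp_logistic_fit(NumericMatrix X, IntegerVector ypm, double C) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> y(ypm.begin(), ypm.end());
  std::vector<double> Xv(n * p);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < p; ++c) Xv[i * p + c] = X(i, c);
  std::vector<double> wb;
  logistic_newton(Xv, y, n, p, C, wb);
  return List::create(_["w"] = NumericVector(wb.begin(), wb.begin() + p),
                      _["b"] = wb[p]);
}

// [[Rcpp::export]]
NumericMatrix cpp_screen_engine(NumericMatrix X, IntegerVector ypm,
                                IntegerMatrix combos, IntegerVector fam,
                                NumericVector par) {
  const int n = X.nrow();
  const int ncomb = combos.ncol();
  const int nbank = fam.size();
  std::vector<int> y(n);
  for (int i = 0; i < n; ++i) y[i] = ypm[i];
  std::vector<int> famv(fam.begin(), fam.end());
  std::vector<double> parv(par.begin(), par.end());
  NumericMatrix acc(ncomb, nbank);
  std::vector<int> preds;
  for (int c = 0; c < ncomb; ++c) {
    std::vector<int> cols(combos.nrow());
    for (int j = 0; j < combos.nrow(); ++j) cols[j] = combos(j, c);
    loocv_bank(X, y, cols, famv, parv, preds);
    for (int bidx = 0; bidx < nbank; ++bidx) {
      int correct = 0;
      for (int i = 0; i < n; ++i) if (preds[bidx * n + i] == y[i]) ++correct;
      acc(c, bidx) = (double)correct / n;
    }
    if (c % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return acc;
}

// [[Rcpp::export]]
List cpp_loocv_detail(NumericMatrix X, IntegerVector ypm, IntegerVector cols,
                      IntegerVector fam, NumericVector par) {
  const int n = X.nrow();
  std::vector<int> y(n);
  for (int i = 0; i < n; ++i) y[i] = ypm[i];
  std::vector<int> colv(cols.begin(), cols.end());
  std::vector<int> famv(fam.begin(), fam.end());
  std::vector<double> parv(par.begin(), par.end());
  std::vector<int> preds;
  loocv_bank(X, y, colv, famv, parv, preds);
  const int nbank = fam.size();
  IntegerMatrix P(nbank, n);
  NumericVector acc(nbank);
  for (int bidx = 0; bidx < nbank; ++bidx) {
    int correct = 0;
    for (int i = 0; i < n; ++i) {
      P(bidx, i) = preds[bidx * n + i];
      if (preds[bidx * n + i] == y[i]) ++correct;
    }
    acc[bidx] = (double)correct / n;
  }
  return List::create(_["accuracy"] = acc, _["predictions"] = P);
}
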