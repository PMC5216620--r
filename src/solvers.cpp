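// Dual coordinate-descent solvers for linear eps-SVR and linear SVM
// (LIBLINEAR-style, with the bias folded into the kernel as a +1 term and
// therefore L2-regularized), plus the full nested leave-one-out
// cross-validation feature-selection / prediction loop, which is far too
// hot for R when wrapped in a permutation test.
//
// SVR dual (beta = alpha+ - alpha-):
//   min_beta 0.5 beta' Q beta - y' beta + eps * sum|beta_i|,  |beta_i| <= C
// with Q_ij = x_i . x_j + 1.  Predictions f(x) = sum_i beta_i (x_i . x + 1).
//
// SVM dual: min 0.5 a' Qb a - e' a, 0 <= a_i <= C, Qb_ij = y_i y_j Q_ij;
// decision f(x) = sum_i a_i y_i (x_i . x + 1).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstddef>
using namespace Rcpp;

static long g_sweeps = 0, g_fits = 0;

// Deterministic xorshift PRNG for the sweep permutations (seeded with a
// fixed constant per solve, so results are reproducible and independent of
// the data).
static inline unsigned int xs_next(unsigned int& st) {
  st ^= st << 13; st ^= st >> 17; st ^= st << 5;
  return st;
}

// One problem: Gram matrix Q (n x n), targets yc; beta and qb = Q beta are
// maintained by the caller so warm starts across nested problems are cheap.
//
// Stopping rule: maximum projected-gradient violation over a sweep < tol
// (LIBLINEAR-style), with shrinking of optimal coordinates and a final full
// verification pass.  Sweeps visit coordinates in a deterministic
// pseudo-random permutation, which breaks the slow cycling of plain cyclic
// CD on the (rank-deficient) Gram matrices that arise with few features.
static int svr_cd(const std::vector<double>& Q, int n, const double* yc,
                  double C, double eps, std::vector<double>& beta,
                  std::vector<double>& qb, double tol, int max_sweeps,
                  std::vector<char>& active, std::vector<int>& perm,
                  bool reset_active = true) {
  if (reset_active || (int)active.size() != n) active.assign(n, 1);
  perm.resize(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  unsigned int rng = 88172645u;
  int sweeps = 0;
  bool verify = false;
  for (; sweeps < max_sweeps; ++sweeps) {
    const bool full = verify;
    // Fisher-Yates with the deterministic PRNG
    for (int i = n - 1; i > 0; --i) {
      const int j = (int)(xs_next(rng) % (unsigned)(i + 1));
      const int t = perm[i]; perm[i] = perm[j]; perm[j] = t;
    }
    double maxv = 0.0;
    for (int ii = 0; ii < n; ++ii) {
      const int i = perm[ii];
      if (!full && !active[i]) continue;
      const double Qii = Q[(std::size_t)i * n + i];
      if (Qii <= 1e-12) { if (!full) active[i] = 0; continue; }
      const double G = qb[i] - yc[i];
      const double bi = beta[i];
      // projected-gradient violation
      double v;
      if (bi >= C)       v = (G + eps > 0.0) ? (G + eps) : 0.0;
      else if (bi <= -C) v = (G - eps < 0.0) ? -(G - eps) : 0.0;
      else if (bi > 0.0) v = std::fabs(G + eps);
      else if (bi < 0.0) v = std::fabs(G - eps);
      else { const double a = std::fabs(G) - eps; v = (a > 0.0) ? a : 0.0; }
      if (v <= tol) {
        if (!full && v == 0.0) active[i] = 0;
        if (v > maxv) maxv = v;
        continue;
      }
      if (v > maxv) maxv = v;
      double s;
      const double sp = bi - (G + eps) / Qii;
      if (sp > 0.0) s = sp;
      else {
        const double sn = bi - (G - eps) / Qii;
        s = (sn < 0.0) ? sn : 0.0;
      }
      if (s > C) s = C; else if (s < -C) s = -C;
      const double d = s - bi;
      if (d != 0.0) {
        beta[i] = s;
        active[i] = 1;
        const double* qcol = &Q[(std::size_t)i * n];
        for (int r = 0; r < n; ++r) qb[r] += d * qcol[r];
      }
    }
    if (full) {
      if (maxv <= tol) { ++sweeps; break; }
      verify = false;               // violations found: keep iterating
    } else if (maxv <= tol) {
      verify = true;                // active set converged: verify all
    }
  }
  return sweeps;
}

// SVR projected-gradient violation and optimal coordinate step.
static inline double svr_violation(double G, double bi, double C,
                                   double eps) {
  if (bi >= C)       return (G + eps > 0.0) ? (G + eps) : 0.0;
  if (bi <= -C)      return (G - eps < 0.0) ? -(G - eps) : 0.0;
  if (bi > 0.0)      return std::fabs(G + eps);
  if (bi < 0.0)      return std::fabs(G - eps);
  const double a = std::fabs(G) - eps;
  return (a > 0.0) ? a : 0.0;
}

static inline double svr_step(double G, double bi, double Qii, double C,
                              double eps) {
  double s;
  const double sp = bi - (G + eps) / Qii;
  if (sp > 0.0) s = sp;
  else {
    const double sn = bi - (G - eps) / Qii;
    s = (sn < 0.0) ? sn : 0.0;
  }
  if (s > C) s = C; else if (s < -C) s = -C;
  return s;
}

// Hybrid solver: a few full permuted sweeps move the bulk of the dual
// variables to their bounds, then greedy (Gauss-Southwell) single-coordinate
// updates fine-position the free support vectors, which is where plain
// sweeps crawl when the eps tube is thin.  Iteration count is returned in
// sweep-equivalents.  Fully deterministic (greedy ties -> smallest index).
static int svr_solve(const std::vector<double>& Q, int n, const double* yc,
                     double C, double eps, std::vector<double>& beta,
                     std::vector<double>& qb, double tol, int max_sweeps,
                     std::vector<char>& active, std::vector<int>& perm,
                     bool warm = false) {
  const int bulk = warm ? 1 : 3;
  int sweeps = svr_cd(Q, n, yc, C, eps, beta, qb, tol, bulk, active, perm,
                      !warm);
  long iters = 0;
  const long max_iters = (long)max_sweeps * n;
  while (iters < max_iters) {
    double maxv = 0.0;
    int best = -1;
    for (int i = 0; i < n; ++i) {
      if (Q[(std::size_t)i * n + i] <= 1e-12) continue;
      const double v = svr_violation(qb[i] - yc[i], beta[i], C, eps);
      if (v > maxv) { maxv = v; best = i; }
    }
    if (maxv <= tol || best < 0) break;
    const double bi = beta[best];
    const double s = svr_step(qb[best] - yc[best], bi,
                              Q[(std::size_t)best * n + best], C, eps);
    const double d = s - bi;
    if (d == 0.0) break;   // numerically stuck: violation cannot be reduced
    beta[best] = s;
    const double* qcol = &Q[(std::size_t)best * n];
    for (int r = 0; r < n; ++r) qb[r] += d * qcol[r];
    ++iters;
  }
  return sweeps + (int)(iters / (n > 0 ? n : 1)) + 1;
}

static int svm_cd(const std::vector<double>& Q, int n, const double* ysign,
                  double C, std::vector<double>& alpha,
                  std::vector<double>& qa, double tol, int max_sweeps) {
  // qa[i] = sum_j Q_ij y_j alpha_j, so the dual gradient of coordinate i is
  // y_i qa[i] - 1.  Same permutation + violation scheme as svr_cd.
  std::vector<char> active(n, 1);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  unsigned int rng = 123456789u;
  int sweeps = 0;
  bool verify = false;
  for (; sweeps < max_sweeps; ++sweeps) {
    const bool full = verify;
    for (int i = n - 1; i > 0; --i) {
      const int j = (int)(xs_next(rng) % (unsigned)(i + 1));
      const int t = perm[i]; perm[i] = perm[j]; perm[j] = t;
    }
    double maxv = 0.0;
    for (int ii = 0; ii < n; ++ii) {
      const int i = perm[ii];
      if (!full && !active[i]) continue;
      const double Qii = Q[(std::size_t)i * n + i];
      const double G = ysign[i] * qa[i] - 1.0;
      const double ai = alpha[i];
      double v;
      if (ai <= 0.0)     v = (G < 0.0) ? -G : 0.0;
      else if (ai >= C)  v = (G > 0.0) ? G : 0.0;
      else               v = std::fabs(G);
      if (v <= tol) {
        if (!full && v == 0.0) active[i] = 0;
        if (v > maxv) maxv = v;
        continue;
      }
      if (v > maxv) maxv = v;
      double a = ai - G / Qii;
      if (a < 0.0) a = 0.0; else if (a > C) a = C;
      const double d = a - ai;
      if (d != 0.0) {
        alpha[i] = a;
        active[i] = 1;
        const double dy = d * ysign[i];
        const double* qcol = &Q[(std::size_t)i * n];
        for (int r = 0; r < n; ++r) qa[r] += dy * qcol[r];
      }
    }
    if (full) {
      if (maxv <= tol) { ++sweeps; break; }
      verify = false;
    } else if (maxv <= tol) {
      verify = true;
    }
  }
  return sweeps;
}

static void gram_plus_one(const std::vector<double>& X, int n, int p,
                          std::vector<double>& Q, double bias = 1.0) {
  Q.assign((std::size_t)n * n, bias);
  for (int c = 0; c < p; ++c) {
    const double* xc = &X[(std::size_t)c * n];
    for (int i = 0; i < n; ++i) {
      const double xi = xc[i];
      if (xi == 0.0) continue;
      double* qrow = &Q[(std::size_t)i * n];
      for (int j = 0; j < n; ++j) qrow[j] += xi * xc[j];
    }
  }
}

// [[Rcpp::export]]
List cpp_svr_fit(NumericMatrix X, NumericVector y, double C, double eps,
                 double tol = 1e-10, int max_sweeps = 5000,
                 bool bias = true) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> Xv(X.begin(), X.end());
  std::vector<double> Q;
  gram_plus_one(Xv, n, p, Q, bias ? 1.0 : 0.0);
  std::vector<double> beta(n, 0.0), qb(n, 0.0);
  std::vector<char> act;
  std::vector<int> perm;
  int sweeps = svr_solve(Q, n, REAL(y), C, eps, beta, qb, tol, max_sweeps,
                         act, perm);
  NumericVector w(p);
  double b = 0.0;
  if (bias) for (int i = 0; i < n; ++i) b += beta[i];
  for (int c = 0; c < p; ++c) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += beta[i] * Xv[(std::size_t)c * n + i];
    w[c] = s;
  }
  return List::create(_["w"] = w, _["b"] = b,
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["sweeps"] = sweeps);
}

// [[Rcpp::export]]
List cpp_svm_fit(NumericMatrix X, NumericVector ysign, double C,
                 double tol = 1e-10, int max_sweeps = 5000) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> Xv(X.begin(), X.end());
  std::vector<double> Q;
  gram_plus_one(Xv, n, p, Q);
  std::vector<double> alpha(n, 0.0), qa(n, 0.0);
  int sweeps = svm_cd(Q, n, REAL(ysign), C, alpha, qa, tol, max_sweeps);
  NumericVector w(p);
  double b = 0.0;
  for (int i = 0; i < n; ++i) b += alpha[i] * ysign[i];
  for (int c = 0; c < p; ++c) {
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      s += alpha[i] * ysign[i] * Xv[(std::size_t)c * n + i];
    w[c] = s;
  }
  return List::create(_["w"] = w, _["b"] = b,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["sweeps"] = sweeps);
}

// Pearson correlation; returns NA when either side is constant.
static double pearson(const double* a, const double* b, int n) {
  double ma = 0, mb = 0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double saa = 0, sbb = 0, sab = 0;
  for (int i = 0; i < n; ++i) {
    const double da = a[i] - ma, db = b[i] - mb;
    saa += da * da; sbb += db * db; sab += da * db;
  }
  if (saa <= 0.0 || sbb <= 0.0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

// Stable ranking of features by |corr| descending, index ascending.
static void rank_by_abscorr(const std::vector<double>& absr,
                            std::vector<int>& order) {
  const int F = (int)absr.size();
  order.resize(F);
  for (int f = 0; f < F; ++f) order[f] = f;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return absr[a] > absr[b]; });
}

// Nested LOOCV feature selection + linear eps-SVR prediction.
//
// Outer loop: hold out subject i.  Inner loop over the S-1 training
// subjects: rank features by |corr with age| on the inner-training data,
// train eps-SVR on the top-k standardized features for every k in 1..F
// (warm-started, with rank-1 Gram updates), predict the inner-held-out
// subject.  k* maximizes the inner r(predicted, observed) (ties -> smaller
// k).  The per-inner-fold selections are the top-k* sets; the fold's
// consensus keeps features selected in >= theta of inner folds (fallback:
// top-ranked feature on the outer training set).  The outer model is an
// eps-SVR on the consensus features, standardized and age-centred with
// outer-training statistics only.
// [[Rcpp::export]]
List cpp_mvpa_nested(NumericMatrix X, NumericVector y, double eps, double C,
                     double theta, double tol = 0.1, int max_sweeps = 150) {
  const int S = X.nrow(), F = X.ncol();
  if (S < 4) stop("need at least 4 subjects");
  std::vector<double> Xv(X.begin(), X.end());
  const double* yv = REAL(y);

  NumericVector pred(S);
  IntegerVector kstar(S);
  LogicalVector fallback(S);
  List perfold(S);

  std::vector<int> tr(S - 1);
  const int n = S - 1;        // outer training size
  const int m = n - 1;        // inner training size
  std::vector<double> predin((std::size_t)n * F);
  std::vector<int> rankings((std::size_t)n * F);
  std::vector<int> in(m);
  std::vector<double> mu(F), sdv(F), absr(F);
  std::vector<double> u(m), Q((std::size_t)m * m), beta(m), qb(m), dtest(m),
      yc(m);
  std::vector<int> order, perm;
  std::vector<char> act;

  for (int i = 0; i < S; ++i) {
    {
      int t = 0;
      for (int s = 0; s < S; ++s) if (s != i) tr[t++] = s;
    }
    // ---- inner folds ----
    for (int j = 0; j < n; ++j) {
      const int jj = tr[j];
      {
        int t = 0;
        for (int s = 0; s < n; ++s) if (s != j) in[t++] = tr[s];
      }
      double ymean = 0.0;
      for (int r = 0; r < m; ++r) ymean += yv[in[r]];
      ymean /= m;
      for (int r = 0; r < m; ++r) yc[r] = yv[in[r]] - ymean;
      double ysd = 0.0;
      for (int r = 0; r < m; ++r) ysd += yc[r] * yc[r];

      for (int f = 0; f < F; ++f) {
        const double* xc = &Xv[(std::size_t)f * S];
        double mf = 0.0;
        for (int r = 0; r < m; ++r) mf += xc[in[r]];
        mf /= m;
        double sxx = 0.0, sxy = 0.0;
        for (int r = 0; r < m; ++r) {
          const double d = xc[in[r]] - mf;
          sxx += d * d;
          sxy += d * yc[r];
        }
        mu[f] = mf;
        if (sxx <= 0.0) { sdv[f] = 0.0; absr[f] = 0.0; }
        else {
          sdv[f] = std::sqrt(sxx / (m - 1));
          absr[f] = (ysd <= 0.0) ? 0.0
                    : std::fabs(sxy / std::sqrt(sxx * ysd));
        }
      }
      rank_by_abscorr(absr, order);
      for (int t = 0; t < F; ++t) rankings[(std::size_t)j * F + t] = order[t];

      // incremental Gram over standardized top-k features (no bias term:
      // features are z-scored and y centred, LIBLINEAR convention)
      std::fill(Q.begin(), Q.end(), 0.0);
      std::fill(beta.begin(), beta.end(), 0.0);
      std::fill(qb.begin(), qb.end(), 0.0);
      std::fill(dtest.begin(), dtest.end(), 0.0);
      for (int k = 0; k < F; ++k) {
        const int f = order[k];
        const double* xc = &Xv[(std::size_t)f * S];
        double utest = 0.0;
        if (sdv[f] > 0.0) {
          for (int r = 0; r < m; ++r) u[r] = (xc[in[r]] - mu[f]) / sdv[f];
          utest = (xc[jj] - mu[f]) / sdv[f];
        } else {
          std::fill(u.begin(), u.end(), 0.0);
        }
        double ub = 0.0;
        for (int r = 0; r < m; ++r) ub += u[r] * beta[r];
        for (int r = 0; r < m; ++r) {
          const double ur = u[r];
          if (ur != 0.0) {
            double* qrow = &Q[(std::size_t)r * m];
            for (int c2 = 0; c2 < m; ++c2) qrow[c2] += ur * u[c2];
          }
          qb[r] += ur * ub;
          dtest[r] += ur * utest;
        }
        ++g_fits;
        g_sweeps += svr_solve(Q, m, yc.data(), C, eps, beta, qb, tol,
                              max_sweeps, act, perm, /*warm=*/k > 0);
        double f_pred = ymean;
        for (int r = 0; r < m; ++r) f_pred += beta[r] * dtest[r];
        predin[(std::size_t)k * n + j] = f_pred;
      }
    }
    // ---- choose k* ----
    std::vector<double> ytr(n);
    for (int j = 0; j < n; ++j) ytr[j] = yv[tr[j]];
    int ks = 0;
    double best = -2.0;
    for (int k = 0; k < F; ++k) {
      double rk = pearson(&predin[(std::size_t)k * n], ytr.data(), n);
      if (ISNAN(rk)) rk = -2.0;
      if (rk > best) { best = rk; ks = k; }
    }
    kstar[i] = ks + 1;
    // ---- consensus over inner folds ----
    std::vector<int> cnt(F, 0);
    for (int j = 0; j < n; ++j)
      for (int t = 0; t <= ks; ++t)
        cnt[rankings[(std::size_t)j * F + t]]++;
    std::vector<int> cons;
    for (int f = 0; f < F; ++f)
      if ((double)cnt[f] + 1e-9 >= theta * n) cons.push_back(f);
    if (cons.empty()) {
      fallback[i] = true;
      // top-ranked feature on the full outer training set
      int bestf = 0;
      double bestr = -1.0;
      for (int f = 0; f < F; ++f) {
        const double* xc = &Xv[(std::size_t)f * S];
        std::vector<double> col(n);
        for (int j = 0; j < n; ++j) col[j] = xc[tr[j]];
        double rf = pearson(col.data(), ytr.data(), n);
        rf = ISNAN(rf) ? 0.0 : std::fabs(rf);
        if (rf > bestr) { bestr = rf; bestf = f; }
      }
      cons.push_back(bestf);
    }
    // ---- final outer model ----
    const int K = (int)cons.size();
    double ymean = 0.0;
    for (int j = 0; j < n; ++j) ymean += ytr[j];
    ymean /= n;
    std::vector<double> ycn(n);
    for (int j = 0; j < n; ++j) ycn[j] = ytr[j] - ymean;
    std::vector<double> Qn((std::size_t)n * n, 0.0), un(n), dti(n, 0.0);
    for (int t = 0; t < K; ++t) {
      const int f = cons[t];
      const double* xc = &Xv[(std::size_t)f * S];
      double mf = 0.0;
      for (int j = 0; j < n; ++j) mf += xc[tr[j]];
      mf /= n;
      double sxx = 0.0;
      for (int j = 0; j < n; ++j) {
        const double d = xc[tr[j]] - mf;
        sxx += d * d;
      }
      double sf = (sxx > 0.0) ? std::sqrt(sxx / (n - 1)) : 0.0;
      double uti = 0.0;
      if (sf > 0.0) {
        for (int j = 0; j < n; ++j) un[j] = (xc[tr[j]] - mf) / sf;
        uti = (xc[i] - mf) / sf;
      } else std::fill(un.begin(), un.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        const double uj = un[j];
        if (uj != 0.0) {
          double* qrow = &Qn[(std::size_t)j * n];
          for (int c2 = 0; c2 < n; ++c2) qrow[c2] += uj * un[c2];
        }
        dti[j] += uj * uti;
      }
    }
    std::vector<double> bn(n, 0.0), qbn(n, 0.0);
    svr_solve(Qn, n, ycn.data(), C, eps, bn, qbn,
              (tol < 1e-6 ? tol : 1e-6), max_sweeps * 5, act, perm);
    double f_pred = ymean;
    for (int j = 0; j < n; ++j) f_pred += bn[j] * dti[j];
    pred[i] = f_pred;

    IntegerVector cv(cons.size());
    for (std::size_t t = 0; t < cons.size(); ++t) cv[t] = cons[t] + 1;
    perfold[i] = cv;
  }
  List out = List::create(_["pred"] = pred, _["kstar"] = kstar,
                      _["per_fold"] = perfold, _["fallback"] = fallback,
                      _["diag"] = NumericVector::create((double)g_fits, (double)g_sweeps));
  g_fits = g_sweeps = 0;
  return out;
}

// Leave-one-out linear SVM decision values with per-fold standardization.
// ysign must be +-1.  Returns the held-out decision value for each subject.
// [[Rcpp::export]]
NumericVector cpp_svm_loocv(NumericMatrix X, NumericVector ysign, double C,
                            double tol = 1e-6, int max_sweeps = 5000) {
  const int S = X.nrow(), F = X.ncol();
  std::vector<double> Xv(X.begin(), X.end());
  const double* yv = REAL(ysign);
  NumericVector dec(S);
  const int n = S - 1;
  std::vector<int> tr(n);
  std::vector<double> Xs((std::size_t)n * F), yt(n), Q, alpha(n), qa(n),
      xte(F);
  for (int i = 0; i < S; ++i) {
    int t = 0;
    for (int s = 0; s < S; ++s) if (s != i) tr[t++] = s;
    for (int j = 0; j < n; ++j) yt[j] = yv[tr[j]];
    for (int f = 0; f < F; ++f) {
      const double* xc = &Xv[(std::size_t)f * S];
      double mf = 0.0;
      for (int j = 0; j < n; ++j) mf += xc[tr[j]];
      mf /= n;
      double sxx = 0.0;
      for (int j = 0; j < n; ++j) {
        const double d = xc[tr[j]] - mf;
        sxx += d * d;
      }
      const double sf = (sxx > 0.0) ? std::sqrt(sxx / (n - 1)) : 0.0;
      for (int j = 0; j < n; ++j)
        Xs[(std::size_t)f * n + j] =
            (sf > 0.0) ? (xc[tr[j]] - mf) / sf : 0.0;
      xte[f] = (sf > 0.0) ? (xc[i] - mf) / sf : 0.0;
    }
    gram_plus_one(Xs, n, F, Q);
    std::fill(alpha.begin(), alpha.end(), 0.0);
    std::fill(qa.begin(), qa.end(), 0.0);
    svm_cd(Q, n, yt.data(), C, alpha, qa, tol, max_sweeps);
    double d = 0.0;
    for (int j = 0; j < n; ++j) {
      if (alpha[j] == 0.0) continue;
      double dot = 1.0;
      for (int f = 0; f < F; ++f)
        dot += Xs[(std::size_t)f * n + j] * xte[f];
      d += alpha[j] * yt[j] * dot;
    }
    dec[i] = d;
  }
  return dec;
}
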