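// L1-regularised linear decoding: coordinate descent on standardised
// features, with nested leave-one-out cross-validation. The objective is
//   (1/2n) * sum(y - b - Xs w)^2 + lambda * sum|w|
// with Xs standardised (population SD) inside each training set only, so
// held-out predictions never see test-set statistics.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double soft(double z, double l) {
  if (z > l) return z - l;
  if (z < -l) return z + l;
  return 0.0;
}

// Standardise columns of X[idx,] into Xs (m x p, column-major).
static void standardize(const NumericMatrix& X, const std::vector<int>& idx,
                        std::vector<double>& Xs, std::vector<double>& center,
                        std::vector<double>& scale) {
  const int m = (int)idx.size(), p = X.ncol();
  for (int j = 0; j < p; ++j) {
    double mu = 0;
    for (int k = 0; k < m; ++k) mu += X(idx[k], j);
    mu /= m;
    double ss = 0;
    for (int k = 0; k < m; ++k) { double d = X(idx[k], j) - mu; ss += d * d; }
    double v = ss / m;
    double sd = (v < 1e-24) ? 1.0 : std::sqrt(v);
    center[j] = mu; scale[j] = sd;
    double* col = &Xs[(size_t)j * m];
    if (v < 1e-24) {
      for (int k = 0; k < m; ++k) col[k] = 0.0;  // constant feature
    } else {
      for (int k = 0; k < m; ++k) col[k] = (X(idx[k], j) - mu) / sd;
    }
  }
}

// Coordinate descent at one lambda; w warm-started, residual r maintained.
static void cd_fit(const std::vector<double>& Xs, int m, int p,
                   std::vector<double>& w, std::vector<double>& r,
                   double lambda, double tol, int maxSweep,
                   int maxActive = 500) {
  std::vector<int> active;
  for (int sweep = 0; sweep < maxSweep; ++sweep) {
    double maxd = 0;
    for (int j = 0; j < p; ++j) {
      const double* col = &Xs[(size_t)j * m];
      double g = 0;
      for (int k = 0; k < m; ++k) g += col[k] * r[k];
      g = g / m + w[j];
      double wn = soft(g, lambda);
      double d = wn - w[j];
      if (d != 0) {
        for (int k = 0; k < m; ++k) r[k] -= col[k] * d;
        w[j] = wn;
        double ad = std::fabs(d);
        if (ad > maxd) maxd = ad;
      }
    }
    if (maxd < tol) return;
    active.clear();
    for (int j = 0; j < p; ++j) if (w[j] != 0) active.push_back(j);
    for (int inner = 0; inner < maxActive; ++inner) {
      double md = 0;
      for (size_t a = 0; a < active.size(); ++a) {
        const int j = active[a];
        const double* col = &Xs[(size_t)j * m];
        double g = 0;
        for (int k = 0; k < m; ++k) g += col[k] * r[k];
        g = g / m + w[j];
        double wn = soft(g, lambda);
        double d = wn - w[j];
        if (d != 0) {
          for (int k = 0; k < m; ++k) r[k] -= col[k] * d;
          w[j] = wn;
          double ad = std::fabs(d);
          if (ad > md) md = ad;
        }
      }
      if (md < tol) break;
    }
  }
}

// Fit the descending-lambda path on X[idx,] and predict rows `predIdx`
// of X for every lambda. predOut is (nLambda x nPred), column-major by
// prediction index. The convergence tolerance is scaled by the SD of the
// training targets so it is invariant to the target's units.
static void path_predict(const NumericMatrix& X, const NumericVector& y,
                         const std::vector<int>& idx,
                         const std::vector<double>& lamDesc,
                         const std::vector<int>& predIdx,
                         std::vector<double>& predOut,
                         double tol, int maxSweep, int maxActive = 500) {
  const int m = (int)idx.size(), p = X.ncol();
  const int nl = (int)lamDesc.size(), np = (int)predIdx.size();
  std::vector<double> Xs((size_t)m * p), center(p), scale(p);
  standardize(X, idx, Xs, center, scale);
  double ymean = 0;
  for (int k = 0; k < m; ++k) ymean += y[idx[k]];
  ymean /= m;
  std::vector<double> r(m), w(p, 0.0);
  double yss = 0;
  for (int k = 0; k < m; ++k) {
    r[k] = y[idx[k]] - ymean;
    yss += r[k] * r[k];
  }
  const double tolScaled = tol * std::max(1.0, std::sqrt(yss / m));
  for (int li = 0; li < nl; ++li) {
    cd_fit(Xs, m, p, w, r, lamDesc[li], tolScaled, maxSweep, maxActive);
    for (int q = 0; q < np; ++q) {
      double pred = ymean;
      for (int j = 0; j < p; ++j) {
        if (w[j] != 0)
          pred += w[j] * (X(predIdx[q], j) - center[j]) / scale[j];
      }
      predOut[(size_t)q * nl + li] = pred;
    }
  }
}

static double pearson(const std::vector<double>& a,
                      const std::vector<double>& b) {
  const int n = (int)a.size();
  double ma = 0, mb = 0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0, sa = 0, sb = 0;
  for (int i = 0; i < n; ++i) {
    double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; sa += da * da; sb += db * db;
  }
  if (sa <= 0 || sb <= 0) return NA_REAL;
  return sab / std::sqrt(sa * sb);
}

// [[Rcpp::export]]
List cppLassoFit(NumericMatrix X, NumericVector y, double lambda,
                 double tol = 1e-6, int maxSweep = 100) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> Xs((size_t)n * p), center(p), scale(p);
  standardize(X, idx, Xs, center, scale);
  double ymean = 0;
  for (int i = 0; i < n; ++i) ymean += y[i];
  ymean /= n;
  std::vector<double> r(n), w(p, 0.0);
  for (int i = 0; i < n; ++i) r[i] = y[i] - ymean;
  cd_fit(Xs, n, p, w, r, lambda, tol, maxSweep);
  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["intercept"] = ymean,
                      _["center"] = NumericVector(center.begin(), center.end()),
                      _["scale"] = NumericVector(scale.begin(), scale.end()));
}

// Inner LOO accuracy per lambda on the units in `idx`; returns accuracies
// ordered as lamDesc.
static void inner_loo_accuracy(const NumericMatrix& X, const NumericVector& y,
                               const std::vector<int>& idx,
                               const std::vector<double>& lamDesc,
                               std::vector<double>& accOut,
                               double tol, int maxSweep, int maxActive = 500) {
  const int m = (int)idx.size(), nl = (int)lamDesc.size();
  std::vector<double> preds((size_t)m * nl);  // [j * nl + li]
  std::vector<int> sub(m - 1), tgt(1);
  std::vector<double> onePred(nl);
  for (int j = 0; j < m; ++j) {
    int s = 0;
    for (int k = 0; k < m; ++k) if (k != j) sub[s++] = idx[k];
    tgt[0] = idx[j];
    path_predict(X, y, sub, lamDesc, tgt, onePred, tol, maxSweep, maxActive);
    for (int li = 0; li < nl; ++li) preds[(size_t)j * nl + li] = onePred[li];
  }
  std::vector<double> actual(m), ph(m);
  for (int j = 0; j < m; ++j) actual[j] = y[idx[j]];
  for (int li = 0; li < nl; ++li) {
    for (int j = 0; j < m; ++j) ph[j] = preds[(size_t)j * nl + li];
    accOut[li] = pearson(ph, actual);
  }
}

// Nested leave-one-out CV: the outer loop holds one unit out; the inner
// leave-one-out over the remaining units evaluates each lambda by mean...
// by the Pearson correlation between inner held-out predictions and
// actuals; the best lambda (ties toward stronger shrinkage) refits on the
// full training set and predicts the held-out unit.
// [[Rcpp::export]]
List cppNestedLoocv(NumericMatrix X, NumericVector y, NumericVector lambdas,
                    double tol = 1e-6, int maxSweep = 100,
                    double innerTol = 1e-3, int innerMaxSweep = 10,
                    int innerMaxActive = 30) {
  const int n = X.nrow();
  if (n < 4) stop("nested leave-one-out needs >= 4 units");
  std::vector<double> lamDesc(lambdas.begin(), lambdas.end());
  std::sort(lamDesc.begin(), lamDesc.end(), std::greater<double>());
  const int nl = (int)lamDesc.size();
  NumericVector pred(n), lamSel(n);
  std::vector<int> train(n - 1), tgt(1);
  std::vector<double> acc(nl), onePred(nl);
  bool anyDegenerate = false;
  for (int i = 0; i < n; ++i) {
    int s = 0;
    for (int k = 0; k < n; ++k) if (k != i) train[s++] = k;
    inner_loo_accuracy(X, y, train, lamDesc, acc, innerTol, innerMaxSweep, innerMaxActive);
    // Degenerate (constant-prediction) accuracies count as 0: an
    // intercept-only model expresses "no relationship". Iterating the
    // grid in descending order breaks ties toward stronger shrinkage.
    int best = 0;
    double bestAcc = -2.0;
    bool allNaN = true;
    for (int li = 0; li < nl; ++li) {
      double a = ISNAN(acc[li]) ? 0.0 : acc[li];
      if (!ISNAN(acc[li])) allNaN = false;
      if (a > bestAcc) { bestAcc = a; best = li; }
    }
    if (allNaN) anyDegenerate = true;
    tgt[0] = i;
    path_predict(X, y, train, lamDesc, tgt, onePred, tol, maxSweep);
    pred[i] = onePred[best];
    lamSel[i] = lamDesc[best];
  }
  return List::create(_["pred"] = pred, _["lambda"] = lamSel,
                      _["innerDegenerate"] = anyDegenerate);
}

// Plain (non-nested) leave-one-out accuracy for each lambda over all
// units; used to pick the penalty of the full transfer model.
// [[Rcpp::export]]
NumericVector cppLoocvAccuracy(NumericMatrix X, NumericVector y,
                               NumericVector lambdas, double tol = 1e-6,
                               int maxSweep = 100) {
  const int n = X.nrow();
  if (n < 3) stop("leave-one-out needs >= 3 units");
  std::vector<double> lamDesc(lambdas.begin(), lambdas.end());
  std::sort(lamDesc.begin(), lamDesc.end(), std::greater<double>());
  const int nl = (int)lamDesc.size();
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  std::vector<double> acc(nl);
  inner_loo_accuracy(X, y, all, lamDesc, acc, tol, maxSweep);
  NumericVector out(nl);
  CharacterVector nm(nl);
  for (int li = 0; li < nl; ++li) out[li] = acc[li];
  out.attr("lambda") = NumericVector(lamDesc.begin(), lamDesc.end());
  return out;
}
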