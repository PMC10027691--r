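// One-vs-one C-SVC on a precomputed linear Gram matrix.
//
// The decoder's feature matrices are tall (up to ~27k correlation features)
// but only 24 exemplars, and label permutations never change the features:
// the linear-kernel Gram matrix can be computed once per unit x subject and
// every permutation's cross-validated fit reduces to tiny dual problems
// (<= 6 points per binary subproblem). This solver is an SMO for the
// standard C-SVC dual with bias, with libsvm's rho and voting conventions,
// and is verified against libsvm (e1071) in the test suite.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// solve binary C-SVC dual on kernel submatrix; returns alpha*y and rho
static void solve_binary(const std::vector<double> &K, int n,
                         const std::vector<int> &y, double C, double eps,
                         std::vector<double> &alpha, double &rho) {
  std::vector<double> G(n, -1.0);  // gradient of 0.5 a'Qa - e'a
  alpha.assign(n, 0.0);
  int max_iter = 10000;
  while (max_iter-- > 0) {
    // maximal violating pair (first-order working set selection)
    double gmax = -INF, gmin = INF;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      bool lo = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (lo && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;
    // analytic update of the (i, j) pair
    double Kii = K[(size_t)i * n + i], Kjj = (double)K[(size_t)j * n + j];
    double Kij = K[(size_t)i * n + j];
    double quad = Kii + Kjj - 2.0 * Kij;
    if (quad <= 0) quad = 1e-12;
    double delta = (gmax - gmin) / quad;  // step along y_i e_i - y_j e_j
    double ai_old = alpha[i], aj_old = alpha[j];
    double ai = ai_old + y[i] * delta * 1.0;
    double aj = aj_old - y[j] * delta * 1.0;
    // clip to the box while keeping sum y*a constant
    double di = y[i] * (ai - ai_old);  // = delta
    double lo_d = -INF, hi_d = INF;
    // bounds from alpha_i in [0, C]
    if (y[i] == 1) { lo_d = std::max(lo_d, -ai_old); hi_d = std::min(hi_d, C - ai_old); }
    else           { lo_d = std::max(lo_d, ai_old - C); hi_d = std::min(hi_d, ai_old); }
    // alpha_j changes by -y_j * delta_y where delta_y = y_i * d_i; keep in box
    if (y[j] == 1) { lo_d = std::max(lo_d, aj_old - C); hi_d = std::min(hi_d, aj_old); }
    else           { lo_d = std::max(lo_d, -aj_old); hi_d = std::min(hi_d, C - aj_old); }
    double d = std::min(std::max(di, lo_d), hi_d);
    ai = ai_old + y[i] * d;
    aj = aj_old - y[j] * d;
    double dai = ai - ai_old, daj = aj - aj_old;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * K[(size_t)i * n + t] * dai +
                      y[j] * K[(size_t)j * n + t] * daj);
    }
    alpha[i] = ai; alpha[j] = aj;
  }
  // rho, libsvm convention
  double ub = INF, lb = -INF, sum_free = 0.0;
  int nr_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] >= C - 1e-12) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else { ++nr_free; sum_free += yG; }
  }
  rho = nr_free > 0 ? sum_free / nr_free : (ub + lb) / 2.0;
}

// predict test labels by one-vs-one voting; K is the full Gram over all
// exemplars, train/test are 0-based row indices, y has labels 1..k
static void ovo_predict(const NumericMatrix &K, const IntegerVector &y,
                        const std::vector<int> &train,
                        const std::vector<int> &test, double C, double eps,
                        std::vector<int> &pred) {
  // classes in order of first appearance in the training data, and pairs
  // scanned in that order with f > 0 voting the earlier class — the libsvm
  // conventions, so predictions are comparable prediction-for-prediction
  std::vector<int> cls;
  for (int t : train) {
    bool seen = false;
    for (int c : cls) if (c == y[t]) { seen = true; break; }
    if (!seen) cls.push_back(y[t]);
  }
  int k = cls.size();
  size_t nte = test.size();
  std::vector<std::vector<int>> votes(nte, std::vector<int>(k, 0));
  std::vector<int> idx, yy;
  std::vector<double> Ksub, alpha;
  for (int i1 = 0; i1 < k; ++i1) {
    for (int i2 = i1 + 1; i2 < k; ++i2) {
      int c1 = cls[i1], c2 = cls[i2];
      idx.clear(); yy.clear();
      for (size_t t = 0; t < train.size(); ++t) {
        int lab = y[train[t]];
        if (lab == c1) { idx.push_back(train[t]); yy.push_back(1); }
        else if (lab == c2) { idx.push_back(train[t]); yy.push_back(-1); }
      }
      int n = idx.size();
      if (n == 0) continue;
      Ksub.assign((size_t)n * n, 0.0);
      for (int a = 0; a < n; ++a)
        for (int b = 0; b < n; ++b)
          Ksub[(size_t)a * n + b] = K(idx[a], idx[b]);
      double rho;
      solve_binary(Ksub, n, yy, C, eps, alpha, rho);
      for (size_t t = 0; t < nte; ++t) {
        double f = -rho;
        for (int a = 0; a < n; ++a)
          f += alpha[a] * yy[a] * K(idx[a], test[t]);
        votes[t][f > 0 ? i1 : i2]++;
      }
    }
  }
  pred.resize(nte);
  for (size_t t = 0; t < nte; ++t) {
    int best = 0;
    for (int c = 1; c < k; ++c)
      if (votes[t][c] > votes[t][best]) best = c;  // ties: earliest class
    pred[t] = cls[best];
  }
}

// [[Rcpp::export]]
IntegerVector ovo_predict_cpp(NumericMatrix K, IntegerVector y,
                              IntegerVector train_idx, IntegerVector test_idx,
                              double C = 1.0, double eps = 1e-6) {
  std::vector<int> train(train_idx.begin(), train_idx.end());
  std::vector<int> test(test_idx.begin(), test_idx.end());
  for (auto &v : train) --v;
  for (auto &v : test) --v;
  std::vector<int> pred;
  ovo_predict(K, y, train, test, C, eps, pred);
  return IntegerVector(pred.begin(), pred.end());
}

// Leave-one-run-out accuracy for a batch of label columns. K is the Gram
// over all exemplars, runs tags the exemplars, Y holds one label set per
// column (e.g. permutations). Returns one accuracy per column.
// [[Rcpp::export]]
NumericVector loro_accuracy_batch_cpp(NumericMatrix K, IntegerVector runs,
                                      IntegerMatrix Y, double C = 1.0,
                                      double eps = 1e-6) {
  int n = runs.size(), P = Y.ncol();
  std::vector<int> urun;
  for (int i = 0; i < n; ++i) {
    bool seen = false;
    for (int u : urun) if (u == runs[i]) { seen = true; break; }
    if (!seen) urun.push_back(runs[i]);
  }
  NumericVector acc(P);
  std::vector<int> train, test, pred;
  for (int p = 0; p < P; ++p) {
    IntegerVector yl = Y(_, p);
    int correct = 0, total = 0;
    for (int u : urun) {
      train.clear(); test.clear();
      for (int i = 0; i < n; ++i) {
        if (runs[i] == u) test.push_back(i); else train.push_back(i);
      }
      ovo_predict(K, yl, train, test, C, eps, pred);
      for (size_t t = 0; t < test.size(); ++t) {
        ++total;
        if (pred[t] == yl[test[t]]) ++correct;
      }
    }
    acc[p] = total ? (double)correct / total : NA_REAL;
  }
  return acc;
}
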