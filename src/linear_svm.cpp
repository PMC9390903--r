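#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>

// Dual coordinate descent for the L1-loss (hinge) linear SVM:
//   min_w 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w.x_i)
// following Hsieh et al.'s coordinate-wise dual update with projected
// gradients. The intercept is a unit-augmented (penalised) bias feature, the
// standard device of large-scale linear solvers. Coordinates are visited in
// a permutation refreshed each epoch from a private linear-congruential
// generator, so fits are deterministic and never touch R's RNG stream.
// Samples are held row-major so the inner dot products stream contiguously;
// the solver is built for the many small fits of a wrapper selection loop.

namespace {

struct Lcg {
  uint64_t state;
  explicit Lcg(uint64_t seed)
      : state(seed * 6364136223846793005ULL + 1442695040888963407ULL) {}
  uint32_t next() {
    state = state * 6364136223846793005ULL + 1442695040888963407ULL;
    return static_cast<uint32_t>(state >> 33);
  }
};

// x: n rows, d columns, row-major, last column is the bias feature (=1).
// y: +1/-1. w (length d) is overwritten with the solution. Uses the
// customary shrinking heuristic: samples pinned at a bound with a strongly
// feasible gradient leave the active set until the reduced problem
// converges, after which one full pass confirms optimality.
void fit_dcd(const double* x, int n, int d, const int* y, double C,
             double eps, int max_epochs, double* w) {
  std::vector<double> alpha(n, 0.0), qd(n);
  std::fill(w, w + d, 0.0);
  for (int i = 0; i < n; ++i) {
    const double* xi = x + static_cast<size_t>(i) * d;
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    qd[i] = s;
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  Lcg rng(88172645463325252ULL);
  int active = n;
  double pgmax_old = HUGE_VAL, pgmin_old = -HUGE_VAL;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    for (int i = active - 1; i > 0; --i) {
      int j = static_cast<int>((static_cast<uint64_t>(rng.next()) * (i + 1)) >> 32);
      std::swap(order[i], order[j]);
    }
    double pgmax = -HUGE_VAL, pgmin = HUGE_VAL;
    for (int k = 0; k < active; ++k) {
      const int i = order[k];
      const double yi = y[i];
      const double* __restrict xi = x + static_cast<size_t>(i) * d;
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * xi[j];
      const double g = yi * wx - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) {
        if (g > pgmax_old) {           // shrink: pinned at 0, far from active
          std::swap(order[k], order[--active]);
          --k;
          continue;
        }
        if (g >= 0.0) pg = 0.0;
      } else if (alpha[i] >= C) {
        if (g < pgmin_old) {           // shrink: pinned at C
          std::swap(order[k], order[--active]);
          --k;
          continue;
        }
        if (g <= 0.0) pg = 0.0;
      }
      if (pg > pgmax) pgmax = pg;
      if (pg < pgmin) pgmin = pg;
      if (std::fabs(pg) > 1e-12) {
        const double a_old = alpha[i];
        double a_new = a_old - g / qd[i];
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > C) a_new = C;
        alpha[i] = a_new;
        const double delta = (a_new - a_old) * yi;
        if (delta != 0.0)
          for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
      }
    }
    if (pgmax - pgmin <= eps) {
      if (active == n) break;
      active = n;                      // one confirming pass over everything
      pgmax_old = HUGE_VAL;
      pgmin_old = -HUGE_VAL;
      continue;
    }
    pgmax_old = pgmax <= 0.0 ? HUGE_VAL : pgmax;
    pgmin_old = pgmin >= 0.0 ? -HUGE_VAL : pgmin;
  }
}

}  // namespace

// Single fit on a column-major R matrix; returns w with the bias last.
// [[Rcpp::export(name = ".dcd_svm_fit")]]
Rcpp::NumericVector dcd_svm_fit(const Rcpp::NumericMatrix& x,
                                const Rcpp::IntegerVector& y,
                                double C, double eps, int max_epochs) {
  const int n = x.nrow(), p = x.ncol(), d = p + 1;
  std::vector<double> xr(static_cast<size_t>(n) * d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xr[static_cast<size_t>(i) * d + j] = x(i, j);
    xr[static_cast<size_t>(i) * d + p] = 1.0;
  }
  Rcpp::NumericVector w(d);
  fit_dcd(xr.data(), n, d, &y[0], C, eps, max_epochs, REAL(w));
  return w;
}

// Mean held-out accuracy over precomputed folds: fits one SVM per fold on
// the remaining rows and scores the held-out rows. fold_id is 1-based.
// [[Rcpp::export(name = ".dcd_cv_accuracy")]]
double dcd_cv_accuracy(const Rcpp::NumericMatrix& x,
                       const Rcpp::IntegerVector& y,
                       const Rcpp::IntegerVector& fold_id, int n_folds,
                       double C, double eps, int max_epochs) {
  const int n = x.nrow(), p = x.ncol(), d = p + 1;
  std::vector<double> xr(static_cast<size_t>(n) * d);
  std::vector<int> ypm(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xr[static_cast<size_t>(i) * d + j] = x(i, j);
    xr[static_cast<size_t>(i) * d + p] = 1.0;
    ypm[i] = y[i] == 1 ? 1 : -1;
  }
  std::vector<double> xtr(xr.size()), w(d);
  std::vector<int> ytr(n);
  double acc_sum = 0.0;
  for (int f = 1; f <= n_folds; ++f) {
    int ntr = 0;
    for (int i = 0; i < n; ++i) {
      if (fold_id[i] == f) continue;
      std::memcpy(&xtr[static_cast<size_t>(ntr) * d],
                  &xr[static_cast<size_t>(i) * d], sizeof(double) * d);
      ytr[ntr++] = ypm[i];
    }
    fit_dcd(xtr.data(), ntr, d, ytr.data(), C, eps, max_epochs, w.data());
    int correct = 0, nte = 0;
    for (int i = 0; i < n; ++i) {
      if (fold_id[i] != f) continue;
      const double* xi = &xr[static_cast<size_t>(i) * d];
      double dec = 0.0;
      for (int j = 0; j < d; ++j) dec += w[j] * xi[j];
      const int pred = dec > 0.0 ? 1 : -1;
      if (pred == ypm[i]) ++correct;
      ++nte;
    }
    if (nte > 0) acc_sum += static_cast<double>(correct) / nte;
  }
  return acc_sum / n_folds;
}
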