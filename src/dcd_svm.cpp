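#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized L1-loss (hinge) linear SVM:
//   min_w 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w.x_i)
// The intercept is trained as an augmented constant feature (value
// bias_scale), so it is lightly regularized, as in liblinear's default.
//
// Xt is the transposed feature matrix (features x samples, dgCMatrix), so
// each sample's nonzeros are one contiguous column. Coordinate order is a
// seeded Fisher-Yates permutation per epoch: deterministic given `seed`.

static inline uint64_t lcg_next(uint64_t &s) {
  s = s * 6364136223846793005ULL + 1442695040888963407ULL;
  return s >> 33;
}

// [[Rcpp::export(name = ".dcd_svm")]]
List dcd_svm(S4 Xt, NumericVector y, double C, int max_epochs, double tol,
             int seed, double bias_scale) {
  IntegerVector p = Xt.slot("p");
  IntegerVector ridx = Xt.slot("i");
  NumericVector xval = Xt.slot("x");
  IntegerVector dim = Xt.slot("Dim");
  const int nfeat = dim[0];
  const int n = dim[1];

  std::vector<double> w(nfeat, 0.0);
  double wb = 0.0;
  std::vector<double> alpha(n, 0.0);
  std::vector<double> qii(n);
  for (int i = 0; i < n; ++i) {
    double s = bias_scale * bias_scale;
    for (int k = p[i]; k < p[i + 1]; ++k) s += xval[k] * xval[k];
    qii[i] = s;
  }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  uint64_t rng = (uint64_t)seed * 2654435761ULL + 1ULL;

  int epoch = 0;
  bool converged = false;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    // seeded shuffle
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(lcg_next(rng) % (uint64_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    double max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = order[t];
      double dec = wb * bias_scale;
      for (int k = p[i]; k < p[i + 1]; ++k) dec += w[ridx[k]] * xval[k];
      const double G = y[i] * dec - 1.0;
      double pg = G;
      if (alpha[i] <= 0.0 && G >= 0.0) pg = 0.0;
      else if (alpha[i] >= C && G <= 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (pg != 0.0) {
        const double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        alpha[i] = a_new;
        const double d = (a_new - a_old) * y[i];
        if (d != 0.0) {
          for (int k = p[i]; k < p[i + 1]; ++k) w[ridx[k]] += d * xval[k];
          wb += d * bias_scale;
        }
      }
    }
    if (max_pg < tol) { converged = true; ++epoch; break; }
  }

  return List::create(
    _["weights"] = NumericVector(w.begin(), w.end()),
    _["bias"] = wb * bias_scale,
    _["epochs"] = epoch,
    _["converged"] = converged
  );
}
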