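// Weighted univariate Gaussian-mixture EM inner loop.
// Case weights multiply every sufficient statistic, so an integer weight is
// exactly equivalent to replicating the observation. Collapsed components
// (weighted responsibility mass below 1e-8) are re-seeded at a random
// observation through R's RNG, keeping runs reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List gmm_em_cpp(NumericVector x, NumericVector w, NumericVector means0,
                NumericVector sds0, NumericVector props0,
                int max_iter, double tol, double var_floor,
                double overall_sd) {
  const int n = x.size();
  const int C = means0.size();
  const double LOG_SQRT_2PI = 0.9189385332046727;

  std::vector<double> means(means0.begin(), means0.end());
  std::vector<double> sds(sds0.begin(), sds0.end());
  std::vector<double> props(props0.begin(), props0.end());
  std::vector<double> trace;
  trace.reserve(max_iter);

  double sw = 0.0;
  for (int i = 0; i < n; ++i) sw += w[i];

  std::vector<double> nc(C), sum_x(C), sum_x2(C), ld(C);
  NumericMatrix r(n, C);
  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false;

  for (int iter = 0; iter < max_iter; ++iter) {
    // E-step and weighted log-likelihood
    ll = 0.0;
    std::vector<double> logc(C);
    for (int c = 0; c < C; ++c)
      logc[c] = std::log(props[c]) - std::log(sds[c]) - LOG_SQRT_2PI;
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int c = 0; c < C; ++c) {
        double u = (x[i] - means[c]) / sds[c];
        ld[c] = -0.5 * u * u + logc[c];
        if (ld[c] > mx) mx = ld[c];
      }
      double s = 0.0;
      for (int c = 0; c < C; ++c) {
        ld[c] = std::exp(ld[c] - mx);   // reuse: unnormalized responsibility
        s += ld[c];
      }
      ll += w[i] * (mx + std::log(s));
      for (int c = 0; c < C; ++c) r(i, c) = ld[c] / s;
    }
    trace.push_back(ll);
    if (R_finite(ll_old) &&
        std::fabs(ll - ll_old) < tol * (std::fabs(ll_old) + 1e-3)) {
      converged = true;
      break;
    }
    ll_old = ll;

    // M-step with weighted responsibilities
    bool reseeded = false;
    for (int c = 0; c < C; ++c) {
      nc[c] = 0.0; sum_x[c] = 0.0;
      for (int i = 0; i < n; ++i) {
        double wr = w[i] * r(i, c);
        nc[c] += wr;
        sum_x[c] += wr * x[i];
      }
    }
    for (int c = 0; c < C; ++c) {
      if (nc[c] < 1e-8) {
        int idx = (int)std::floor(unif_rand() * n);
        if (idx >= n) idx = n - 1;
        means[c] = x[idx];
        sds[c] = overall_sd;
        props[c] = 1.0 / C;
        reseeded = true;
      }
    }
    if (reseeded) {
      double ps = 0.0;
      for (int c = 0; c < C; ++c) ps += props[c];
      for (int c = 0; c < C; ++c) props[c] /= ps;
      ll_old = R_NegInf;
      continue;
    }
    for (int c = 0; c < C; ++c) {
      props[c] = nc[c] / sw;
      means[c] = sum_x[c] / nc[c];
      double v = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - means[c];
        v += w[i] * r(i, c) * d * d;
      }
      v /= nc[c];
      if (v < var_floor) v = var_floor;
      sds[c] = std::sqrt(v);
    }
  }

  return List::create(
    _["means"] = NumericVector(means.begin(), means.end()),
    _["sds"] = NumericVector(sds.begin(), sds.end()),
    _["proportions"] = NumericVector(props.begin(), props.end()),
    _["loglik"] = ll,
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["converged"] = converged
  );
}
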