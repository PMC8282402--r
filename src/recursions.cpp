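#include <Rcpp.h>
using namespace Rcpp;

// Conditional (CSS) ARMA residual recursion with zero pre-sample values:
//   eps_t = w_t - sum_k ar_k w_{t-k} - sum_k ma_k eps_{t-k}
// Indices before t=1 contribute 0 for both w and eps.
// [[Rcpp::export]]
NumericVector arma_residuals_cpp(NumericVector w, NumericVector ar, NumericVector ma) {
  const int n = w.size(), p = ar.size(), q = ma.size();
  NumericVector eps(n);
  for (int t = 0; t < n; ++t) {
    double e = w[t];
    for (int k = 0; k < p; ++k)
      if (t - k - 1 >= 0) e -= ar[k] * w[t - k - 1];
    for (int k = 0; k < q; ++k)
      if (t - k - 1 >= 0) e -= ma[k] * eps[t - k - 1];
    eps[t] = e;
  }
  return eps;
}

// Variance recursion shared by ARCH / GARCH / GJR-GARCH:
//   sigma2_t = a0 + sum_i alpha_i y_{t-i}^2 + sum_j beta_j sigma2_{t-j}
//            + sum_i gamma_i I(y_{t-i} < 0) y_{t-i}^2
// gamma has length 0 (plain (G)ARCH) or q (GJR). The first max(p, q) values
// carry the pre-sample initialisation sigma2_init; the recursion runs beyond
// them (pre-sample y^2 terms are 0).
// [[Rcpp::export]]
NumericVector garch_path_cpp(NumericVector y, double alpha0, NumericVector alpha,
                             NumericVector beta, NumericVector gamma,
                             double sigma2_init) {
  const int n = y.size(), q = alpha.size(), p = beta.size();
  const int m = std::max(p, q);
  const bool gjr = gamma.size() > 0;
  NumericVector s2(n);
  for (int t = 0; t < std::min(m, n); ++t) s2[t] = sigma2_init;
  for (int t = m; t < n; ++t) {
    double v = alpha0;
    for (int i = 0; i < q; ++i) {
      int lag = t - i - 1;
      if (lag >= 0) {
        double y2 = y[lag] * y[lag];
        v += alpha[i] * y2;
        if (gjr && y[lag] < 0) v += gamma[i] * y2;
      }
    }
    for (int j = 0; j < p; ++j) {
      int lag = t - j - 1;
      v += beta[j] * (lag >= 0 ? s2[lag] : sigma2_init);
    }
    s2[t] = v;
  }
  return s2;
}

// EGARCH log-variance recursion, coefficients as printed in the source model:
//   log sigma2_t = a0 + sum_{k=1}^{q} shock_k * g(Z_{t-k})
//                     + sum_{k=1}^{p} persist_k * log sigma2_{t-k}
//   g(Z) = theta Z + lambda (|Z| - sqrt(2/pi)),  Z_t = y_t / sigma_t
// The first max(p, q) values carry log_s2_init; pre-sample g terms are 0.
// [[Rcpp::export]]
List egarch_path_cpp(NumericVector y, double alpha0, NumericVector shock,
                     NumericVector persist, double theta, double lambda,
                     double log_s2_init) {
  const int n = y.size(), q = shock.size(), p = persist.size();
  const int m = std::max(p, q);
  const double eabs = std::sqrt(2.0 / M_PI);
  NumericVector ls2(n), g(n), z(n);
  for (int t = 0; t < std::min(m, n); ++t) {
    ls2[t] = log_s2_init;
    double sd = std::exp(0.5 * ls2[t]);
    z[t] = y[t] / sd;
    g[t] = theta * z[t] + lambda * (std::fabs(z[t]) - eabs);
  }
  for (int t = m; t < n; ++t) {
    double v = alpha0;
    for (int k = 0; k < q; ++k) {
      int lag = t - k - 1;
      if (lag >= 0) v += shock[k] * g[lag];
    }
    for (int k = 0; k < p; ++k) {
      int lag = t - k - 1;
      v += persist[k] * (lag >= 0 ? ls2[lag] : log_s2_init);
    }
    ls2[t] = v;
    double sd = std::exp(0.5 * v);
    z[t] = y[t] / sd;
    g[t] = theta * z[t] + lambda * (std::fabs(z[t]) - eabs);
  }
  return List::create(_["log_sigma2"] = ls2, _["z"] = z);
}

// Generative GARCH/GJR recursion driven by a supplied standard-normal stream.
// [[Rcpp::export]]
List garch_sim_cpp(NumericVector z, double alpha0, NumericVector alpha,
                   NumericVector beta, NumericVector gamma, double sigma2_init) {
  const int n = z.size(), q = alpha.size(), p = beta.size();
  const bool gjr = gamma.size() > 0;
  NumericVector y(n), s2(n);
  for (int t = 0; t < n; ++t) {
    double v = alpha0;
    for (int i = 0; i < q; ++i) {
      int lag = t - i - 1;
      if (lag >= 0) {
        double y2 = y[lag] * y[lag];
        v += alpha[i] * y2;
        if (gjr && y[lag] < 0) v += gamma[i] * y2;
      }
    }
    for (int j = 0; j < p; ++j) {
      int lag = t - j - 1;
      v += beta[j] * (lag >= 0 ? s2[lag] : sigma2_init);
    }
    s2[t] = v;
    y[t] = std::sqrt(v) * z[t];
  }
  return List::create(_["y"] = y, _["sigma2"] = s2);
}

// Generative EGARCH recursion driven by a supplied standard-normal stream.
// [[Rcpp::export]]
List egarch_sim_cpp(NumericVector z, double alpha0, NumericVector shock,
                    NumericVector persist, double theta, double lambda,
                    double log_s2_init) {
  const int n = z.size(), q = shock.size(), p = persist.size();
  const double eabs = std::sqrt(2.0 / M_PI);
  NumericVector y(n), ls2(n), g(n);
  for (int t = 0; t < n; ++t) {
    double v = alpha0;
    for (int k = 0; k < q; ++k) {
      int lag = t - k - 1;
      if (lag >= 0) v += shock[k] * g[lag];
    }
    for (int k = 0; k < p; ++k) {
      int lag = t - k - 1;
      v += persist[k] * (lag >= 0 ? ls2[lag] : log_s2_init);
    }
    ls2[t] = v;
    g[t] = theta * z[t] + lambda * (std::fabs(z[t]) - eabs);
    y[t] = std::exp(0.5 * v) * z[t];
  }
  return List::create(_["y"] = y, _["sigma2"] = exp(ls2));
}
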