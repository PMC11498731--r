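#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for a hidden Markov model with per-step
// transition matrices and burst restarts. General K; the R surface
// exercises K = 2.
//
// ldens:    T x K log emission densities
// trans:    K x K x T array; trans(.,.,t) moves the chain from step t-1 to
//           step t (row = from, col = to); unused where newburst[t] is true
// newburst: length-T flags; TRUE restarts the chain with delta(t, .)
// delta:    T x K initial distributions (rows used only at burst starts)
// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix ldens, NumericVector trans,
                          LogicalVector newburst, NumericMatrix delta) {
  int T = ldens.nrow(), K = ldens.ncol();
  std::vector<double> alpha(K), tmp(K);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double m = ldens(t, 0);
    for (int k = 1; k < K; ++k) if (ldens(t, k) > m) m = ldens(t, k);
    if (!R_finite(m)) m = 0.0;  // all-zero row handled via underflow check
    if (newburst[t]) {
      for (int j = 0; j < K; ++j)
        tmp[j] = delta(t, j) * std::exp(ldens(t, j) - m);
    } else {
      for (int j = 0; j < K; ++j) {
        double s = 0.0;
        for (int k = 0; k < K; ++k)
          s += alpha[k] * trans[k + K * j + K * K * t];
        tmp[j] = s * std::exp(ldens(t, j) - m);
      }
    }
    double c = 0.0;
    for (int j = 0; j < K; ++j) c += tmp[j];
    if (!(c > 0.0) || !R_finite(c)) return R_NegInf;
    for (int j = 0; j < K; ++j) alpha[j] = tmp[j] / c;
    ll += std::log(c) + m;
  }
  return ll;
}

// Full negative log-likelihood of the 2-state movement HMM, computed from
// raw data so optimizer evaluations avoid R-level vector assembly.
// s: step lengths; ang: turning angles with angok flagging defined ones;
// Z: T x p standardized covariates (p may be 0); newburst restarts the
// chain with the stationary distribution of the local transition matrix.
// The transition into step t uses the covariates of step t-1.
// [[Rcpp::export]]
double hmm_nll_cpp(NumericVector s, NumericVector ang, LogicalVector angok,
                   NumericMatrix Z, LogicalVector newburst,
                   NumericVector mu, NumericVector sigma,
                   NumericVector zm, NumericVector thet, NumericVector rho,
                   NumericVector b12, NumericVector b21) {
  int T = s.size(), p = Z.ncol();
  double shape[2], rate[2], lnorm[2], lzm[2], l1mzm[2], lrho[2], rho2[2];
  for (int k = 0; k < 2; ++k) {
    shape[k] = mu[k] * mu[k] / (sigma[k] * sigma[k]);
    rate[k] = mu[k] / (sigma[k] * sigma[k]);
    if (!(shape[k] > 0) || !(rate[k] > 0) ||
        shape[k] > 1e8 || rate[k] > 1e8) return 1e10;
    lnorm[k] = shape[k] * std::log(rate[k]) - std::lgamma(shape[k]);
    lzm[k] = zm[k] > 0 ? std::log(zm[k]) : R_NegInf;
    l1mzm[k] = std::log1p(-zm[k]);
    lrho[k] = std::log1p(-rho[k] * rho[k]) - std::log(2.0 * M_PI);
    rho2[k] = rho[k] * rho[k];
  }
  double alpha0 = 0.0, alpha1 = 0.0, ll = 0.0;
  double eta12_prev = 0.0, eta21_prev = 0.0;
  for (int t = 0; t < T; ++t) {
    double ld[2];
    for (int k = 0; k < 2; ++k) {
      if (s[t] == 0.0) {
        ld[k] = lzm[k];
      } else {
        ld[k] = l1mzm[k] + lnorm[k] + (shape[k] - 1.0) * std::log(s[t]) -
          rate[k] * s[t];
      }
      if (angok[t]) {
        ld[k] += lrho[k] -
          std::log(1.0 + rho2[k] - 2.0 * rho[k] * std::cos(ang[t] - thet[k]));
      }
    }
    double eta12 = b12[0], eta21 = b21[0];
    for (int j = 0; j < p; ++j) {
      eta12 += b12[j + 1] * Z(t, j);
      eta21 += b21[j + 1] * Z(t, j);
    }
    double m = ld[0] > ld[1] ? ld[0] : ld[1];
    if (!R_finite(m)) m = 0.0;
    double e0 = std::exp(ld[0] - m), e1 = std::exp(ld[1] - m);
    double t0, t1;
    if (newburst[t]) {
      double g12 = 1.0 / (1.0 + std::exp(-eta12));
      double g21 = 1.0 / (1.0 + std::exp(-eta21));
      double d1 = g21 / (g12 + g21);
      t0 = d1 * e0;
      t1 = (1.0 - d1) * e1;
    } else {
      double g12 = 1.0 / (1.0 + std::exp(-eta12_prev));
      double g21 = 1.0 / (1.0 + std::exp(-eta21_prev));
      t0 = (alpha0 * (1.0 - g12) + alpha1 * g21) * e0;
      t1 = (alpha0 * g12 + alpha1 * (1.0 - g21)) * e1;
    }
    double c = t0 + t1;
    if (!(c > 0.0) || !R_finite(c)) return 1e10;
    alpha0 = t0 / c; alpha1 = t1 / c;
    ll += std::log(c) + m;
    eta12_prev = eta12; eta21_prev = eta21;
  }
  if (!R_finite(ll)) return 1e10;
  return -ll;
}

// Viterbi decoding with the same conventions as forward_loglik_cpp.
// Ties break toward the lower state index. Returns 1-based states.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix ldens, NumericVector trans,
                          LogicalVector newburst, NumericMatrix delta) {
  int T = ldens.nrow(), K = ldens.ncol();
  NumericMatrix lv(T, K);
  IntegerMatrix bp(T, K);
  for (int t = 0; t < T; ++t) {
    if (newburst[t]) {
      for (int j = 0; j < K; ++j) {
        double d = delta(t, j);
        lv(t, j) = (d > 0.0 ? std::log(d) : R_NegInf) + ldens(t, j);
        bp(t, j) = -1;
      }
    } else {
      for (int j = 0; j < K; ++j) {
        double best = R_NegInf;
        int arg = 0;
        for (int k = 0; k < K; ++k) {
          double g = trans[k + K * j + K * K * t];
          double v = lv(t - 1, k) + (g > 0.0 ? std::log(g) : R_NegInf);
          if (v > best) { best = v; arg = k; }
        }
        lv(t, j) = best + ldens(t, j);
        bp(t, j) = arg;
      }
    }
  }
  IntegerVector path(T);
  // backtrack burst by burst (a burst ends where the next step restarts)
  int end = T - 1;
  while (end >= 0) {
    int start = end;
    while (start > 0 && !newburst[start]) --start;
    int arg = 0;
    for (int j = 1; j < K; ++j) if (lv(end, j) > lv(end, arg)) arg = j;
    path[end] = arg + 1;
    for (int t = end; t > start; --t) {
      arg = bp(t, arg);
      path[t - 1] = arg + 1;
    }
    end = start - 1;
  }
  return path;
}
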