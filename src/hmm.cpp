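#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian log-density, sigma assumed > 0 (floored on the R side).
static inline double ldnorm(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.918938533204672741780329736406; // log(sqrt(2*pi))
}

// One E-step of Baum-Welch for a Gaussian-emission HMM over multiple
// sequences, with per-frame renormalised emission weights so that tiny
// sigmas (near-noiseless traces) do not underflow. Returns the total
// log-likelihood and the sufficient statistics the M-step needs.
//
// x: concatenated observations; len: sequence lengths; means/sigmas: K;
// A: K x K row-stochastic transition matrix; pi0: K initial probabilities.
// [[Rcpp::export]]
List hmm_estep(NumericVector x, IntegerVector len, NumericVector means,
               NumericVector sigmas, NumericMatrix A, NumericVector pi0) {
  const int K = means.size();
  const int S = len.size();
  double loglik = 0.0;

  NumericVector g1(K);          // sum of gamma at t = 1 over sequences
  NumericMatrix xi(K, K);       // summed transition responsibilities
  NumericVector gsum(K), gx(K), gx2(K); // emission sufficient statistics

  int off = 0;
  for (int s = 0; s < S; ++s) {
    const int T = len[s];
    NumericMatrix b(T, K);      // renormalised emission weights
    NumericVector bmax(T);
    for (int t = 0; t < T; ++t) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double lb = ldnorm(x[off + t], means[k], sigmas[k]);
        b(t, k) = lb;
        if (lb > m) m = lb;
      }
      bmax[t] = m;
      for (int k = 0; k < K; ++k) b(t, k) = std::exp(b(t, k) - m);
      loglik += m;
    }

    NumericMatrix alpha(T, K), beta(T, K);
    NumericVector c(T);         // scaling factors
    double z = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = pi0[k] * b(0, k); z += alpha(0, k); }
    if (z <= 0.0) stop("forward pass underflowed at the first frame");
    c[0] = z;
    for (int k = 0; k < K; ++k) alpha(0, k) /= z;
    for (int t = 1; t < T; ++t) {
      z = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
        a *= b(t, k);
        alpha(t, k) = a;
        z += a;
      }
      if (z <= 0.0) stop("forward pass underflowed (zero total emission weight)");
      c[t] = z;
      for (int k = 0; k < K; ++k) alpha(t, k) /= z;
    }
    for (int t = 0; t < T; ++t) loglik += std::log(c[t]);

    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int j = 0; j < K; ++j) {
        double v = 0.0;
        for (int k = 0; k < K; ++k) v += A(j, k) * b(t + 1, k) * beta(t + 1, k);
        beta(t, j) = v / c[t + 1];
      }
    }

    for (int t = 0; t < T; ++t) {
      double gz = 0.0;
      for (int k = 0; k < K; ++k) gz += alpha(t, k) * beta(t, k);
      for (int k = 0; k < K; ++k) {
        double g = alpha(t, k) * beta(t, k) / gz;
        if (t == 0) g1[k] += g;
        gsum[k] += g;
        gx[k] += g * x[off + t];
        gx2[k] += g * x[off + t] * x[off + t];
      }
    }
    for (int t = 0; t < T - 1; ++t) {
      double zz = 0.0;
      NumericMatrix e(K, K);
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k) {
          double v = alpha(t, j) * A(j, k) * b(t + 1, k) * beta(t + 1, k);
          e(j, k) = v;
          zz += v;
        }
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k) xi(j, k) += e(j, k) / zz;
    }
    off += T;
  }

  return List::create(_["loglik"] = loglik, _["gamma1"] = g1, _["xi"] = xi,
                      _["gsum"] = gsum, _["gx"] = gx, _["gx2"] = gx2);
}

// Viterbi decoding in the log domain. Ties resolved toward the lower state
// index (strict > when scanning ascending indices).
// [[Rcpp::export]]
List hmm_viterbi(NumericVector x, NumericVector means, NumericVector sigmas,
                 NumericMatrix A, NumericVector pi0) {
  const int T = x.size(), K = means.size();
  NumericMatrix logA(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logA(j, k) = A(j, k) > 0 ? std::log(A(j, k)) : R_NegInf;

  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k)
    delta(0, k) = (pi0[k] > 0 ? std::log(pi0[k]) : R_NegInf) + ldnorm(x[0], means[k], sigmas[k]);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + ldnorm(x[t], means[k], sigmas[k]);
      psi(t, k) = arg;
    }

  IntegerVector path(T);
  double best = R_NegInf;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); path[T - 1] = k; }
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);

  return List::create(_["path"] = path, _["logprob"] = best);
}
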