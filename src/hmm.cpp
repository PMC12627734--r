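#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a discrete-time HMM.
// logdens: T x K matrix of log emission densities.
// Returns log-likelihood, posterior state probabilities (gamma),
// summed transition posteriors (xi_sum, K x K) and gamma at t = 0.
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logdens, NumericMatrix A,
                          NumericVector pi) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix B(T, K);
  for (int t = 0; t < T; ++t) {
    double m = logdens(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logdens(t, k));
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logdens(t, k) - m);
  }
  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);
  double loglik = 0.0;
  for (int k = 0; k < K; ++k) alpha(0, k) = pi[k] * B(0, k);
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += alpha(0, k);
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      a *= B(t, k);
      alpha(t, k) = a;
      s += a;
    }
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  for (int t = 0; t < T; ++t) {
    double m = logdens(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logdens(t, k));
    loglik += std::log(c[t]) + m;
  }
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / c[t + 1];
    }
  }
  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  NumericMatrix xi_sum(K, K);
  for (int t = 0; t < T - 1; ++t) {
    double z = 0.0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        z += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi_sum(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) *
                        beta(t + 1, k) / z;
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum);
}

// Most likely state path (Viterbi). Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logdens, NumericMatrix A,
                          NumericVector pi) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix logA(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logA(j, k) = std::log(A(j, k));
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = std::log(pi[k]) + logdens(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + logA(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logdens(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > delta(T - 1, arg)) arg = k;
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}

// Cascade of biquad sections (direct form II transposed) with initial
// state zi scaled to match a given reference level per section, as in
// zero-phase filtering practice: a constant input then yields a constant
// output with no startup transient.
// sos: rows [b0 b1 b2 1 a1 a2].
// [[Rcpp::export]]
NumericVector sosfilt_zi(NumericVector x, NumericMatrix sos, double x0) {
  const int n = x.size(), S = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < S; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    const double h = (b0 + b1 + b2) / (1.0 + a1 + a2);  // DC gain
    // steady state of the two delay registers for constant input x0
    double z2 = (b2 - a2 * h) * x0;
    double z1 = (b1 - a1 * h) * x0 + z2;
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi + z2 - a1 * yi;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
    x0 = h * x0;  // reference level seen by the next section
  }
  return y;
}
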