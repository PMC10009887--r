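#include <Rcpp.h>
using namespace Rcpp;

// Exponentially weighted recursive least squares realised through QR
// decomposition updates (Givens rotations on the upper-triangular
// square-root factor). The regressor at sample n is the concatenation of
// the last `taps` samples of each reference column. The returned output is
// the a priori error e(n) = d(n) - w(n-1)' u(n), i.e. the abdominal signal
// with the reference-explained (maternal) component removed.
// [[Rcpp::export(name = ".qrd_rls_core")]]
List qrd_rls_core(NumericVector d, NumericMatrix refs, int taps,
                  double lambda, double delta) {
  const int n = d.size();
  const int n_ref = refs.ncol();
  const int M = taps * n_ref;
  if (refs.nrow() != n) stop("reference length mismatch");
  if (lambda <= 0.0 || lambda > 1.0) stop("lambda must be in (0, 1]");
  if (taps < 1) stop("taps must be >= 1");

  const double sl = std::sqrt(lambda);
  // Upper-triangular factor R (M x M) and rotated right-hand side p.
  std::vector<double> R(M * M, 0.0), p(M, 0.0), w(M, 0.0), u(M);
  for (int i = 0; i < M; ++i) R[i * M + i] = delta;

  NumericVector e(n);
  for (int t = 0; t < n; ++t) {
    // Build regressor u(t).
    for (int k = 0; k < n_ref; ++k) {
      for (int j = 0; j < taps; ++j) {
        int idx = t - j;
        u[k * taps + j] = idx >= 0 ? refs(idx, k) : 0.0;
      }
    }
    // A priori error with previous weights.
    double yhat = 0.0;
    for (int i = 0; i < M; ++i) yhat += w[i] * u[i];
    e[t] = d[t] - yhat;

    // Exponential forgetting, then annihilate u into R with Givens rotations.
    double dd = d[t];
    for (int i = 0; i < M; ++i) {
      p[i] *= sl;
      for (int j = i; j < M; ++j) R[i * M + j] *= sl;
    }
    for (int i = 0; i < M; ++i) {
      double a = R[i * M + i], b = u[i];
      if (b == 0.0) continue;
      double r = std::hypot(a, b);
      double c = a / r, s = b / r;
      R[i * M + i] = r;
      for (int j = i + 1; j < M; ++j) {
        double Rij = R[i * M + j], uj = u[j];
        R[i * M + j] = c * Rij + s * uj;
        u[j] = -s * Rij + c * uj;
      }
      double pi = p[i];
      p[i] = c * pi + s * dd;
      dd = -s * pi + c * dd;
    }
    // Back-substitution: R w = p.
    for (int i = M - 1; i >= 0; --i) {
      double acc = p[i];
      for (int j = i + 1; j < M; ++j) acc -= R[i * M + j] * w[j];
      w[i] = acc / R[i * M + i];
    }
  }

  return List::create(_["e"] = e,
                      _["weights"] = NumericVector(w.begin(), w.end()));
}
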