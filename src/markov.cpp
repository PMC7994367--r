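#include <Rcpp.h>
using namespace Rcpp;

// Emit a first-order Markov chain over {A,C,G,T} as one string.
//
// u supplies one uniform(0,1) variate per emitted base, drawn in R so the
// caller's RNG state (set.seed) governs the sequence. When gradient is true
// the per-position transition matrix is the mixture
//   P(x) = (1 - w(x)) * P_center + w(x) * P_edge,  w(x) = (2 x / L - 1)^2,
// an edge-heavy parabolic weight along the chromosome (x = 0 .. L-1).
// [[Rcpp::export]]
std::string markov_emit_cpp(NumericVector pi0, NumericMatrix P_center,
                            NumericMatrix P_edge, NumericVector u,
                            bool gradient) {
  const int n = u.size();
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string out;
  if (n == 0) return out;
  out.resize(n);

  // row-major copies for cache-friendly access
  double pc[16], pe[16];
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) {
      pc[4 * a + b] = P_center(a, b);
      pe[4 * a + b] = P_edge(a, b);
    }

  // initial base from pi0
  int state = 3;
  {
    double cum = 0.0, v = u[0];
    for (int b = 0; b < 4; ++b) {
      cum += pi0[b];
      if (v <= cum) { state = b; break; }
    }
  }
  out[0] = bases[state];

  const double L = static_cast<double>(n);
  for (int x = 1; x < n; ++x) {
    const double *row_c = pc + 4 * state;
    double v = u[x], cum = 0.0;
    int next = 3;
    if (!gradient) {
      for (int b = 0; b < 4; ++b) {
        cum += row_c[b];
        if (v <= cum) { next = b; break; }
      }
    } else {
      const double *row_e = pe + 4 * state;
      const double t = 2.0 * static_cast<double>(x) / L - 1.0;
      const double w = t * t;
      for (int b = 0; b < 4; ++b) {
        cum += (1.0 - w) * row_c[b] + w * row_e[b];
        if (v <= cum) { next = b; break; }
      }
    }
    state = next;
    out[x] = bases[state];
  }
  return out;
}
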