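// Fast path for scalogram rendering: |coefs| -> min-max normalize ->
// piecewise-linear jet. Must stay bit-identical to the R-level
// jet_color(): value = round(255 * clamp(1.5 - |4 v - kappa|, 0, 1)) with
// kappa = 3, 2, 1 for r, g, b and round-half-to-even (R's round()).

#include <RcppArmadillo.h>
#include <cfenv>
// [[Rcpp::depends(RcppArmadillo)]]

static inline double jet_chan(double v, double kappa) {
  double x = 1.5 - std::fabs(4.0 * v - kappa);
  x = std::min(std::max(x, 0.0), 1.0);
  return std::nearbyint(255.0 * x); // FE_TONEAREST: ties to even, as in R
}

// coefs: S x T matrix; returns S x T x 3 numeric array of jet values
// [[Rcpp::export]]
arma::cube jet_field_cpp(const arma::mat& coefs) {
  std::fesetround(FE_TONEAREST);
  const arma::mat m = arma::abs(coefs);
  const double lo = m.min(), hi = m.max();
  const double span = hi - lo;
  arma::cube out(m.n_rows, m.n_cols, 3);
  const double* src = m.memptr();
  double* r = out.slice(0).memptr();
  double* g = out.slice(1).memptr();
  double* b = out.slice(2).memptr();
  for (arma::uword i = 0; i < m.n_elem; ++i) {
    const double v = span > 0 ? (src[i] - lo) / span : 0.0;
    r[i] = jet_chan(v, 3.0);
    g[i] = jet_chan(v, 2.0);
    b[i] = jet_chan(v, 1.0);
  }
  return out;
}
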