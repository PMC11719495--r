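// Continuous wavelet transform with the real Morlet wavelet
// psi(t) = exp(-t^2/2) * cos(5 t)
//
// W(a, b) = a^{-1/2} * sum_{n=0}^{T-1} x[n] * psi((n - b)/a),  b = 0..T-1
//
// The sum is a linear convolution of x with the sampled kernel
// k_a[d] = psi(d/a), d = -L..L (psi is even, so correlation == convolution),
// evaluated exactly by zero-padded FFT. The kernel is truncated where
// |t| > 8 (psi(8) ~ 1.3e-14), far below the double-precision noise floor
// of the sum itself.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static arma::vec morlet_kernel(double a, int L) {
  arma::vec k(2 * L + 1);
  for (int d = -L; d <= L; ++d) {
    double t = static_cast<double>(d) / a;
    k[d + L] = std::exp(-0.5 * t * t) * std::cos(5.0 * t);
  }
  return k;
}

// x: T x n_channels matrix (one column per channel)
// returns cube: n_scales x T x n_channels
// [[Rcpp::export]]
arma::cube cwt_stack_cpp(const arma::mat& x, const arma::vec& scales) {
  const int T = x.n_rows;
  const int C = x.n_cols;
  const int S = scales.n_elem;
  if (T < 2) Rcpp::stop("signal must have at least 2 samples");
  for (int s = 0; s < S; ++s)
    if (!(scales[s] > 0)) Rcpp::stop("scales must be positive");

  std::vector<int> Ls(S);
  int Lmax = 0;
  for (int s = 0; s < S; ++s) {
    Ls[s] = std::min(static_cast<int>(std::ceil(8.0 * scales[s])), T - 1);
    Lmax = std::max(Lmax, Ls[s]);
  }
  int need = T + 2 * Lmax; // >= linear convolution length for every scale
  int N = 1;
  while (N < need) N <<= 1;

  arma::cx_mat Kf(N, S);
  for (int s = 0; s < S; ++s) {
    arma::vec kp(N, arma::fill::zeros);
    arma::vec k = morlet_kernel(scales[s], Ls[s]);
    kp.head(k.n_elem) = k;
    Kf.col(s) = arma::fft(kp);
  }

  arma::cube W(S, T, C);
  for (int c = 0; c < C; ++c) {
    arma::vec xp(N, arma::fill::zeros);
    xp.head(T) = x.col(c);
    arma::cx_vec Xf = arma::fft(xp);
    for (int s = 0; s < S; ++s) {
      arma::cx_vec y = arma::ifft(arma::cx_vec(Xf % Kf.col(s)));
      const double norm = 1.0 / std::sqrt(scales[s]);
      const int L = Ls[s];
      for (int b = 0; b < T; ++b) W(s, b, c) = norm * y[b + L].real();
    }
  }
  return W;
}
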