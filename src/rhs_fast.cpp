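// Compiled fast path for the eliminated-ODE right-hand side: standard
// Hodgkin-Huxley / passive segments under DC or sinusoidal current
// injection, with the (closed-loop) self-consistency operator folded into
// the constant matrix Q = I + A (I - T A)^{-1} T, so that
//   dVm/dt = (Q (A Vm + I_inj) - I_ion) / C.
// Systems with synapses, custom stimuli or user models take the R path.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline double vtrap_f(double x, double y) {
  double q = x / y;
  if (std::fabs(q) < 1e-7) return y * (1.0 + q / 2.0);
  return x / (1.0 - std::exp(-q));
}

// [[Rcpp::export]]
arma::vec rhs_fast(double t, const arma::vec& y, const arma::mat& A,
                   const arma::mat& Q, const arma::vec& C,
                   const arma::ivec& code, const arma::mat& par,
                   const arma::mat& stim) {
  const int n = A.n_rows;
  int nh = 0;
  for (int i = 0; i < n; ++i) if (code(i) == 1) ++nh;
  vec v = y.subvec(0, n - 1);
  vec s0 = A * v;
  for (int i = 0; i < n; ++i) {
    s0(i) += stim(i, 0);
    if (stim(i, 1) != 0.0) {
      s0(i) += stim(i, 1) *
        std::sin(2.0 * M_PI * stim(i, 2) * t / 1000.0 + stim(i, 3));
    }
  }
  vec num = Q * s0;
  vec dy(y.n_elem, fill::zeros);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    double iion;
    if (code(i) == 1) {
      double m = y(n + k), h = y(n + nh + k), nn = y(n + 2 * nh + k);
      iion = par(i, 0) * m * m * m * h * (v(i) - par(i, 3)) +
             par(i, 1) * nn * nn * nn * nn * (v(i) - par(i, 4)) +
             par(i, 2) * (v(i) - par(i, 5));
      double am = 0.1 * vtrap_f(v(i) + 40.0, 10.0);
      double bm = 4.0 * std::exp(-(v(i) + 65.0) / 18.0);
      double ah = 0.07 * std::exp(-(v(i) + 65.0) / 20.0);
      double bh = 1.0 / (1.0 + std::exp(-(v(i) + 35.0) / 10.0));
      double an = 0.01 * vtrap_f(v(i) + 55.0, 10.0);
      double bn = 0.125 * std::exp(-(v(i) + 65.0) / 80.0);
      dy(n + k) = am * (1.0 - m) - bm * m;
      dy(n + nh + k) = ah * (1.0 - h) - bh * h;
      dy(n + 2 * nh + k) = an * (1.0 - nn) - bn * nn;
      ++k;
    } else {
      iion = par(i, 2) * (v(i) - par(i, 5));
    }
    dy(i) = (num(i) - iion) / C(i);
  }
  return dy;
}
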