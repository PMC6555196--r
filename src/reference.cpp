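// Fixed-step backward-Euler reference integrator with (modified) Newton
// iteration, for open-loop compartmental networks of Hodgkin-Huxley and
// passive segments under DC / sinusoidal current injection. This solver is
// deliberately independent of the adaptive deSolve path: it shares the
// spatial discretization (axial matrix, capacitances, conductances) but no
// time-stepping code, and serves as the in-repo accuracy oracle.
//
// Units: V in mV, t in ms, conductances pre-scaled to uS, currents in nA,
// capacitances in nF (so uS * mV = nA and nF * mV/ms = nA).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline double vtrap(double x, double y) {
  double q = x / y;
  if (std::fabs(q) < 1e-7) return y * (1.0 + q / 2.0);
  return x / (1.0 - std::exp(-q));
}

struct Rates {
  double am, bm, ah, bh, an, bn;
};

static inline Rates hh_rates(double v) {
  Rates r;
  r.am = 0.1 * vtrap(v + 40.0, 10.0);
  r.bm = 4.0 * std::exp(-(v + 65.0) / 18.0);
  r.ah = 0.07 * std::exp(-(v + 65.0) / 20.0);
  r.bh = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  r.an = 0.01 * vtrap(v + 55.0, 10.0);
  r.bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
  return r;
}

// layout: y = [V (n) | m (nh) | h (nh) | n (nh)] where nh = # HH segments
struct Sys {
  const mat& A;        // axial conductance matrix, uS
  const vec& C;        // capacitance, nF
  const ivec& code;    // 0 passive, 1 HH
  const mat& par;      // n x 6: gna_uS gk_uS gl_uS ena ek el
  const mat& stim;     // n x 4: dc_nA amp_sin_nA freq_Hz phase
  ivec hpos;           // position of segment i in the HH blocks, else -1
  int n, nh, nst;
};

static vec rhs(const Sys& S, double t, const vec& y) {
  const int n = S.n, nh = S.nh;
  vec v = y.subvec(0, n - 1);
  vec inj(n);
  for (int i = 0; i < n; ++i) {
    inj(i) = S.stim(i, 0);
    if (S.stim(i, 1) != 0.0) {
      inj(i) += S.stim(i, 1) *
        std::sin(2.0 * M_PI * S.stim(i, 2) * t / 1000.0 + S.stim(i, 3));
    }
  }
  vec axial = S.A * v;
  vec dy(S.nst, fill::zeros);
  for (int i = 0; i < n; ++i) {
    double iion;
    if (S.code(i) == 1) {
      int k = S.hpos(i);
      double m = y(n + k), h = y(n + nh + k), nn = y(n + 2 * nh + k);
      iion = S.par(i, 0) * m * m * m * h * (v(i) - S.par(i, 3)) +
             S.par(i, 1) * nn * nn * nn * nn * (v(i) - S.par(i, 4)) +
             S.par(i, 2) * (v(i) - S.par(i, 5));
      Rates r = hh_rates(v(i));
      dy(n + k) = r.am * (1.0 - m) - r.bm * m;
      dy(n + nh + k) = r.ah * (1.0 - h) - r.bh * h;
      dy(n + 2 * nh + k) = r.an * (1.0 - nn) - r.bn * nn;
    } else {
      iion = S.par(i, 2) * (v(i) - S.par(i, 5));
    }
    dy(i) = (axial(i) + inj(i) - iion) / S.C(i);
  }
  return dy;
}

// analytic Jacobian of the rhs
static void jac(const Sys& S, double t, const vec& y, mat& J) {
  (void)t;
  const int n = S.n, nh = S.nh;
  J.zeros();
  J.submat(0, 0, n - 1, n - 1) = S.A;
  const double dv = 1e-5;
  for (int i = 0; i < n; ++i) {
    double vi = y(i);
    if (S.code(i) == 1) {
      int k = S.hpos(i);
      double m = y(n + k), h = y(n + nh + k), nn = y(n + 2 * nh + k);
      double g = S.par(i, 0) * m * m * m * h + S.par(i, 1) * nn * nn * nn * nn +
                 S.par(i, 2);
      J(i, i) -= g;
      J(i, n + k) = -3.0 * S.par(i, 0) * m * m * h * (vi - S.par(i, 3));
      J(i, n + nh + k) = -S.par(i, 0) * m * m * m * (vi - S.par(i, 3));
      J(i, n + 2 * nh + k) = -4.0 * S.par(i, 1) * nn * nn * nn * (vi - S.par(i, 4));
      Rates rp = hh_rates(vi + dv), rm = hh_rates(vi - dv);
      J(n + k, i) = ((rp.am - rm.am) * (1.0 - m) - (rp.bm - rm.bm) * m) / (2 * dv);
      J(n + nh + k, i) = ((rp.ah - rm.ah) * (1.0 - h) - (rp.bh - rm.bh) * h) / (2 * dv);
      J(n + 2 * nh + k, i) = ((rp.an - rm.an) * (1.0 - nn) - (rp.bn - rm.bn) * nn) / (2 * dv);
      Rates r = hh_rates(vi);
      J(n + k, n + k) = -(r.am + r.bm);
      J(n + nh + k, n + nh + k) = -(r.ah + r.bh);
      J(n + 2 * nh + k, n + 2 * nh + k) = -(r.an + r.bn);
    } else {
      J(i, i) -= S.par(i, 2);
    }
  }
  for (int i = 0; i < n; ++i) J.row(i) /= S.C(i);
}

// [[Rcpp::export]]
Rcpp::List be_reference_solve(const arma::mat& A, const arma::vec& C,
                              const arma::ivec& model_code,
                              const arma::mat& par, const arma::mat& stim,
                              const arma::vec& y0, double t0, double t1,
                              double dt, int store_every) {
  Sys S{A, C, model_code, par, stim, ivec(), (int)A.n_rows, 0, 0};
  S.hpos.set_size(S.n);
  S.hpos.fill(-1);
  for (int i = 0; i < S.n; ++i) if (model_code(i) == 1) S.hpos(i) = S.nh++;
  S.nst = S.n + 3 * S.nh;
  if ((int)y0.n_elem != S.nst) Rcpp::stop("state length mismatch");

  long nsteps = (long)std::llround((t1 - t0) / dt);
  long nstore = nsteps / store_every + 2;
  mat Y(nstore, S.nst);
  vec times(nstore);
  vec y = y0, yprev = y0;
  Y.row(0) = y.t();
  times(0) = t0;
  long isave = 1;

  mat J(S.nst, S.nst), L, U, P;
  bool have_lu = false, fresh = false;
  const double tol = 1e-10;

  for (long k = 1; k <= nsteps; ++k) {
    double tnew = t0 + (double)k * dt;
    yprev = y;
    fresh = false;
    if (!have_lu) {
      jac(S, tnew, y, J);
      mat JF = eye(S.nst, S.nst) - dt * J;
      if (!lu(L, U, P, JF)) Rcpp::stop("LU factorization failed at step %ld", k);
      have_lu = true;
      fresh = true;
    }
    bool converged = false;
    int it = 0;
    while (it < 12) {
      ++it;
      vec r = y - yprev - dt * rhs(S, tnew, y);
      vec delta = solve(trimatu(U), solve(trimatl(L), P * (-r)));
      y += delta;
      if (norm(delta, "inf") < tol) { converged = true; break; }
      if (it >= 4 && !fresh) {
        jac(S, tnew, y, J);
        mat JF = eye(S.nst, S.nst) - dt * J;
        if (!lu(L, U, P, JF)) Rcpp::stop("LU factorization failed at step %ld", k);
        fresh = true;
        it = 0;  // restart the count with the fresh Jacobian
      }
    }
    if (!converged) {
      Rcpp::stop("Newton iteration did not converge at step %ld (t = %g ms)",
                 k, tnew);
    }
    if (!fresh && it > 3) have_lu = false;  // stale factor is struggling
    if (k % store_every == 0 || k == nsteps) {
      if (isave < nstore) {
        Y.row(isave) = y.t();
        times(isave) = tnew;
        ++isave;
      }
    }
    if (k % 5000 == 0) Rcpp::checkUserInterrupt();
  }
  if (isave < nstore) {
    Y.resize(isave, S.nst);
    times.resize(isave);
  }
  return Rcpp::List::create(Rcpp::Named("times") = times,
                            Rcpp::Named("y") = Y);
}
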