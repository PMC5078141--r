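// Core numerical kernels for the spectral DCM engine.
//
// The generative model maps a stable neural coupling matrix A (Hz), region-wise
// haemodynamic (balloon) constants and power-law spectral noise parameters to
// the cross-spectral density of the observed BOLD signal:
//
//   S(f) = T(f) G_v(f) T(f)^H + G_e(f),   T(f) = diag(K(f)) (i 2 pi f I - A)^-1
//
// where K_r(f) is the transfer function of the balloon cascade linearised
// about its resting fixed point, and G_v / G_e are diagonal power-law spectra
// amp * f^(-exp) of the endogenous fluctuations and observation noise.
// These kernels sit inside the finite-difference Jacobian loop of the
// variational-Laplace inversion, hence C++.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Jacobian of the balloon cascade (states s, f, v, q) at the fixed point
// (0, 1, 1, 1), for one region.
static mat balloon_jacobian(double kappa, double gamma, double tau,
                            double alpha, double E0) {
  const double cf = (E0 + (1.0 - E0) * std::log(1.0 - E0)) / E0;
  const double cv = 1.0 / alpha - 1.0;
  mat J(4, 4, fill::zeros);
  J(0, 0) = -kappa; J(0, 1) = -gamma;
  J(1, 0) = 1.0;
  J(2, 1) = 1.0 / tau; J(2, 2) = -1.0 / (alpha * tau);
  J(3, 1) = cf / tau;  J(3, 2) = -cv / tau; J(3, 3) = -1.0 / tau;
  return J;
}

// Frequency response K_r(f) = C (i 2 pi f I - J)^-1 B of the linearised
// balloon cascade; rows = frequencies, cols = regions.
// [[Rcpp::export]]
arma::cx_mat hemo_kernel_cpp(const arma::vec& tau, double kappa, double gamma,
                             double alpha, double E0, double V0,
                             const arma::vec& freqs) {
  const double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;
  const uword n = tau.n_elem, nf = freqs.n_elem;
  rowvec Cr(4, fill::zeros);
  Cr(2) = V0 * (k2 - k3);
  Cr(3) = -V0 * (k1 + k2);
  vec B(4, fill::zeros);
  B(0) = 1.0;
  cx_mat K(nf, n);
  for (uword r = 0; r < n; ++r) {
    mat J = balloon_jacobian(kappa, gamma, tau(r), alpha, E0);
    cx_mat Jc = cx_mat(J, mat(4, 4, fill::zeros));
    for (uword k = 0; k < nf; ++k) {
      std::complex<double> iw(0.0, 2.0 * datum::pi * freqs(k));
      cx_mat M = iw * cx_mat(eye(4, 4), mat(4, 4, fill::zeros)) - Jc;
      cx_vec x = solve(M, cx_vec(B, vec(4, fill::zeros)));
      K(k, r) = as_scalar(cx_rowvec(Cr, rowvec(4, fill::zeros)) * x);
    }
  }
  return K;
}

// Predicted cross-spectral density cube (n x n x nf).
// [[Rcpp::export]]
arma::cx_cube csd_predict_cpp(const arma::mat& A, const arma::vec& tau,
                              double kappa, double gamma, double alpha,
                              double E0, double V0,
                              const arma::vec& ampv, const arma::vec& expv,
                              const arma::vec& ampe, const arma::vec& expe,
                              const arma::vec& freqs) {
  const uword n = A.n_rows, nf = freqs.n_elem;
  cx_mat K = hemo_kernel_cpp(tau, kappa, gamma, alpha, E0, V0, freqs);
  cx_cube S(n, n, nf);
  cx_mat I = cx_mat(eye(n, n), mat(n, n, fill::zeros));
  cx_mat Ac = cx_mat(A, mat(n, n, fill::zeros));
  for (uword k = 0; k < nf; ++k) {
    const double f = freqs(k);
    std::complex<double> iw(0.0, 2.0 * datum::pi * f);
    cx_mat T = solve(iw * I - Ac, I);        // (i w I - A)^-1
    for (uword r = 0; r < n; ++r) T.row(r) *= K(k, r);
    vec gv(n), ge(n);
    for (uword r = 0; r < n; ++r) {
      gv(r) = ampv(r) * std::pow(f, -expv(r));
      ge(r) = ampe(r) * std::pow(f, -expe(r));
    }
    cx_mat Sk = T * diagmat(cx_vec(gv, vec(n, fill::zeros))) * T.t();  // .t() is conj-transpose
    Sk.diag() += cx_vec(ge, vec(n, fill::zeros));
    S.slice(k) = 0.5 * (Sk + Sk.t());        // enforce exact Hermitian symmetry
  }
  return S;
}

// Stack a Hermitian CSD cube into the real data vector used by the
// likelihood: per frequency, Re of the upper triangle (including diagonal,
// column-major), then Im of the strict upper triangle (column-major).
// `wts` (empty = all 1) rescales each frequency slice; the inversion uses
// inverse-power weights so every band contributes comparably.
// [[Rcpp::export]]
arma::vec csd_stack_cpp(const arma::cx_cube& S, const arma::vec& wts) {
  const uword n = S.n_rows, nf = S.n_slices;
  const uword per = n * (n + 1) / 2 + n * (n - 1) / 2;  // = n^2
  vec y(per * nf);
  uword t = 0;
  for (uword k = 0; k < nf; ++k) {
    const double w = wts.n_elem ? wts(k) : 1.0;
    for (uword j = 0; j < n; ++j)
      for (uword i = 0; i <= j; ++i) y(t++) = w * S(i, j, k).real();
    for (uword j = 0; j < n; ++j)
      for (uword i = 0; i < j; ++i) y(t++) = w * S(i, j, k).imag();
  }
  return y;
}

// Predicted CSD already stacked (single call for the Jacobian loop).
// [[Rcpp::export]]
arma::vec csd_predict_stacked_cpp(const arma::mat& A, const arma::vec& tau,
                                  double kappa, double gamma, double alpha,
                                  double E0, double V0,
                                  const arma::vec& ampv, const arma::vec& expv,
                                  const arma::vec& ampe, const arma::vec& expe,
                                  const arma::vec& freqs,
                                  const arma::vec& wts) {
  return csd_stack_cpp(csd_predict_cpp(A, tau, kappa, gamma, alpha, E0, V0,
                                       ampv, expv, ampe, expe, freqs), wts);
}

// --- packed-parameter evaluation (the inner loop of variational Laplace) ---
//
// Parameter layout: [free couplings (na), self log-scales (n), transit
// log-scales (n), log_amp_v, log_amp_e, exp_v, exp_e]. Self connections are
// -0.5 exp(theta); transit times tau0 exp(theta); noise amplitudes
// av0/ae0 exp(theta), shared across regions.

static bool unpack_eval(const vec& theta, const uvec& free_i,
                        const uvec& free_j, uword n, const vec& tau0,
                        double kappa, double gamma, double alpha, double E0,
                        double V0, double av0, double ae0, const vec& freqs,
                        const vec& wts, vec& g) {
  const uword na = free_i.n_elem;
  mat A(n, n, fill::zeros);
  for (uword k = 0; k < na; ++k) A(free_i(k), free_j(k)) = theta(k);
  for (uword r = 0; r < n; ++r) A(r, r) = -0.5 * std::exp(theta(na + r));
  cx_vec ev;
  if (!eig_gen(ev, A)) return false;
  if (real(ev).max() > -1e-6) return false;
  vec tau = tau0 % exp(theta.subvec(na + n, na + 2 * n - 1));
  const double av = av0 * std::exp(theta(na + 2 * n));
  const double ae = ae0 * std::exp(theta(na + 2 * n + 1));
  const double evx = theta(na + 2 * n + 2), eex = theta(na + 2 * n + 3);
  vec ampv(n, fill::value(av)), ampe(n, fill::value(ae)),
      expv(n, fill::value(evx)), expe(n, fill::value(eex));
  g = csd_stack_cpp(csd_predict_cpp(A, tau, kappa, gamma, alpha, E0, V0,
                                    ampv, expv, ampe, expe, freqs), wts);
  return true;
}

// [[Rcpp::export]]
Rcpp::List spdcm_eval_cpp(const arma::vec& theta, const arma::uvec& free_i,
                          const arma::uvec& free_j, int n,
                          const arma::vec& tau0, double kappa, double gamma,
                          double alpha, double E0, double V0, double av0,
                          double ae0, const arma::vec& freqs,
                          const arma::vec& wts) {
  vec g;
  bool ok = unpack_eval(theta, free_i, free_j, (uword)n, tau0, kappa, gamma,
                        alpha, E0, V0, av0, ae0, freqs, wts, g);
  return Rcpp::List::create(Rcpp::Named("ok") = ok, Rcpp::Named("g") = g);
}

// Forward-difference Jacobian of the stacked (weighted) prediction; falls
// back to a backward step for perturbations that destabilise the system.
// [[Rcpp::export]]
Rcpp::List spdcm_jac_cpp(const arma::vec& theta, const arma::uvec& free_i,
                         const arma::uvec& free_j, int n,
                         const arma::vec& tau0, double kappa, double gamma,
                         double alpha, double E0, double V0, double av0,
                         double ae0, const arma::vec& freqs,
                         const arma::vec& wts, double h) {
  vec g0;
  bool ok = unpack_eval(theta, free_i, free_j, (uword)n, tau0, kappa, gamma,
                        alpha, E0, V0, av0, ae0, freqs, wts, g0);
  if (!ok)
    return Rcpp::List::create(Rcpp::Named("ok") = false);
  const uword p = theta.n_elem;
  mat J(g0.n_elem, p);
  vec gp;
  for (uword j = 0; j < p; ++j) {
    vec tp = theta; tp(j) += h;
    if (unpack_eval(tp, free_i, free_j, (uword)n, tau0, kappa, gamma, alpha,
                    E0, V0, av0, ae0, freqs, wts, gp)) {
      J.col(j) = (gp - g0) / h;
    } else {
      tp(j) = theta(j) - h;
      if (!unpack_eval(tp, free_i, free_j, (uword)n, tau0, kappa, gamma,
                       alpha, E0, V0, av0, ae0, freqs, wts, gp))
        return Rcpp::List::create(Rcpp::Named("ok") = false);
      J.col(j) = (g0 - gp) / h;
    }
  }
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("g") = g0, Rcpp::Named("J") = J);
}

// Euler integration of the coupled neural + balloon system.
// v: n_t x n matrix of endogenous fluctuation inputs (already synthesised).
// The positive haemodynamic states (flow f, volume v, deoxyhaemoglobin q)
// are integrated in log space, which keeps them positive under large
// excursions. Returns latent neural states x and BOLD fractional signal
// change y (both n_t x n). Errors on non-finite states, reporting step and
// region.
// [[Rcpp::export]]
Rcpp::List balloon_sim_cpp(const arma::mat& A, const arma::mat& v, double dt,
                           const arma::vec& tau, double kappa, double gamma,
                           double alpha, double E0, double V0) {
  const uword nt = v.n_rows, n = v.n_cols;
  const double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;
  mat x(nt, n, fill::zeros), y(nt, n, fill::zeros);
  vec xs(n, fill::zeros), s(n, fill::zeros), zf(n, fill::zeros),
      zv(n, fill::zeros), zq(n, fill::zeros);
  for (uword t = 0; t < nt; ++t) {
    x.row(t) = xs.t();
    vec fb = exp(zf), vb = exp(zv), q = exp(zq);
    for (uword r = 0; r < n; ++r)
      y(t, r) = V0 * (k1 * (1.0 - q(r)) + k2 * (1.0 - q(r) / vb(r)) +
                      k3 * (1.0 - vb(r)));
    vec dx = A * xs + v.row(t).t();
    vec ds = xs - kappa * s - gamma * (fb - 1.0);
    vec vexp(n), Ef(n);
    for (uword r = 0; r < n; ++r) {
      vexp(r) = std::pow(vb(r), 1.0 / alpha);
      Ef(r) = 1.0 - std::pow(1.0 - E0, 1.0 / fb(r));
    }
    vec dzf = s / fb;
    vec dzv = (fb - vexp) / (tau % vb);
    vec dzq = (fb % Ef / E0 - vexp % q / vb) / (tau % q);
    xs += dt * dx; s += dt * ds; zf += dt * dzf; zv += dt * dzv;
    zq += dt * dzq;
    // physiological guard: cap log-states at |z| = 4 (f, v, q within
    // [e^-4, e^4]); sustained neural drive below -gamma would otherwise
    // push the flow equilibrium negative and the log-state to -Inf
    zf = clamp(zf, -4.0, 4.0); zv = clamp(zv, -4.0, 4.0);
    zq = clamp(zq, -4.0, 4.0);
    if (!xs.is_finite() || !zf.is_finite() || !zv.is_finite() ||
        !zq.is_finite()) {
      uword bad = 0;
      for (uword r = 0; r < n; ++r)
        if (!std::isfinite(xs(r)) || !std::isfinite(zf(r)) ||
            !std::isfinite(zv(r)) || !std::isfinite(zq(r))) { bad = r; break; }
      Rcpp::stop("non-finite state at t = %.2f s in region %d",
                 (t + 1) * dt, (int)bad + 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("x") = x, Rcpp::Named("y") = y);
}
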