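#include <Rcpp.h>
using namespace Rcpp;

// Steady axisymmetric Stokes flow in stream function-vorticity form on a
// boundary-fitted (z, s) grid, s = r / F(z).
//
// Interior equations (S_rr = 0 for this mapping):
//   vorticity:  A W_ss + B W_sz + W_zz + (Szz + Sr/(F s)) W_s - W/(F s)^2 = 0
//   Poisson:    A P_ss + B P_sz + P_zz + (Szz - Sr/(F s)) P_s + F s W = 0
// with A = Sr^2 + Sz^2, B = 2 Sz.
//
// Boundary data: P = W = 0 on the axis (s = 0) and at the pole columns;
// P = 0 and W = tau/mu + 2 v_t / R at the cell surface (s = 1), where v_t
// is the tangential slip speed (positive from source, z = +L, towards
// drain) obtained from a second-order one-sided normal derivative of P,
// and R is the meridional curvature radius (Inf on straight segments).
//
// The vorticity equation is marched to steady state with explicit Euler
// pseudo-time steps (step = safety / max diagonal), interleaved with SOR
// sweeps of the Poisson equation; the wall vorticity is refreshed (with
// under-relaxation) every outer iteration. Convergence requires the
// largest update of both fields in one outer iteration to fall below tol.

// [[Rcpp::export(name = ".stokes_core")]]
List stokes_core(NumericVector z, NumericVector s,
                 NumericVector F, NumericVector dF,
                 NumericVector Sr, NumericMatrix Sz, NumericMatrix Szz,
                 NumericVector tau_wall, NumericVector R_curv,
                 double mu,
                 double sor_omega, double dt_safety, double wall_relax,
                 double tol, int max_outer, int sor_sweeps, int euler_steps) {
  const int nj = z.size();
  const int nk = s.size();
  const double dz = z[1] - z[0];
  const double ds = s[1] - s[0];
  const double dz2 = dz * dz, ds2 = ds * ds;

  NumericMatrix P(nj, nk), W(nj, nk), Wn(nj, nk);

  // precomputed interior coefficients
  NumericMatrix A(nj, nk), Dw(nj, nk), Dp(nj, nk), E(nj, nk), Fs(nj, nk);
  double diag_max = 0.0;
  for (int j = 1; j < nj - 1; ++j) {
    for (int k = 1; k < nk - 1; ++k) {
      const double fs = F[j] * s[k];
      A(j, k) = Sr[j] * Sr[j] + Sz(j, k) * Sz(j, k);
      Dw(j, k) = Szz(j, k) + Sr[j] / fs;
      Dp(j, k) = Szz(j, k) - Sr[j] / fs;
      E(j, k) = -1.0 / (fs * fs);
      Fs(j, k) = fs;
      const double d = 2.0 * A(j, k) / ds2 + 2.0 / dz2 - E(j, k);
      if (d > diag_max) diag_max = d;
    }
  }
  const double dt = dt_safety / diag_max;

  double max_dw = R_PosInf, max_dp = R_PosInf;
  int iter = 0;
  bool converged = false;
  std::vector<double> hist;

  NumericVector vt(nj);

  for (iter = 1; iter <= max_outer; ++iter) {
    max_dw = 0.0;
    max_dp = 0.0;

    // wall vorticity from current stream function (Thom-type coupling)
    for (int j = 1; j < nj - 1; ++j) {
      // one-sided dP/ds at the wall; P(j, nk-1) = 0
      const double Ps = (P(j, nk - 3) - 4.0 * P(j, nk - 2)) / (2.0 * ds);
      const double g = std::sqrt(1.0 + dF[j] * dF[j]);
      vt[j] = -g / (F[j] * F[j]) * Ps; // positive source -> drain
      double w_new = tau_wall[j] / mu;
      if (R_finite(R_curv[j])) w_new += 2.0 * vt[j] / R_curv[j];
      const double w_old = W(j, nk - 1);
      const double w_rel = (1.0 - wall_relax) * w_old + wall_relax * w_new;
      const double d = std::fabs(w_rel - w_old);
      if (d > max_dw) max_dw = d;
      W(j, nk - 1) = w_rel;
    }

    // explicit Euler pseudo-time steps on the vorticity equation
    for (int m = 0; m < euler_steps; ++m) {
      for (int j = 1; j < nj - 1; ++j) {
        for (int k = 1; k < nk - 1; ++k) {
          const double mixed = (W(j + 1, k + 1) - W(j + 1, k - 1) -
                                W(j - 1, k + 1) + W(j - 1, k - 1)) /
                               (4.0 * dz * ds);
          const double res =
              A(j, k) * (W(j, k + 1) - 2.0 * W(j, k) + W(j, k - 1)) / ds2 +
              2.0 * Sz(j, k) * mixed +
              (W(j + 1, k) - 2.0 * W(j, k) + W(j - 1, k)) / dz2 +
              Dw(j, k) * (W(j, k + 1) - W(j, k - 1)) / (2.0 * ds) +
              E(j, k) * W(j, k);
          Wn(j, k) = W(j, k) + dt * res;
          const double d = std::fabs(dt * res);
          if (d > max_dw) max_dw = d;
        }
      }
      for (int j = 1; j < nj - 1; ++j)
        for (int k = 1; k < nk - 1; ++k) W(j, k) = Wn(j, k);
    }

    // SOR sweeps on the Poisson equation for the stream function
    for (int m = 0; m < sor_sweeps; ++m) {
      for (int j = 1; j < nj - 1; ++j) {
        for (int k = 1; k < nk - 1; ++k) {
          const double mixed = (P(j + 1, k + 1) - P(j + 1, k - 1) -
                                P(j - 1, k + 1) + P(j - 1, k - 1)) /
                               (4.0 * dz * ds);
          const double num =
              A(j, k) * (P(j, k + 1) + P(j, k - 1)) / ds2 +
              2.0 * Sz(j, k) * mixed +
              (P(j + 1, k) + P(j - 1, k)) / dz2 +
              Dp(j, k) * (P(j, k + 1) - P(j, k - 1)) / (2.0 * ds) +
              Fs(j, k) * W(j, k);
          const double diag = 2.0 * A(j, k) / ds2 + 2.0 / dz2;
          const double p_gs = num / diag;
          const double p_new = (1.0 - sor_omega) * P(j, k) + sor_omega * p_gs;
          const double d = std::fabs(p_new - P(j, k));
          if (d > max_dp) max_dp = d;
          P(j, k) = p_new;
        }
      }
    }

    if (iter % 100 == 0) hist.push_back(std::max(max_dw, max_dp));
    if (max_dw < tol && max_dp < tol) {
      converged = true;
      break;
    }
    bool bad = false;
    for (int j = 1; j < nj - 1 && !bad; ++j)
      for (int k = 1; k < nk - 1 && !bad; ++k)
        if (!R_finite(W(j, k)) || !R_finite(P(j, k))) bad = true;
    if (bad) {
      stop("vorticity iteration diverged (NaN); reduce the pseudo-time "
           "safety factor or wall relaxation");
    }
  }

  return List::create(
      _["Psi"] = P, _["Omega"] = W, _["vt_wall"] = vt,
      _["iterations"] = std::min(iter, max_outer),
      _["max_dpsi"] = max_dp, _["max_domega"] = max_dw,
      _["dt"] = dt, _["converged"] = converged,
      _["residual_history"] = hist);
}
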