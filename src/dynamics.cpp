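// Core numerics for LVC surface hopping in the spin-mixed (diagonal) basis.
//
// Everything here works in Hartree atomic units (hbar = 1) and in
// dimensionless mass-frequency-scaled mode coordinates q, p, for which the
// classical Hamiltonian is
//     H = sum_i omega_i p_i^2 / 2 + V_active(q),
// so dq_i/dt = omega_i p_i and dp_i/dt = -dV/dq_i.
//
// The diabatic (MCH) potential matrix is
//     H_nn(q) = eps_n + sum_i omega_i q_i^2 / 2 + sum_i kappa_i^(n) q_i
//     H_nm(q) = sum_i lambda_i^(nm) q_i            (same spin multiplicity)
//     H_nm    = V_SO^(nm)                          (singlet-triplet, constant)
// and the propagation basis is its eigenbasis at the current geometry.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static cx_mat build_H(const vec& eps, const vec& omega, const mat& kappa,
                      const cube& lambda, const cx_mat& soc, const vec& q) {
  const uword nS = eps.n_elem, nM = q.n_elem;
  const double v0 = 0.5 * dot(omega, q % q);
  cx_mat H = soc;
  for (uword n = 0; n < nS; ++n)
    H(n, n) += cx_double(eps(n) + v0 + dot(kappa.row(n).t(), q), 0.0);
  for (uword i = 0; i < nM; ++i)
    if (q(i) != 0.0)
      H += cx_double(q(i), 0.0) *
           cx_mat(lambda.slice(i), mat(nS, nS, fill::zeros));
  return H;
}

// Eigen-decomposition with the package's phase convention: eigenvalues
// ascending; each eigenvector's largest-magnitude component made real and
// positive.  When a previous eigenvector set is supplied the phases are
// instead locked to it by maximal overlap (continuity for the overlap-based
// amplitude propagation).  Returns the smallest per-column |overlap| seen
// (1.0 when no previous set is given) so the caller can flag tracking
// failures.
static double eig_fixed(const cx_mat& H, vec& evals, cx_mat& U,
                        const cx_mat* Uprev) {
  eig_sym(evals, U, H);
  double min_ov = 1.0;
  for (uword k = 0; k < U.n_cols; ++k) {
    uword imax = index_max(abs(U.col(k)));
    cx_double z = U(imax, k);
    if (std::abs(z) > 0) U.col(k) *= std::conj(z) / std::abs(z);
  }
  if (Uprev != nullptr) {
    for (uword k = 0; k < U.n_cols; ++k) {
      cx_double ov = cdot(Uprev->col(k), U.col(k));
      double a = std::abs(ov);
      if (a < min_ov) min_ov = a;
      if (a > 1e-12) U.col(k) *= std::conj(ov) / a;
    }
  }
  return min_ov;
}

// Hellmann-Feynman gradient of diagonal state k: dE_k/dq_i = <u_k|dH/dq_i|u_k>
static mat diag_gradients(const vec& omega, const mat& kappa,
                          const cube& lambda, const vec& q, const cx_mat& U) {
  const uword nS = U.n_cols, nM = q.n_elem;
  mat g(nS, nM);
  for (uword i = 0; i < nM; ++i) {
    mat dH = lambda.slice(i);
    dH.diag() += omega(i) * q(i) + kappa.col(i);
    cx_mat dHc(dH, mat(dH.n_rows, dH.n_cols, fill::zeros));
    for (uword k = 0; k < nS; ++k)
      g(k, i) = std::real(cdot(U.col(k), dHc * U.col(k)));
  }
  return g;
}

// Loewdin orthogonalization: the unitary closest (in Frobenius norm) to S.
static cx_mat lowdin(const cx_mat& S) {
  cx_mat W, V;
  vec s;
  svd(W, s, V, S);
  return W * V.t();
}

// [[Rcpp::export]]
Rcpp::List sh_eval_cpp(const arma::vec& eps, const arma::vec& omega,
                       const arma::mat& kappa, const arma::cube& lambda,
                       const arma::cx_mat& soc, const arma::vec& q) {
  cx_mat H = build_H(eps, omega, kappa, lambda, soc, q);
  vec evals;
  cx_mat U;
  eig_fixed(H, evals, U, nullptr);
  mat gdiag = diag_gradients(omega, kappa, lambda, q, U);
  // MCH (diabatic-state) gradients: derivative of the diagonal of H
  const uword nS = eps.n_elem, nM = q.n_elem;
  mat gmch(nS, nM);
  for (uword i = 0; i < nM; ++i)
    gmch.col(i) = omega(i) * q(i) + kappa.col(i);
  return Rcpp::List::create(
      Rcpp::Named("h_mch") = H, Rcpp::Named("mch_energies") = real(H.diag()),
      Rcpp::Named("diag_energies") = evals, Rcpp::Named("transform") = U,
      Rcpp::Named("grad_diag") = gdiag, Rcpp::Named("grad_mch") = gmch);
}

// [[Rcpp::export]]
arma::cx_mat sh_lowdin_cpp(const arma::cx_mat& S) { return lowdin(S); }

// Fewest-switches hopping probabilities in the propagator (local
// diabatization) formulation: the decrease of the active population over the
// classical step is apportioned among target states by the cross terms of
// the step propagator P (c_after = P c_before).  Negative contributions are
// clamped to zero; if the clamping pushes the total above one, the vector is
// rescaled so it remains a probability vector.
// [[Rcpp::export]]
arma::vec sh_hop_probs_cpp(const arma::cx_vec& c0, const arma::cx_vec& c1,
                           const arma::cx_mat& P, int active) {
  const uword nS = c0.n_elem;
  const uword a = static_cast<uword>(active - 1);  // R is 1-based
  vec probs(nS, fill::zeros);
  double pa0 = std::norm(c0(a)), pa1 = std::norm(c1(a));
  if (pa0 <= 1e-30) return probs;
  double decrease = 1.0 - pa1 / pa0;
  if (decrease <= 0) return probs;
  double den = pa0 - std::real(c1(a) * std::conj(P(a, a)) * std::conj(c0(a)));
  if (den <= 0) return probs;
  for (uword b = 0; b < nS; ++b) {
    if (b == a) continue;
    double num = std::real(c1(b) * std::conj(P(b, a)) * std::conj(c0(a)));
    probs(b) = decrease * std::max(num, 0.0) / den;
  }
  double tot = accu(probs);
  if (tot > 1.0) probs /= tot;
  return probs;
}

// Energy-based decoherence correction (hbar = 1):
//   tau_k = (1 / |E_k - E_active|) * (1 + C / e_kin)
// Non-active amplitudes are damped by exp(-dt / tau_k); the active amplitude
// is rescaled so the total population is exactly one, preserving all phases.
// [[Rcpp::export]]
arma::cx_vec sh_decoherence_cpp(const arma::cx_vec& c, const arma::vec& evals,
                                int active, double ekin, double C, double dt) {
  const uword a = static_cast<uword>(active - 1);
  cx_vec out = c;
  if (ekin <= 0) return out;  // caller logs the skip
  double fac = 1.0 + C / ekin;
  double sum_other = 0.0;
  for (uword k = 0; k < c.n_elem; ++k) {
    if (k == a) continue;
    double de = std::abs(evals(k) - evals(a));
    if (de > 0) out(k) *= std::exp(-dt * de / fac);
    sum_other += std::norm(out(k));
  }
  double pa = std::norm(out(a));
  if (pa > 0) {
    out(a) *= std::sqrt(std::max(0.0, 1.0 - sum_other) / pa);
  } else if (sum_other > 0) {
    out /= std::sqrt(sum_other);
  }
  return out;
}

// Full surface-hopping trajectory.  Returns per-frame arrays plus the hop
// event table.  Uses R's RNG (one uniform variate per classical step), so
// results are reproducible under set.seed().
// [[Rcpp::export]]
Rcpp::List sh_propagate_cpp(const arma::vec& eps, const arma::vec& omega,
                            const arma::mat& kappa, const arma::cube& lambda,
                            const arma::cx_mat& soc, const arma::vec& q0_in,
                            const arma::vec& p0_in, int init_mch,
                            double dt, int nsteps, int substeps,
                            double decoherence_C, int frustrated_reflect,
                            int hopping, int freeze_nuclei,
                            int nuc_substeps) {
  const uword nS = eps.n_elem, nM = omega.n_elem;
  const uword nf = static_cast<uword>(nsteps) + 1;
  const double sdt = dt / substeps;

  mat Q(nf, nM), Pm(nf, nM), Ediag(nf, nS), Emch(nf, nS), PopMCH(nf, nS);
  cx_mat Amp(nf, nS);
  ivec active_diag(nf), active_mch(nf);
  vec ekin_v(nf), epot_v(nf), etot_v(nf);

  std::vector<int> hop_step, hop_from_d, hop_to_d, hop_from_m, hop_to_m,
      hop_frust;
  std::vector<double> hop_gap;
  int n_track_fail = 0, n_decoh_skip = 0, n_frustrated = 0;

  vec q = q0_in, p = p0_in;
  cx_mat H = build_H(eps, omega, kappa, lambda, soc, q);
  vec E;
  cx_mat U;
  eig_fixed(H, E, U, nullptr);

  // initial electronic state: pure MCH state expressed in the diagonal basis
  const uword n0 = static_cast<uword>(init_mch - 1);
  cx_vec c = U.row(n0).t();  // c_diag = U^dagger e_mch (conj by .t())
  c /= norm(c);
  uword active = index_max(abs(U.row(n0).t()));

  auto mch_parent = [&](const cx_mat& Uc, uword k) {
    return static_cast<int>(index_max(abs(Uc.col(k)))) + 1;
  };
  auto record = [&](uword f) {
    Q.row(f) = q.t();
    Pm.row(f) = p.t();
    Ediag.row(f) = E.t();
    Emch.row(f) = real(H.diag()).t();
    Amp.row(f) = c.st();
    cx_vec cm = U * c;
    for (uword n = 0; n < nS; ++n) PopMCH(f, n) = std::norm(cm(n));
    active_diag(f) = static_cast<int>(active) + 1;
    active_mch(f) = mch_parent(U, active);
    double ek = 0.5 * dot(omega, p % p);
    ekin_v(f) = ek;
    epot_v(f) = E(active);
    etot_v(f) = ek + E(active);
  };
  record(0);

  mat grads = diag_gradients(omega, kappa, lambda, q, U);
  for (int step = 1; step <= nsteps; ++step) {
    vec qold = q;
    cx_mat Uold = U;
    vec Eold = E;
    cx_vec c0 = c;

    if (!freeze_nuclei) {
      // velocity Verlet over the classical step, internally subdivided for
      // accurate integration through narrowly avoided crossings; hop
      // decisions, decoherence and amplitude propagation stay at dt
      const int nsub = std::max(1, nuc_substeps);
      const double h = dt / nsub;
      for (int j = 0; j < nsub; ++j) {
        vec F0 = -grads.row(active).t();
        vec phalf = p + 0.5 * h * F0;
        q = q + h * (omega % phalf);
        H = build_H(eps, omega, kappa, lambda, soc, q);
        cx_mat Uref = U;
        double ov = eig_fixed(H, E, U, &Uref);
        if (ov < 0.5) ++n_track_fail;
        grads = diag_gradients(omega, kappa, lambda, q, U);
        vec F1 = -grads.row(active).t();
        p = phalf + 0.5 * h * F1;
      }
    }
    // else: q, p, H, E, U unchanged

    // local-diabatization amplitude propagation over the classical step
    cx_mat S = Uold.t() * U;  // MCH basis is geometry-independent
    cx_mat T = freeze_nuclei ? cx_mat(eye<mat>(nS, nS), zeros<mat>(nS, nS))
                             : lowdin(S);
    cx_mat A0(diagmat(Eold), mat(nS, nS, fill::zeros));
    cx_mat A1 = T * cx_mat(diagmat(E), mat(nS, nS, fill::zeros)) * T.t();
    cx_mat Prop(eye<mat>(nS, nS), zeros<mat>(nS, nS));
    vec w;
    cx_mat V;
    for (int m = 0; m < substeps; ++m) {
      double s = (m + 0.5) / substeps;
      cx_mat Hbar = (1.0 - s) * A0 + s * A1;
      eig_sym(w, V, Hbar);
      cx_vec ph = exp(cx_double(0, -sdt) * conv_to<cx_vec>::from(w));
      Prop = V * diagmat(ph) * V.t() * Prop;
    }
    cx_mat Pfull = T.t() * Prop;
    cx_vec c1 = Pfull * c0;

    // hop decision
    if (hopping) {
      vec probs = sh_hop_probs_cpp(c0, c1, Pfull, static_cast<int>(active) + 1);
      double r = unif_rand();
      double acc = 0.0;
      int target = -1;
      for (uword b = 0; b < nS; ++b) {
        acc += probs(b);
        if (r < acc) { target = static_cast<int>(b); break; }
      }
      if (target >= 0) {
        uword b = static_cast<uword>(target);
        double gap = E(b) - E(active);
        double ek = 0.5 * dot(omega, p % p);
        bool allowed = (ek > 0 && ek >= gap) || (ek <= 0 && gap == 0.0);
        if (allowed) {
          if (ek > 0) p *= std::sqrt(1.0 - gap / ek);
          hop_step.push_back(step);
          hop_from_d.push_back(static_cast<int>(active) + 1);
          hop_to_d.push_back(static_cast<int>(b) + 1);
          hop_from_m.push_back(mch_parent(U, active));
          hop_to_m.push_back(mch_parent(U, b));
          hop_frust.push_back(0);
          hop_gap.push_back(gap);
          active = b;
        } else {
          ++n_frustrated;
          hop_step.push_back(step);
          hop_from_d.push_back(static_cast<int>(active) + 1);
          hop_to_d.push_back(static_cast<int>(b) + 1);
          hop_from_m.push_back(mch_parent(U, active));
          hop_to_m.push_back(mch_parent(U, b));
          hop_frust.push_back(1);
          hop_gap.push_back(gap);
          if (frustrated_reflect) p = -p;
        }
      }
    }

    // decoherence, once per classical step, after the hop decision
    if (decoherence_C >= 0) {
      double ek = 0.5 * dot(omega, p % p);
      if (ek > 0) {
        c1 = sh_decoherence_cpp(c1, E, static_cast<int>(active) + 1, ek,
                                decoherence_C, dt);
      } else {
        ++n_decoh_skip;
      }
    }
    c = c1;
    record(static_cast<uword>(step));
  }

  return Rcpp::List::create(
      Rcpp::Named("q") = Q, Rcpp::Named("p") = Pm,
      Rcpp::Named("e_diag") = Ediag, Rcpp::Named("e_mch") = Emch,
      Rcpp::Named("amplitudes") = Amp, Rcpp::Named("pop_mch") = PopMCH,
      Rcpp::Named("active_diag") = active_diag,
      Rcpp::Named("active_mch") = active_mch,
      Rcpp::Named("e_kin") = ekin_v, Rcpp::Named("e_pot") = epot_v,
      Rcpp::Named("e_tot") = etot_v,
      Rcpp::Named("hop_step") = hop_step,
      Rcpp::Named("hop_from_diag") = hop_from_d,
      Rcpp::Named("hop_to_diag") = hop_to_d,
      Rcpp::Named("hop_from_mch") = hop_from_m,
      Rcpp::Named("hop_to_mch") = hop_to_m,
      Rcpp::Named("hop_frustrated") = hop_frust,
      Rcpp::Named("hop_gap") = hop_gap,
      Rcpp::Named("n_track_fail") = n_track_fail,
      Rcpp::Named("n_decoherence_skipped") = n_decoh_skip,
      Rcpp::Named("n_frustrated") = n_frustrated);
}
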