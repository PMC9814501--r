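// Compiled engine for the density-matrix propagators (mean-field and
// GKBA second Born). Mirrors the R reference implementation in
// R/dynamics.R step for step: exponential midpoint predictor-corrector for
// the mean-field part, trapezoidal memory integral and Adams-Bashforth-2
// for the collision term. Engine equivalence is asserted in the tests.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static cx_mat expm_step_cpp(const cx_mat& h, double dt_au) {
  if (!h.is_finite())
    Rcpp::stop("propagation diverged (non-finite Hamiltonian)");
  if (norm(h - h.t(), "inf") < 1e-13) {
    vec eval;
    cx_mat evec;
    eig_sym(eval, evec, h);
    return evec * diagmat(exp(cx_double(0, -dt_au) * conv_to<cx_vec>::from(eval))) * evec.t();
  }
  cx_vec eval;
  cx_mat evec;
  eig_gen(eval, evec, h);
  return evec * diagmat(exp(cx_double(0, -dt_au) * eval)) * inv(evec);
}

// out[p,v] = sum_{qrstuw} v[p,q,r,s] X[t,u,v,w] M1[r,t] M2[s,u] Gb[w,q]
static cx_mat sb_term_cpp(const cx_mat& w_pqrs, const cx_mat& x_mat,
                          const cx_mat& m1, const cx_mat& m2,
                          const cx_mat& gb, uword k) {
  // y1: (r) x (u,v,w)
  cx_mat y1 = m1 * x_mat;
  // permute (r,u) -> (u,r) within each of the k^2 trailing blocks
  cx_mat y1p(k, k * k * k);
  for (uword blk = 0; blk < k * k; ++blk) {
    // columns blk*k .. blk*k+k-1 hold a k x k matrix (r rows, u cols)
    y1p.cols(blk * k, blk * k + k - 1) =
      y1.cols(blk * k, blk * k + k - 1).st();
  }
  cx_mat y2 = m2 * y1p; // (s) x (r,v,w)
  cx_mat y2p(k, k * k * k);
  for (uword blk = 0; blk < k * k; ++blk) {
    y2p.cols(blk * k, blk * k + k - 1) =
      y2.cols(blk * k, blk * k + k - 1).st();
  }
  // z: (p,q) x (v,w)
  cx_mat z = w_pqrs * reshape(y2p, k * k, k * k);
  // permute (p,q,v,w) -> (p,v,q,w), then contract with gb(w,q) over (q,w)
  cx_vec gvec = vectorise(gb.st()); // index (q,w), q fastest
  cx_mat out(k, k, fill::zeros);
  for (uword w0 = 0; w0 < k; ++w0)
    for (uword q = 0; q < k; ++q) {
      cx_double g = gvec(q + k * w0);
      if (g == cx_double(0, 0)) continue;
      // z(p + k*q, v + k*w0) over p, v
      for (uword v0 = 0; v0 < k; ++v0)
        for (uword p = 0; p < k; ++p)
          out(p, v0) += z(p + k * q, v0 + k * w0) * g;
    }
  return out;
}

struct SigmaPair { cx_mat alpha, beta; };

static SigmaPair sigma_2b_cpp(const cx_mat& w_pqrs, const cx_mat& x_dir,
                              const cx_mat& x_ex,
                              const cx_mat& a_al, const cx_mat& a_be,
                              const cx_mat& g_al, const cx_mat& g_be,
                              uword k) {
  cx_mat d_aa = sb_term_cpp(w_pqrs, x_dir, a_al, a_al, g_al, k);
  cx_mat d_ab = sb_term_cpp(w_pqrs, x_dir, a_al, a_be, g_be, k);
  cx_mat d_ba = sb_term_cpp(w_pqrs, x_dir, a_be, a_al, g_al, k);
  cx_mat d_bb = sb_term_cpp(w_pqrs, x_dir, a_be, a_be, g_be, k);
  cx_mat e_aa = sb_term_cpp(w_pqrs, x_ex, a_al, a_al, g_al, k);
  cx_mat e_bb = sb_term_cpp(w_pqrs, x_ex, a_be, a_be, g_be, k);
  SigmaPair s;
  s.alpha = d_aa + d_ab - e_aa;
  s.beta = d_bb + d_ba - e_bb;
  return s;
}

// [[Rcpp::export]]
Rcpp::List propagate_core_cpp(
    const arma::cx_vec& e_complex,   // a.u., includes -i cap/2
    const arma::mat& dmat,           // full-space dipole projection, a.u.
    const arma::uvec& int_idx0,      // 0-based interacting indices
    const arma::cx_mat& w_hart,      // (k^2 x k^2) [(p,r),(q,s)]
    const arma::cx_mat& w_exch,
    const arma::cx_mat& w_pqrs,      // (k^2 x k^2) [(p,q),(r,s)]
    const arma::cx_mat& x_dir,       // (k x k^3)
    const arma::cx_mat& x_ex,
    const arma::cx_mat& rho0a,
    const arma::cx_mat& rho0b,
    const arma::vec& efield,         // at each grid time, length nt
    double dt_au,
    int n_mem,
    bool collisions,
    bool has_coupling,
    int stride) {
  const uword m = e_complex.n_elem;
  const uword k = int_idx0.n_elem;
  const uword nt = efield.n_elem;
  const cx_mat id = eye<cx_mat>(m, m);

  auto h_hf = [&](const cx_mat& rho_same, const cx_mat& rho_tot, double ef) {
    cx_mat h = diagmat(e_complex);
    if (has_coupling) {
      cx_mat rt_int = rho_tot.submat(int_idx0, int_idx0);
      cx_mat rs_int = rho_same.submat(int_idx0, int_idx0);
      cx_mat vh = reshape(w_hart * vectorise(rt_int.st()), k, k);
      cx_mat vx = reshape(w_exch * vectorise(rs_int.st()), k, k);
      h.submat(int_idx0, int_idx0) += vh - vx;
    }
    if (ef != 0.0) h -= ef * conv_to<cx_mat>::from(dmat);
    return h;
  };

  std::vector<cx_mat> hist_ra(nt), hist_rb(nt), hist_u(nt), hist_uinv(nt);
  cx_mat ra = rho0a, rb = rho0b;
  hist_ra[0] = ra; hist_rb[0] = rb;
  hist_u[0] = id; hist_uinv[0] = id;

  mat occ(nt, 2 * m);
  cx_cube rho_a(m, m, nt), rho_b(m, m, nt);
  occ.row(0) = join_rows(real(ra.diag()).t(), real(rb.diag()).t());
  rho_a.slice(0) = ra; rho_b.slice(0) = rb;

  cx_mat kprev_a, kprev_b;
  bool have_prev = false;

  auto collision_term = [&](uword n, cx_mat& ia, cx_mat& ib) {
    ia.zeros(m, m); ib.zeros(m, m);
    uword lo = (n >= (uword)n_mem) ? n - n_mem : 0;
    uword nwin = n - lo + 1;
    if (nwin < 2) return;
    const cx_mat& un = hist_u[n];
    cx_mat ia_int(k, k, fill::zeros), ib_int(k, k, fill::zeros);
    for (uword s = lo; s <= n; ++s) {
      double wt = dt_au;
      if (s == lo || s == n) wt = dt_au / 2.0;
      cx_mat uts = un * hist_uinv[s];
      cx_mat uts_h = uts.t();
      const cx_mat& rs_a = hist_ra[s];
      const cx_mat& rs_b = hist_rb[s];
      cx_mat rbar_a = id - rs_a, rbar_b = id - rs_b;
      cx_double iu(0, 1);
      cx_mat t1 = iu * uts * rs_a;    cx_mat gl_ts_a = t1.submat(int_idx0, int_idx0);
      cx_mat t2 = iu * uts * rs_b;    cx_mat gl_ts_b = t2.submat(int_idx0, int_idx0);
      cx_mat t3 = -iu * uts * rbar_a; cx_mat gg_ts_a = t3.submat(int_idx0, int_idx0);
      cx_mat t4 = -iu * uts * rbar_b; cx_mat gg_ts_b = t4.submat(int_idx0, int_idx0);
      cx_mat t5 = iu * rs_a * uts_h;  cx_mat gl_st_a = t5.submat(int_idx0, int_idx0);
      cx_mat t6 = iu * rs_b * uts_h;  cx_mat gl_st_b = t6.submat(int_idx0, int_idx0);
      cx_mat t7 = -iu * rbar_a * uts_h; cx_mat gg_st_a = t7.submat(int_idx0, int_idx0);
      cx_mat t8 = -iu * rbar_b * uts_h; cx_mat gg_st_b = t8.submat(int_idx0, int_idx0);
      SigmaPair sg = sigma_2b_cpp(w_pqrs, x_dir, x_ex,
                                  gg_ts_a, gg_ts_b, gl_st_a, gl_st_b, k);
      SigmaPair sl = sigma_2b_cpp(w_pqrs, x_dir, x_ex,
                                  gl_ts_a, gl_ts_b, gg_st_a, gg_st_b, k);
      ia_int += wt * (sg.alpha * gl_st_a - sl.alpha * gg_st_a);
      ib_int += wt * (sg.beta * gl_st_b - sl.beta * gg_st_b);
    }
    ia.submat(int_idx0, int_idx0) = ia_int;
    ib.submat(int_idx0, int_idx0) = ib_int;
  };

  bool do_coll = collisions && has_coupling;
  cx_mat kn_a, kn_b;
  bool have_cache = false;
  for (uword n = 0; n + 1 < nt; ++n) {
    if (do_coll && (n % (uword)stride == 0 || !have_cache)) {
      collision_term(n, kn_a, kn_b);
      have_cache = true;
    }
    cx_mat h1a = h_hf(ra, ra + rb, efield(n));
    cx_mat h1b = h_hf(rb, ra + rb, efield(n));
    cx_mat ua_p = expm_step_cpp(h1a, dt_au);
    cx_mat ub_p = expm_step_cpp(h1b, dt_au);
    cx_mat ra_p = ua_p * ra * ua_p.t();
    cx_mat rb_p = ub_p * rb * ub_p.t();
    if (do_coll) {
      ra_p -= dt_au * (kn_a + kn_a.t());
      rb_p -= dt_au * (kn_b + kn_b.t());
    }
    cx_mat h2a = h_hf(ra_p, ra_p + rb_p, efield(n + 1));
    cx_mat h2b = h_hf(rb_p, ra_p + rb_p, efield(n + 1));
    cx_mat ua = expm_step_cpp((h1a + h2a) / 2.0, dt_au);
    cx_mat ub = expm_step_cpp((h1b + h2b) / 2.0, dt_au);
    ra = ua * ra * ua.t();
    rb = ub * rb * ub.t();
    if (do_coll) {
      cx_mat ka = kn_a, kb = kn_b;
      if (have_prev) {
        ka = 1.5 * kn_a - 0.5 * kprev_a;
        kb = 1.5 * kn_b - 0.5 * kprev_b;
      }
      ra -= dt_au * (ka + ka.t());
      rb -= dt_au * (kb + kb.t());
      kprev_a = kn_a; kprev_b = kn_b;
      have_prev = true;
    }
    hist_ra[n + 1] = ra; hist_rb[n + 1] = rb;
    hist_u[n + 1] = ua * hist_u[n];
    hist_uinv[n + 1] = hist_uinv[n] * inv(ua);
    occ.row(n + 1) = join_rows(real(ra.diag()).t(), real(rb.diag()).t());
    rho_a.slice(n + 1) = ra; rho_b.slice(n + 1) = rb;
  }

  return Rcpp::List::create(Rcpp::Named("occ") = occ,
                            Rcpp::Named("rho_a") = rho_a,
                            Rcpp::Named("rho_b") = rho_b);
}
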