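// Fast path for the conductance-based spectral forward model: fixed-point
// search, analytic Jacobian with first-order delay correction, and
// per-frequency resolvent assembly of the predicted cross-spectral density.
// Mirrors the R reference implementation in R/forward.R exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Model {
  mat WA, WG, WN;          // population-level firing -> conductance weights
  vec Cvec, tauA, tauG, tauN;
  double VL, VAMPA, VGABA, VNMDA, alpha, thr, slope, gL;
  int np;                  // number of populations (regions * 4)
  int nx;                  // number of states (np * 4)
};

inline vec sigmoid(const vec& V, const Model& m) {
  return 1.0 / (1.0 + exp(-m.slope * (V - m.thr)));
}
inline vec mg_gate(const vec& V, const Model& m) {
  return 1.0 / (1.0 + 0.2 * exp(-m.alpha * V));
}

void derivatives(const vec& x, const Model& m, vec& dx) {
  const int np = m.np;
  vec V(np), gA(np), gG(np), gN(np);
  for (int p = 0; p < np; ++p) {
    V[p] = x[4 * p]; gA[p] = x[4 * p + 1];
    gG[p] = x[4 * p + 2]; gN[p] = x[4 * p + 3];
  }
  vec sig = sigmoid(V, m), mg = mg_gate(V, m);
  vec SA = m.WA * sig, SG = m.WG * sig, SN = m.WN * sig;
  for (int p = 0; p < np; ++p) {
    double dV = (m.gL * (m.VL - V[p]) + gA[p] * (m.VAMPA - V[p]) +
                 gG[p] * (m.VGABA - V[p]) +
                 gN[p] * mg[p] * (m.VNMDA - V[p])) / m.Cvec[p];
    dx[4 * p] = dV;
    dx[4 * p + 1] = (SA[p] - gA[p]) / m.tauA[p];
    dx[4 * p + 2] = (SG[p] - gG[p]) / m.tauG[p];
    dx[4 * p + 3] = (SN[p] - gN[p]) / m.tauN[p];
  }
}

void raw_jacobian(const vec& x, const Model& m, mat& J) {
  const int np = m.np;
  J.zeros(m.nx, m.nx);
  vec V(np), gA(np), gG(np), gN(np);
  for (int p = 0; p < np; ++p) {
    V[p] = x[4 * p]; gA[p] = x[4 * p + 1];
    gG[p] = x[4 * p + 2]; gN[p] = x[4 * p + 3];
  }
  vec sig = sigmoid(V, m), mg = mg_gate(V, m);
  vec sg = m.slope * sig % (1.0 - sig);
  vec mgg = m.alpha * mg % (1.0 - mg);
  for (int p = 0; p < np; ++p) {
    int a = 4 * p;
    J(a, a) = (-m.gL - gA[p] - gG[p] +
               gN[p] * (mgg[p] * (m.VNMDA - V[p]) - mg[p])) / m.Cvec[p];
    J(a, a + 1) = (m.VAMPA - V[p]) / m.Cvec[p];
    J(a, a + 2) = (m.VGABA - V[p]) / m.Cvec[p];
    J(a, a + 3) = mg[p] * (m.VNMDA - V[p]) / m.Cvec[p];
    for (int q = 0; q < np; ++q) {
      int b = 4 * q;
      if (m.WA(p, q) != 0) J(a + 1, b) = m.WA(p, q) * sg[q] / m.tauA[p];
      if (m.WG(p, q) != 0) J(a + 2, b) = m.WG(p, q) * sg[q] / m.tauG[p];
      if (m.WN(p, q) != 0) J(a + 3, b) = m.WN(p, q) * sg[q] / m.tauN[p];
    }
    J(a + 1, a + 1) = -1.0 / m.tauA[p];
    J(a + 2, a + 2) = -1.0 / m.tauG[p];
    J(a + 3, a + 3) = -1.0 / m.tauN[p];
  }
}

// damped Newton with infinity-norm line search; fast near the solution
bool newton(vec& x, const Model& m, double tol, int maxit) {
  vec f(m.nx), fn(m.nx);
  mat J(m.nx, m.nx);
  for (int k = 0; k < maxit; ++k) {
    derivatives(x, m, f);
    double f0 = abs(f).max();
    if (f0 < tol) return true;
    raw_jacobian(x, m, J);
    vec step;
    if (!solve(step, J, -f)) return false;
    double lam = 1.0, fnorm = datum::inf;
    vec xn;
    while (true) {
      xn = x + lam * step;
      derivatives(xn, m, fn);
      fnorm = fn.is_finite() ? abs(fn).max() : datum::inf;
      if (fnorm < f0 || lam < 1e-4) break;
      lam *= 0.5;
    }
    if (!std::isfinite(fnorm) || fnorm >= f0) return false;
    x = xn;
  }
  derivatives(x, m, f);
  return abs(f).max() < tol;
}

// equilibrium search: Newton, falling back to semi-implicit
// (Rosenbrock-Euler) integration of the stiff flow followed by a Newton
// polish. Deterministic.
bool fixed_point(vec& x, const Model& m, double tol) {
  if (newton(x, m, tol, 64)) return true;
  vec f(m.nx);
  mat J(m.nx, m.nx);
  double dt = 1.0; // ms
  for (int k = 0; k < 2000; ++k) {
    derivatives(x, m, f);
    if (!f.is_finite()) return false;
    if (abs(f).max() < 1e-4) break;
    raw_jacobian(x, m, J);
    mat M = eye(m.nx, m.nx) / dt - J;
    vec step;
    if (!solve(step, M, f)) return false;
    vec xn = x + step;
    if (!xn.is_finite()) {
      dt *= 0.5;
      if (dt < 1e-4) return false;
      continue;
    }
    x = xn;
  }
  return newton(x, m, tol, 64);
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_forward_csd(const arma::mat& WA, const arma::mat& WG,
                           const arma::mat& WN, const arma::vec& Cvec,
                           const arma::vec& tauA, const arma::vec& tauG,
                           const arma::vec& tauN,
                           const Rcpp::NumericVector& consts,
                           const arma::mat& D, const arma::mat& B,
                           const arma::mat& W, const arma::vec& freqs,
                           const arma::vec& gu, const arma::vec& taper,
                           const arma::cx_cube& go,
                           const arma::vec& x_init, double tol) {
  Model m;
  m.WA = WA; m.WG = WG; m.WN = WN;
  m.Cvec = Cvec; m.tauA = tauA; m.tauG = tauG; m.tauN = tauN;
  m.VL = consts["VL"]; m.VAMPA = consts["VAMPA"];
  m.VGABA = consts["VGABA"]; m.VNMDA = consts["VNMDA"];
  m.alpha = consts["alpha_nmda"]; m.thr = consts["sigmoid_threshold"];
  m.slope = consts["sigmoid_slope"]; m.gL = consts["gL"];
  m.np = WA.n_rows;
  m.nx = 4 * m.np;

  vec x = x_init;
  bool ok = fixed_point(x, m, tol);
  if (!ok) {
    vec f(m.nx);
    if (x.is_finite()) derivatives(x, m, f); else f.fill(datum::inf);
    return Rcpp::List::create(
        Rcpp::Named("ok") = false,
        Rcpp::Named("reason") = "fixed_point",
        Rcpp::Named("residual") = abs(f).max());
  }

  mat J(m.nx, m.nx);
  raw_jacobian(x, m, J);
  mat M = eye(m.nx, m.nx) + J % D;
  mat Jeff;
  if (!solve(Jeff, M, J))
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("reason") = "delay_singular");
  cx_vec ev;
  cx_mat U;
  bool have_vectors = eig_gen(ev, U, Jeff);
  if (!have_vectors && !eig_gen(ev, Jeff))
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("reason") = "eig_failure");
  double max_re = real(ev).max();
  if (max_re >= 0)
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("reason") = "unstable",
                              Rcpp::Named("max_re") = max_re);

  const int nf = freqs.n_elem;
  const int R = W.n_rows;
  cx_cube out(R, R, nf);
  cx_mat Jc = conv_to<cx_mat>::from(Jeff);
  cx_mat Bc = conv_to<cx_mat>::from(B);
  cx_mat Wc = conv_to<cx_mat>::from(W);
  // resolvent via the eigendecomposition J = U diag(ev) U^-1 when U is
  // well conditioned, else direct per-frequency solves
  bool use_eig = have_vectors && (rcond(U) > 1e-10);
  cx_mat WU, UB;
  if (use_eig) {
    WU = Wc * U;
    if (!solve(UB, U, Bc)) use_eig = false;
  }
  for (int k = 0; k < nf; ++k) {
    double om = 2.0 * datum::pi * freqs[k] / 1000.0; // rad/ms
    cx_mat K;
    if (use_eig) {
      cx_vec dinv = 1.0 / (cx_double(0, om) - ev);
      K = WU * (UB.each_col() % dinv);
    } else {
      cx_mat A = cx_double(0, om) * eye<cx_mat>(m.nx, m.nx) - Jc;
      cx_mat X;
      if (!solve(X, A, Bc))
        return Rcpp::List::create(Rcpp::Named("ok") = false,
                                  Rcpp::Named("reason") = "resolvent");
      K = Wc * X;
    }
    out.slice(k) = taper[k] * gu[k] * (K * K.t()) + go.slice(k);
  }
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("values") = out,
                            Rcpp::Named("x0") = x,
                            Rcpp::Named("max_re") = max_re);
}

// ---------------------------------------------------------------------------
// Packed evaluator: the whole parameter-to-feature map (structure scatter,
// spectra, fixed point, resolvent, feature stacking) in one place, so the
// finite-difference Jacobian of the inversion runs without per-evaluation
// R overhead. The pack is assembled once per model context in R.

namespace {

struct Pack {
  int R, np, nx, nf, nth;
  uvec wa_i, wa_c, wg_i, wg_c, wn_i, wn_c;    // 0-based scatter indices
  vec wa_b, wg_b, wn_b;
  uvec cT, cC;                                 // coordinate indices
  vec T_base, C_base;
  uvec w_row, w_col, w_cL;
  ivec w_cJ;                                   // -1 when absent
  vec w_base;
  mat D_int, D_ext;                            // base-scaled delay masks
  uvec cD;
  vec freqs, lf, bump_lo, bump_hi;
  mat cosmat;                                  // nf x 4
  uvec ca, cd, cb, cc, cf;
  mat B;
  Rcpp::NumericVector consts;
  uvec re_idx, im_idx;                         // into (R x R x nf) cube
  vec x_cold;
};

Pack parse_pack(const Rcpp::List& pk) {
  Pack p;
  p.R = Rcpp::as<int>(pk["R"]);
  p.np = Rcpp::as<int>(pk["np"]);
  p.nx = Rcpp::as<int>(pk["nx"]);
  p.nf = Rcpp::as<int>(pk["nf"]);
  p.nth = Rcpp::as<int>(pk["nth"]);
  auto u = [&](const char* nm) {
    arma::ivec tmp = Rcpp::as<arma::ivec>(pk[nm]);
    return arma::conv_to<arma::uvec>::from(tmp - 1); // 1-based -> 0-based
  };
  p.wa_i = u("wa_i"); p.wa_c = u("wa_c");
  p.wg_i = u("wg_i"); p.wg_c = u("wg_c");
  p.wn_i = u("wn_i"); p.wn_c = u("wn_c");
  p.wa_b = Rcpp::as<arma::vec>(pk["wa_b"]);
  p.wg_b = Rcpp::as<arma::vec>(pk["wg_b"]);
  p.wn_b = Rcpp::as<arma::vec>(pk["wn_b"]);
  p.cT = u("cT"); p.cC = u("cC");
  p.T_base = Rcpp::as<arma::vec>(pk["T_base"]);
  p.C_base = Rcpp::as<arma::vec>(pk["C_base"]);
  p.w_row = u("w_row"); p.w_col = u("w_col"); p.w_cL = u("w_cL");
  p.w_cJ = Rcpp::as<arma::ivec>(pk["w_cJ"]) - 1;
  p.w_base = Rcpp::as<arma::vec>(pk["w_base"]);
  p.D_int = Rcpp::as<arma::mat>(pk["D_int"]);
  p.D_ext = Rcpp::as<arma::mat>(pk["D_ext"]);
  p.cD = u("cD");
  p.freqs = Rcpp::as<arma::vec>(pk["freqs"]);
  p.lf = log(p.freqs);
  p.bump_lo = Rcpp::as<arma::vec>(pk["bump_lo"]);
  p.bump_hi = Rcpp::as<arma::vec>(pk["bump_hi"]);
  p.cosmat = Rcpp::as<arma::mat>(pk["cosmat"]);
  p.ca = u("ca"); p.cd = u("cd"); p.cb = u("cb");
  p.cc = u("cc"); p.cf = u("cf");
  p.B = Rcpp::as<arma::mat>(pk["B"]);
  p.consts = Rcpp::as<Rcpp::NumericVector>(pk["consts"]);
  p.re_idx = u("re_idx"); p.im_idx = u("im_idx");
  p.x_cold = Rcpp::as<arma::vec>(pk["x_cold"]);
  return p;
}

// evaluate features; returns 0 ok, 1 fixed-point failure, 2 unstable/other
int eval_features(const Pack& p, const vec& th, vec& x, vec& feats) {
  vec eth = exp(th);
  Model m;
  m.np = p.np; m.nx = p.nx;
  m.WA.zeros(p.np, p.np); m.WG.zeros(p.np, p.np); m.WN.zeros(p.np, p.np);
  for (uword k = 0; k < p.wa_i.n_elem; ++k)
    m.WA(p.wa_i[k]) += p.wa_b[k] * eth[p.wa_c[k]];
  for (uword k = 0; k < p.wg_i.n_elem; ++k)
    m.WG(p.wg_i[k]) += p.wg_b[k] * eth[p.wg_c[k]];
  for (uword k = 0; k < p.wn_i.n_elem; ++k)
    m.WN(p.wn_i[k]) += p.wn_b[k] * eth[p.wn_c[k]];
  m.Cvec.set_size(p.np);
  for (uword k = 0; k < p.cC.n_elem; ++k)
    m.Cvec[k] = p.C_base[k] * eth[p.cC[k]];
  // cT holds per-region (AMPA, GABA, NMDA) coordinates
  m.tauA.set_size(p.np); m.tauG.set_size(p.np); m.tauN.set_size(p.np);
  for (int r = 0; r < p.R; ++r) {
    double tA = p.T_base[3 * r + 0] * eth[p.cT[3 * r + 0]];
    double tG = p.T_base[3 * r + 1] * eth[p.cT[3 * r + 1]];
    double tN = p.T_base[3 * r + 2] * eth[p.cT[3 * r + 2]];
    for (int q = 0; q < 4; ++q) {
      m.tauA[4 * r + q] = tA; m.tauG[4 * r + q] = tG; m.tauN[4 * r + q] = tN;
    }
  }
  m.VL = p.consts["VL"]; m.VAMPA = p.consts["VAMPA"];
  m.VGABA = p.consts["VGABA"]; m.VNMDA = p.consts["VNMDA"];
  m.alpha = p.consts["alpha_nmda"]; m.thr = p.consts["sigmoid_threshold"];
  m.slope = p.consts["sigmoid_slope"]; m.gL = p.consts["gL"];

  if (!fixed_point(x, m, 1e-8)) return 1;

  mat J(p.nx, p.nx);
  raw_jacobian(x, m, J);
  mat D = p.D_int * eth[p.cD[0]] + p.D_ext * eth[p.cD[1]];
  mat M = eye(p.nx, p.nx) + J % D;
  mat Jeff;
  if (!solve(Jeff, M, J)) return 2;
  cx_vec ev;
  cx_mat U;
  if (!eig_gen(ev, U, Jeff)) return 2;
  if (real(ev).max() >= 0) return 2;

  mat W(p.R, p.nx, fill::zeros);
  for (uword k = 0; k < p.w_row.n_elem; ++k) {
    double jf = p.w_cJ[k] >= 0 ? eth[p.w_cJ[k]] : 1.0;
    W(p.w_row[k], p.w_col[k]) = p.w_base[k] * eth[p.w_cL[k]] * jf;
  }
  cx_mat Wc = conv_to<cx_mat>::from(W);
  cx_mat Bc = conv_to<cx_mat>::from(p.B);
  cx_mat WU, UB;
  bool use_eig = true;
  {
    WU = Wc * U;
    if (!solve(UB, U, Bc)) use_eig = false;
    if (use_eig) {
      // cheap conditioning probe: reconstruction of B from U UB
      double err = norm(U * UB - conv_to<cx_mat>::from(p.B), "fro");
      if (!(err < 1e-6 * (1.0 + norm(p.B, "fro")))) use_eig = false;
    }
  }
  cx_mat Jc = conv_to<cx_mat>::from(Jeff);

  // spectra
  vec mod = 1.0 + p.cosmat * th.elem(p.cd);
  mod = clamp(mod, 1e-8, 1e30);
  vec gu = exp(th[p.ca[0]] - eth[p.ca[1]] * p.lf) % mod;
  vec taper = exp(th[p.cf[0]] * p.bump_lo + th[p.cf[1]] * p.bump_hi);
  vec common = exp(th[p.cb[0]] - eth[p.cb[1]] * p.lf);
  vec specific = exp(th[p.cc[0]] - eth[p.cc[1]] * p.lf);

  cx_cube out(p.R, p.R, p.nf);
  for (int k = 0; k < p.nf; ++k) {
    double om = 2.0 * datum::pi * p.freqs[k] / 1000.0;
    cx_mat K;
    if (use_eig) {
      cx_vec dinv = 1.0 / (cx_double(0, om) - ev);
      K = WU * (UB.each_col() % dinv);
    } else {
      cx_mat A = cx_double(0, om) * eye<cx_mat>(p.nx, p.nx) - Jc;
      cx_mat X;
      if (!solve(X, A, Bc)) return 2;
      K = Wc * X;
    }
    out.slice(k) = taper[k] * gu[k] * (K * K.t());
    out.slice(k).diag() += taper[k] * specific[k];
    out.slice(k) += taper[k] * common[k];
  }
  const cx_double* v = out.memptr();
  feats.set_size(p.re_idx.n_elem + p.im_idx.n_elem);
  for (uword k = 0; k < p.re_idx.n_elem; ++k)
    feats[k] = v[p.re_idx[k]].real();
  for (uword k = 0; k < p.im_idx.n_elem; ++k)
    feats[p.re_idx.n_elem + k] = v[p.im_idx[k]].imag();
  return 0;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_eval_features(const Rcpp::List& pack, const arma::vec& th,
                             const arma::vec& x_init) {
  Pack p = parse_pack(pack);
  vec x = x_init, feats;
  int status = eval_features(p, th, x, feats);
  return Rcpp::List::create(Rcpp::Named("ok") = (status == 0),
                            Rcpp::Named("status") = status,
                            Rcpp::Named("features") = feats,
                            Rcpp::Named("x0") = x);
}

// [[Rcpp::export]]
Rcpp::List cpp_eval_jacobian(const Rcpp::List& pack, const arma::vec& th,
                             double fd_step, const arma::vec& x_init) {
  Pack p = parse_pack(pack);
  vec x = x_init, h0;
  int status = eval_features(p, th, x, h0);
  if (status != 0)
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("status") = status);
  vec x_base = x;
  mat J(h0.n_elem, p.nth, fill::zeros);
  for (int i = 0; i < p.nth; ++i) {
    vec tp = th, tm = th;
    tp[i] += fd_step; tm[i] -= fd_step;
    vec hp, hm;
    vec xp = x_base, xm = x_base;
    int sp = eval_features(p, tp, xp, hp);
    int sm = eval_features(p, tm, xm, hm);
    if (sp == 0 && sm == 0) J.col(i) = (hp - hm) / (2 * fd_step);
    else if (sp == 0)       J.col(i) = (hp - h0) / fd_step;
    else if (sm == 0)       J.col(i) = (h0 - hm) / fd_step;
  }
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("features") = h0,
                            Rcpp::Named("jacobian") = J,
                            Rcpp::Named("x0") = x_base);
}
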