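// Time-stepping residual: BDF2 (backward-Euler bootstrap) kinematic mismatch
// stacked with the constraint residuals, evaluated with either the planar
// FCM backend or the local-drag (RFT) backend. Also provides the
// finite-difference per-swimmer Jacobian blocks (RFT closure) used to seed
// Broyden's method.
#include <Rcpp.h>
#include <cmath>
#include "model.h"

using namespace Rcpp;

static RftCoeffs rft_from_list(const List& cl) {
  RftCoeffs c;
  c.xi_par = as<double>(cl["xi_par"]);
  c.xi_perp = as<double>(cl["xi_perp"]);
  c.zeta_rot_seg = as<double>(cl["zeta_rot_seg"]);
  c.zeta_head_t = as<double>(cl["zeta_head_t"]);
  c.zeta_head_r = as<double>(cl["zeta_head_r"]);
  return c;
}

struct Workspace {
  std::vector<double> F, Tz, g, Ux, Uy, Wz, px, py, fx, fy;
  std::vector<int> cls;
  void resize(const ModelDesc& m) {
    int nb = m.nbodies();
    F.resize(2 * nb); Tz.resize(nb); g.resize(m.nlam());
    Ux.resize(nb); Uy.resize(nb); Wz.resize(nb);
    px.resize(nb); py.resize(nb); fx.resize(nb); fy.resize(nb);
    cls.resize(nb);
    int bps = m.bodies_per_sw();
    for (int b = 0; b < nb; ++b) cls[b] = (b % bps == 0) ? 1 : 0;
  }
};

// residual of one implicit step. scheme: 2 = BDF2, 1 = backward Euler.
// X = [q (3 per body), lambda]; res same layout.
static void eval_residual(const PlanarCtx* ctx, const ModelDesc& m,
                          bool use_fcm, const RftCoeffs& rc, const double* X,
                          const double* q1, const double* q2, const double* Phi,
                          double dt, int scheme, double* res, Workspace& ws,
                          bool want_diag, double* Ffl = nullptr,
                          double* Tfl = nullptr, double* Uout = nullptr) {
  const int nq = m.nq();
  const int nb = m.nbodies();
  const double* q = X;
  const double* lam = X + nq;
  ws.resize(m);
  assemble_forces(m, q, lam, Phi, ws.F.data(), ws.Tz.data(), ws.g.data());
  if (use_fcm) {
    for (int b = 0; b < nb; ++b) {
      ws.px[b] = q[3 * b]; ws.py[b] = q[3 * b + 1];
      ws.fx[b] = ws.F[2 * b]; ws.fy[b] = ws.F[2 * b + 1];
    }
    planar_mobility(*ctx, nb, ws.px.data(), ws.py.data(), ws.fx.data(),
                    ws.fy.data(), ws.Tz.data(), ws.cls.data(), ws.Ux.data(),
                    ws.Uy.data(), ws.Wz.data());
  } else {
    rft_mobility_c(m, rc, q, ws.F.data(), ws.Tz.data(), ws.Ux.data(),
                   ws.Uy.data(), ws.Wz.data());
  }
  double c1 = (scheme == 2) ? 4.0 / 3.0 : 1.0;
  double c2 = (scheme == 2) ? -1.0 / 3.0 : 0.0;
  double cd = (scheme == 2) ? 2.0 / 3.0 : 1.0;
  for (int b = 0; b < nb; ++b) {
    double vx = ws.Ux[b], vy = ws.Uy[b], w = ws.Wz[b];
    res[3 * b] = q[3 * b] - c1 * q1[3 * b] - c2 * q2[3 * b] - cd * dt * vx;
    res[3 * b + 1] =
        q[3 * b + 1] - c1 * q1[3 * b + 1] - c2 * q2[3 * b + 1] - cd * dt * vy;
    res[3 * b + 2] =
        q[3 * b + 2] - c1 * q1[3 * b + 2] - c2 * q2[3 * b + 2] - cd * dt * w;
  }
  for (int i = 0; i < m.nlam(); ++i) res[nq + i] = ws.g[i];
  if (want_diag) {
    for (int b = 0; b < nb; ++b) {
      Ffl[2 * b] = ws.F[2 * b]; Ffl[2 * b + 1] = ws.F[2 * b + 1];
      Tfl[b] = ws.Tz[b];
      Uout[3 * b] = ws.Ux[b]; Uout[3 * b + 1] = ws.Uy[b];
      Uout[3 * b + 2] = ws.Wz[b];
    }
  }
}

// [[Rcpp::export(name = ".residual_cpp")]]
SEXP residual_cpp(SEXP ctxp, NumericVector X, NumericVector q1,
                  NumericVector q2, NumericVector Phi, double dt, int scheme,
                  bool use_fcm, List rft, bool want_diag = false) {
  XPtr<PlanarCtx> ctx(ctxp);
  const ModelDesc& m = ctx->model;
  if ((int)X.size() != m.ndof()) stop("state vector length mismatch");
  RftCoeffs rc = rft_from_list(rft);
  static Workspace ws;
  NumericVector res(m.ndof());
  if (!want_diag) {
    eval_residual(ctx, m, use_fcm, rc, X.begin(), q1.begin(), q2.begin(),
                  Phi.begin(), dt, scheme, res.begin(), ws, false);
    return res;
  }
  int nb = m.nbodies();
  NumericVector Ffl(2 * nb), Tfl(nb), U(3 * nb);
  eval_residual(ctx, m, use_fcm, rc, X.begin(), q1.begin(), q2.begin(),
                Phi.begin(), dt, scheme, res.begin(), ws, true, Ffl.begin(),
                Tfl.begin(), U.begin());
  return List::create(_["res"] = res, _["F_fluid"] = Ffl, _["T_fluid"] = Tfl,
                      _["V"] = U);
}

// forces, torques and constraint residuals at a configuration (diagnostics,
// observables, unit tests)
// [[Rcpp::export(name = ".forces_cpp")]]
List forces_cpp(List model, NumericVector q, NumericVector lam,
                NumericVector Phi) {
  ModelDesc m;
  m.nsw = as<int>(model["nsw"]); m.nseg = as<int>(model["nseg"]);
  m.ds = as<double>(model["ds"]); m.KB = as<double>(model["KB"]);
  m.K0 = as<double>(model["K0"]); m.kwave = as<double>(model["kwave"]);
  m.len = as<double>(model["l"]); m.gamma_tip = as<double>(model["gamma_tip"]);
  m.off_h = as<double>(model["off_h"]); m.FS = as<double>(model["FS"]);
  m.chi = as<double>(model["chi"]);
  m.rad_head = as<double>(model["rad_head"]);
  m.rad_seg = as<double>(model["rad_seg"]);
  m.steric = as<bool>(model["steric"]);
  m.Lx = as<double>(model["Lx"]); m.Ly = as<double>(model["Ly"]);
  m.phase = as<std::vector<double>>(model["phase"]);
  int nb = m.nbodies();
  NumericVector F(2 * nb), Tz(nb), g(m.nlam());
  assemble_forces(m, q.begin(), lam.begin(), Phi.begin(), F.begin(),
                  Tz.begin(), g.begin());
  return List::create(_["F"] = F, _["Tz"] = Tz, _["g"] = g);
}

// Per-swimmer dense Jacobian blocks of the implicit-step residual under the
// RFT closure, by central finite differences; used as the Broyden seed.
// Returns a list of (3*bps + nlam) x (3*bps + nlam) matrices.
// [[Rcpp::export(name = ".rft_jac_blocks")]]
List rft_jac_blocks(SEXP ctxp, NumericVector X, NumericVector q1,
                    NumericVector q2, NumericVector Phi, double dt,
                    int scheme, List rft) {
  XPtr<PlanarCtx> ctx(ctxp);
  const ModelDesc& m = ctx->model;
  RftCoeffs rc = rft_from_list(rft);
  static Workspace ws;
  const int nq = m.nq(), bps = m.bodies_per_sw(), nl = m.nlam_per_sw();
  const int nd = 3 * bps + nl;
  std::vector<double> Xp(X.begin(), X.end());
  std::vector<double> rplus(m.ndof()), rminus(m.ndof());
  List out(m.nsw);
  for (int s = 0; s < m.nsw; ++s) {
    NumericMatrix J(nd, nd);
    for (int c = 0; c < nd; ++c) {
      int gi = (c < 3 * bps) ? (3 * bps * s + c) : (nq + nl * s + c - 3 * bps);
      double h = (c < 3 * bps) ? 1e-6 * std::max(1.0, m.ds) : 1e-6 * m.KB;
      double save = Xp[gi];
      Xp[gi] = save + h;
      eval_residual(ctx, m, false, rc, Xp.data(), q1.begin(), q2.begin(),
                    Phi.begin(), dt, scheme, rplus.data(), ws, false);
      Xp[gi] = save - h;
      eval_residual(ctx, m, false, rc, Xp.data(), q1.begin(), q2.begin(),
                    Phi.begin(), dt, scheme, rminus.data(), ws, false);
      Xp[gi] = save;
      for (int r = 0; r < nd; ++r) {
        int gr =
            (r < 3 * bps) ? (3 * bps * s + r) : (nq + nl * s + r - 3 * bps);
        J(r, c) = (rplus[gr] - rminus[gr]) / (2.0 * h);
      }
    }
    out[s] = J;
  }
  return out;
}

// [[Rcpp::export(name = ".rft_mobility_cpp")]]
List rft_mobility_cpp(List model, NumericVector q, NumericVector F,
                      NumericVector Tz, List rft) {
  ModelDesc m;
  m.nsw = as<int>(model["nsw"]); m.nseg = as<int>(model["nseg"]);
  m.ds = as<double>(model["ds"]);
  int nb = m.nbodies();
  RftCoeffs rc = rft_from_list(rft);
  NumericVector Ux(nb), Uy(nb), Wz(nb);
  rft_mobility_c(m, rc, q.begin(), F.begin(), Tz.begin(), Ux.begin(),
                 Uy.begin(), Wz.begin());
  return List::create(_["Ux"] = Ux, _["Uy"] = Uy, _["Wz"] = Wz);
}
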