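// Non-hydrodynamic force assembly for the discrete swimmer: driven elastic
// joint moments, inextensibility/clamp constraint forces via exact virtual
// work, steric barrier forces, and constraint residuals.
#include <Rcpp.h>
#include <cmath>
#include "model.h"

static inline double ramp(const ModelDesc& m, double s) {
  double s0 = (1.0 - m.gamma_tip) * m.len;
  if (s <= s0) return 1.0;
  if (s >= m.len) return 0.0;
  return (m.len - s) / (m.gamma_tip * m.len);
}

// preferred curvature at arclength s for swimmer sw at integrated phase Phi
static inline double kappa0(const ModelDesc& m, double s, double Phi,
                            double phase) {
  return m.K0 * ramp(m, s) * std::sin(m.kwave * s + Phi + phase);
}

// q layout: per body (x, y, theta); bodies per swimmer: head then segments.
// lam layout per swimmer: head joint (2), clamp (1), interior joints (2 each).
// Outputs F (2 per body), Tz (1 per body) are the forces/torques the bodies
// exert on the fluid (constraint + steric forces; elastic + driving +
// constraint torques); g is the stacked constraint residual.
void assemble_forces(const ModelDesc& m, const double* q, const double* lam,
                     const double* Phi, double* F, double* Tz, double* g) {
  const int bps = m.bodies_per_sw();
  const int nlam = m.nlam_per_sw();
  const int nb = m.nbodies();
  for (int i = 0; i < 2 * nb; ++i) F[i] = 0.0;
  for (int i = 0; i < nb; ++i) Tz[i] = 0.0;

  for (int s = 0; s < m.nsw; ++s) {
    const double* qs = q + 3 * bps * s;
    const double* ls = lam + nlam * s;
    double* Fs = F + 2 * bps * s;
    double* Ts = Tz + bps * s;
    double* gs = g + nlam * s;

    // driven elastic moments at interior joints j = 1..nseg-1 between
    // segment bodies j and j+1 (arclength s_j = j*ds)
    for (int j = 1; j < m.nseg; ++j) {
      double thA = qs[3 * j + 2];      // segment j
      double thB = qs[3 * (j + 1) + 2]; // segment j+1
      double k0 = kappa0(m, j * m.ds, Phi[s], m.phase[s]);
      double mom = (m.KB / m.ds) * std::sin(thB - thA) - m.KB * k0;
      Ts[j] += mom;
      Ts[j + 1] -= mom;
    }

    // head linkage: first segment centre at off_h along the head axis
    double th0 = qs[2];
    double c0 = std::cos(th0), s0 = std::sin(th0);
    double lhx = ls[0], lhy = ls[1], lc = ls[2];
    gs[0] = qs[3] - qs[0] - m.off_h * c0;
    gs[1] = qs[4] - qs[1] - m.off_h * s0;
    gs[2] = qs[5] - th0; // clamped end: tangent parallel to head axis
    Fs[2] -= lhx; Fs[3] -= lhy;       // on segment 1
    Fs[0] += lhx; Fs[1] += lhy;       // on head
    Ts[0] += m.off_h * (-s0 * lhx + c0 * lhy); // head linkage reaction torque
    Ts[1] -= lc;
    Ts[0] += lc;

    // inextensibility joints
    for (int j = 1; j < m.nseg; ++j) {
      const double* lj = ls + 3 + 2 * (j - 1);
      double thA = qs[3 * j + 2], thB = qs[3 * (j + 1) + 2];
      double cA = std::cos(thA), sA = std::sin(thA);
      double cB = std::cos(thB), sB = std::sin(thB);
      gs[3 + 2 * (j - 1)] =
          qs[3 * (j + 1)] - qs[3 * j] - 0.5 * m.ds * (cA + cB);
      gs[3 + 2 * (j - 1) + 1] =
          qs[3 * (j + 1) + 1] - qs[3 * j + 1] - 0.5 * m.ds * (sA + sB);
      Fs[2 * (j + 1)] -= lj[0]; Fs[2 * (j + 1) + 1] -= lj[1];
      Fs[2 * j] += lj[0]; Fs[2 * j + 1] += lj[1];
      Ts[j] += 0.5 * m.ds * (-sA * lj[0] + cA * lj[1]);
      Ts[j + 1] += 0.5 * m.ds * (-sB * lj[0] + cB * lj[1]);
    }
  }

  if (m.steric && m.FS > 0.0) steric_accumulate(m, q, F);
}

// Quartic short-range barrier between non-bonded bodies; pairwise
// equal-and-opposite, magnitude FS at contact r = ai + aj, zero beyond
// chi*(ai+aj). Minimum-image in the periodic box. Deterministic plain
// pairwise sweep (desk-scale body counts).
void steric_accumulate(const ModelDesc& m, const double* q, double* F) {
  const int bps = m.bodies_per_sw();
  const int nb = m.nbodies();
  const double chi2 = m.chi * m.chi;
  for (int i = 0; i < nb; ++i) {
    double ri = (i % bps == 0) ? m.rad_head : m.rad_seg;
    for (int j = i + 1; j < nb; ++j) {
      if (i / bps == j / bps && std::abs(i % bps - j % bps) <= 2) continue;
      double rj = (j % bps == 0) ? m.rad_head : m.rad_seg;
      double sum = ri + rj, Rref2 = chi2 * sum * sum;
      double dxp = q[3 * i] - q[3 * j];
      double dyp = q[3 * i + 1] - q[3 * j + 1];
      if (m.Lx > 0.0) {
        dxp -= m.Lx * std::round(dxp / m.Lx);
        dyp -= m.Ly * std::round(dyp / m.Ly);
      }
      double r2 = dxp * dxp + dyp * dyp;
      if (r2 >= Rref2) continue;
      double rmin = 0.1 * sum;
      if (r2 < rmin * rmin) r2 = rmin * rmin; // clamp near-overlap
      double x = (Rref2 - r2) / (Rref2 - sum * sum);
      double x2 = x * x;
      double mag = m.FS * x2 * x2;
      // bounded barrier: deep interpenetration (which converged dynamics
      // never reach) must not produce unrecoverable forces
      if (mag > 20.0 * m.FS) mag = 20.0 * m.FS;
      double r = std::sqrt(r2);
      double fx = mag * dxp / r, fy = mag * dyp / r;
      F[2 * i] += fx; F[2 * i + 1] += fy;
      F[2 * j] -= fx; F[2 * j + 1] -= fy;
    }
  }
}

// Local drag closure: anisotropic segment drag decomposed along the segment
// tangent, isotropic in-plane head drag; no body-body coupling.
void rft_mobility_c(const ModelDesc& m, const RftCoeffs& c, const double* q,
                    const double* F, const double* Tz, double* Ux, double* Uy,
                    double* Wz) {
  const int bps = m.bodies_per_sw();
  const int nb = m.nbodies();
  const double zt = c.xi_par * m.ds, zn = c.xi_perp * m.ds;
  for (int i = 0; i < nb; ++i) {
    double fx = F[2 * i], fy = F[2 * i + 1];
    if (i % bps == 0) {
      Ux[i] = fx / c.zeta_head_t;
      Uy[i] = fy / c.zeta_head_t;
      Wz[i] = Tz[i] / c.zeta_head_r;
    } else {
      double th = q[3 * i + 2];
      double tx = std::cos(th), ty = std::sin(th);
      double fpar = fx * tx + fy * ty;
      double fperpx = fx - fpar * tx, fperpy = fy - fpar * ty;
      Ux[i] = fpar * tx / zt + fperpx / zn;
      Uy[i] = fpar * ty / zt + fperpy / zn;
      Wz[i] = Tz[i] / c.zeta_rot_seg;
    }
  }
}
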