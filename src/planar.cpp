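// Planar-collapsed FCM mobility. With every body on the midplane z = Lz/2
// (a grid plane), spreading/interpolation Gaussians factorize as
// g2(x,y) * h(z) and the triply periodic spectral Stokes solve reduces to
// 2D transforms with kz-summed kernels
//   K_ab^{cr}(kx,ky) = (1/Nz) sum_kz P_ab(k) h_c(kz) h_r(kz),
//   P_ab(k) = (delta_ab - k_a k_b / |k|^2) / (eta |k|^2),
// one kernel per pair of envelope classes. This is algebraically identical
// to the full 3D grid solve with the same sampled Gaussians (asserted
// against the plain 3D route in the tests). Torques enter as antisymmetric
// (rotlet) dipoles, f_hat += -(i/2) (T x k) Dhat(k), and angular velocities
// as half the spectral curl averaged with the dipole envelope.
#include <Rcpp.h>
#include <cmath>
#include "model.h"

using namespace Rcpp;

static const double TRUNC_SD = 7.0; // Gaussian truncation radius in sigmas

// DFT of the z-profile of a sampled, truncated, normalized Gaussian centred
// on a grid plane (real and even, so the transform is real).
static std::vector<double> zprofile_hat(int nz, double dx, double sigma) {
  std::vector<double> h(nz, 0.0);
  double norm = 1.0 / std::sqrt(2.0 * M_PI * sigma * sigma);
  double rc = TRUNC_SD * sigma;
  double Lz = nz * dx;
  for (int j = 0; j < nz; ++j) {
    for (int m = -3; m <= 3; ++m) { // periodized sampled profile
      double dz = j * dx + m * Lz;
      if (std::abs(dz) <= rc)
        h[j] += norm * std::exp(-0.5 * dz * dz / (sigma * sigma));
    }
  }
  std::vector<double> hh(nz, 0.0);
  for (int mz = 0; mz < nz; ++mz) {
    double acc = 0.0;
    for (int j = 0; j < nz; ++j)
      acc += h[j] * std::cos(2.0 * M_PI * mz * j / nz);
    hh[mz] = acc;
  }
  return hh;
}

static void build_kernels(PlanarCtx& ctx) {
  const int nx = ctx.nx, ny = ctx.ny, nz = ctx.nz;
  const double L = nx * ctx.dx, Ly = ny * ctx.dx, Lz = nz * ctx.dx;
  std::vector<std::vector<double>> hh(4);
  for (int c = 0; c < 4; ++c) hh[c] = zprofile_hat(nz, ctx.dx, ctx.sig[c]);

  const size_t ng = (size_t)nx * ny;
  for (int p = 0; p < 3; ++p)
    for (int c = 0; c < 3; ++c) ctx.Kmm[p][c].assign(ng, 0.0);
  for (int p = 0; p < 4; ++p)
    for (int c = 0; c < 2; ++c) ctx.Krm[p][c].assign(ng, 0.0);
  for (int p = 0; p < 3; ++p) ctx.Krr[p].assign(ng, 0.0);

  std::vector<double> kzv(nz);
  for (int mz = 0; mz < nz; ++mz) {
    int f = (mz <= nz / 2) ? mz : mz - nz;
    kzv[mz] = 2.0 * M_PI * f / Lz;
  }

  for (int j = 0; j < ny; ++j) {
    int fy = (j <= ny / 2) ? j : j - ny;
    double ky = 2.0 * M_PI * fy / Ly;
    // odd (derivative) factors vanish at the Nyquist mode
    double epsx = (j == ny / 2) ? 0.0 : -ky;
    for (int i = 0; i < nx; ++i) {
      int fx = (i <= nx / 2) ? i : i - nx;
      double kx = 2.0 * M_PI * fx / L;
      double epsy = (i == nx / 2) ? 0.0 : kx;
      size_t idx = (size_t)i + (size_t)nx * j;
      double kp2 = kx * kx + ky * ky;
      double acc_mm[3][3] = {{0}}, acc_rm[4][2] = {{0}}, acc_rr[3] = {0};
      for (int mz = 0; mz < nz; ++mz) {
        double kz = kzv[mz];
        double k2 = kp2 + kz * kz;
        if (k2 == 0.0) continue;
        double inv = 1.0 / (ctx.eta * k2 * k2);
        double Pxx = (k2 - kx * kx) * inv;
        double Pyy = (k2 - ky * ky) * inv;
        double Pxy = (-kx * ky) * inv;
        // mono-mono envelope pairs: (s,s), (s,h), (h,h)
        const int mpair[3][2] = {{0, 0}, {0, 2}, {2, 2}};
        for (int p = 0; p < 3; ++p) {
          double E = hh[mpair[p][0]][mz] * hh[mpair[p][1]][mz];
          acc_mm[p][0] += Pxx * E;
          acc_mm[p][1] += Pxy * E;
          acc_mm[p][2] += Pyy * E;
        }
        // rot-mono pairs: (sd,s), (sd,h), (hd,s), (hd,h)
        double PEx = Pxx * epsx + Pxy * epsy;
        double PEy = Pxy * epsx + Pyy * epsy;
        const int rpair[4][2] = {{1, 0}, {1, 2}, {3, 0}, {3, 2}};
        for (int p = 0; p < 4; ++p) {
          double E = hh[rpair[p][0]][mz] * hh[rpair[p][1]][mz];
          acc_rm[p][0] += 0.5 * PEx * E;
          acc_rm[p][1] += 0.5 * PEy * E;
        }
        // rot-rot pairs: (sd,sd), (sd,hd), (hd,hd)
        double ePe = epsx * PEx + epsy * PEy;
        const int dpair[3][2] = {{1, 1}, {1, 3}, {3, 3}};
        for (int p = 0; p < 3; ++p) {
          double E = hh[dpair[p][0]][mz] * hh[dpair[p][1]][mz];
          acc_rr[p] += 0.25 * ePe * E;
        }
      }
      for (int p = 0; p < 3; ++p)
        for (int c = 0; c < 3; ++c) ctx.Kmm[p][c][idx] = acc_mm[p][c] / nz;
      for (int p = 0; p < 4; ++p)
        for (int c = 0; c < 2; ++c) ctx.Krm[p][c][idx] = acc_rm[p][c] / nz;
      for (int p = 0; p < 3; ++p) ctx.Krr[p][idx] = acc_rr[p] / nz;
    }
  }
}

static void build_mid_kernels(PlanarCtx& ctx) {
  const int nx = ctx.nx, ny = ctx.ny, nz = ctx.nz;
  const double L = nx * ctx.dx, Ly = ny * ctx.dx, Lz = nz * ctx.dx;
  std::vector<std::vector<double>> hh(4);
  for (int c = 0; c < 4; ++c) hh[c] = zprofile_hat(nz, ctx.dx, ctx.sig[c]);
  const size_t ng = (size_t)nx * ny;
  for (int p = 0; p < 2; ++p)
    for (int c = 0; c < 3; ++c) ctx.Mmm[p][c].assign(ng, 0.0);
  for (int p = 0; p < 2; ++p)
    for (int c = 0; c < 2; ++c) ctx.Mrm[p][c].assign(ng, 0.0);
  for (int j = 0; j < ny; ++j) {
    int fy = (j <= ny / 2) ? j : j - ny;
    double ky = 2.0 * M_PI * fy / Ly;
    double epsx = (j == ny / 2) ? 0.0 : -ky;
    for (int i = 0; i < nx; ++i) {
      int fx = (i <= nx / 2) ? i : i - nx;
      double kx = 2.0 * M_PI * fx / L;
      double epsy = (i == nx / 2) ? 0.0 : kx;
      size_t idx = (size_t)i + (size_t)nx * j;
      double kp2 = kx * kx + ky * ky;
      for (int mz = 0; mz < nz; ++mz) {
        int f = (mz <= nz / 2) ? mz : mz - nz;
        double kz = 2.0 * M_PI * f / Lz;
        double k2 = kp2 + kz * kz;
        if (k2 == 0.0) continue;
        double inv = 1.0 / (ctx.eta * k2 * k2);
        double Pxx = (k2 - kx * kx) * inv;
        double Pyy = (k2 - ky * ky) * inv;
        double Pxy = (-kx * ky) * inv;
        double PEx = Pxx * epsx + Pxy * epsy;
        double PEy = Pxy * epsx + Pyy * epsy;
        const int mono[2] = {0, 2}, dip[2] = {1, 3};
        for (int p = 0; p < 2; ++p) {
          double E = hh[mono[p]][mz] / nz;
          ctx.Mmm[p][0][idx] += Pxx * E;
          ctx.Mmm[p][1][idx] += Pxy * E;
          ctx.Mmm[p][2][idx] += Pyy * E;
          double Ed = hh[dip[p]][mz] / nz;
          ctx.Mrm[p][0][idx] += 0.5 * PEx * Ed;
          ctx.Mrm[p][1][idx] += 0.5 * PEy * Ed;
        }
      }
    }
  }
  ctx.have_mid = true;
}

// sampled 1D Gaussian weights along one axis around position x (grid units)
static void gauss_line(double x, double dx, int n, double sigma, int supp,
                       int* i0_out, std::vector<double>& w) {
  int ic = (int)std::floor(x / dx + 0.5);
  int i0 = ic - supp;
  *i0_out = i0;
  double norm = 1.0 / std::sqrt(2.0 * M_PI * sigma * sigma);
  for (int t = 0; t <= 2 * supp; ++t) {
    double xi = (i0 + t) * dx;
    double r = xi - x;
    w[t] = norm * std::exp(-0.5 * r * r / (sigma * sigma));
  }
}

static inline int wrap(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// spread val * g2 into complex grid (re or im part chosen by scale)
static void spread2d(std::vector<cplx>& grid, int nx, int ny, double dx,
                     double x, double y, cplx val, double sigma, int supp) {
  std::vector<double> wx(2 * supp + 1), wy(2 * supp + 1);
  int ix0, iy0;
  gauss_line(x, dx, nx, sigma, supp, &ix0, wx);
  gauss_line(y, dx, ny, sigma, supp, &iy0, wy);
  for (int ty = 0; ty <= 2 * supp; ++ty) {
    int jy = wrap(iy0 + ty, ny);
    cplx vy = val * wy[ty];
    size_t row = (size_t)nx * jy;
    for (int tx = 0; tx <= 2 * supp; ++tx) {
      int jx = wrap(ix0 + tx, nx);
      grid[row + jx] += vy * wx[tx];
    }
  }
}

static cplx interp2d(const std::vector<cplx>& grid, int nx, int ny, double dx,
                     double x, double y, double sigma, int supp) {
  std::vector<double> wx(2 * supp + 1), wy(2 * supp + 1);
  int ix0, iy0;
  gauss_line(x, dx, nx, sigma, supp, &ix0, wx);
  gauss_line(y, dx, ny, sigma, supp, &iy0, wy);
  cplx acc(0.0, 0.0);
  for (int ty = 0; ty <= 2 * supp; ++ty) {
    int jy = wrap(iy0 + ty, ny);
    size_t row = (size_t)nx * jy;
    cplx rowacc(0.0, 0.0);
    for (int tx = 0; tx <= 2 * supp; ++tx)
      rowacc += grid[row + wrap(ix0 + tx, nx)] * wx[tx];
    acc += rowacc * wy[ty];
  }
  return acc;
}

// Full planar mobility: forces/torques on bodies -> velocities/spin.
// cls: 0 = segment, 1 = head (envelope classes (0,1) and (2,3)).
void planar_mobility(const PlanarCtx& ctx, int nb, const double* px,
                     const double* py, const double* Fx, const double* Fy,
                     const double* Tz, const int* cls, double* Ux, double* Uy,
                     double* Wz) {
  const int nx = ctx.nx, ny = ctx.ny;
  const size_t ng = (size_t)nx * ny;
  std::vector<cplx> Zs(ng, cplx(0, 0)), Zh(ng, cplx(0, 0)),
      Zr(ng, cplx(0, 0));
  for (int b = 0; b < nb; ++b) {
    if (cls[b] == 0) {
      spread2d(Zs, nx, ny, ctx.dx, px[b], py[b], cplx(Fx[b], Fy[b]),
               ctx.sig[0], ctx.supp[0]);
      if (Tz[b] != 0.0)
        spread2d(Zr, nx, ny, ctx.dx, px[b], py[b], cplx(Tz[b], 0.0),
                 ctx.sig[1], ctx.supp[1]);
    } else {
      spread2d(Zh, nx, ny, ctx.dx, px[b], py[b], cplx(Fx[b], Fy[b]),
               ctx.sig[2], ctx.supp[2]);
      if (Tz[b] != 0.0)
        spread2d(Zr, nx, ny, ctx.dx, px[b], py[b], cplx(0.0, Tz[b]),
                 ctx.sig[3], ctx.supp[3]);
    }
  }
  spfft::fft2(Zs.data(), nx, ny, false);
  spfft::fft2(Zh.data(), nx, ny, false);
  spfft::fft2(Zr.data(), nx, ny, false);

  std::vector<cplx> Us(ng), Uh(ng), V(ng);
  const cplx I(0.0, 1.0);
  for (int j = 0; j < ny; ++j) {
    int jn = (ny - j) % ny;
    for (int i = 0; i < nx; ++i) {
      int in = (nx - i) % nx;
      size_t k = (size_t)i + (size_t)nx * j;
      size_t kn = (size_t)in + (size_t)nx * jn;
      // unpack two real fields from each packed transform
      cplx zs = Zs[k], zsc = std::conj(Zs[kn]);
      cplx fx = 0.5 * (zs + zsc), fy = -0.5 * I * (zs - zsc);
      cplx zh = Zh[k], zhc = std::conj(Zh[kn]);
      cplx hx = 0.5 * (zh + zhc), hy = -0.5 * I * (zh - zhc);
      cplx zr = Zr[k], zrc = std::conj(Zr[kn]);
      cplx rs = 0.5 * (zr + zrc), rh = -0.5 * I * (zr - zrc);

      cplx ux = ctx.Kmm[0][0][k] * fx + ctx.Kmm[0][1][k] * fy +
                ctx.Kmm[1][0][k] * hx + ctx.Kmm[1][1][k] * hy -
                I * (ctx.Krm[0][0][k] * rs + ctx.Krm[2][0][k] * rh);
      cplx uy = ctx.Kmm[0][1][k] * fx + ctx.Kmm[0][2][k] * fy +
                ctx.Kmm[1][1][k] * hx + ctx.Kmm[1][2][k] * hy -
                I * (ctx.Krm[0][1][k] * rs + ctx.Krm[2][1][k] * rh);
      cplx vx = ctx.Kmm[1][0][k] * fx + ctx.Kmm[1][1][k] * fy +
                ctx.Kmm[2][0][k] * hx + ctx.Kmm[2][1][k] * hy -
                I * (ctx.Krm[1][0][k] * rs + ctx.Krm[3][0][k] * rh);
      cplx vy = ctx.Kmm[1][1][k] * fx + ctx.Kmm[1][2][k] * fy +
                ctx.Kmm[2][1][k] * hx + ctx.Kmm[2][2][k] * hy -
                I * (ctx.Krm[1][1][k] * rs + ctx.Krm[3][1][k] * rh);
      // vorticity/2 received by segment-dipole and head-dipole envelopes
      cplx ws = I * (ctx.Krm[0][0][k] * fx + ctx.Krm[0][1][k] * fy +
                     ctx.Krm[1][0][k] * hx + ctx.Krm[1][1][k] * hy) +
                ctx.Krr[0][k] * rs + ctx.Krr[1][k] * rh;
      cplx wh = I * (ctx.Krm[2][0][k] * fx + ctx.Krm[2][1][k] * fy +
                     ctx.Krm[3][0][k] * hx + ctx.Krm[3][1][k] * hy) +
                ctx.Krr[1][k] * rs + ctx.Krr[2][k] * rh;
      Us[k] = ux + I * uy;
      Uh[k] = vx + I * vy;
      V[k] = ws + I * wh;
    }
  }
  spfft::fft2(Us.data(), nx, ny, true);
  spfft::fft2(Uh.data(), nx, ny, true);
  spfft::fft2(V.data(), nx, ny, true);
  double scale = ctx.dx * ctx.dx * ctx.dx / ng;
  for (int b = 0; b < nb; ++b) {
    if (cls[b] == 0) {
      cplx u = interp2d(Us, nx, ny, ctx.dx, px[b], py[b], ctx.sig[0],
                        ctx.supp[0]);
      cplx w = interp2d(V, nx, ny, ctx.dx, px[b], py[b], ctx.sig[1],
                        ctx.supp[1]);
      Ux[b] = scale * u.real();
      Uy[b] = scale * u.imag();
      Wz[b] = scale * w.real();
    } else {
      cplx u = interp2d(Uh, nx, ny, ctx.dx, px[b], py[b], ctx.sig[2],
                        ctx.supp[2]);
      cplx w = interp2d(V, nx, ny, ctx.dx, px[b], py[b], ctx.sig[3],
                        ctx.supp[3]);
      Ux[b] = scale * u.real();
      Uy[b] = scale * u.imag();
      Wz[b] = scale * w.imag();
    }
  }
}

// ---- Rcpp interface -------------------------------------------------------

static ModelDesc model_from_list(const List& ml) {
  ModelDesc m;
  m.nsw = as<int>(ml["nsw"]);
  m.nseg = as<int>(ml["nseg"]);
  m.ds = as<double>(ml["ds"]);
  m.KB = as<double>(ml["KB"]);
  m.K0 = as<double>(ml["K0"]);
  m.kwave = as<double>(ml["kwave"]);
  m.len = as<double>(ml["l"]);
  m.gamma_tip = as<double>(ml["gamma_tip"]);
  m.off_h = as<double>(ml["off_h"]);
  m.FS = as<double>(ml["FS"]);
  m.chi = as<double>(ml["chi"]);
  m.rad_head = as<double>(ml["rad_head"]);
  m.rad_seg = as<double>(ml["rad_seg"]);
  m.steric = as<bool>(ml["steric"]);
  m.Lx = as<double>(ml["Lx"]);
  m.Ly = as<double>(ml["Ly"]);
  m.phase = as<std::vector<double>>(ml["phase"]);
  return m;
}

// [[Rcpp::export(name = ".planar_ctx_new")]]
SEXP planar_ctx_new(int nx, int ny, int nz, double dx, double eta,
                    NumericVector sigma, List model) {
  PlanarCtx* ctx = new PlanarCtx();
  ctx->nx = nx; ctx->ny = ny; ctx->nz = nz;
  ctx->dx = dx; ctx->eta = eta;
  for (int c = 0; c < 4; ++c) {
    ctx->sig[c] = sigma[c];
    ctx->supp[c] = (int)std::ceil(TRUNC_SD * sigma[c] / dx);
    if (2 * ctx->supp[c] + 1 > std::min(nx, ny))
      stop("Gaussian support exceeds grid extent");
    if (sigma[c] / dx < 1.0)
      stop("unresolved FCM envelope: sigma/dx = %.3f < 1", sigma[c] / dx);
  }
  ctx->model = model_from_list(model);
  build_kernels(*ctx);
  XPtr<PlanarCtx> ptr(ctx, true);
  return ptr;
}

// [[Rcpp::export(name = ".planar_update_model")]]
void planar_update_model(SEXP ctxp, List model) {
  XPtr<PlanarCtx> ctx(ctxp);
  ctx->model = model_from_list(model);
}

// [[Rcpp::export(name = ".planar_mobility_cpp")]]
List planar_mobility_cpp(SEXP ctxp, NumericVector px, NumericVector py,
                         NumericVector Fx, NumericVector Fy, NumericVector Tz,
                         IntegerVector cls) {
  XPtr<PlanarCtx> ctx(ctxp);
  int nb = px.size();
  NumericVector Ux(nb), Uy(nb), Wz(nb);
  planar_mobility(*ctx, nb, px.begin(), py.begin(), Fx.begin(), Fy.begin(),
                  Tz.begin(), cls.begin(), Ux.begin(), Uy.begin(), Wz.begin());
  return List::create(_["Ux"] = Ux, _["Uy"] = Uy, _["Wz"] = Wz);
}

// Midplane in-plane velocity field u(x, y, Lz/2) produced by the given
// forces/torques (for energy spectra and flow visualization).
// [[Rcpp::export(name = ".planar_midplane_field")]]
List planar_midplane_field(SEXP ctxp, NumericVector px, NumericVector py,
                           NumericVector Fx, NumericVector Fy,
                           NumericVector Tz, IntegerVector cls) {
  XPtr<PlanarCtx> ctx(ctxp);
  if (!ctx->have_mid) build_mid_kernels(*ctx);
  const int nx = ctx->nx, ny = ctx->ny;
  const size_t ng = (size_t)nx * ny;
  std::vector<cplx> Zs(ng, cplx(0, 0)), Zh(ng, cplx(0, 0)),
      Zr(ng, cplx(0, 0));
  int nb = px.size();
  for (int b = 0; b < nb; ++b) {
    if (cls[b] == 0) {
      spread2d(Zs, nx, ny, ctx->dx, px[b], py[b], cplx(Fx[b], Fy[b]),
               ctx->sig[0], ctx->supp[0]);
      if (Tz[b] != 0.0)
        spread2d(Zr, nx, ny, ctx->dx, px[b], py[b], cplx(Tz[b], 0.0),
                 ctx->sig[1], ctx->supp[1]);
    } else {
      spread2d(Zh, nx, ny, ctx->dx, px[b], py[b], cplx(Fx[b], Fy[b]),
               ctx->sig[2], ctx->supp[2]);
      if (Tz[b] != 0.0)
        spread2d(Zr, nx, ny, ctx->dx, px[b], py[b], cplx(0.0, Tz[b]),
                 ctx->sig[3], ctx->supp[3]);
    }
  }
  spfft::fft2(Zs.data(), nx, ny, false);
  spfft::fft2(Zh.data(), nx, ny, false);
  spfft::fft2(Zr.data(), nx, ny, false);
  std::vector<cplx> U(ng);
  const cplx I(0.0, 1.0);
  for (int j = 0; j < ny; ++j) {
    int jn = (ny - j) % ny;
    for (int i = 0; i < nx; ++i) {
      int in = (nx - i) % nx;
      size_t k = (size_t)i + (size_t)nx * j;
      size_t kn = (size_t)in + (size_t)nx * jn;
      cplx zs = Zs[k], zsc = std::conj(Zs[kn]);
      cplx fx = 0.5 * (zs + zsc), fy = -0.5 * I * (zs - zsc);
      cplx zh = Zh[k], zhc = std::conj(Zh[kn]);
      cplx hx = 0.5 * (zh + zhc), hy = -0.5 * I * (zh - zhc);
      cplx zr = Zr[k], zrc = std::conj(Zr[kn]);
      cplx rs = 0.5 * (zr + zrc), rh = -0.5 * I * (zr - zrc);
      cplx ux = ctx->Mmm[0][0][k] * fx + ctx->Mmm[0][1][k] * fy +
                ctx->Mmm[1][0][k] * hx + ctx->Mmm[1][1][k] * hy -
                I * (ctx->Mrm[0][0][k] * rs + ctx->Mrm[1][0][k] * rh);
      cplx uy = ctx->Mmm[0][1][k] * fx + ctx->Mmm[0][2][k] * fy +
                ctx->Mmm[1][1][k] * hx + ctx->Mmm[1][2][k] * hy -
                I * (ctx->Mrm[0][1][k] * rs + ctx->Mrm[1][1][k] * rh);
      U[k] = ux + I * uy;
    }
  }
  spfft::fft2(U.data(), nx, ny, true);
  NumericMatrix ux(nx, ny), uy(nx, ny);
  double scale = 1.0 / ng;
  for (size_t k = 0; k < ng; ++k) {
    ux[k] = scale * U[k].real();
    uy[k] = scale * U[k].imag();
  }
  return List::create(_["ux"] = ux, _["uy"] = uy);
}

// context carrying only the model description (local-drag backend runs need
// no grid or kernels)
// [[Rcpp::export(name = ".model_ctx_new")]]
SEXP model_ctx_new(List model) {
  PlanarCtx* ctx = new PlanarCtx();
  ctx->model = model_from_list(model);
  XPtr<PlanarCtx> ptr(ctx, true);
  return ptr;
}
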