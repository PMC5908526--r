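// Full 3D spectral Stokes solve for forcing at arbitrary z (not restricted
// to the midplane), returning the midplane in-plane velocity slice. Used for
// the uncorrelated-forcing spectrum experiment; the pure-R 3D route is the
// small-grid oracle for this path.
#include <Rcpp.h>
#include <cmath>
#include "model.h"

using namespace Rcpp;

static const double TRUNC_SD3 = 7.0;

// [[Rcpp::export(name = ".film_slice_cpp")]]
List film_slice_cpp(int nx, int ny, int nz, double dx, double eta,
                    double sigma, NumericMatrix pos, NumericMatrix Fmat) {
  const size_t ng = (size_t)nx * ny * nz;
  std::vector<cplx> gx(ng, cplx(0, 0)), gy(ng, cplx(0, 0));
  // pack fz with fy? keep two complex grids: (fx + i fy) and fz ignored if 0
  int nf = pos.nrow();
  int supp = (int)std::ceil(TRUNC_SD3 * sigma / dx);
  std::vector<double> wx(2 * supp + 1), wy(2 * supp + 1), wz(2 * supp + 1);
  double norm = std::pow(2.0 * M_PI * sigma * sigma, -0.5);
  bool any_fz = false;
  for (int n = 0; n < nf; ++n)
    if (Fmat(n, 2) != 0.0) any_fz = true;
  std::vector<cplx> gz(any_fz ? ng : 0, cplx(0, 0));
  for (int n = 0; n < nf; ++n) {
    int i0 = (int)std::floor(pos(n, 0) / dx + 0.5) - supp;
    int j0 = (int)std::floor(pos(n, 1) / dx + 0.5) - supp;
    int k0 = (int)std::floor(pos(n, 2) / dx + 0.5) - supp;
    for (int t = 0; t <= 2 * supp; ++t) {
      double rx = (i0 + t) * dx - pos(n, 0);
      double ry = (j0 + t) * dx - pos(n, 1);
      double rz = (k0 + t) * dx - pos(n, 2);
      wx[t] = norm * std::exp(-0.5 * rx * rx / (sigma * sigma));
      wy[t] = norm * std::exp(-0.5 * ry * ry / (sigma * sigma));
      wz[t] = norm * std::exp(-0.5 * rz * rz / (sigma * sigma));
    }
    cplx f(Fmat(n, 0), Fmat(n, 1));
    double fz = Fmat(n, 2);
    for (int tz = 0; tz <= 2 * supp; ++tz) {
      int kz = ((k0 + tz) % nz + nz) % nz;
      size_t off_z = (size_t)nx * ny * kz;
      for (int ty = 0; ty <= 2 * supp; ++ty) {
        int jy = ((j0 + ty) % ny + ny) % ny;
        size_t off = off_z + (size_t)nx * jy;
        double wyz = wy[ty] * wz[tz];
        for (int tx = 0; tx <= 2 * supp; ++tx) {
          int ix = ((i0 + tx) % nx + nx) % nx;
          gx[off + ix] += f * (wx[tx] * wyz);
          if (any_fz) gz[off + ix] += fz * (wx[tx] * wyz);
        }
      }
    }
  }
  spfft::fft3(gx.data(), nx, ny, nz, false);
  if (any_fz) spfft::fft3(gz.data(), nx, ny, nz, false);

  // project, divide by eta k^2, and sum over kz with the midplane phase
  // (z0 = (nz/2) dx is a grid plane; the DFT index phase is exp(i kz z0))
  int iz0 = nz / 2;
  std::vector<cplx> sx((size_t)nx * ny, cplx(0, 0)),
      sy((size_t)nx * ny, cplx(0, 0));
  double Lx = nx * dx, Ly = ny * dx, Lz = nz * dx;
  for (int mz = 0; mz < nz; ++mz) {
    int fz_ = (mz <= nz / 2) ? mz : mz - nz;
    double kz = 2.0 * M_PI * fz_ / Lz;
    // e^{i 2 pi mz iz0 / nz}: for iz0 = nz/2 this is (-1)^mz
    if (iz0 * 2 != nz) stop("midplane must be a grid plane");
    double ph = (mz % 2 == 0) ? 1.0 : -1.0;
    size_t off_z = (size_t)nx * ny * mz;
    for (int j = 0; j < ny; ++j) {
      int fy_ = (j <= ny / 2) ? j : j - ny;
      double ky = 2.0 * M_PI * fy_ / Ly;
      for (int i = 0; i < nx; ++i) {
        int fx_ = (i <= nx / 2) ? i : i - nx;
        double kx = 2.0 * M_PI * fx_ / Lx;
        double k2 = kx * kx + ky * ky + kz * kz;
        if (k2 == 0.0) continue;
        size_t idx = off_z + (size_t)nx * j + i;
        size_t id2 = (size_t)nx * j + i;
        cplx zf = gx[idx];
        cplx zc = std::conj(
            gx[(size_t)nx * ny * ((nz - mz) % nz) +
               (size_t)nx * ((ny - j) % ny) + ((nx - i) % nx)]);
        cplx fx = 0.5 * (zf + zc);
        cplx fy = cplx(0, -0.5) * (zf - zc);
        cplx fzc = any_fz ? gz[idx] : cplx(0, 0);
        cplx kf = (kx * fx + ky * fy + kz * fzc) / k2;
        cplx ux = (fx - kx * kf) / (eta * k2);
        cplx uy = (fy - ky * kf) / (eta * k2);
        sx[id2] += ph * ux;
        sy[id2] += ph * uy;
      }
    }
  }
  // back to real space in-plane
  std::vector<cplx> U((size_t)nx * ny);
  for (size_t k = 0; k < (size_t)nx * ny; ++k)
    U[k] = sx[k] + cplx(0, 1) * sy[k];
  // note: sx, sy are each Hermitian only after kz summation of a real
  // field's transform; the packing trick applies as in the planar solver
  spfft::fft2(U.data(), nx, ny, true);
  NumericMatrix ux(nx, ny), uy(nx, ny);
  double scale = 1.0 / ((double)nx * ny * nz);
  for (size_t k = 0; k < (size_t)nx * ny; ++k) {
    ux[k] = scale * U[k].real();
    uy[k] = scale * U[k].imag();
  }
  return List::create(_["ux"] = ux, _["uy"] = uy);
}
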