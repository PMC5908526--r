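#ifndef SPERMFILM_MODEL_H
#define SPERMFILM_MODEL_H

#include <vector>
#include <complex>

typedef std::complex<double> cplx;

namespace spfft {
void fft1(cplx* a, int n, bool inverse);
void fft2(cplx* a, int nx, int ny, bool inverse);
void fft3(cplx* a, int nx, int ny, int nz, bool inverse);
}

// Discrete swimmer model: one head (body 0) + nseg flagellum segments per
// swimmer, planar configuration coordinates (x, y, theta) per body.
struct ModelDesc {
  int nsw = 1;
  int nseg = 29;
  double ds = 2.2;       // segment spacing l/nseg
  double KB = 1800.0;    // bending modulus
  double K0 = 0.2;       // curvature amplitude
  double kwave = 0.0;    // 2*pi/l
  double len = 63.8;     // flagellum length l
  double gamma_tip = 0.2;
  double off_h = 0.0;    // head centre to first segment centre: 1.1a + ds/2
  double FS = 0.0;       // steric contact force
  double chi = 1.1;      // steric range factor
  double rad_head = 3.0; // steric radius of head
  double rad_seg = 1.0;  // steric radius of segments
  bool steric = true;
  double Lx = 0.0, Ly = 0.0; // periodic box (minimum image for steric)
  std::vector<double> phase; // static phase offset per swimmer

  int bodies_per_sw() const { return nseg + 1; }
  int nlam_per_sw() const { return 3 + 2 * (nseg - 1); }
  int nbodies() const { return nsw * bodies_per_sw(); }
  int nq() const { return 3 * nbodies(); }
  int nlam() const { return nsw * nlam_per_sw(); }
  int ndof() const { return nq() + nlam(); }
};

// Local anisotropic drag model (resistive force theory)
struct RftCoeffs {
  double xi_par = 0.0;     // tangential drag per unit length
  double xi_perp = 0.0;    // normal drag per unit length
  double zeta_rot_seg = 0.0; // rotational drag per segment
  double zeta_head_t = 0.0;  // head translational drag (in-plane, isotropic)
  double zeta_head_r = 0.0;  // head rotational drag about z
};

// Planar FCM context: grid geometry plus kz-summed spectral kernels for the
// four Gaussian envelope classes (segment monopole/dipole, head
// monopole/dipole). All bodies sit on the midplane z = Lz/2, which makes the
// triply periodic Stokes solve exactly equivalent to these 2D operations.
struct PlanarCtx {
  int nx = 0, ny = 0, nz = 0;
  double dx = 0.0, eta = 1.0;
  double sig[4];     // envelope widths: seg mono, seg dip, head mono, head dip
  int supp[4];       // spreading support half-widths (grid cells)
  // kernels, each length nx*ny, index = i + nx*j
  // mono->mono pairs: 0 = (s,s), 1 = (s,h), 2 = (h,h); comps xx, xy, yy
  std::vector<double> Kmm[3][3];
  // rot->mono pairs: 0 = (sd,s), 1 = (sd,h), 2 = (hd,s), 3 = (hd,h); comps x,y
  std::vector<double> Krm[4][2];
  // rot->rot pairs: 0 = (sd,sd), 1 = (sd,hd), 2 = (hd,hd)
  std::vector<double> Krr[3];
  // midplane-evaluation kernels (receiver = grid point), built lazily
  bool have_mid = false;
  std::vector<double> Mmm[2][3]; // (s,h) -> point, comps xx, xy, yy
  std::vector<double> Mrm[2][2]; // (sd,hd) -> point, comps x, y

  ModelDesc model;
};

void assemble_forces(const ModelDesc& m, const double* q, const double* lam,
                     const double* Phi, double* F, double* Tz, double* g);
void steric_accumulate(const ModelDesc& m, const double* q, double* F);
void planar_mobility(const PlanarCtx& ctx, int nb, const double* px,
                     const double* py, const double* Fx, const double* Fy,
                     const double* Tz, const int* cls, double* Ux, double* Uy,
                     double* Wz);
void rft_mobility_c(const ModelDesc& m, const RftCoeffs& c, const double* q,
                    const double* F, const double* Tz, double* Ux, double* Uy,
                    double* Wz);

#endif
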