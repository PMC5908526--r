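// Iterative radix-2 complex FFT (power-of-two sizes) with cached twiddle
// tables, plus 2D/3D wrappers used by the planar Stokes solver. Kept
// dependency-free; the pure-R route through stats::fft serves as the
// independent cross-check in the test suite.
#include <Rcpp.h>
#include <complex>
#include <vector>
#include <map>
#include <cmath>

typedef std::complex<double> cplx;

namespace spfft {

struct Plan {
  int n;
  std::vector<int> rev;
  std::vector<cplx> w_fwd, w_inv; // twiddles per stage, concatenated
};

static std::map<int, Plan>& plan_cache() {
  static std::map<int, Plan> cache;
  return cache;
}

static const Plan& get_plan(int n) {
  auto& cache = plan_cache();
  auto it = cache.find(n);
  if (it != cache.end()) return it->second;
  if (n <= 0 || (n & (n - 1)) != 0)
    Rcpp::stop("planar FFT requires power-of-two sizes (got %d)", n);
  Plan p;
  p.n = n;
  p.rev.resize(n);
  int lg = 0;
  while ((1 << lg) < n) ++lg;
  for (int i = 0; i < n; ++i) {
    int r = 0;
    for (int b = 0; b < lg; ++b) if (i & (1 << b)) r |= 1 << (lg - 1 - b);
    p.rev[i] = r;
  }
  // stage s has half-length len/2 twiddles, len = 2,4,...,n
  for (int len = 2; len <= n; len <<= 1) {
    double ang = -2.0 * M_PI / len;
    for (int j = 0; j < len / 2; ++j) {
      p.w_fwd.push_back(cplx(std::cos(ang * j), std::sin(ang * j)));
      p.w_inv.push_back(cplx(std::cos(-ang * j), std::sin(-ang * j)));
    }
  }
  cache[n] = std::move(p);
  return cache[n];
}

// in-place transform of contiguous array of length n; inverse is
// unnormalized (like stats::fft(inverse = TRUE)).
void fft1(cplx* a, int n, bool inverse) {
  const Plan& p = get_plan(n);
  for (int i = 0; i < n; ++i) {
    int r = p.rev[i];
    if (i < r) std::swap(a[i], a[r]);
  }
  const std::vector<cplx>& twv = inverse ? p.w_inv : p.w_fwd;
  // twiddle-free first stage
  for (int i = 0; i < n; i += 2) {
    cplx u = a[i], v = a[i + 1];
    a[i] = u + v;
    a[i + 1] = u - v;
  }
  size_t off = 1;
  for (int len = 4; len <= n; len <<= 1) {
    int half = len / 2;
    const cplx* tw = twv.data() + off;
    for (int i = 0; i < n; i += len) {
      cplx* lo = a + i;
      cplx* hi = a + i + half;
      for (int j = 0; j < half; ++j) {
        double tr = tw[j].real(), ti = tw[j].imag();
        double hr = hi[j].real(), hj = hi[j].imag();
        double vr = hr * tr - hj * ti;
        double vi = hr * ti + hj * tr;
        double ur = lo[j].real(), ui = lo[j].imag();
        lo[j] = cplx(ur + vr, ui + vi);
        hi[j] = cplx(ur - vr, ui - vi);
      }
    }
    off += half;
  }
}

// blocked out-of-place transpose (cache-friendly)
static void transpose(const cplx* src, cplx* dst, int nr, int nc) {
  const int B = 32;
  for (int jb = 0; jb < nc; jb += B)
    for (int ib = 0; ib < nr; ib += B) {
      int je = std::min(jb + B, nc), ie = std::min(ib + B, nr);
      for (int j = jb; j < je; ++j)
        for (int i = ib; i < ie; ++i)
          dst[(size_t)i * nc + j] = src[(size_t)j * nr + i];
    }
}

// 2D transform of column-major nx x ny array (R layout), in place.
void fft2(cplx* a, int nx, int ny, bool inverse) {
  // columns are contiguous in column-major: transform along x first
  for (int j = 0; j < ny; ++j) fft1(a + (size_t)j * nx, nx, inverse);
  // rows via transpose -> contiguous transforms -> transpose back
  std::vector<cplx> t((size_t)nx * ny);
  transpose(a, t.data(), nx, ny);
  for (int i = 0; i < nx; ++i) fft1(t.data() + (size_t)i * ny, ny, inverse);
  transpose(t.data(), a, ny, nx);
}

void fft3(cplx* a, int nx, int ny, int nz, bool inverse) {
  size_t plane = (size_t)nx * ny;
  for (int k = 0; k < nz; ++k) fft2(a + plane * k, nx, ny, inverse);
  std::vector<cplx> buf(nz);
  for (size_t ij = 0; ij < plane; ++ij) {
    for (int k = 0; k < nz; ++k) buf[k] = a[plane * k + ij];
    fft1(buf.data(), nz, inverse);
    for (int k = 0; k < nz; ++k) a[plane * k + ij] = buf[k];
  }
}

} // namespace spfft

// [[Rcpp::export(name = ".fft2_cpp")]]
Rcpp::ComplexMatrix fft2_cpp(Rcpp::ComplexMatrix z, bool inverse = false) {
  Rcpp::ComplexMatrix out = Rcpp::clone(z);
  spfft::fft2(reinterpret_cast<cplx*>(out.begin()), out.nrow(), out.ncol(),
              inverse);
  return out;
}

// [[Rcpp::export(name = ".fft3_cpp")]]
Rcpp::ComplexVector fft3_cpp(Rcpp::ComplexVector z, int nx, int ny, int nz,
                             bool inverse = false) {
  if ((size_t)z.size() != (size_t)nx * ny * nz)
    Rcpp::stop("length mismatch in fft3");
  Rcpp::ComplexVector out = Rcpp::clone(z);
  spfft::fft3(reinterpret_cast<cplx*>(out.begin()), nx, ny, nz, inverse);
  return out;
}
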