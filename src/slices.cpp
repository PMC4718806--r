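// Fourier-slice operators shared by the projector, the reconstructor, the
// signal subtractor and the EM classifier.  All Fourier arrays use the
// centered layout (DC at index M/2, 0-based) and column-major order, and
// sizes are even.  A slice sample for image frequency h = (h1, h2) is read
// from the padded 3D transform at position  center + pad * (h1 * R[1,] +
// h2 * R[2,])  (rows of the ZYZ rotation matrix), by trilinear
// interpolation.  Frequencies with |h| > rmax are excluded (zero), which
// keeps every sample strictly inside the padded cube.

#include <Rcpp.h>
#include <complex>
using namespace Rcpp;
typedef std::complex<double> cd;

static inline cd tri_sample(const cd *F, int M, double x, double y, double z) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  cd out(0.0, 0.0);
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        double w = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) *
                   (dz ? fz : 1.0 - fz);
        out += w * F[(size_t)(x0 + dx) + (size_t)M * (y0 + dy) +
                     (size_t)M * M * (z0 + dz)];
      }
  return out;
}

static inline void tri_spread(cd *num, double *den, int M, double x, double y,
                              double z, cd val, double wden) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        double w = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) *
                   (dz ? fz : 1.0 - fz);
        size_t idx = (size_t)(x0 + dx) + (size_t)M * (y0 + dy) +
                     (size_t)M * M * (z0 + dz);
        num[idx] += w * val;
        den[idx] += w * wden;
      }
}

// Extract CTF-affected, offset-shifted central slices for n particles.
// F: centered padded FT (length M^3); rot: 3x3xn; shifts: 2xn (pixels);
// ctf: N^2 x n matrix or R_NilValue.  Returns an N^2 x n complex matrix of
// image-space Fourier transforms (centered layout).
// [[Rcpp::export(name = "cf_project_slices")]]
ComplexMatrix cf_project_slices(ComplexVector F, int M, int N, int pad,
                                NumericVector rot, NumericMatrix shifts,
                                SEXP ctf, double rmax) {
  const cd *Fp = reinterpret_cast<const cd *>(COMPLEX(F));
  int n = shifts.ncol();
  ComplexMatrix out(N * N, n);
  cd *op = reinterpret_cast<cd *>(COMPLEX(out));
  const double *rp = REAL(rot);
  const double *cp = Rf_isNull(ctf) ? nullptr : REAL(ctf);
  double c0 = M / 2.0, r2max = rmax * rmax;
  double twopi = 2.0 * M_PI;
  for (int i = 0; i < n; ++i) {
    const double *R = rp + 9 * (size_t)i;
    double r1x = R[0], r1y = R[3], r1z = R[6]; // row 1
    double r2x = R[1], r2y = R[4], r2z = R[7]; // row 2
    double ox = shifts(0, i), oy = shifts(1, i);
    for (int j2 = 0; j2 < N; ++j2) {
      double h2 = j2 - N / 2.0;
      for (int j1 = 0; j1 < N; ++j1) {
        double h1 = j1 - N / 2.0;
        size_t oidx = (size_t)(j1 + N * j2) + (size_t)N * N * i;
        if (h1 * h1 + h2 * h2 > r2max) { op[oidx] = cd(0, 0); continue; }
        double kx = pad * (h1 * r1x + h2 * r2x);
        double ky = pad * (h1 * r1y + h2 * r2y);
        double kz = pad * (h1 * r1z + h2 * r2z);
        cd v = tri_sample(Fp, M, c0 + kx, c0 + ky, c0 + kz);
        double ph = -twopi * (h1 * ox + h2 * oy) / N;
        v *= cd(std::cos(ph), std::sin(ph));
        if (cp) v *= cp[(size_t)(j1 + N * j2) + (size_t)N * N * i];
        op[oidx] = v;
      }
    }
  }
  return out;
}

// Adjoint: spread weight * ctf * (phase-unshifted data) into the numerator
// grid and weight * ctf^2 into the denominator grid, for n particles.
// dataft: N^2 x n centered image FTs.  With friedel = true each sample is
// also inserted conjugated at the point-mirrored position, so the
// accumulated grid is (nearly) Hermitian.  Modifies num/den in place.
// [[Rcpp::export(name = "cf_backproject_many")]]
void cf_backproject_many(ComplexVector num, NumericVector den, int M, int N,
                         int pad, NumericVector rot, NumericMatrix shifts,
                         ComplexMatrix dataft, SEXP ctf,
                         NumericVector weights, double rmax, bool friedel) {
  cd *np = reinterpret_cast<cd *>(COMPLEX(num));
  double *dp = REAL(den);
  const cd *da = reinterpret_cast<const cd *>(COMPLEX(dataft));
  const double *rp = REAL(rot);
  const double *cp = Rf_isNull(ctf) ? nullptr : REAL(ctf);
  int n = shifts.ncol();
  double c0 = M / 2.0, r2max = rmax * rmax;
  double twopi = 2.0 * M_PI;
  for (int i = 0; i < n; ++i) {
    double w = weights[i];
    if (!R_finite(w)) stop("non-finite backprojection weight");
    if (w == 0.0) continue;
    const double *R = rp + 9 * (size_t)i;
    double r1x = R[0], r1y = R[3], r1z = R[6];
    double r2x = R[1], r2y = R[4], r2z = R[7];
    double ox = shifts(0, i), oy = shifts(1, i);
    for (int j2 = 0; j2 < N; ++j2) {
      double h2 = j2 - N / 2.0;
      for (int j1 = 0; j1 < N; ++j1) {
        double h1 = j1 - N / 2.0;
        if (h1 * h1 + h2 * h2 > r2max) continue;
        size_t didx = (size_t)(j1 + N * j2) + (size_t)N * N * i;
        double c = cp ? cp[didx] : 1.0;
        double ph = twopi * (h1 * ox + h2 * oy) / N; // undo the shift
        cd val = da[didx] * cd(std::cos(ph), std::sin(ph)) * (c * w);
        double wden = c * c * w;
        double kx = pad * (h1 * r1x + h2 * r2x);
        double ky = pad * (h1 * r1y + h2 * r2y);
        double kz = pad * (h1 * r1z + h2 * r2z);
        tri_spread(np, dp, M, c0 + kx, c0 + ky, c0 + kz, val, wden);
        if (friedel)
          tri_spread(np, dp, M, c0 - kx, c0 - ky, c0 - kz, std::conj(val),
                     wden);
      }
    }
  }
}

// One EM expectation pass: per-particle, per-class Gaussian log-likelihood
// terms  -0.5 * sum_f |D_i(f) - CTF_i(f) P_{r_i}(V_k)(f)|^2 / sigma2(s(f))
// plus the per-shell residual sums needed for the noise-spectrum update.
// Flist: K centered padded FTs; shell: N^2 integer shell indices (0-based,
// -1 = excluded); sigma2: per-shell variances.  Returns list(loglik = n x K,
// shell_res = S x K x n array of residual power sums).
// [[Rcpp::export(name = "cf_estep")]]
List cf_estep(List Flist, int M, int N, int pad, NumericVector rot,
              NumericMatrix shifts, ComplexMatrix dataft, NumericMatrix ctf,
              NumericVector sigma2, IntegerVector shell) {
  int K = Flist.size();
  int n = shifts.ncol();
  int S = sigma2.size();
  std::vector<const cd *> Fp(K);
  for (int k = 0; k < K; ++k) {
    ComplexVector F = Flist[k];
    Fp[k] = reinterpret_cast<const cd *>(COMPLEX(F));
  }
  const cd *da = reinterpret_cast<const cd *>(COMPLEX(dataft));
  const double *rp = REAL(rot);
  const double *cp = REAL(ctf);
  const int *sh = INTEGER(shell);
  NumericMatrix loglik(n, K);
  NumericVector shell_res(Dimension(S, K, n));
  double *srp = REAL(shell_res);
  double c0 = M / 2.0;
  double twopi = 2.0 * M_PI;
  std::vector<double> res(S * K);
  for (int i = 0; i < n; ++i) {
    const double *R = rp + 9 * (size_t)i;
    double r1x = R[0], r1y = R[3], r1z = R[6];
    double r2x = R[1], r2y = R[4], r2z = R[7];
    double ox = shifts(0, i), oy = shifts(1, i);
    std::fill(res.begin(), res.end(), 0.0);
    // the slice geometry (interpolation cell and weights) is shared by all
    // classes, so compute it once per frequency
    for (int j2 = 0; j2 < N; ++j2) {
      double h2 = j2 - N / 2.0;
      for (int j1 = 0; j1 < N; ++j1) {
        int s = sh[j1 + N * j2];
        if (s < 0) continue;
        double h1 = j1 - N / 2.0;
        size_t didx = (size_t)(j1 + N * j2) + (size_t)N * N * i;
        double x = c0 + pad * (h1 * r1x + h2 * r2x);
        double y = c0 + pad * (h1 * r1y + h2 * r2y);
        double z = c0 + pad * (h1 * r1z + h2 * r2z);
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
        double fx = x - x0, fy = y - y0, fz = z - z0;
        double w[8];
        size_t idx[8];
        int t = 0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx, ++t) {
              w[t] = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) *
                     (dz ? fz : 1.0 - fz);
              idx[t] = (size_t)(x0 + dx) + (size_t)M * (y0 + dy) +
                       (size_t)M * M * (z0 + dz);
            }
        double ph = -twopi * (h1 * ox + h2 * oy) / N;
        cd phase(std::cos(ph), std::sin(ph));
        double c = cp[didx];
        cd d = da[didx];
        for (int k = 0; k < K; ++k) {
          const cd *F = Fp[k];
          cd v(0.0, 0.0);
          for (int t2 = 0; t2 < 8; ++t2) v += w[t2] * F[idx[t2]];
          cd diff = d - v * phase * c;
          res[s + S * k] += std::norm(diff);
        }
      }
    }
    for (int k = 0; k < K; ++k) {
      double ll = 0.0;
      for (int s = 0; s < S; ++s) {
        ll -= 0.5 * res[s + S * k] / sigma2[s];
        srp[s + (size_t)S * k + (size_t)S * K * i] = res[s + S * k];
      }
      if (!R_finite(ll)) stop("non-finite log-likelihood for particle %d", i + 1);
      loglik(i, k) = ll;
    }
  }
  return List::create(_["loglik"] = loglik, _["shell_res"] = shell_res);
}
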