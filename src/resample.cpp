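#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Resample a 3D volume onto an output grid.
// M is a 4x4 matrix mapping 0-based output voxel indices to 0-based
// continuous input voxel coordinates. mode: 0 = trilinear, 1 = nearest.
// Out-of-field samples get `oob`.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector in_dim,
                                  NumericMatrix M, IntegerVector out_dim,
                                  int mode, double oob) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out(static_cast<R_xlen_t>(ox) * oy * oz);
  const double *v = vol.begin();
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t p = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      for (int i = 0; i < ox; ++i, ++p) {
        const double sx = m00*i + m01*j + m02*k + m03;
        const double sy = m10*i + m11*j + m12*k + m13;
        const double sz = m20*i + m21*j + m22*k + m23;
        if (mode == 1) {
          const int ri = (int) std::lround(sx);
          const int rj = (int) std::lround(sy);
          const int rk = (int) std::lround(sz);
          if (ri < 0 || rj < 0 || rk < 0 || ri >= nx || rj >= ny || rk >= nz) {
            out[p] = oob;
          } else {
            out[p] = v[ri + (R_xlen_t) nx * (rj + (R_xlen_t) ny * rk)];
          }
        } else {
          const double fx = std::floor(sx), fy = std::floor(sy), fz = std::floor(sz);
          const int i0 = (int) fx, j0 = (int) fy, k0 = (int) fz;
          if (i0 < -1 || j0 < -1 || k0 < -1 ||
              i0 >= nx || j0 >= ny || k0 >= nz) {
            out[p] = oob;
            continue;
          }
          const double wx = sx - fx, wy = sy - fy, wz = sz - fz;
          double acc = 0.0, wsum = 0.0;
          bool any_oob = false;
          for (int dk = 0; dk <= 1; ++dk) {
            const int kk = k0 + dk;
            const double wk = dk ? wz : 1.0 - wz;
            if (wk == 0.0) continue;
            for (int dj = 0; dj <= 1; ++dj) {
              const int jj = j0 + dj;
              const double wj = dj ? wy : 1.0 - wy;
              if (wj == 0.0) continue;
              for (int di = 0; di <= 1; ++di) {
                const int ii = i0 + di;
                const double wi = di ? wx : 1.0 - wx;
                if (wi == 0.0) continue;
                const double w = wi * wj * wk;
                if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) {
                  any_oob = true;
                } else {
                  acc += w * v[ii + (R_xlen_t) nx * (jj + (R_xlen_t) ny * kk)];
                  wsum += w;
                }
              }
            }
          }
          // a corner outside the field counts as `oob` mass
          if (any_oob) {
            if (ISNAN(oob)) { out[p] = oob; continue; }
            acc += (1.0 - wsum) * oob;
          }
          out[p] = acc;
        }
      }
    }
  }
  out.attr("dim") = out_dim;
  return out;
}
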