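// 3D convolution / pooling kernels used by the U-Net.
//
// Layout conventions (column-major, as R stores arrays):
//   volumes:  dim = (nx, ny, nz, channels)
//   weights:  dim = (k, k, k, c_in, c_out), k odd, "same" zero padding
//
// Convolutions are evaluated slab-by-slab (one output z-plane at a time)
// via im2col + BLAS dgemm: the weight array in its natural layout is the
// (k^3 c_in) x c_out matrix, and the column matrix holds the k^3 c_in
// shifted input values for each (x, y) of the plane.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Fill the im2col matrix for output plane z. col is (k^3 * cin) x (nx*ny),
// column-major with rows ordered (dx fastest, dy, dz, ci) to match the
// natural weight layout.
static void im2col_plane(const double *in, int nx, int ny, int nz, int cin,
                         int k, int z, std::vector<double> &col) {
  const int off = k / 2;
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  const R_xlen_t chan = plane * nz;
  const int rows = k * k * k * cin;
  std::fill(col.begin(), col.end(), 0.0);
  for (int ci = 0; ci < cin; ++ci) {
    const double *icv = in + chan * ci;
    for (int dz = 0; dz < k; ++dz) {
      const int zz = z + dz - off;
      if (zz < 0 || zz >= nz) continue;
      for (int dy = 0; dy < k; ++dy) {
        const int sy = dy - off;
        const int y0 = sy < 0 ? -sy : 0, y1 = sy > 0 ? ny - sy : ny;
        for (int dx = 0; dx < k; ++dx) {
          const int sx = dx - off;
          const int x0 = sx < 0 ? -sx : 0, x1 = sx > 0 ? nx - sx : nx;
          const int row = dx + k * (dy + k * (dz + k * ci));
          const double *src = icv + (R_xlen_t)zz * plane;
          for (int y = y0; y < y1; ++y) {
            double *dst = col.data() + (R_xlen_t)(y * nx) * rows + row;
            const double *s = src + (R_xlen_t)(y + sy) * nx + sx;
            for (int x = x0; x < x1; ++x) dst[(R_xlen_t)x * rows] = s[x];
          }
        }
      }
    }
  }
}

// Adjoint of im2col_plane: scatter-add col back into the input gradient.
static void col2im_plane(double *gin, int nx, int ny, int nz, int cin,
                         int k, int z, const std::vector<double> &col) {
  const int off = k / 2;
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  const R_xlen_t chan = plane * nz;
  const int rows = k * k * k * cin;
  for (int ci = 0; ci < cin; ++ci) {
    double *icv = gin + chan * ci;
    for (int dz = 0; dz < k; ++dz) {
      const int zz = z + dz - off;
      if (zz < 0 || zz >= nz) continue;
      for (int dy = 0; dy < k; ++dy) {
        const int sy = dy - off;
        const int y0 = sy < 0 ? -sy : 0, y1 = sy > 0 ? ny - sy : ny;
        for (int dx = 0; dx < k; ++dx) {
          const int sx = dx - off;
          const int x0 = sx < 0 ? -sx : 0, x1 = sx > 0 ? nx - sx : nx;
          const int row = dx + k * (dy + k * (dz + k * ci));
          double *dstp = icv + (R_xlen_t)zz * plane;
          for (int y = y0; y < y1; ++y) {
            const double *s = col.data() + (R_xlen_t)(y * nx) * rows + row;
            double *dst = dstp + (R_xlen_t)(y + sy) * nx + sx;
            for (int x = x0; x < x1; ++x) dst[x] += s[(R_xlen_t)x * rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector vol, IntegerVector vdim,
                         NumericVector W, NumericVector b,
                         int k, int cin, int cout) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  const R_xlen_t chan = plane * nz;
  const int rows = k * k * k * cin;
  NumericVector out((R_xlen_t)chan * cout);
  std::vector<double> col((R_xlen_t)rows * plane);
  std::vector<double> oplane(plane * (R_xlen_t)cout);
  const double one = 1.0, zero = 0.0;
  const int m = (int)plane;
  for (int z = 0; z < nz; ++z) {
    im2col_plane(vol.begin(), nx, ny, nz, cin, k, z, col);
    // oplane (plane x cout) = col^T (plane x rows) * W (rows x cout)
    F77_CALL(dgemm)("T", "N", &m, &cout, &rows, &one, col.data(), &rows,
                    W.begin(), &rows, &zero, oplane.data(), &m
                    FCONE FCONE);
    for (int co = 0; co < cout; ++co) {
      double *dst = out.begin() + chan * co + (R_xlen_t)z * plane;
      const double *s = oplane.data() + (R_xlen_t)co * plane;
      const double bc = b[co];
      for (R_xlen_t i = 0; i < plane; ++i) dst[i] = s[i] + bc;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector conv3d_grad_input(NumericVector gout, IntegerVector vdim,
                                NumericVector W, int k, int cin, int cout) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  const R_xlen_t chan = plane * nz;
  const int rows = k * k * k * cin;
  NumericVector gin((R_xlen_t)chan * cin);
  std::vector<double> col((R_xlen_t)rows * plane);
  std::vector<double> gplane(plane * (R_xlen_t)cout);
  const double one = 1.0, zero = 0.0;
  const int m = (int)plane;
  for (int z = 0; z < nz; ++z) {
    for (int co = 0; co < cout; ++co) {
      const double *s = gout.begin() + chan * co + (R_xlen_t)z * plane;
      double *dst = gplane.data() + (R_xlen_t)co * plane;
      std::copy(s, s + plane, dst);
    }
    // col (rows x plane) = W (rows x cout) * gplane^T (cout x plane)
    F77_CALL(dgemm)("N", "T", &rows, &m, &cout, &one, W.begin(), &rows,
                    gplane.data(), &m, &zero, col.data(), &rows
                    FCONE FCONE);
    col2im_plane(gin.begin(), nx, ny, nz, cin, k, z, col);
  }
  return gin;
}

// [[Rcpp::export]]
List conv3d_grad_weights(NumericVector vol, NumericVector gout,
                         IntegerVector vdim, int k, int cin, int cout) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  const R_xlen_t chan = plane * nz;
  const int rows = k * k * k * cin;
  NumericVector gW((R_xlen_t)rows * cout);
  NumericVector gb(cout);
  std::vector<double> col((R_xlen_t)rows * plane);
  std::vector<double> gplane(plane * (R_xlen_t)cout);
  const double one = 1.0;
  const int m = (int)plane;
  for (int z = 0; z < nz; ++z) {
    im2col_plane(vol.begin(), nx, ny, nz, cin, k, z, col);
    for (int co = 0; co < cout; ++co) {
      const double *s = gout.begin() + chan * co + (R_xlen_t)z * plane;
      double *dst = gplane.data() + (R_xlen_t)co * plane;
      std::copy(s, s + plane, dst);
      double acc = 0.0;
      for (R_xlen_t i = 0; i < plane; ++i) acc += s[i];
      gb[co] += acc;
    }
    // gW (rows x cout) += col (rows x plane) * gplane (plane x cout)
    F77_CALL(dgemm)("N", "N", &rows, &cout, &m, &one, col.data(), &rows,
                    gplane.data(), &m, &one, gW.begin(), &rows
                    FCONE FCONE);
  }
  return List::create(_["gW"] = gW, _["gb"] = gb);
}

// 2x2x2 max pooling with stride 2 (even input dims required upstream).
// Returns pooled values and 0-based argmax linear indices into the input.
// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector vol, IntegerVector vdim, int nc) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const R_xlen_t ichan = (R_xlen_t)nx * ny * nz;
  const R_xlen_t ochan = (R_xlen_t)ox * oy * oz;
  NumericVector out(ochan * nc);
  IntegerVector arg(ochan * nc);
  const double *pin = vol.begin();

  for (int c = 0; c < nc; ++c) {
    const R_xlen_t ibase = ichan * c;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int x = 0; x < ox; ++x) {
          double best = R_NegInf;
          R_xlen_t bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                R_xlen_t ii = ibase +
                  (R_xlen_t)(2 * z + dz) * nx * ny +
                  (R_xlen_t)(2 * y + dy) * nx + (2 * x + dx);
                if (pin[ii] > best) { best = pin[ii]; bidx = ii; }
              }
          R_xlen_t oo = ochan * c + (R_xlen_t)z * ox * oy +
                        (R_xlen_t)y * ox + x;
          out[oo] = best;
          arg[oo] = (int)bidx;
        }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector gout, IntegerVector argmax,
                            double input_len) {
  NumericVector gin((R_xlen_t)input_len);
  const double *pg = gout.begin();
  const int *pa = argmax.begin();
  double *pi = gin.begin();
  for (R_xlen_t i = 0; i < gout.size(); ++i) pi[pa[i]] += pg[i];
  return gin;
}
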