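// Minimal 3D convolutional-network primitives (forward + gradients) used
// by the dose-prediction U-net.  Tensors are column-major arrays laid out
// as [x, y, z, channel, sample]; weights as [kx, ky, kz, c_in, c_out].
// Convolutions use odd kernels with "same" zero padding; the transposed
// convolution uses a 2x2x2 kernel with stride 2 (non-overlapping), which
// exactly doubles each spatial dimension.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

struct Dims5 {
  int nx, ny, nz, nc, nn;
  long long sp() const { return (long long)nx * ny * nz; }
  long long per_sample() const { return sp() * nc; }
};

static Dims5 dims5(IntegerVector d) {
  Dims5 r; r.nx = d[0]; r.ny = d[1]; r.nz = d[2]; r.nc = d[3]; r.nn = d[4];
  return r;
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector input, IntegerVector din,
                         NumericVector weight, IntegerVector dw,
                         NumericVector bias) {
  Dims5 di = dims5(din);
  int K = dw[0], cin = dw[3], cout = dw[4];
  int C = K / 2;
  NumericVector out((R_xlen_t)(di.sp() * cout * di.nn));
  double *o = REAL(out);
  const double *in = REAL(input), *W = REAL(weight), *B = REAL(bias);
  long long sp = di.sp();
  // init bias
  for (int n = 0; n < di.nn; ++n)
    for (int co = 0; co < cout; ++co) {
      double b = B[co];
      double *op = o + sp * (co + (long long)cout * n);
      for (long long s = 0; s < sp; ++s) op[s] = b;
    }
  for (int n = 0; n < di.nn; ++n)
    for (int co = 0; co < cout; ++co) {
      double *obase = o + sp * (co + (long long)cout * n);
      for (int ci = 0; ci < cin; ++ci) {
        const double *ibase = in + sp * (ci + (long long)cin * n);
        for (int kz = 0; kz < K; ++kz) {
          int oz = kz - C;
          for (int ky = 0; ky < K; ++ky) {
            int oy = ky - C;
            for (int kx = 0; kx < K; ++kx) {
              int ox = kx - C;
              double w = W[kx + K * (ky + K * (kz + K *
                          (ci + (long long)cin * co)))];
              if (w == 0.0) continue;
              int x0 = std::max(0, -ox), x1 = di.nx - std::max(0, ox);
              int y0 = std::max(0, -oy), y1 = di.ny - std::max(0, oy);
              int z0 = std::max(0, -oz), z1 = di.nz - std::max(0, oz);
              for (int z = z0; z < z1; ++z)
                for (int y = y0; y < y1; ++y) {
                  double *op = obase + di.nx * (y + (long long)di.ny * z);
                  const double *ip = ibase + ox +
                    di.nx * ((y + oy) + (long long)di.ny * (z + oz));
                  for (int x = x0; x < x1; ++x) op[x] += w * ip[x];
                }
            }
          }
        }
      }
    }
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector input, IntegerVector din,
                NumericVector weight, IntegerVector dw,
                NumericVector gout) {
  Dims5 di = dims5(din);
  int K = dw[0], cin = dw[3], cout = dw[4];
  int C = K / 2;
  long long sp = di.sp();
  NumericVector gin((R_xlen_t)(sp * cin * di.nn));
  NumericVector gW((R_xlen_t)weight.size());
  NumericVector gB(cout);
  double *gi = REAL(gin), *gw = REAL(gW), *gb = REAL(gB);
  const double *in = REAL(input), *W = REAL(weight), *go = REAL(gout);
  for (int n = 0; n < di.nn; ++n)
    for (int co = 0; co < cout; ++co) {
      const double *gobase = go + sp * (co + (long long)cout * n);
      // bias gradient
      double acc = 0.0;
      for (long long s = 0; s < sp; ++s) acc += gobase[s];
      gb[co] += acc;
      for (int ci = 0; ci < cin; ++ci) {
        const double *ibase = in + sp * (ci + (long long)cin * n);
        double *gibase = gi + sp * (ci + (long long)cin * n);
        for (int kz = 0; kz < K; ++kz) {
          int oz = kz - C;
          for (int ky = 0; ky < K; ++ky) {
            int oy = ky - C;
            for (int kx = 0; kx < K; ++kx) {
              int ox = kx - C;
              long long wi = kx + K * (ky + K * (kz + K *
                             (ci + (long long)cin * co)));
              double w = W[wi];
              double wacc = 0.0;
              int x0 = std::max(0, -ox), x1 = di.nx - std::max(0, ox);
              int y0 = std::max(0, -oy), y1 = di.ny - std::max(0, oy);
              int z0 = std::max(0, -oz), z1 = di.nz - std::max(0, oz);
              for (int z = z0; z < z1; ++z)
                for (int y = y0; y < y1; ++y) {
                  const double *gop = gobase +
                    di.nx * (y + (long long)di.ny * z);
                  const double *ip = ibase + ox +
                    di.nx * ((y + oy) + (long long)di.ny * (z + oz));
                  double *gip = gibase + ox +
                    di.nx * ((y + oy) + (long long)di.ny * (z + oz));
                  for (int x = x0; x < x1; ++x) {
                    wacc += ip[x] * gop[x];
                    gip[x] += w * gop[x];
                  }
                }
              gw[wi] += wacc;
            }
          }
        }
      }
    }
  return List::create(_["gin"] = gin, _["gw"] = gW, _["gb"] = gB);
}

// [[Rcpp::export(name = ".maxpool3d_fwd")]]
List maxpool3d_fwd(NumericVector input, IntegerVector din) {
  Dims5 di = dims5(din);
  int ox = di.nx / 2, oy = di.ny / 2, oz = di.nz / 2;
  long long osp = (long long)ox * oy * oz;
  NumericVector out((R_xlen_t)(osp * di.nc * di.nn));
  IntegerVector arg((R_xlen_t)(osp * di.nc * di.nn));
  const double *in = REAL(input);
  double *o = REAL(out);
  int *a = INTEGER(arg);
  long long isp = di.sp();
  long long p = 0;
  for (int n = 0; n < di.nn; ++n)
    for (int c = 0; c < di.nc; ++c) {
      const double *ib = in + isp * (c + (long long)di.nc * n);
      for (int z = 0; z < oz; ++z)
        for (int y = 0; y < oy; ++y)
          for (int x = 0; x < ox; ++x, ++p) {
            double best = -1e300; long long bi = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  long long ii = (2 * x + dx) +
                    (long long)di.nx * ((2 * y + dy) +
                    (long long)di.ny * (2 * z + dz));
                  if (ib[ii] > best) { best = ib[ii]; bi = ii; }
                }
            o[p] = best;
            a[p] = (int)bi;   // index within the [x,y,z] block of (c,n)
          }
    }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3d_bwd")]]
NumericVector maxpool3d_bwd(NumericVector gout, IntegerVector arg,
                            IntegerVector din) {
  Dims5 di = dims5(din);
  NumericVector gin((R_xlen_t)(di.sp() * di.nc * di.nn));
  double *gi = REAL(gin);
  const double *go = REAL(gout);
  const int *a = INTEGER(arg);
  long long osp = (long long)(di.nx / 2) * (di.ny / 2) * (di.nz / 2);
  long long isp = di.sp();
  long long p = 0;
  for (int n = 0; n < di.nn; ++n)
    for (int c = 0; c < di.nc; ++c) {
      double *gib = gi + isp * (c + (long long)di.nc * n);
      for (long long s = 0; s < osp; ++s, ++p) gib[a[p]] += go[p];
    }
  return gin;
}

// Transposed convolution, kernel 2x2x2, stride 2 (exactly doubles dims).
// weight layout [2,2,2,c_in,c_out].
// [[Rcpp::export(name = ".deconv3d_fwd")]]
NumericVector deconv3d_fwd(NumericVector input, IntegerVector din,
                           NumericVector weight, NumericVector bias,
                           int cout) {
  Dims5 di = dims5(din);
  int cin = di.nc;
  int ox = 2 * di.nx, oy = 2 * di.ny, oz = 2 * di.nz;
  long long osp = (long long)ox * oy * oz;
  NumericVector out((R_xlen_t)(osp * cout * di.nn));
  double *o = REAL(out);
  const double *in = REAL(input), *W = REAL(weight), *B = REAL(bias);
  long long isp = di.sp();
  for (int n = 0; n < di.nn; ++n)
    for (int co = 0; co < cout; ++co) {
      double *ob = o + osp * (co + (long long)cout * n);
      for (long long s = 0; s < osp; ++s) ob[s] = B[co];
      for (int ci = 0; ci < cin; ++ci) {
        const double *ib = in + isp * (ci + (long long)cin * n);
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              double w = W[dx + 2 * (dy + 2 * (dz + 2 *
                          (ci + (long long)cin * co)))];
              for (int z = 0; z < di.nz; ++z)
                for (int y = 0; y < di.ny; ++y) {
                  const double *ip = ib + di.nx * (y + (long long)di.ny * z);
                  double *op = ob + (2LL * 0 + dx) +
                    (long long)ox * ((2 * y + dy) +
                    (long long)oy * (2 * z + dz));
                  for (int x = 0; x < di.nx; ++x)
                    op[2 * x] += w * ip[x];
                }
            }
      }
    }
  return out;
}

// [[Rcpp::export(name = ".deconv3d_bwd")]]
List deconv3d_bwd(NumericVector input, IntegerVector din,
                  NumericVector weight, int cout, NumericVector gout) {
  Dims5 di = dims5(din);
  int cin = di.nc;
  int ox = 2 * di.nx, oy = 2 * di.ny, oz = 2 * di.nz;
  long long osp = (long long)ox * oy * oz;
  long long isp = di.sp();
  NumericVector gin((R_xlen_t)(isp * cin * di.nn));
  NumericVector gW((R_xlen_t)weight.size());
  NumericVector gB(cout);
  double *gi = REAL(gin), *gw = REAL(gW), *gb = REAL(gB);
  const double *in = REAL(input), *W = REAL(weight), *go = REAL(gout);
  for (int n = 0; n < di.nn; ++n)
    for (int co = 0; co < cout; ++co) {
      const double *gob = go + osp * (co + (long long)cout * n);
      double acc = 0.0;
      for (long long s = 0; s < osp; ++s) acc += gob[s];
      gb[co] += acc;
      for (int ci = 0; ci < cin; ++ci) {
        const double *ib = in + isp * (ci + (long long)cin * n);
        double *gib = gi + isp * (ci + (long long)cin * n);
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              long long wi = dx + 2 * (dy + 2 * (dz + 2 *
                             (ci + (long long)cin * co)));
              double w = W[wi];
              double wacc = 0.0;
              for (int z = 0; z < di.nz; ++z)
                for (int y = 0; y < di.ny; ++y) {
                  const double *ip = ib + di.nx * (y + (long long)di.ny * z);
                  double *gip = gib + di.nx * (y + (long long)di.ny * z);
                  const double *gop = gob + dx +
                    (long long)ox * ((2 * y + dy) +
                    (long long)oy * (2 * z + dz));
                  for (int x = 0; x < di.nx; ++x) {
                    wacc += ip[x] * gop[2 * x];
                    gip[x] += w * gop[2 * x];
                  }
                }
              gw[wi] += wacc;
            }
      }
    }
  return List::create(_["gin"] = gin, _["gw"] = gW, _["gb"] = gB);
}
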