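#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>

using namespace Rcpp;

// Trilinear interpolation of `vol` (dims dv) at the tensor grid given by
// 1-based continuous coordinates xs, ys, zs; clamped at the edges.
// [[Rcpp::export(name = "trilinear_resample")]]
NumericVector trilinear_resample(NumericVector vol, IntegerVector dv,
                                 NumericVector xs, NumericVector ys,
                                 NumericVector zs) {
  int nx = dv[0], ny = dv[1], nz = dv[2];
  int ox = xs.size(), oy = ys.size(), oz = zs.size();
  NumericVector out(ox * oy * oz);
  const double *v = REAL(vol);
  auto at = [&](int i, int j, int k) {
    return v[i + nx * (j + ny * k)];
  };
  std::vector<int> ix0(ox), iy0(oy), iz0(oz);
  std::vector<double> fx(ox), fy(oy), fz(oz);
  auto prep = [](NumericVector c, int n, std::vector<int> &i0,
                 std::vector<double> &f, int len) {
    for (int i = 0; i < len; ++i) {
      double x = c[i] - 1.0;           // 0-based
      if (x < 0) x = 0;
      if (x > n - 1) x = n - 1;
      int a = (int)std::floor(x);
      if (a > n - 2) a = n - 2;
      if (a < 0) a = 0;
      i0[i] = a;
      f[i] = n == 1 ? 0.0 : x - a;
    }
  };
  prep(xs, nx, ix0, fx, ox);
  prep(ys, ny, iy0, fy, oy);
  prep(zs, nz, iz0, fz, oz);
  int p = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++p) {
        int a = ix0[i], b = iy0[j], c = iz0[k];
        double tx = fx[i], ty = fy[j], tz = fz[k];
        int a1 = std::min(a + 1, nx - 1), b1 = std::min(b + 1, ny - 1),
          c1 = std::min(c + 1, nz - 1);
        double v00 = at(a, b, c) * (1 - tx) + at(a1, b, c) * tx;
        double v10 = at(a, b1, c) * (1 - tx) + at(a1, b1, c) * tx;
        double v01 = at(a, b, c1) * (1 - tx) + at(a1, b, c1) * tx;
        double v11 = at(a, b1, c1) * (1 - tx) + at(a1, b1, c1) * tx;
        double v0 = v00 * (1 - ty) + v10 * ty;
        double v1 = v01 * (1 - ty) + v11 * ty;
        out[p] = v0 * (1 - tz) + v1 * tz;
      }
  return out;
}

// Direct (spatial-domain) 3D convolution with an odd-sized centred kernel
// and zero padding: out[j] = sum_i in[i] * ker[j - i + c].
// [[Rcpp::export(name = ".conv3d_direct")]]
NumericVector conv3d_direct(NumericVector input, IntegerVector di,
                            NumericVector kernel, IntegerVector dk) {
  int nx = di[0], ny = di[1], nz = di[2];
  int kx = dk[0], ky = dk[1], kz = dk[2];
  int cx = kx / 2, cy = ky / 2, cz = kz / 2;
  NumericVector out(nx * ny * nz);
  const double *in = REAL(input), *ker = REAL(kernel);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int c = 0; c < kz; ++c) {
          int sz = k - (c - cz);
          if (sz < 0 || sz >= nz) continue;
          for (int b = 0; b < ky; ++b) {
            int sy = j - (b - cy);
            if (sy < 0 || sy >= ny) continue;
            const double *inp = in + nx * (sy + ny * sz);
            const double *kp = ker + kx * (b + ky * c);
            for (int a = 0; a < kx; ++a) {
              int sx = i - (a - cx);
              if (sx < 0 || sx >= nx) continue;
              acc += inp[sx] * kp[a];
            }
          }
        }
        out[i + nx * (j + ny * k)] = acc;
      }
  return out;
}

// 6-connected component labelling of a logical mask; labels 1..n in
// first-encounter order, 0 outside the mask.
// [[Rcpp::export(name = ".label_components6")]]
IntegerVector label_components6(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        int w = ii + nx * (jj + ny * kk);
        if (mask[w] && lab[w] == 0) { lab[w] = next; q.push(w); }
      }
    }
  }
  return lab;
}
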