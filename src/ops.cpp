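#include <Rcpp.h>
#include <array>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Volumes are stored as R arrays with dim (z, y, x); the linear index of
// voxel (z, y, x) (0-based) is z + Z*y + Z*Y*x.  Multi-channel tensors are
// matrices with one column per channel in that same voxel order.

static inline int lin(int z, int y, int x, int Z, int Y) {
  return z + Z * (y + Y * x);
}

// Offsets for 6- / 18- / 26-connectivity neighbourhoods.
static std::vector<std::array<int, 3>> neighbourhood(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

// im2col for a 3x3x3 kernel with zero padding 1 ("same" convolution).
// Input: (nvox x in_ch) matrix; output: (nvox x in_ch*27) with column
// ic*27 + k, where k runs over kernel offsets in (dz, dy, dx) row-major
// order dz slowest.
// [[Rcpp::export]]
NumericMatrix cpp_im2col3(const NumericMatrix& x, const IntegerVector& dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int nvox = Z * Y * X, in_ch = x.ncol();
  NumericMatrix out(nvox, in_ch * 27);
  for (int ic = 0; ic < in_ch; ++ic) {
    const double* xc = &x(0, ic);
    int k = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx, ++k) {
          double* oc = &out(0, ic * 27 + k);
          for (int xx = 0; xx < X; ++xx) {
            int sx = xx + dx;
            if (sx < 0 || sx >= X) continue;
            for (int yy = 0; yy < Y; ++yy) {
              int sy = yy + dy;
              if (sy < 0 || sy >= Y) continue;
              int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
              const double* src = xc + lin(z0 + dz, sy, sx, Z, Y);
              double* dst = oc + lin(z0, yy, xx, Z, Y);
              for (int zz = z0; zz < z1; ++zz) *dst++ = *src++;
            }
          }
        }
  }
  return out;
}

// Adjoint of cpp_im2col3: scatter-add columns back into (nvox x in_ch).
// [[Rcpp::export]]
NumericMatrix cpp_col2im3(const NumericMatrix& cols, const IntegerVector& dims,
                          int in_ch) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int nvox = Z * Y * X;
  NumericMatrix out(nvox, in_ch);
  for (int ic = 0; ic < in_ch; ++ic) {
    double* oc = &out(0, ic);
    int k = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx, ++k) {
          const double* cc = &cols(0, ic * 27 + k);
          for (int xx = 0; xx < X; ++xx) {
            int sx = xx + dx;
            if (sx < 0 || sx >= X) continue;
            for (int yy = 0; yy < Y; ++yy) {
              int sy = yy + dy;
              if (sy < 0 || sy >= Y) continue;
              int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
              double* dst = oc + lin(z0 + dz, sy, sx, Z, Y);
              const double* src = cc + lin(z0, yy, xx, Z, Y);
              for (int zz = z0; zz < z1; ++zz) *dst++ += *src++;
            }
          }
        }
  }
  return out;
}

// Fused direct "same" 3x3x3 convolution (+ optional ReLU), tiled over
// (y, x) columns so the z-contiguous inner loops stay in cache.  Weight
// layout matches cpp_im2col3: row ic*27 + k with k over (dz, dy, dx)
// offsets, dz slowest; the im2col + GEMM route serves as the independent
// reference for these kernels.
// [[Rcpp::export]]
NumericMatrix cpp_conv3_fwd(const NumericMatrix& x, const IntegerVector& dims,
                            const NumericMatrix& W, const NumericVector& b,
                            bool relu) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int nvox = Z * Y * X, inC = x.ncol(), outC = W.ncol();
  NumericMatrix y(nvox, outC);
  std::vector<double> buf(Z * outC);
  for (int xx = 0; xx < X; ++xx) {
    for (int yy = 0; yy < Y; ++yy) {
      for (int oc = 0; oc < outC; ++oc)
        std::fill(buf.begin() + oc * Z, buf.begin() + (oc + 1) * Z, b[oc]);
      int k = 0;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx, ++k) {
            int sx = xx + dx, sy = yy + dy;
            if (sx < 0 || sx >= X || sy < 0 || sy >= Y) continue;
            int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
            int n = z1 - z0;
            for (int ic = 0; ic < inC; ++ic) {
              const double* src = &x(lin(z0 + dz, sy, sx, Z, Y), ic);
              const double* wr = &W(ic * 27 + k, 0);
              const int ldw = W.nrow();
              for (int oc = 0; oc < outC; ++oc) {
                double w = wr[oc * ldw];
                if (w == 0.0) continue;
                double* bo = buf.data() + oc * Z + z0;
                for (int i = 0; i < n; ++i) bo[i] += w * src[i];
              }
            }
          }
      for (int oc = 0; oc < outC; ++oc) {
        double* dst = &y(lin(0, yy, xx, Z, Y), oc);
        const double* bo = buf.data() + oc * Z;
        if (relu)
          for (int i = 0; i < Z; ++i) dst[i] = bo[i] > 0.0 ? bo[i] : 0.0;
        else
          for (int i = 0; i < Z; ++i) dst[i] = bo[i];
      }
    }
  }
  return y;
}

// Backward of the fused convolution: given the layer input x, its (post
// ReLU) output y and the incoming gradient dY, produces dW, db and dX.
// [[Rcpp::export]]
List cpp_conv3_bwd(const NumericMatrix& x, const IntegerVector& dims,
                   const NumericMatrix& W, const NumericMatrix& y,
                   const NumericMatrix& dY, bool relu) {
  const int Z = dims[0], Yd = dims[1], X = dims[2];
  const int nvox = Z * Yd * X, inC = x.ncol(), outC = W.ncol();
  NumericMatrix dW(W.nrow(), outC), dX(nvox, inC);
  NumericVector db(outC);
  std::vector<double> dpre(Z * outC);
  const int ldw = W.nrow();
  for (int xx = 0; xx < X; ++xx) {
    for (int yy = 0; yy < Yd; ++yy) {
      int base = lin(0, yy, xx, Z, Yd);
      for (int oc = 0; oc < outC; ++oc) {
        const double* dyc = &dY(base, oc);
        double* dp = dpre.data() + oc * Z;
        double acc = 0.0;
        if (relu) {
          const double* yc = &y(base, oc);
          for (int i = 0; i < Z; ++i) {
            dp[i] = yc[i] > 0.0 ? dyc[i] : 0.0;
            acc += dp[i];
          }
        } else {
          for (int i = 0; i < Z; ++i) { dp[i] = dyc[i]; acc += dp[i]; }
        }
        db[oc] += acc;
      }
      int k = 0;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx, ++k) {
            int sx = xx + dx, sy = yy + dy;
            if (sx < 0 || sx >= X || sy < 0 || sy >= Yd) continue;
            int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
            int n = z1 - z0;
            for (int ic = 0; ic < inC; ++ic) {
              int src_off = lin(z0 + dz, sy, sx, Z, Yd);
              const double* src = &x(src_off, ic);
              double* dxc = &dX(src_off, ic);
              const double* wr = &W(ic * 27 + k, 0);
              double* dwr = &dW(ic * 27 + k, 0);
              for (int oc = 0; oc < outC; ++oc) {
                double w = wr[oc * ldw];
                const double* dp = dpre.data() + oc * Z + z0;
                double dwacc = 0.0;
                for (int i = 0; i < n; ++i) {
                  dxc[i] += w * dp[i];
                  dwacc += src[i] * dp[i];
                }
                dwr[oc * ldw] += dwacc;
              }
            }
          }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// 2x2x2 max pooling; all dims must be even.  Returns the pooled tensor and
// the 1-based linear index of each maximum for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool3_fwd(const NumericMatrix& x, const IntegerVector& dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2], C = x.ncol();
  const int Zo = Z / 2, Yo = Y / 2, Xo = X / 2, nvo = Zo * Yo * Xo;
  NumericMatrix y(nvo, C);
  IntegerMatrix idx(nvo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int xo = 0; xo < Xo; ++xo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int zo = 0; zo < Zo; ++zo) {
          double best = R_NegInf; int bi = -1;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy)
              for (int dz = 0; dz < 2; ++dz) {
                int i = lin(2 * zo + dz, 2 * yo + dy, 2 * xo + dx, Z, Y);
                if (xc[i] > best) { best = xc[i]; bi = i; }
              }
          int o = lin(zo, yo, xo, Zo, Yo);
          y(o, c) = best;
          idx(o, c) = bi + 1;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool3_bwd(const NumericMatrix& dy, const IntegerMatrix& idx,
                               int nvox) {
  const int C = dy.ncol();
  NumericMatrix dx(nvox, C);
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < dy.nrow(); ++i)
      dx(idx(i, c) - 1, c) += dy(i, c);
  return dx;
}

// Nearest-neighbour 2x upsampling, (Z,Y,X) -> (2Z,2Y,2X).
// [[Rcpp::export]]
NumericMatrix cpp_upsample3_fwd(const NumericMatrix& x, const IntegerVector& dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2], C = x.ncol();
  const int Zo = 2 * Z, Yo = 2 * Y, Xo = 2 * X;
  NumericMatrix y(Zo * Yo * Xo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double* yc = &y(0, c);
    for (int xo = 0; xo < Xo; ++xo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int zo = 0; zo < Zo; ++zo)
          yc[lin(zo, yo, xo, Zo, Yo)] = xc[lin(zo / 2, yo / 2, xo / 2, Z, Y)];
  }
  return y;
}

// Adjoint of nearest upsampling: sum over each 2x2x2 block.
// [[Rcpp::export]]
NumericMatrix cpp_upsample3_bwd(const NumericMatrix& dy, const IntegerVector& out_dims) {
  const int Zo = out_dims[0], Yo = out_dims[1], Xo = out_dims[2], C = dy.ncol();
  const int Z = Zo / 2, Y = Yo / 2, X = Xo / 2;
  NumericMatrix dx(Z * Y * X, C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = &dy(0, c);
    double* dxc = &dx(0, c);
    for (int xo = 0; xo < Xo; ++xo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int zo = 0; zo < Zo; ++zo)
          dxc[lin(zo / 2, yo / 2, xo / 2, Z, Y)] += dyc[lin(zo, yo, xo, Zo, Yo)];
  }
  return dx;
}

// Connected-component labelling of a binary mask by breadth-first search.
// Components are numbered 1..k in order of discovery (raster order of seed).
// [[Rcpp::export]]
IntegerVector cpp_cc_label(const LogicalVector& mask, const IntegerVector& dims,
                           int connectivity) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int nvox = Z * Y * X;
  IntegerVector lab(nvox);
  std::vector<std::array<int, 3>> off = neighbourhood(connectivity);
  int next = 0;
  std::queue<int> q;
  for (int i = 0; i < nvox; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int z = v % Z, y = (v / Z) % Y, x = v / (Z * Y);
      for (const auto& o : off) {
        int nz = z + o[0], ny = y + o[1], nx = x + o[2];
        if (nz < 0 || nz >= Z || ny < 0 || ny >= Y || nx < 0 || nx >= X) continue;
        int ni = lin(nz, ny, nx, Z, Y);
        if (mask[ni] && !lab[ni]) { lab[ni] = next; q.push(ni); }
      }
    }
  }
  return lab;
}

// Binary dilation: a voxel is set if it or any neighbour is set.
// [[Rcpp::export]]
LogicalVector cpp_binary_dilate(const LogicalVector& mask, const IntegerVector& dims,
                                int connectivity, int iterations) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int nvox = Z * Y * X;
  std::vector<std::array<int, 3>> off = neighbourhood(connectivity);
  std::vector<char> cur(mask.begin(), mask.end()), nxt(nvox);
  for (int it = 0; it < iterations; ++it) {
    for (int x = 0; x < X; ++x)
      for (int y = 0; y < Y; ++y)
        for (int z = 0; z < Z; ++z) {
          int i = lin(z, y, x, Z, Y);
          char v = cur[i];
          if (!v) {
            for (const auto& o : off) {
              int nz = z + o[0], ny = y + o[1], nx = x + o[2];
              if (nz < 0 || nz >= Z || ny < 0 || ny >= Y || nx < 0 || nx >= X)
                continue;
              if (cur[lin(nz, ny, nx, Z, Y)]) { v = 1; break; }
            }
          }
          nxt[i] = v;
        }
    cur.swap(nxt);
  }
  return LogicalVector(cur.begin(), cur.end());
}

// Binary erosion: a voxel survives only if all neighbours are set; voxels
// outside the grid count as background, so the mask also erodes at borders.
// [[Rcpp::export]]
LogicalVector cpp_binary_erode(const LogicalVector& mask, const IntegerVector& dims,
                               int connectivity, int iterations) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int nvox = Z * Y * X;
  std::vector<std::array<int, 3>> off = neighbourhood(connectivity);
  std::vector<char> cur(mask.begin(), mask.end()), nxt(nvox);
  for (int it = 0; it < iterations; ++it) {
    for (int x = 0; x < X; ++x)
      for (int y = 0; y < Y; ++y)
        for (int z = 0; z < Z; ++z) {
          int i = lin(z, y, x, Z, Y);
          char v = cur[i];
          if (v) {
            for (const auto& o : off) {
              int nz = z + o[0], ny = y + o[1], nx = x + o[2];
              if (nz < 0 || nz >= Z || ny < 0 || ny >= Y || nx < 0 || nx >= X ||
                  !cur[lin(nz, ny, nx, Z, Y)]) { v = 0; break; }
            }
          }
          nxt[i] = v;
        }
    cur.swap(nxt);
  }
  return LogicalVector(cur.begin(), cur.end());
}
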