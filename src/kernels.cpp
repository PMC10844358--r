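#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Squared Euclidean distance transforms (Felzenszwalb & Huttenlocher,
// separable lower-envelope-of-parabolas scheme, exact for squared distances)
// and connected-component labeling. These back the morphological engine:
// dilation by a Euclidean disk/ball of radius r is exactly {dist^2 <= r^2}.

static const double DT_INF = 1e20;

static void dt1d(const double* f, double* d, int n, int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = (((double)f[q] + (double)q * q) -
                ((double)f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = (((double)f[q] + (double)q * q) -
           ((double)f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt2d_sq(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  NumericMatrix out(H, W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W)), z(std::max(H, W) + 1);
  std::vector<int> v(std::max(H, W));
  // pass 1: along rows (first dimension), per column
  for (int x = 0; x < W; x++) {
    for (int y = 0; y < H; y++) f[y] = mask(y, x) ? 0.0 : DT_INF;
    dt1d(f.data(), d.data(), H, v.data(), z.data());
    for (int y = 0; y < H; y++) out(y, x) = d[y];
  }
  // pass 2: along columns, per row
  for (int y = 0; y < H; y++) {
    for (int x = 0; x < W; x++) f[x] = out(y, x);
    dt1d(f.data(), d.data(), W, v.data(), z.data());
    for (int x = 0; x < W; x++) out(y, x) = d[x];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_edt3d_sq(LogicalVector mask, IntegerVector dim) {
  int H = dim[0], W = dim[1], D = dim[2];
  R_xlen_t n = (R_xlen_t)H * W * D;
  NumericVector out(n);
  int m = std::max(H, std::max(W, D));
  std::vector<double> f(m), d(m), z(m + 1);
  std::vector<int> v(m);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : DT_INF;
  // along dim 1 (contiguous)
  for (int k = 0; k < D; k++)
    for (int x = 0; x < W; x++) {
      R_xlen_t base = (R_xlen_t)k * H * W + (R_xlen_t)x * H;
      for (int y = 0; y < H; y++) f[y] = out[base + y];
      dt1d(f.data(), d.data(), H, v.data(), z.data());
      for (int y = 0; y < H; y++) out[base + y] = d[y];
    }
  // along dim 2
  for (int k = 0; k < D; k++)
    for (int y = 0; y < H; y++) {
      R_xlen_t base = (R_xlen_t)k * H * W + y;
      for (int x = 0; x < W; x++) f[x] = out[base + (R_xlen_t)x * H];
      dt1d(f.data(), d.data(), W, v.data(), z.data());
      for (int x = 0; x < W; x++) out[base + (R_xlen_t)x * H] = d[x];
    }
  // along dim 3
  R_xlen_t HW = (R_xlen_t)H * W;
  for (int x = 0; x < W; x++)
    for (int y = 0; y < H; y++) {
      R_xlen_t base = (R_xlen_t)x * H + y;
      for (int k = 0; k < D; k++) f[k] = out[base + (R_xlen_t)k * HW];
      dt1d(f.data(), d.data(), D, v.data(), z.data());
      for (int k = 0; k < D; k++) out[base + (R_xlen_t)k * HW] = d[k];
    }
  return out;
}

// Connected components of TRUE pixels. connectivity = 4 or 8.
// Labels assigned in column-major scan order, so label 1 is the component
// whose first pixel appears earliest in R's linear order (deterministic).
// [[Rcpp::export]]
IntegerMatrix cpp_label2d(LogicalMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  const int dy4[] = {-1, 1, 0, 0}, dx4[] = {0, 0, -1, 1};
  const int dy8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dx8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dy = connectivity == 8 ? dy8 : dy4;
  const int* dx = connectivity == 8 ? dx8 : dx4;
  int nn = connectivity == 8 ? 8 : 4;
  for (int x = 0; x < W; x++)
    for (int y = 0; y < H; y++) {
      if (!mask(y, x) || lab(y, x)) continue;
      next++;
      lab(y, x) = next;
      stack.push_back(std::make_pair(y, x));
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int j = 0; j < nn; j++) {
          int yy = p.first + dy[j], xx = p.second + dx[j];
          if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
          if (mask(yy, xx) && !lab(yy, xx)) {
            lab(yy, xx) = next;
            stack.push_back(std::make_pair(yy, xx));
          }
        }
      }
    }
  return lab;
}

// 6-connected components of TRUE voxels in a 3D array.
// [[Rcpp::export]]
IntegerVector cpp_label3d6(LogicalVector mask, IntegerVector dim) {
  int H = dim[0], W = dim[1], D = dim[2];
  R_xlen_t HW = (R_xlen_t)H * W, n = HW * D;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i]) continue;
    next++;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int k = (int)(p / HW);
      int rem = (int)(p % HW);
      int x = rem / H, y = rem % H;
      const int off[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                             {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
      for (int j = 0; j < 6; j++) {
        int yy = y + off[j][0], xx = x + off[j][1], kk = k + off[j][2];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W || kk < 0 || kk >= D) continue;
        R_xlen_t q = (R_xlen_t)kk * HW + (R_xlen_t)xx * H + yy;
        if (mask[q] && !lab[q]) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Separable convolution of a 3D array with one odd-length 1D kernel applied
// along every axis; borders use zero padding.
// [[Rcpp::export]]
NumericVector cpp_sepconv3d(NumericVector arr, IntegerVector dim, NumericVector kernel) {
  int H = dim[0], W = dim[1], D = dim[2];
  int kl = kernel.size(), kr = kl / 2;
  R_xlen_t HW = (R_xlen_t)H * W, n = HW * D;
  NumericVector a = clone(arr), b(n);
  // axis 1
  for (int k = 0; k < D; k++)
    for (int x = 0; x < W; x++) {
      R_xlen_t base = k * HW + (R_xlen_t)x * H;
      for (int y = 0; y < H; y++) {
        double s = 0;
        for (int j = 0; j < kl; j++) {
          int yy = y + j - kr;
          if (yy >= 0 && yy < H) s += kernel[j] * a[base + yy];
        }
        b[base + y] = s;
      }
    }
  // axis 2
  for (int k = 0; k < D; k++)
    for (int y = 0; y < H; y++) {
      R_xlen_t base = k * HW + y;
      for (int x = 0; x < W; x++) {
        double s = 0;
        for (int j = 0; j < kl; j++) {
          int xx = x + j - kr;
          if (xx >= 0 && xx < W) s += kernel[j] * b[base + (R_xlen_t)xx * H];
        }
        a[base + (R_xlen_t)x * H] = s;
      }
    }
  // axis 3
  for (int x = 0; x < W; x++)
    for (int y = 0; y < H; y++) {
      R_xlen_t base = (R_xlen_t)x * H + y;
      for (int k = 0; k < D; k++) {
        double s = 0;
        for (int j = 0; j < kl; j++) {
          int kk = k + j - kr;
          if (kk >= 0 && kk < D) s += kernel[j] * a[base + kk * HW];
        }
        b[base + k * HW] = s;
      }
    }
  return b;
}
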