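#include <Rcpp.h>
using namespace Rcpp;

// Mirror indexing without edge duplication (reflect101), valid while |i| < n.
static inline int reflect_idx(int i, int n) {
  if (i < 0) i = -i;
  if (i >= n) i = 2 * n - 2 - i;
  if (i < 0) i = 0;            // degenerate n == 1
  if (i >= n) i = n - 1;
  return i;
}

// Separable 2-D convolution of a single channel with reflective borders.
// ky runs down columns (vertical), kx along rows (horizontal); either may be
// length 1 for a purely horizontal/vertical pass.
static void sep_conv2_core(const double* x, double* out, double* tmp,
                           int H, int W,
                           const double* kxp, int nx,
                           const double* kyp, int ny) {
  const int rx = (nx - 1) / 2, ry = (ny - 1) / 2;
  // vertical pass (columns are contiguous)
  for (int j = 0; j < W; ++j) {
    const double* col = x + (size_t)j * H;
    double* tcol = tmp + (size_t)j * H;
    int lo = ry < H ? ry : H, hi = H - ry;
    if (hi < lo) hi = lo;
    for (int i = 0; i < lo; ++i) {
      double s = 0.0;
      for (int k = 0; k < ny; ++k) s += kyp[k] * col[reflect_idx(i + k - ry, H)];
      tcol[i] = s;
    }
    for (int i = lo; i < hi; ++i) {
      double s = 0.0;
      const double* p = col + i - ry;
      for (int k = 0; k < ny; ++k) s += kyp[k] * p[k];
      tcol[i] = s;
    }
    for (int i = hi; i < H; ++i) {
      double s = 0.0;
      for (int k = 0; k < ny; ++k) s += kyp[k] * col[reflect_idx(i + k - ry, H)];
      tcol[i] = s;
    }
  }
  // horizontal pass: build each output column once (stays in L1)
  for (int j = 0; j < W; ++j) {
    double* dst = out + (size_t)j * H;
    const double* src0 = tmp + (size_t)reflect_idx(j - rx, W) * H;
    const double w0 = kxp[0];
    for (int i = 0; i < H; ++i) dst[i] = w0 * src0[i];
    for (int k = 1; k < nx; ++k) {
      const double w = kxp[k];
      const double* src = tmp + (size_t)reflect_idx(j + k - rx, W) * H;
      for (int i = 0; i < H; ++i) dst[i] += w * src[i];
    }
  }
}

// [[Rcpp::export(name = ".sep_conv2")]]
NumericMatrix sep_conv2(const NumericMatrix& x,
                        const NumericVector& kx,
                        const NumericVector& ky) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H, W);
  std::vector<double> tmp((size_t)H * W);
  sep_conv2_core(&x[0], &out[0], tmp.data(), H, W,
                 &kx[0], kx.size(), &ky[0], ky.size());
  return out;
}

// Separable convolution of all three channels of an H x W x 3 array.
// [[Rcpp::export(name = ".sep_conv2_3")]]
NumericVector sep_conv2_3(const NumericVector& arr, int H, int W,
                          const NumericVector& kx, const NumericVector& ky) {
  NumericVector out(no_init((size_t)H * W * 3));
  std::vector<double> tmp((size_t)H * W);
  for (int c = 0; c < 3; ++c) {
    sep_conv2_core(&arr[0] + (size_t)c * H * W, &out[0] + (size_t)c * H * W,
                   tmp.data(), H, W, &kx[0], kx.size(), &ky[0], ky.size());
  }
  out.attr("dim") = IntegerVector::create(H, W, 3);
  return out;
}

// Luma (BT.601 weights) of an H x W x 3 array stored column-major.
// [[Rcpp::export(name = ".rgb_gray")]]
NumericMatrix rgb_gray(const NumericVector& arr, int H, int W) {
  NumericMatrix g(H, W);
  const int plane = H * W;
  for (int p = 0; p < plane; ++p)
    g[p] = 0.299 * arr[p] + 0.587 * arr[p + plane] + 0.114 * arr[p + 2 * plane];
  return g;
}

// Variance of the 4-neighbour Laplacian over interior pixels.
// [[Rcpp::export(name = ".laplacian_variance")]]
double laplacian_variance(const NumericMatrix& g) {
  const int H = g.nrow(), W = g.ncol();
  if (H < 3 || W < 3) return 0.0;
  const double n = (double)(H - 2) * (W - 2);
  double sum = 0.0, sumsq = 0.0;
  for (int j = 1; j < W - 1; ++j) {
    for (int i = 1; i < H - 1; ++i) {
      double v = g(i - 1, j) + g(i + 1, j) + g(i, j - 1) + g(i, j + 1) -
                 4.0 * g(i, j);
      sum += v;
      sumsq += v * v;
    }
  }
  double mean = sum / n;
  return sumsq / n - mean * mean;
}

// Skin-pixel marginal counts for a classic RGB skin rule.
// [[Rcpp::export(name = ".skin_marginals")]]
List skin_marginals(const NumericVector& arr, int H, int W) {
  IntegerVector rows(H), cols(W);
  const int plane = H * W;
  long total = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int p = j * H + i;
      double r = arr[p], g = arr[p + plane], b = arr[p + 2 * plane];
      double mx = r > g ? (r > b ? r : b) : (g > b ? g : b);
      double mn = r < g ? (r < b ? r : b) : (g < b ? g : b);
      bool skin = r > 95 && g > 40 && b > 20 && r > g && r > b && (mx - mn) > 15;
      if (skin) { rows[i]++; cols[j]++; total++; }
    }
  }
  return List::create(_["rows"] = rows, _["cols"] = cols,
                      _["total"] = (double)total);
}

// Bilinear resize of a half-open box [x0, x0+bw) x [y0, y0+bh) (0-based) of an
// H x W x C array to out_h x out_w. Pixel-centre mapping, so an identity-size
// request copies exactly.
// [[Rcpp::export(name = ".bilinear_resize")]]
NumericVector bilinear_resize(const NumericVector& arr, int H, int W, int C,
                              int x0, int y0, int bw, int bh,
                              int out_h, int out_w) {
  NumericVector out(out_h * out_w * C);
  const size_t plane = (size_t)H * W, oplane = (size_t)out_h * out_w;
  const double sy_scale = (double)bh / out_h, sx_scale = (double)bw / out_w;
  std::vector<int> iy0v(out_h), iy1v(out_h);
  std::vector<double> wyv(out_h);
  for (int oi = 0; oi < out_h; ++oi) {
    double sy = y0 + (oi + 0.5) * sy_scale - 0.5;
    if (sy < y0) sy = y0;
    if (sy > y0 + bh - 1) sy = y0 + bh - 1;
    int iy0 = (int)std::floor(sy);
    iy0v[oi] = iy0;
    iy1v[oi] = iy0 + 1 > y0 + bh - 1 ? iy0 : iy0 + 1;
    wyv[oi] = sy - iy0;
  }
  for (int c = 0; c < C; ++c) {
    const double* ch = &arr[0] + c * plane;
    double* och = &out[0] + c * oplane;
    for (int oj = 0; oj < out_w; ++oj) {
      double sx = x0 + (oj + 0.5) * sx_scale - 0.5;
      if (sx < x0) sx = x0;
      if (sx > x0 + bw - 1) sx = x0 + bw - 1;
      int jx0 = (int)std::floor(sx);
      int jx1 = jx0 + 1 > x0 + bw - 1 ? jx0 : jx0 + 1;
      double wx = sx - jx0;
      const double* c0 = ch + (size_t)jx0 * H;
      const double* c1 = ch + (size_t)jx1 * H;
      double* ocol = och + (size_t)oj * out_h;
      for (int oi = 0; oi < out_h; ++oi) {
        const double wy = wyv[oi];
        const int iy0 = iy0v[oi], iy1 = iy1v[oi];
        double top = c0[iy0] + wx * (c1[iy0] - c0[iy0]);
        double bot = c0[iy1] + wx * (c1[iy1] - c0[iy1]);
        ocol[oi] = top + wy * (bot - top);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(out_h, out_w, C);
  return out;
}

// In one pass: multiply by a scalar, round to integer, clip to [0, 255].
// [[Rcpp::export(name = ".mul_round_clip")]]
NumericVector mul_round_clip(const NumericVector& arr, double factor) {
  NumericVector out(arr.size());
  for (int i = 0; i < arr.size(); ++i) {
    double v = std::round(arr[i] * factor);
    out[i] = v < 0 ? 0 : (v > 255 ? 255 : v);
  }
  out.attr("dim") = arr.attr("dim");
  return out;
}
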