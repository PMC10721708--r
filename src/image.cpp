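#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Separable Gaussian blur with edge-replicate boundary handling.
// Kernel radius 3*sigma (rounded up), normalised to sum 1.
// [[Rcpp::export(name = ".cpp_gauss_blur")]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(H, W), out(H, W);
  const double* im = img.begin();
  double* tm = tmp.begin();
  double* ot = out.begin();
  // vertical pass: contiguous within each column; clamp only at borders
  for (int j = 0; j < W; ++j) {
    const double* src = im + (size_t)j * H;
    double* dst = tm + (size_t)j * H;
    const int lo = std::min(rad, H);
    const int hi = std::max(lo, H - rad);
    for (int i = 0; i < lo; ++i) {
      double acc = 0.0;
      for (int d = -rad; d <= rad; ++d)
        acc += k[d + rad] * src[std::min(std::max(i + d, 0), H - 1)];
      dst[i] = acc;
    }
    for (int i = lo; i < hi; ++i) {
      double acc = 0.0;
      const double* s = src + i - rad;
      for (int d = 0; d <= 2 * rad; ++d) acc += k[d] * s[d];
      dst[i] = acc;
    }
    for (int i = hi; i < H; ++i) {
      double acc = 0.0;
      for (int d = -rad; d <= rad; ++d)
        acc += k[d + rad] * src[std::min(std::max(i + d, 0), H - 1)];
      dst[i] = acc;
    }
  }
  // horizontal pass: accumulate weighted columns (axpy over contiguous H)
  for (int j = 0; j < W; ++j) {
    double* dst = ot + (size_t)j * H;
    for (int d = -rad; d <= rad; ++d) {
      const int jj = std::min(std::max(j + d, 0), W - 1);
      const double kd = k[d + rad];
      const double* src = tm + (size_t)jj * H;
      for (int i = 0; i < H; ++i) dst[i] += kd * src[i];
    }
  }
  return out;
}

// Per-pixel median across a stack of frames given as an (npix x nframes)
// matrix; returns npix vector.  Standard sample median (mean of the two
// central order statistics for even n).
// [[Rcpp::export(name = ".cpp_stack_median")]]
NumericVector cpp_stack_median(const NumericMatrix& stack) {
  const int npix = stack.nrow(), n = stack.ncol();
  NumericVector out(npix);
  std::vector<double> buf(n);
  for (int p = 0; p < npix; ++p) {
    for (int j = 0; j < n; ++j) buf[j] = stack(p, j);
    int m = n / 2;
    std::nth_element(buf.begin(), buf.begin() + m, buf.end());
    double hi = buf[m];
    if (n % 2 == 1) {
      out[p] = hi;
    } else {
      double lo = *std::max_element(buf.begin(), buf.begin() + m);
      out[p] = 0.5 * (lo + hi);
    }
  }
  return out;
}

// Add Gaussian sensor noise (from R's RNG stream), clamp to the bit-depth
// range and round to integers in one pass.
// [[Rcpp::export(name = ".cpp_finalize_frame")]]
IntegerMatrix cpp_finalize_frame(const NumericMatrix& img, double noise_sd,
                                 double maxval) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix out(H, W);
  const double* src = img.begin();
  int* dst = out.begin();
  const R_xlen_t n = (R_xlen_t)H * W;
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = src[i];
    if (noise_sd > 0) v += noise_sd * R::norm_rand();
    if (v < 0) v = 0;
    if (v > maxval) v = maxval;
    dst[i] = (int)std::lround(v);
  }
  return out;
}

// Connected-component labelling of a logical mask, 4- or 8-connectivity.
// Returns an integer matrix of labels (0 = background), labels assigned in
// raster-scan (column-major) order of first encounter.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> cur = q.front();
        q.pop();
        for (int d = 0; d < nn; ++d) {
          int r = cur.first + dr8[d], c = cur.second + dc8[d];
          if (r < 0 || r >= H || c < 0 || c >= W) continue;
          if (mask(r, c) && lab(r, c) == 0) {
            lab(r, c) = next;
            q.push(std::make_pair(r, c));
          }
        }
      }
    }
  }
  return lab;
}
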