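#include <Rcpp.h>

// Batch normalization over (H, W, T, N) per channel, with an optionally
// fused ReLU.  Single-pass loops over the (HWT, C, N) view of the array;
// the backward pass recovers the standard BN gradient from the cached
// normalized activations.

using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_bn_forward")]]
List cpp_bn_forward(const NumericVector& x, const IntegerVector& dim5,
                    const NumericVector& gamma, const NumericVector& beta,
                    const NumericVector& rm, const NumericVector& rv,
                    bool training, double momentum, double eps, bool act) {
  const R_xlen_t HWT = (R_xlen_t)dim5[0] * dim5[1] * dim5[2];
  const int C = dim5[3], N = dim5[4];
  const R_xlen_t total = HWT * C * N;
  NumericVector mu(C), var(C);
  if (training) {
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < C; ++c) {
        const double* xs = x.begin() + HWT * (c + (R_xlen_t)C * n);
        double s = 0, s2 = 0;
        for (R_xlen_t i = 0; i < HWT; ++i) {
          s += xs[i];
          s2 += xs[i] * xs[i];
        }
        mu[c] += s;
        var[c] += s2;
      }
    }
    const double nobs = (double)HWT * N;
    for (int c = 0; c < C; ++c) {
      mu[c] /= nobs;
      var[c] = std::max(var[c] / nobs - mu[c] * mu[c], 0.0);
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = rm[c];
      var[c] = rv[c];
    }
  }
  NumericVector inv(C);
  for (int c = 0; c < C; ++c) inv[c] = 1.0 / std::sqrt(var[c] + eps);

  NumericVector y(total), xhat(total);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = HWT * (c + (R_xlen_t)C * n);
      const double* xs = x.begin() + off;
      double* ys = y.begin() + off;
      double* hs = xhat.begin() + off;
      const double m = mu[c], iv = inv[c], g = gamma[c], b = beta[c];
      for (R_xlen_t i = 0; i < HWT; ++i) {
        const double h = (xs[i] - m) * iv;
        hs[i] = h;
        double v = g * h + b;
        if (act && v < 0) v = 0;
        ys[i] = v;
      }
    }
  }
  y.attr("dim") = dim5;
  List out = List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv);
  if (training) {
    NumericVector rm2(C), rv2(C);
    for (int c = 0; c < C; ++c) {
      rm2[c] = (1 - momentum) * rm[c] + momentum * mu[c];
      rv2[c] = (1 - momentum) * rv[c] + momentum * var[c];
    }
    out["rm"] = rm2;
    out["rv"] = rv2;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_bn_backward")]]
List cpp_bn_backward(const NumericVector& dy, const NumericVector& y,
                     const NumericVector& xhat, const NumericVector& inv,
                     const NumericVector& gamma, const IntegerVector& dim5,
                     bool training, bool act) {
  const R_xlen_t HWT = (R_xlen_t)dim5[0] * dim5[1] * dim5[2];
  const int C = dim5[3], N = dim5[4];
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  // first pass: per-channel sums of (masked) dy and dy * xhat
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = HWT * (c + (R_xlen_t)C * n);
      const double* ds = dy.begin() + off;
      const double* hs = xhat.begin() + off;
      const double* ys = y.begin() + off;
      double a = 0, b = 0;
      for (R_xlen_t i = 0; i < HWT; ++i) {
        const double d = (act && ys[i] <= 0) ? 0.0 : ds[i];
        a += d;
        b += d * hs[i];
      }
      dbeta[c] += a;
      dgamma[c] += b;
    }
  }
  const double nobs = (double)HWT * N;
  for (int c = 0; c < C; ++c) {
    s1[c] = dbeta[c] * gamma[c];
    s2[c] = dgamma[c] * gamma[c];
  }
  NumericVector dx(dy.size());
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = HWT * (c + (R_xlen_t)C * n);
      const double* ds = dy.begin() + off;
      const double* hs = xhat.begin() + off;
      const double* ys = y.begin() + off;
      double* os = dx.begin() + off;
      const double g = gamma[c], iv = inv[c];
      if (training) {
        const double a1 = s1[c] / nobs, a2 = s2[c] / nobs;
        for (R_xlen_t i = 0; i < HWT; ++i) {
          const double d = (act && ys[i] <= 0) ? 0.0 : ds[i];
          os[i] = iv * (g * d - a1 - hs[i] * a2);
        }
      } else {
        for (R_xlen_t i = 0; i < HWT; ++i) {
          const double d = (act && ys[i] <= 0) ? 0.0 : ds[i];
          os[i] = iv * g * d;
        }
      }
    }
  }
  dx.attr("dim") = dim5;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
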