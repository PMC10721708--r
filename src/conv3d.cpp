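#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// 3-D convolution via im2col + GEMM, batched: the unfolded column matrix
// covers the whole batch (K x M*N) so the multiply is one large GEMM, and
// the forward pass returns the column matrix for reuse in the backward
// pass (no re-unfolding).
//
// Layouts (R column-major arrays):
//   x : (H, W, T, Cin, N)      w : (kh, kw, kt, Cin, Cout)
//   y : (Ho, Wo, To, Cout, N)
// Zero padding, integer strides.

using namespace Rcpp;

static inline int out_len(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Unfold one sample into columns col[, m] (column m of length K at
// colbase + (size_t)m * K).
// The h axis is innermost both in x and in the column layout, so each
// (c, dt, dw) slot is a contiguous run of kh values: copy the valid part
// in one go and zero-fill the padded remainder.
static void im2col(const double* x, int H, int W, int T, int C,
                   int kh, int kw, int kt, int sh, int sw, int st,
                   int ph, int pw, int pt, int Ho, int Wo, int To,
                   double* colbase) {
  const int K = kh * kw * kt * C;
  for (int to = 0; to < To; ++to) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int m = ho + Ho * (wo + Wo * to);
        double* dst = colbase + (size_t)m * K;
        const int h0 = ho * sh - ph;
        const int dh_lo = std::max(0, -h0);
        const int dh_hi = std::min(kh, H - h0);
        for (int c = 0; c < C; ++c) {
          for (int dt = 0; dt < kt; ++dt) {
            const int t = to * st - pt + dt;
            const bool t_ok = (t >= 0 && t < T);
            for (int dw = 0; dw < kw; ++dw) {
              const int wcol = wo * sw - pw + dw;
              double* d = dst + kh * (dw + kw * (dt + (size_t)kt * c));
              if (!t_ok || wcol < 0 || wcol >= W || dh_lo >= dh_hi) {
                std::fill(d, d + kh, 0.0);
                continue;
              }
              const double* s =
                x + h0 + (size_t)H * (wcol + (size_t)W * (t + (size_t)T * c));
              if (dh_lo > 0) std::fill(d, d + dh_lo, 0.0);
              std::copy(s + dh_lo, s + dh_hi, d + dh_lo);
              if (dh_hi < kh) std::fill(d + dh_hi, d + kh, 0.0);
            }
          }
        }
      }
    }
  }
}

static void col2im(const double* colbase, double* dx, int H, int W, int T,
                   int C, int kh, int kw, int kt, int sh, int sw, int st,
                   int ph, int pw, int pt, int Ho, int Wo, int To) {
  const int K = kh * kw * kt * C;
  for (int to = 0; to < To; ++to) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int m = ho + Ho * (wo + Wo * to);
        const double* src = colbase + (size_t)m * K;
        const int h0 = ho * sh - ph;
        const int dh_lo = std::max(0, -h0);
        const int dh_hi = std::min(kh, H - h0);
        if (dh_lo >= dh_hi) continue;
        for (int c = 0; c < C; ++c) {
          for (int dt = 0; dt < kt; ++dt) {
            const int t = to * st - pt + dt;
            if (t < 0 || t >= T) continue;
            for (int dw = 0; dw < kw; ++dw) {
              const int wcol = wo * sw - pw + dw;
              if (wcol < 0 || wcol >= W) continue;
              const double* s = src + kh * (dw + kw * (dt + (size_t)kt * c));
              double* d =
                dx + h0 + (size_t)H * (wcol + (size_t)W * (t + (size_t)T * c));
              for (int dh = dh_lo; dh < dh_hi; ++dh) d[dh] += s[dh];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv3d_forward")]]
List cpp_conv3d_forward(const NumericVector& x, const IntegerVector& dimx,
                        const NumericVector& w, const IntegerVector& dimw,
                        const NumericVector& bias,
                        const IntegerVector& stride,
                        const IntegerVector& pad,
                        bool keep_col) {
  const int H = dimx[0], W = dimx[1], T = dimx[2], C = dimx[3], N = dimx[4];
  const int kh = dimw[0], kw = dimw[1], kt = dimw[2], Cout = dimw[4];
  if (dimw[3] != C) stop("input channels do not match kernel");
  const int sh = stride[0], sw = stride[1], st = stride[2];
  const int ph = pad[0], pw = pad[1], pt = pad[2];
  const int Ho = out_len(H, kh, sh, ph), Wo = out_len(W, kw, sw, pw),
            To = out_len(T, kt, st, pt);
  const int K = kh * kw * kt * C, M = Ho * Wo * To;

  const arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector col((R_xlen_t)K * M * N);
  const size_t xs = (size_t)H * W * T * C;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xs, H, W, T, C, kh, kw, kt, sh, sw, st,
           ph, pw, pt, Ho, Wo, To, col.begin() + (size_t)n * M * K);
  }
  arma::mat colall(col.begin(), K, (size_t)M * N, false, true);
  arma::mat Yall = colall.t() * Wmat;  // (M*N) x Cout

  NumericVector y((R_xlen_t)M * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, To, Cout, N);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double* src = Yall.colptr(co) + (size_t)n * M;
      double* dst = y.begin() + (size_t)n * M * Cout + (size_t)co * M;
      const double b = bias[co];
      for (int m = 0; m < M; ++m) dst[m] = src[m] + b;
    }
  }
  if (keep_col) return List::create(_["y"] = y, _["col"] = col);
  return List::create(_["y"] = y);
}

// [[Rcpp::export(name = ".cpp_conv3d_backward")]]
List cpp_conv3d_backward(const NumericVector& col, const IntegerVector& dimx,
                         const NumericVector& w, const IntegerVector& dimw,
                         const NumericVector& dy,
                         const IntegerVector& stride,
                         const IntegerVector& pad) {
  const int H = dimx[0], W = dimx[1], T = dimx[2], C = dimx[3], N = dimx[4];
  const int kh = dimw[0], kw = dimw[1], kt = dimw[2], Cout = dimw[4];
  const int sh = stride[0], sw = stride[1], st = stride[2];
  const int ph = pad[0], pw = pad[1], pt = pad[2];
  const int Ho = out_len(H, kh, sh, ph), Wo = out_len(W, kw, sw, pw),
            To = out_len(T, kt, st, pt);
  const int K = kh * kw * kt * C, M = Ho * Wo * To;

  // gather dy into (M*N) x Cout
  arma::mat dYall((size_t)M * N, Cout);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double* src = dy.begin() + (size_t)n * M * Cout + (size_t)co * M;
      double* dst = dYall.colptr(co) + (size_t)n * M;
      std::copy(src, src + M, dst);
    }
  }
  const arma::mat colall(const_cast<double*>(col.begin()), K, (size_t)M * N,
                         false, true);
  const arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);

  NumericVector dw((R_xlen_t)w.size());
  dw.attr("dim") = dimw;
  arma::mat dWmat(dw.begin(), K, Cout, false, true);
  dWmat = colall * dYall;
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) {
    db[co] = arma::accu(dYall.col(co));
  }

  arma::mat dcol = Wmat * dYall.t();  // K x (M*N)
  NumericVector dx((R_xlen_t)H * W * T * C * N);
  dx.attr("dim") = dimx;
  const size_t xs = (size_t)H * W * T * C;
  for (int n = 0; n < N; ++n) {
    col2im(dcol.colptr(0) + (size_t)n * M * K, dx.begin() + n * xs,
           H, W, T, C, kh, kw, kt, sh, sw, st, ph, pw, pt, Ho, Wo, To);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
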