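#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are numeric arrays with dim (H, W, C, N), column-major as R
// stores them.  "Same" padding throughout: pad = dilation*(K-1)/2 per side,
// so output spatial dims are ceil(dim/stride).

static inline int out_dim(int d, int stride) { return (d + stride - 1) / stride; }

// [[Rcpp::export]]
NumericVector dw_conv_fwd_cpp(NumericVector x, NumericVector w,
                              int stride, int dilation) {
  IntegerVector xd = x.attr("dim");   // H W C N
  IntegerVector wd = w.attr("dim");   // K K C
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], K = wd[0];
  int pad = dilation * (K - 1) / 2;
  int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  NumericVector y(R_xlen_t(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xp = &x[(R_xlen_t(n) * C + c) * H * W];
      const double *wp = &w[R_xlen_t(c) * K * K];
      double *yp = &y[(R_xlen_t(n) * C + c) * Ho * Wo];
      for (int wo = 0; wo < Wo; ++wo) {
        int wi0 = wo * stride - pad;
        for (int ho = 0; ho < Ho; ++ho) {
          int hi0 = ho * stride - pad;
          double acc = 0.0;
          for (int kw = 0; kw < K; ++kw) {
            int wi = wi0 + kw * dilation;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              int hi = hi0 + kh * dilation;
              if (hi < 0 || hi >= H) continue;
              acc += xp[R_xlen_t(wi) * H + hi] * wp[kw * K + kh];
            }
          }
          yp[R_xlen_t(wo) * Ho + ho] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dw_conv_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int dilation) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], K = wd[0];
  int pad = dilation * (K - 1) / 2;
  int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xp = &x[(R_xlen_t(n) * C + c) * H * W];
      const double *wp = &w[R_xlen_t(c) * K * K];
      const double *dyp = &dy[(R_xlen_t(n) * C + c) * Ho * Wo];
      double *dxp = &dx[(R_xlen_t(n) * C + c) * H * W];
      double *dwp = &dw[R_xlen_t(c) * K * K];
      for (int wo = 0; wo < Wo; ++wo) {
        int wi0 = wo * stride - pad;
        for (int ho = 0; ho < Ho; ++ho) {
          int hi0 = ho * stride - pad;
          double g = dyp[R_xlen_t(wo) * Ho + ho];
          if (g == 0.0) continue;
          for (int kw = 0; kw < K; ++kw) {
            int wi = wi0 + kw * dilation;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              int hi = hi0 + kh * dilation;
              if (hi < 0 || hi >= H) continue;
              dxp[R_xlen_t(wi) * H + hi] += wp[kw * K + kh] * g;
              dwp[kw * K + kh] += xp[R_xlen_t(wi) * H + hi] * g;
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Unfold into a (Ho*Wo*N) x (K*K*C) matrix; column order kh, kw, c matches
// matrix(w, K*K*C, Cout) on a (K,K,C,Cout) weight array, row order ho, wo, n.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int K, int stride, int dilation) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int pad = dilation * (K - 1) / 2;
  int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  NumericMatrix cols(Ho * Wo * N, K * K * C);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        int col = kh + K * kw + K * K * c;
        double *cp = &cols(0, col);
        for (int n = 0; n < N; ++n) {
          const double *xp = &x[(R_xlen_t(n) * C + c) * H * W];
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + kw * dilation;
            bool win = (wi >= 0 && wi < W);
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + kh * dilation;
              double v = 0.0;
              if (win && hi >= 0 && hi < H) v = xp[R_xlen_t(wi) * H + hi];
              cp[R_xlen_t(n) * Ho * Wo + R_xlen_t(wo) * Ho + ho] = v;
            }
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add the unfolded gradient back onto the input layout.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int K, int stride, int dilation) {
  int pad = dilation * (K - 1) / 2;
  int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  NumericVector dx(R_xlen_t(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        int col = kh + K * kw + K * K * c;
        const double *cp = &cols(0, col);
        for (int n = 0; n < N; ++n) {
          double *dxp = &dx[(R_xlen_t(n) * C + c) * H * W];
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + kw * dilation;
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + kh * dilation;
              if (hi < 0 || hi >= H) continue;
              dxp[R_xlen_t(wi) * H + hi] +=
                cp[R_xlen_t(n) * Ho * Wo + R_xlen_t(wo) * Ho + ho];
            }
          }
        }
      }
    }
  }
  return dx;
}

// Max pooling, pad (K-1)/2, padded cells never win.  idx holds the 0-based
// winning position within the (H,W) slice, for the backward scatter.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int K, int stride) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int pad = (K - 1) / 2;
  int Ho = out_dim(H, stride), Wo = out_dim(W, stride);
  NumericVector y(R_xlen_t(Ho) * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xp = &x[(R_xlen_t(n) * C + c) * H * W];
      R_xlen_t off = (R_xlen_t(n) * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        int wi0 = wo * stride - pad;
        for (int ho = 0; ho < Ho; ++ho) {
          int hi0 = ho * stride - pad;
          double best = R_NegInf;
          int besti = -1;
          for (int kw = 0; kw < K; ++kw) {
            int wi = wi0 + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              int hi = hi0 + kh;
              if (hi < 0 || hi >= H) continue;
              double v = xp[R_xlen_t(wi) * H + hi];
              if (v > best) { best = v; besti = wi * H + hi; }
            }
          }
          y[off + R_xlen_t(wo) * Ho + ho] = best;
          idx[off + R_xlen_t(wo) * Ho + ho] = besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector idx,
                              int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx(R_xlen_t(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      R_xlen_t off = (R_xlen_t(n) * C + c) * Ho * Wo;
      double *dxp = &dx[(R_xlen_t(n) * C + c) * H * W];
      for (R_xlen_t k = 0; k < R_xlen_t(Ho) * Wo; ++k) {
        int i = idx[off + k];
        if (i >= 0) dxp[i] += dy[off + k];
      }
    }
  }
  return dx;
}

// Instrumented naive convolutions: literally perform the "same"-padding
// stride-1 convolution on a materialized zero-padded input and count one unit
// per scalar multiplication executed.  These are the measurement side of the
// analytic cost formulas and share no code with them.

// [[Rcpp::export]]
double naive_conv_mult_count_cpp(NumericVector x, NumericVector w) {
  IntegerVector xd = x.attr("dim");   // H W Cin (single image)
  IntegerVector wd = w.attr("dim");   // K K Cin Cout
  int H = xd[0], W = xd[1], Cin = xd[2], K = wd[0], Cout = wd[3];
  int pad = (K - 1) / 2;
  int Hp = H + 2 * pad, Wp = W + 2 * pad;
  std::vector<double> xpad(R_xlen_t(Hp) * Wp * Cin, 0.0);
  for (int c = 0; c < Cin; ++c)
    for (int wi = 0; wi < W; ++wi)
      for (int hi = 0; hi < H; ++hi)
        xpad[(R_xlen_t(c) * Wp + (wi + pad)) * Hp + (hi + pad)] =
          x[(R_xlen_t(c) * W + wi) * H + hi];
  double count = 0.0, sink = 0.0;
  for (int co = 0; co < Cout; ++co)
    for (int wo = 0; wo < W; ++wo)
      for (int ho = 0; ho < H; ++ho) {
        double acc = 0.0;
        for (int ci = 0; ci < Cin; ++ci)
          for (int kw = 0; kw < K; ++kw)
            for (int kh = 0; kh < K; ++kh) {
              acc += xpad[(R_xlen_t(ci) * Wp + (wo + kw)) * Hp + (ho + kh)] *
                     w[((R_xlen_t(co) * Cin + ci) * K + kw) * K + kh];
              count += 1.0;
            }
        sink += acc;
      }
  if (!R_finite(sink)) count = -1.0;  // keep the computation observable
  return count;
}

// Depthwise stage followed by the 1x1 pointwise stage, counting multiplies.
// [[Rcpp::export]]
double naive_dws_mult_count_cpp(NumericVector x, NumericVector wd_,
                                NumericVector wp_) {
  IntegerVector xd = x.attr("dim");    // H W Cin
  IntegerVector wdd = wd_.attr("dim"); // K K Cin
  IntegerVector wpd = wp_.attr("dim"); // Cin Cout
  int H = xd[0], W = xd[1], Cin = xd[2], K = wdd[0], Cout = wpd[1];
  int pad = (K - 1) / 2;
  int Hp = H + 2 * pad, Wp = W + 2 * pad;
  std::vector<double> xpad(R_xlen_t(Hp) * Wp * Cin, 0.0);
  for (int c = 0; c < Cin; ++c)
    for (int wi = 0; wi < W; ++wi)
      for (int hi = 0; hi < H; ++hi)
        xpad[(R_xlen_t(c) * Wp + (wi + pad)) * Hp + (hi + pad)] =
          x[(R_xlen_t(c) * W + wi) * H + hi];
  double count = 0.0, sink = 0.0;
  std::vector<double> mid(R_xlen_t(H) * W * Cin);
  for (int c = 0; c < Cin; ++c)
    for (int wo = 0; wo < W; ++wo)
      for (int ho = 0; ho < H; ++ho) {
        double acc = 0.0;
        for (int kw = 0; kw < K; ++kw)
          for (int kh = 0; kh < K; ++kh) {
            acc += xpad[(R_xlen_t(c) * Wp + (wo + kw)) * Hp + (ho + kh)] *
                   wd_[(R_xlen_t(c) * K + kw) * K + kh];
            count += 1.0;
          }
        mid[(R_xlen_t(c) * W + wo) * H + ho] = acc;
      }
  for (int co = 0; co < Cout; ++co)
    for (int wo = 0; wo < W; ++wo)
      for (int ho = 0; ho < H; ++ho) {
        double acc = 0.0;
        for (int ci = 0; ci < Cin; ++ci) {
          acc += mid[(R_xlen_t(ci) * W + wo) * H + ho] *
                 wp_[R_xlen_t(co) * Cin + ci];
          count += 1.0;
        }
        sink += acc;
      }
  if (!R_finite(sink)) count = -1.0;
  return count;
}
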