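// Minimal CPU convolution kernels for the completion network.
// Tensors are R arrays in column-major order:
//   activations: H x W x C x N, conv weights: kh x kw x Cin x Cout.
// Forward/backward use im2col + BLAS GEMM via Armadillo; transposed
// convolutions use direct scatter loops (they are a small share of the cost).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad, int dil) {
  int dk = (k - 1) * dil + 1;
  return (n + 2 * pad - dk) / stride + 1;
}

static void im2col(const double* xn, int H, int W, int C,
                   int kh, int kw, int stride, int pad, int dil,
                   int OH, int OW, arma::mat& cols) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int krow = i + kh * (j + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          const int win = ow * stride - pad + j * dil;
          if (win < 0 || win >= W) {
            for (int oh = 0; oh < OH; ++oh) cols(krow, oh + OH * ow) = 0.0;
          } else {
            const double* xcol = xn + (size_t)H * (win + (size_t)W * c);
            for (int oh = 0; oh < OH; ++oh) {
              const int hin = oh * stride - pad + i * dil;
              cols(krow, oh + OH * ow) =
                  (hin >= 0 && hin < H) ? xcol[hin] : 0.0;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv: input has %d channels, kernel expects %d", C, Cin);
  const int OH = out_size(H, kh, stride, pad, dil);
  const int OW = out_size(W, kw, stride, pad, dil);
  if (OH <= 0 || OW <= 0) stop("conv: output size would be non-positive");
  const int K = kh * kw * C, P = OH * OW;

  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector y((size_t)P * Cout * N);
  y.attr("dim") = IntegerVector::create(OH, OW, Cout, N);
  arma::mat cols(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           dil, OH, OW, cols);
    arma::mat ym = Wm.t() * cols;  // Cout x P
    double* yn = y.begin() + (size_t)P * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      for (int p = 0; p < P; ++p) yn[p + (size_t)P * co] = ym(co, p) + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector gy,
                  int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int OH = out_size(H, kh, stride, pad, dil);
  const int OW = out_size(W, kw, stride, pad, dil);
  const int K = kh * kw * C, P = OH * OW;

  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector gx((size_t)H * W * C * N), gw((size_t)K * Cout), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  arma::mat gWm(gw.begin(), K, Cout, false, true);
  arma::mat cols(K, P), gym(Cout, P);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           dil, OH, OW, cols);
    const double* gyn = gy.begin() + (size_t)P * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      double s = 0.0;
      for (int p = 0; p < P; ++p) {
        const double v = gyn[p + (size_t)P * co];
        gym(co, p) = v;
        s += v;
      }
      gb[co] += s;
    }
    gWm += cols * gym.t();
    arma::mat gcols = Wm * gym;  // K x P
    double* gxn = gx.begin() + (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          const int krow = i + kh * (j + kw * c);
          for (int ow = 0; ow < OW; ++ow) {
            const int win = ow * stride - pad + j * dil;
            if (win < 0 || win >= W) continue;
            double* gxcol = gxn + (size_t)H * (win + (size_t)W * c);
            for (int oh = 0; oh < OH; ++oh) {
              const int hin = oh * stride - pad + i * dil;
              if (hin >= 0 && hin < H) gxcol[hin] += gcols(krow, oh + OH * ow);
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution: y[s*h - p + i, s*w - p + j, co] += x[h,w,ci]*W[i,j,ci,co]
// [[Rcpp::export]]
NumericVector cpp_convt_fwd(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("convT: input has %d channels, kernel expects %d", C, Cin);
  const int OH = (H - 1) * stride - 2 * pad + kh;
  const int OW = (W - 1) * stride - 2 * pad + kw;
  if (OH <= 0 || OW <= 0) stop("convT: output size would be non-positive");

  NumericVector y((size_t)OH * OW * Cout * N);
  y.attr("dim") = IntegerVector::create(OH, OW, Cout, N);
  for (int n = 0; n < N; ++n) {
    double* yn = y.begin() + (size_t)OH * OW * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + (size_t)OH * OW * co;
      for (size_t p = 0; p < (size_t)OH * OW; ++p) yc[p] = b[co];
    }
    const double* xn = x.begin() + (size_t)H * W * C * n;
    for (int ci = 0; ci < C; ++ci) {
      for (int ww = 0; ww < W; ++ww) {
        for (int hh = 0; hh < H; ++hh) {
          const double xv = xn[hh + (size_t)H * (ww + (size_t)W * ci)];
          if (xv == 0.0) continue;
          for (int co = 0; co < Cout; ++co) {
            const double* wc = w.begin() + (size_t)kh * kw * (ci + (size_t)C * co);
            double* yc = yn + (size_t)OH * OW * co;
            for (int j = 0; j < kw; ++j) {
              const int ow = ww * stride - pad + j;
              if (ow < 0 || ow >= OW) continue;
              for (int i = 0; i < kh; ++i) {
                const int oh = hh * stride - pad + i;
                if (oh < 0 || oh >= OH) continue;
                yc[oh + (size_t)OH * ow] += xv * wc[i + (size_t)kh * j];
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt_bwd(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int OH = (H - 1) * stride - 2 * pad + kh;
  const int OW = (W - 1) * stride - 2 * pad + kw;

  NumericVector gx((size_t)H * W * C * N), gw(w.size()), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    const double* gyn = gy.begin() + (size_t)OH * OW * Cout * n;
    double* gxn = gx.begin() + (size_t)H * W * C * n;
    for (int co = 0; co < Cout; ++co) {
      const double* gyc = gyn + (size_t)OH * OW * co;
      double s = 0.0;
      for (size_t p = 0; p < (size_t)OH * OW; ++p) s += gyc[p];
      gb[co] += s;
    }
    for (int ci = 0; ci < C; ++ci) {
      for (int ww = 0; ww < W; ++ww) {
        for (int hh = 0; hh < H; ++hh) {
          const size_t xi = hh + (size_t)H * (ww + (size_t)W * ci);
          const double xv = xn[xi];
          double acc = 0.0;
          for (int co = 0; co < Cout; ++co) {
            const double* gyc = gyn + (size_t)OH * OW * co;
            const double* wc = w.begin() + (size_t)kh * kw * (ci + (size_t)C * co);
            double* gwc = gw.begin() + (size_t)kh * kw * (ci + (size_t)C * co);
            for (int j = 0; j < kw; ++j) {
              const int ow = ww * stride - pad + j;
              if (ow < 0 || ow >= OW) continue;
              for (int i = 0; i < kh; ++i) {
                const int oh = hh * stride - pad + i;
                if (oh < 0 || oh >= OH) continue;
                const double g = gyc[oh + (size_t)OH * ow];
                acc += g * wc[i + (size_t)kh * j];
                gwc[i + (size_t)kh * j] += g * xv;
              }
            }
          }
          gxn[xi] += acc;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
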