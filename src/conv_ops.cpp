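// Core dense tensor kernels: grouped/dilated 2-D convolution (forward and
// backward via im2col + GEMM) and windowed max/average pooling.
//
// Tensor layout throughout: column-major R arrays dim = c(H, W, C, N)
// (height fastest).  Convolution weights: dim = c(kh, kw, Cin/groups, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad, int dil) {
  int eff = (k - 1) * dil + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

// Gather one sample/group into column matrix K x P, K = kh*kw*cing,
// P = Ho*Wo, column p = ho + Ho*wo, row = khi + kh*(kwi + kw*ci).
static void im2col(const double* x, int H, int W, int cing, int c0,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int dh, int dw, int Ho, int Wo, arma::mat& col) {
  for (int ci = 0; ci < cing; ++ci) {
    const double* xc = x + (size_t)(c0 + ci) * H * W;
    for (int kwi = 0; kwi < kw; ++kwi) {
      for (int khi = 0; khi < kh; ++khi) {
        int row = khi + kh * (kwi + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * sw - pw + kwi * dw;
          double* dst = col.colptr(Ho * wo) + row; // stride K between cols
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) dst[(size_t)ho * col.n_rows] = 0.0;
          } else {
            const double* xcol = xc + (size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * sh - ph + khi * dh;
              dst[(size_t)ho * col.n_rows] =
                (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
            }
          }
        }
      }
    }
  }
}

// Scatter-add the column matrix back onto the (padded) input gradient.
static void col2im(const arma::mat& col, double* gx, int H, int W, int cing,
                   int c0, int kh, int kw, int sh, int sw, int ph, int pw,
                   int dh, int dw, int Ho, int Wo) {
  for (int ci = 0; ci < cing; ++ci) {
    double* gc = gx + (size_t)(c0 + ci) * H * W;
    for (int kwi = 0; kwi < kw; ++kwi) {
      for (int khi = 0; khi < kh; ++khi) {
        int row = khi + kh * (kwi + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * sw - pw + kwi * dw;
          if (wi < 0 || wi >= W) continue;
          const double* src = col.colptr(Ho * wo) + row;
          double* gcol = gc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * sh - ph + khi * dh;
            if (hi >= 0 && hi < H) gcol[hi] += src[(size_t)ho * col.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector bias, IntegerVector stride,
                             IntegerVector pad, IntegerVector dil,
                             int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], cing = wd[2], Cout = wd[3];
  int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  int dh = dil[0], dw = dil[1];
  if (Cin != cing * groups) stop("channel/group mismatch");
  int Ho = out_dim(H, kh, sh, ph, dh), Wo = out_dim(W, kw, sw, pw, dw);
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  int coutg = Cout / groups, K = kh * kw * cing, P = Ho * Wo;
  bool has_b = bias.size() > 0;

  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(K, P);
  for (int g = 0; g < groups; ++g) {
    // weight block for group g as K x coutg (each column contiguous)
    arma::mat Wg(const_cast<double*>(&w[0]) + (size_t)g * coutg * K, K, coutg,
                 false, true);
    for (int n = 0; n < N; ++n) {
      const double* xn = &x[0] + (size_t)n * H * W * Cin;
      im2col(xn, H, W, cing, g * cing, kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo,
             col);
      arma::mat res = col.t() * Wg; // P x coutg
      for (int c = 0; c < coutg; ++c) {
        double* yp = &y[0] +
          (size_t)n * Ho * Wo * Cout + (size_t)(g * coutg + c) * Ho * Wo;
        const double* rp = res.colptr(c);
        double b = has_b ? bias[g * coutg + c] : 0.0;
        for (int p = 0; p < P; ++p) yp[p] = rp[p] + b;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    IntegerVector stride, IntegerVector pad, IntegerVector dil,
                    int groups, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], cing = wd[2], Cout = wd[3];
  int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  int dh = dil[0], dw = dil[1];
  int Ho = out_dim(H, kh, sh, ph, dh), Wo = out_dim(W, kw, sw, pw, dw);
  int coutg = Cout / groups, K = kh * kw * cing, P = Ho * Wo;

  NumericVector gx(x.size()); gx.attr("dim") = xd;
  NumericVector gw(w.size()); gw.attr("dim") = wd;
  NumericVector gb(has_bias ? Cout : 0);
  arma::mat col(K, P), gyg(P, coutg);
  for (int g = 0; g < groups; ++g) {
    arma::mat Wg(const_cast<double*>(&w[0]) + (size_t)g * coutg * K, K, coutg,
                 false, true);
    arma::mat gWg(&gw[0] + (size_t)g * coutg * K, K, coutg, false, true);
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < coutg; ++c) {
        const double* gp = &gy[0] +
          (size_t)n * Ho * Wo * Cout + (size_t)(g * coutg + c) * Ho * Wo;
        std::copy(gp, gp + P, gyg.colptr(c));
        if (has_bias) gb[g * coutg + c] += arma::accu(gyg.col(c));
      }
      const double* xn = &x[0] + (size_t)n * H * W * Cin;
      im2col(xn, H, W, cing, g * cing, kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo,
             col);
      gWg += col * gyg;                    // K x coutg
      arma::mat gcol = Wg * gyg.t();       // K x P
      col2im(gcol, &gx[0] + (size_t)n * H * W * Cin, H, W, cing, g * cing, kh,
             kw, sh, sw, ph, pw, dh, dw, Ho, Wo);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Windowed pooling.  type 0 = max (argmax recorded, 1-based flat index into
// the H*W plane), 1 = average.
// [[Rcpp::export(name = ".cpp_pool2d_fwd")]]
List cpp_pool2d_fwd(NumericVector x, IntegerVector ksize, IntegerVector stride,
                    int type) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = ksize[0], kw = ksize[1], sh = stride[0], sw = stride[1];
  if (kh > H || kw > W) stop("pooling window larger than input");
  int Ho = (H - kh) / sh + 1, Wo = (W - kw) / sw + 1;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector am(type == 0 ? y.size() : 0);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = &x[0] + ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -INFINITY, acc = 0.0; int bi = 0;
          for (int j = 0; j < kw; ++j)
            for (int i = 0; i < kh; ++i) {
              int hi = ho * sh + i, wi = wo * sw + j;
              double v = xp[hi + (size_t)wi * H];
              if (type == 0) { if (v > best) { best = v; bi = hi + wi * H; } }
              else acc += v;
            }
          size_t oi = (size_t)n * C * Ho * Wo + (size_t)c * Ho * Wo +
            ho + (size_t)Ho * wo;
          if (type == 0) { y[oi] = best; am[oi] = bi + 1; }
          else y[oi] = acc / (kh * kw);
          ++o;
        }
    }
  if (type == 0) return List::create(_["y"] = y, _["argmax"] = am);
  return List::create(_["y"] = y);
}

// [[Rcpp::export(name = ".cpp_pool2d_bwd")]]
NumericVector cpp_pool2d_bwd(NumericVector gy, IntegerVector xdim,
                             IntegerVector ksize, IntegerVector stride,
                             int type, IntegerVector argmax) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int kh = ksize[0], kw = ksize[1], sh = stride[0], sw = stride[1];
  int Ho = (H - kh) / sh + 1, Wo = (W - kw) / sw + 1;
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* gp = &gx[0] + ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t oi = (size_t)n * C * Ho * Wo + (size_t)c * Ho * Wo +
            ho + (size_t)Ho * wo;
          double g = gy[oi];
          if (type == 0) gp[argmax[oi] - 1] += g;
          else {
            double gavg = g / (kh * kw);
            for (int j = 0; j < kw; ++j)
              for (int i = 0; i < kh; ++i)
                gp[(ho * sh + i) + (size_t)(wo * sw + j) * H] += gavg;
          }
        }
    }
  return gx;
}
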