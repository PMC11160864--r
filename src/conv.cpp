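// Minimal 2-D convolution kernels (im2col + GEMM) for the autodiff tape.
// Tensor layout everywhere: H x W x C x B, column-major (R array order).
// Weights: KH x KW x Cin x Cout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill the patch matrix M (Ho*Wo*B) x (KH*KW*Cin); row order (ho, wo, b),
// column order (kh, kw, c) to match the R flattening of the weight array.
static void im2col(const double* x, int H, int W, int C, int B,
                   int KH, int KW, int stride, int pad, arma::mat& M) {
  const int Ho = out_size(H, KH, stride, pad);
  const int Wo = out_size(W, KW, stride, pad);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x + (std::size_t)H * W * (c + (std::size_t)C * b);
      for (int kw = 0; kw < KW; ++kw) {
        for (int kh = 0; kh < KH; ++kh) {
          const int col = kh + KH * (kw + KW * c);
          double* Mcol = M.colptr(col);
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride + kw - pad;
            const std::size_t rbase = (std::size_t)Ho * (wo + (std::size_t)Wo * b);
            if (w < 0 || w >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride + kh - pad;
              if (h < 0 || h >= H) continue;
              Mcol[rbase + ho] = xc[h + (std::size_t)H * w];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fwd(NumericVector x, NumericVector w, NumericVector bias,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels but weight expects %d", C, Cin);
  const int Ho = out_size(H, KH, stride, pad), Wo = out_size(W, KW, stride, pad);

  arma::mat M((std::size_t)Ho * Wo * B, (std::size_t)KH * KW * Cin, arma::fill::zeros);
  im2col(x.begin(), H, W, C, B, KH, KW, stride, pad, M);
  const arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)KH * KW * Cin, Cout, false, true);
  arma::mat Y = M * Wm;  // (Ho*Wo*B) x Cout

  NumericVector out((std::size_t)Ho * Wo * Cout * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  double* yp = out.begin();
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Cout; ++co) {
      const double* src = Y.colptr(co) + (std::size_t)Ho * Wo * b;
      double* dst = yp + (std::size_t)Ho * Wo * (co + (std::size_t)Cout * b);
      const double bv = bias[co];
      for (std::size_t i = 0; i < (std::size_t)Ho * Wo; ++i) dst[i] = src[i] + bv;
    }
  return out;
}

// [[Rcpp::export]]
List nn_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];

  // dY reordered to (Ho*Wo*B) x Cout
  arma::mat dYm((std::size_t)Ho * Wo * B, Cout);
  const double* dyp = dy.begin();
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Cout; ++co) {
      const double* src = dyp + (std::size_t)Ho * Wo * (co + (std::size_t)Cout * b);
      double* dst = dYm.colptr(co) + (std::size_t)Ho * Wo * b;
      std::copy(src, src + (std::size_t)Ho * Wo, dst);
    }

  arma::mat M((std::size_t)Ho * Wo * B, (std::size_t)KH * KW * Cin, arma::fill::zeros);
  im2col(x.begin(), H, W, C, B, KH, KW, stride, pad, M);
  const arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)KH * KW * Cin, Cout, false, true);

  arma::mat dW = M.t() * dYm;           // (KH*KW*Cin) x Cout
  arma::rowvec db = arma::sum(dYm, 0);  // 1 x Cout
  arma::mat dM = dYm * Wm.t();          // col2im scatter-add below

  NumericVector dx((std::size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  double* dxp = dx.begin();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      double* xc = dxp + (std::size_t)H * W * (c + (std::size_t)C * b);
      for (int kw = 0; kw < KW; ++kw) {
        for (int kh = 0; kh < KH; ++kh) {
          const int col = kh + KH * (kw + KW * c);
          const double* Mcol = dM.colptr(col);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wpos = wo * stride + kw - pad;
            if (wpos < 0 || wpos >= W) continue;
            const std::size_t rbase = (std::size_t)Ho * (wo + (std::size_t)Wo * b);
            for (int ho = 0; ho < Ho; ++ho) {
              const int hpos = ho * stride + kh - pad;
              if (hpos < 0 || hpos >= H) continue;
              xc[hpos + (std::size_t)H * wpos] += Mcol[rbase + ho];
            }
          }
        }
      }
    }
  }

  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = IntegerVector::create(KH, KW, Cin, Cout);
  NumericVector dbv(db.begin(), db.end());
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}
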