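// im2col-based 2-D convolution kernels for the training engine.
// Array layout follows R column-major conventions throughout:
//   images  (H, W, C, N)
//   filters (kh, kw, Cin, Cout)
// "Valid" region handling is left to the caller, which supplies the top/left
// zero-padding (pt, pl) and output spatial size (Ho, Wo) for same-padding
// strided convolutions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather padded k x k patches of one image into a (kh*kw*C) x (Ho*Wo) matrix.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int s, int pt, int pl,
                   int Ho, int Wo, arma::mat& cols) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = wo * Ho + ho;
      const int hi0 = ho * s - pt, wi0 = wo * s - pl;
      double* dst = cols.colptr(p);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wi0 + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = hi0 + ki;
            dst[ki + kh * (kj + kw * c)] =
              (hi >= 0 && hi < H && wi >= 0 && wi < W)
                ? x[hi + (size_t)H * (wi + (size_t)W * c)] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add a (kh*kw*C) x (Ho*Wo) gradient matrix back onto one image.
static void col2im(const arma::mat& cols, double* dx, int H, int W, int C,
                   int kh, int kw, int s, int pt, int pl, int Ho, int Wo) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = wo * Ho + ho;
      const int hi0 = ho * s - pt, wi0 = wo * s - pl;
      const double* src = cols.colptr(p);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wi0 + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = hi0 + ki;
            if (hi < 0 || hi >= H) continue;
            dx[hi + (size_t)H * (wi + (size_t)W * c)] +=
              src[ki + kh * (kj + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w,
                           int stride, int pt, int pl, int Ho, int Wo) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  if (dw[2] != C) stop("filter input channels do not match image channels");
  const int K = kh * kw * C, P = Ho * Wo;
  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector out((size_t)P * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
           kh, kw, stride, pt, pl, Ho, Wo, cols);
    arma::mat y(out.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    y = cols.t() * Wm;
  }
  return out;
}

// Gradient w.r.t. the convolution input; also the forward pass of the
// matching transposed convolution (the adjoint operator).
// [[Rcpp::export]]
NumericVector cpp_conv_bwd_input(NumericVector dy, NumericVector w,
                                 int stride, int pt, int pl, int H, int W) {
  IntegerVector dd = dy.attr("dim"), dw = w.attr("dim");
  const int Ho = dd[0], Wo = dd[1], Cout = dd[2], N = dd[3];
  const int kh = dw[0], kw = dw[1], C = dw[2];
  if (dw[3] != Cout) stop("filter output channels do not match gradient channels");
  const int K = kh * kw * C, P = Ho * Wo;
  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector out((size_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat cols(K, P);
  for (int n = 0; n < N; ++n) {
    arma::mat g(dy.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    cols = Wm * g.t();
    col2im(cols, out.begin() + (size_t)H * W * C * n, H, W, C,
           kh, kw, stride, pt, pl, Ho, Wo);
  }
  return out;
}

// Gradient w.r.t. the filters, accumulated over the batch.
// [[Rcpp::export]]
NumericVector cpp_conv_bwd_filter(NumericVector x, NumericVector dy,
                                  int kh, int kw, int stride, int pt, int pl) {
  IntegerVector dx = x.attr("dim"), dd = dy.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = dd[0], Wo = dd[1], Cout = dd[2];
  if (dd[3] != N) stop("batch sizes differ between input and gradient");
  const int K = kh * kw * C, P = Ho * Wo;
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::mat cols(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
           kh, kw, stride, pt, pl, Ho, Wo, cols);
    arma::mat g(dy.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    dW += cols * g;
  }
  NumericVector out(dW.begin(), dW.end());
  out.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  return out;
}
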