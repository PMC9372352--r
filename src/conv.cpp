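// 2D convolution primitives for the VB-Net layers.
//
// Tensor layout (column-major R arrays):
//   activations: (H, W, C, N)
//   weights:     (kh, kw, C_in, C_out)
// The three primitives below (forward, gradient w.r.t. input, gradient
// w.r.t. weights) also realize transposed convolution: its forward pass is
// conv_grad_input_cpp and its backward passes reuse conv_fwd_cpp /
// conv_grad_weight_cpp with the argument roles swapped.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather input patches into a (kh*kw*C) x (oH*oW) matrix.  Row ordering
// matches the column-major flattening of the weight array.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int oH, int oW, arma::mat& M) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * c);
        for (int ow = 0; ow < oW; ++ow) {
          int w0 = ow * stride - pad + j;
          if (w0 < 0 || w0 >= W) {
            for (int oh = 0; oh < oH; ++oh) M(row, oh + oH * ow) = 0.0;
            continue;
          }
          const double* col = xc + (size_t)H * w0;
          for (int oh = 0; oh < oH; ++oh) {
            int h0 = oh * stride - pad + i;
            M(row, oh + oH * ow) = (h0 < 0 || h0 >= H) ? 0.0 : col[h0];
          }
        }
      }
  }
}

// Scatter-add a (kh*kw*C) x (oH*oW) matrix back onto the input grid.
static void col2im(const arma::mat& M, double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad, int oH, int oW) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * c);
        for (int ow = 0; ow < oW; ++ow) {
          int w0 = ow * stride - pad + j;
          if (w0 < 0 || w0 >= W) continue;
          double* col = xc + (size_t)H * w0;
          for (int oh = 0; oh < oH; ++oh) {
            int h0 = oh * stride - pad + i;
            if (h0 >= 0 && h0 < H) col[h0] += M(row, oh + oH * ow);
          }
        }
      }
  }
}

// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch between input and weights");
  int oH = out_size(H, kh, stride, pad), oW = out_size(W, kw, stride, pad);
  NumericVector out((R_xlen_t)oH * oW * Cout * N);
  out.attr("dim") = IntegerVector::create(oH, oW, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * C, Cout,
               false, true);
  arma::mat M((size_t)kh * kw * C, (size_t)oH * oW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           oH, oW, M);
    arma::mat O(out.begin() + (size_t)oH * oW * Cout * n, (size_t)oH * oW,
                Cout, false, true);
    O = M.t() * Wm;
    if (b.size() == Cout)
      for (int co = 0; co < Cout; ++co) O.col(co) += b[co];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector conv_grad_input_cpp(NumericVector gout, NumericVector w,
                                  int stride, int pad, int inH, int inW) {
  IntegerVector gd = gout.attr("dim"), wd = w.attr("dim");
  int oH = gd[0], oW = gd[1], Cout = gd[2], N = gd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2];
  if (wd[3] != Cout) stop("channel mismatch between gradient and weights");
  NumericVector gin((R_xlen_t)inH * inW * Cin * N);
  gin.attr("dim") = IntegerVector::create(inH, inW, Cin, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout,
               false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat G(const_cast<double*>(gout.begin()) + (size_t)oH * oW * Cout * n,
                (size_t)oH * oW, Cout, false, true);
    arma::mat M = Wm * G.t();
    col2im(M, gin.begin() + (size_t)inH * inW * Cin * n, inH, inW, Cin,
           kh, kw, stride, pad, oH, oW);
  }
  return gin;
}

// [[Rcpp::export]]
NumericVector conv_grad_weight_cpp(NumericVector x, NumericVector gout,
                                   int kh, int kw, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), gd = gout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int oH = gd[0], oW = gd[1], Cout = gd[2];
  NumericVector gw((R_xlen_t)kh * kw * C * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  arma::mat GW(gw.begin(), (size_t)kh * kw * C, Cout, false, true);
  arma::mat M((size_t)kh * kw * C, (size_t)oH * oW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           oH, oW, M);
    arma::mat G(const_cast<double*>(gout.begin()) + (size_t)oH * oW * Cout * n,
                (size_t)oH * oW, Cout, false, true);
    GW += M * G;
  }
  return gw;
}
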