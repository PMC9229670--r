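#include <Rcpp.h>
using namespace Rcpp;

// Patch-matrix extraction for 2D convolution on an (H, W, C) array.
//
// Row p of the result corresponds to output pixel p in column-major order
// (row index fastest); column k = ki + kh*kj + kh*kw*c matches the
// column-major flattening of a weight array with dim (kh, kw, Cin, Cout),
// so conv forward is  matrix(im2col(x)) %*% matrix(W, kh*kw*Cin, Cout).
// Out-of-image taps read as zero (zero padding).

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int kh, int kw, int sh, int sw,
                         int pt, int pl, int Ho, int Wo) {
  const int N = Ho * Wo, K = kh * kw * C;
  NumericMatrix out(N, K);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double *plane = px + (R_xlen_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * kj + kh * kw * c;
        double *pout = &out(0, col);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * sw - pl + kj;
          if (wi < 0 || wi >= W) continue;
          const double *colsrc = plane + (R_xlen_t)wi * H;
          double *pdst = pout + (R_xlen_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * sh - pt + ki;
            if (hi >= 0 && hi < H) pdst[ho] = colsrc[hi];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add patch rows back into an (H, W, C)
// array. Used for conv input gradients and transposed-conv forward passes.

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int sh, int sw,
                         int pt, int pl, int Ho, int Wo) {
  NumericVector x((R_xlen_t)H * W * C);
  double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    double *plane = px + (R_xlen_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * kj + kh * kw * c;
        const double *pin = &cols(0, col);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * sw - pl + kj;
          if (wi < 0 || wi >= W) continue;
          double *coldst = plane + (R_xlen_t)wi * H;
          const double *psrc = pin + (R_xlen_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * sh - pt + ki;
            if (hi >= 0 && hi < H) coldst[hi] += psrc[ho];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}
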