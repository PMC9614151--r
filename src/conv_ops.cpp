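// Hot loops of the 1-D convolution layers. The stacked activation layout is
// a (B*L) x C matrix with row (b-1)*L + t. im2col lays the k zero-padded
// shifts side by side as (B*L) x (C*k) for a single GEMM; col2im is its
// adjoint, scattering column blocks back onto input positions. Doing these
// in C++ avoids large intermediate copies in R.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& X, int B, int L, int C, int k) {
  const int p = (k - 1) / 2;
  // allocated uninitialized: every entry is either copied from X below or
  // explicitly zeroed at the sequence edges
  NumericMatrix out(Rcpp::no_init(B * L, C * k));
  for (int j = 0; j < k; ++j) {
    const int off = j - p;                  // source offset of shift j
    const int t_lo = std::max(0, -off);    // valid output positions (0-based)
    const int t_hi = std::min(L, L - off);
    for (int c = 0; c < C; ++c) {
      const double* src = &X(0, c);
      double* dst = &out(0, j * C + c);
      for (int b = 0; b < B; ++b) {
        const int base = b * L;
        for (int t = 0; t < t_lo; ++t) dst[base + t] = 0.0;
        for (int t = t_lo; t < t_hi; ++t) dst[base + t] = src[base + t + off];
        for (int t = t_hi; t < L; ++t) dst[base + t] = 0.0;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dXcol, int B, int L, int C,
                         int k) {
  const int p = (k - 1) / 2;
  NumericMatrix out(B * L, C);
  for (int j = 0; j < k; ++j) {
    const int off = j - p;
    const int t_lo = std::max(0, -off);
    const int t_hi = std::min(L, L - off);
    for (int c = 0; c < C; ++c) {
      const double* src = &dXcol(0, j * C + c);
      double* dst = &out(0, c);
      for (int b = 0; b < B; ++b) {
        const int base = b * L;
        for (int t = t_lo; t < t_hi; ++t) {
          dst[base + t + off] += src[base + t];
        }
      }
    }
  }
  return out;
}
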