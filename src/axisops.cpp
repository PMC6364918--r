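#include <Rcpp.h>
using namespace Rcpp;

// Circular (periodic) convolution / correlation along one axis of an
// n-dimensional array, with an a-trous dilated kernel.
//
// Convolution:   y[i] = sum_k a[k] * x[(i - s*(off+k)) mod len]
// Correlation:   y[i] = sum_k a[k] * x[(i + s*(off+k)) mod len]
// where s is the dilation stride (2^(l-1) at level l) and off the
// support offset of the first tap. Correlation is the exact adjoint of
// convolution with the same kernel, which is what the frame transpose
// W' needs.
//
// [[Rcpp::export(name = ".axisFilter")]]
NumericVector axisFilter(NumericVector x, IntegerVector dim,
                         NumericVector kernel, int offset,
                         int axis, int dilation, bool adjoint) {
  const int nd = dim.size();
  if (axis < 1 || axis > nd) stop("axis out of range");
  R_xlen_t n = 1;
  for (int i = 0; i < nd; ++i) n *= dim[i];
  if (n != x.size()) stop("dim does not match length of x");
  const int len = dim[axis - 1];
  const int nk = kernel.size();

  R_xlen_t stride = 1;
  for (int i = 0; i < axis - 1; ++i) stride *= dim[i];
  const R_xlen_t block = stride * len;
  const R_xlen_t nblocks = n / block;

  // Precompute, for each in-axis position i and tap k, the wrapped
  // source position; shifts only depend on (i, k).
  std::vector<int> shift(nk);
  for (int k = 0; k < nk; ++k) {
    long s = (long)dilation * (offset + k);
    s %= len;
    if (adjoint) s = -s;
    // convolution reads at i - s
    long m = ((long)s % len + len) % len;
    shift[k] = (int)m;
  }

  NumericVector y(n);
  const double *px = x.begin();
  double *py = y.begin();
  for (R_xlen_t b = 0; b < nblocks; ++b) {
    const R_xlen_t base = b * block;
    for (int k = 0; k < nk; ++k) {
      const double a = kernel[k];
      if (a == 0.0) continue;
      const int sh = shift[k];
      for (int i = 0; i < len; ++i) {
        int src = i - sh;
        if (src < 0) src += len;
        const double *xs = px + base + (R_xlen_t)src * stride;
        double *yd = py + base + (R_xlen_t)i * stride;
        for (R_xlen_t s = 0; s < stride; ++s) yd[s] += a * xs[s];
      }
    }
  }
  y.attr("dim") = dim;
  return y;
}
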