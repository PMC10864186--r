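#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Separable 2-D convolution with an odd symmetric 1-D kernel and
// replicate (clamp-to-edge) boundaries.  All smoothing kernels in this
// package are Gaussians, so the two-pass separable form is exact and far
// cheaper than a full 2-D convolution.
// One box-blur pass of radius r (window 2r+1) with replicate boundaries,
// separable and computed with running sums: O(1) per pixel regardless of
// radius.  Three passes approximate a wide Gaussian closely enough for
// the flow regularizer.
// [[Rcpp::export]]
NumericMatrix boxconv_replicate_cpp(NumericMatrix img, int r) {
  const int h = img.nrow(), w = img.ncol();
  const double norm = 1.0 / (2 * r + 1);
  NumericMatrix tmp(h, w), out(h, w);
  for (int j = 0; j < w; ++j) {
    double s = 0.0;
    for (int t = -r; t <= r; ++t) {
      int ii = t < 0 ? 0 : (t >= h ? h - 1 : t);
      s += img(ii, j);
    }
    for (int i = 0; i < h; ++i) {
      tmp(i, j) = s * norm;
      int add = i + r + 1; if (add >= h) add = h - 1;
      int rem = i - r; if (rem < 0) rem = 0;
      s += img(add, j) - img(rem, j);
    }
  }
  for (int i = 0; i < h; ++i) {
    double s = 0.0;
    for (int t = -r; t <= r; ++t) {
      int jj = t < 0 ? 0 : (t >= w ? w - 1 : t);
      s += tmp(i, jj);
    }
    for (int j = 0; j < w; ++j) {
      out(i, j) = s * norm;
      int add = j + r + 1; if (add >= w) add = w - 1;
      int rem = j - r; if (rem < 0) rem = 0;
      s += tmp(i, add) - tmp(i, rem);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix sepconv_replicate_cpp(NumericMatrix img, NumericVector k) {
  const int h = img.nrow(), w = img.ncol();
  const int r = (k.size() - 1) / 2;
  NumericMatrix tmp(h, w), out(h, w);
  // vertical pass (along rows within a column)
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double s = 0.0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0; else if (ii >= h) ii = h - 1;
        s += k[t + r] * img(ii, j);
      }
      tmp(i, j) = s;
    }
  }
  // horizontal pass
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      double s = 0.0;
      for (int t = -r; t <= r; ++t) {
        int jj = j + t;
        if (jj < 0) jj = 0; else if (jj >= w) jj = w - 1;
        s += k[t + r] * tmp(i, jj);
      }
      out(i, j) = s;
    }
  }
  return out;
}
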