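// Minimal float32 convolution kernels for the frozen CNN backbones.
// Feature maps are H x W x C arrays (R column-major); weights arrive as
// (k*k*Cin) x Cout matrices whose row order matches R's flattening of a
// k x k x Cin array (row index fastest).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static fcube as_fcube(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  fcube out(d[0], d[1], d[2]);
  const double* p = x.begin();
  std::copy(p, p + x.size(), out.memptr());
  return out;
}

static Rcpp::NumericVector as_r_array(const fcube& x) {
  Rcpp::NumericVector out(x.n_elem);
  std::copy(x.memptr(), x.memptr() + x.n_elem, out.begin());
  out.attr("dim") = Rcpp::IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

// [[Rcpp::export(name = ".cpp_conv2d")]]
Rcpp::NumericVector cpp_conv2d(Rcpp::NumericVector x_, Rcpp::NumericMatrix w_,
                               int k, int stride, int pad) {
  fcube x = as_fcube(x_);
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int cout = w_.ncol();
  const int h2 = (h + 2 * pad - k) / stride + 1;
  const int w2 = (w + 2 * pad - k) / stride + 1;

  fmat W(w_.nrow(), cout);
  std::copy(w_.begin(), w_.end(), W.memptr());

  fcube out(h2, w2, cout);
  fmat res((float*)out.memptr(), (size_t)h2 * w2, cout, false, true);

  if (k == 1 && stride == 1 && pad == 0) {
    // pointwise convolution: plain GEMM on the channel matrix
    const fmat X((float*)x.memptr(), (size_t)h * w, cin, false, true);
    res = X * W;
    return as_r_array(out);
  }

  // im2col with contiguous k-long copies per (pixel, channel, kj)
  fmat patches(k * k * cin, (size_t)h2 * w2, fill::zeros);
  const int prow = patches.n_rows;
  for (int oj = 0; oj < w2; ++oj) {
    for (int oi = 0; oi < h2; ++oi) {
      float* col = patches.colptr((size_t)oj * h2 + oi);
      const int si0 = oi * stride - pad;
      const int lo = std::max(0, -si0), hi = std::min(k, h - si0);
      if (lo >= hi) continue;
      for (int c = 0; c < cin; ++c) {
        const fmat& plane = x.slice(c);
        for (int kj = 0; kj < k; ++kj) {
          const int sj = oj * stride + kj - pad;
          if (sj < 0 || sj >= w) continue;
          const float* src = plane.colptr(sj) + si0 + lo;
          std::copy(src, src + (hi - lo), col + c * k * k + kj * k + lo);
        }
      }
    }
  }
  res = patches.t() * W;
  (void)prow;
  return as_r_array(out);
}

// [[Rcpp::export(name = ".cpp_depthwise")]]
Rcpp::NumericVector cpp_depthwise(Rcpp::NumericVector x_, Rcpp::NumericMatrix w_,
                                  int k, int stride, int pad) {
  fcube x = as_fcube(x_);
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int h2 = (h + 2 * pad - k) / stride + 1;
  const int w2 = (w + 2 * pad - k) / stride + 1;
  fcube out(h2, w2, c, fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    const fmat& plane = x.slice(ch);
    fmat& osl = out.slice(ch);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const float wv = (float)w_(kj * k + ki, ch);
        if (wv == 0.0f) continue;
        for (int oj = 0; oj < w2; ++oj) {
          const int sj = oj * stride + kj - pad;
          if (sj < 0 || sj >= w) continue;
          for (int oi = 0; oi < h2; ++oi) {
            const int si = oi * stride + ki - pad;
            if (si >= 0 && si < h) osl(oi, oj) += wv * plane(si, sj);
          }
        }
      }
    }
  }
  return as_r_array(out);
}

// [[Rcpp::export(name = ".cpp_pool")]]
Rcpp::NumericVector cpp_pool(Rcpp::NumericVector x_, int k, int stride,
                             int pad, bool use_max) {
  fcube x = as_fcube(x_);
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int h2 = (h + 2 * pad - k) / stride + 1;
  const int w2 = (w + 2 * pad - k) / stride + 1;
  fcube out(h2, w2, c);
  for (int ch = 0; ch < c; ++ch) {
    const fmat& plane = x.slice(ch);
    fmat& osl = out.slice(ch);
    for (int oj = 0; oj < w2; ++oj) {
      for (int oi = 0; oi < h2; ++oi) {
        float acc = use_max ? -std::numeric_limits<float>::infinity() : 0.0f;
        int n = 0;
        for (int kj = 0; kj < k; ++kj) {
          const int sj = oj * stride + kj - pad;
          if (sj < 0 || sj >= w) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int si = oi * stride + ki - pad;
            if (si < 0 || si >= h) continue;
            const float v = plane(si, sj);
            if (use_max) acc = std::max(acc, v); else acc += v;
            ++n;
          }
        }
        osl(oi, oj) = use_max ? acc : (n > 0 ? acc / n : 0.0f);
      }
    }
  }
  return as_r_array(out);
}
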