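#include <Rcpp.h>
using namespace Rcpp;

// Image batches are laid out (H, W, N, C), column-major.  im2col unrolls
// k x k receptive fields into a (k*k*C) x (Ho*Wo*N) matrix whose row index
// runs (kh, kw, c) fastest-first and whose column index runs (ho, wo, n),
// so a convolution is crossprod(cols, Wmat) with Wmat of shape (k*k*Cin,
// Cout).  Zero padding.

// [[Rcpp::export(name = ".im2col")]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int nrow = k * k * C, ncol = Ho * Wo * N;
  NumericMatrix out(nrow, ncol);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const double *plane = px + (size_t)H * W * (n + (size_t)N * c);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
          double *pcol = po + col * nrow + (size_t)k * k * c;
          const int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            if (w < 0 || w >= W) {
              for (int kh = 0; kh < k; ++kh) pcol[kh + k * kw] = 0.0;
              continue;
            }
            const double *pw = plane + (size_t)H * w;
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              pcol[kh + k * kw] = (h >= 0 && h < H) ? pw[h] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-adds patch columns back into an (H, W, N, C)
// image.  Used for convolution input gradients and the forward pass of
// transposed convolution.

// [[Rcpp::export(name = ".col2im")]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((size_t)H * W * N * C);
  const int nrow = k * k * C;
  const double *pc = cols.begin();
  double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      double *plane = px + (size_t)H * W * (n + (size_t)N * c);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
          const double *pcol = pc + col * nrow + (size_t)k * k * c;
          const int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            if (w < 0 || w >= W) continue;
            double *pw = plane + (size_t)H * w;
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              if (h >= 0 && h < H) pw[h] += pcol[kh + k * kw];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, N, C);
  return x;
}

// Bilinear sampling of a single-channel image at arbitrary (row, col)
// coordinates (1-based, clamped to the image border).  Backbone of the
// smooth random warp in the degradation model and of resampling helpers.

// [[Rcpp::export(name = ".bilinearSample")]]
NumericVector bilinear_sample_cpp(NumericMatrix img, NumericVector rows,
                                  NumericVector cols) {
  const int H = img.nrow(), W = img.ncol();
  const R_xlen_t n = rows.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double r = rows[i] - 1.0, c = cols[i] - 1.0;
    if (r < 0) r = 0; if (r > H - 1) r = H - 1;
    if (c < 0) c = 0; if (c > W - 1) c = W - 1;
    const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    const int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
    const double fr = r - r0, fc = c - c0;
    out[i] = (1 - fr) * (1 - fc) * img(r0, c0) + fr * (1 - fc) * img(r1, c0)
           + (1 - fr) * fc * img(r0, c1) + fr * fc * img(r1, c1);
  }
  return out;
}

// In-place Adam update with bias correction; buffers m and v are modified
// alongside the parameter values.  gradScale undoes static loss scaling.

// [[Rcpp::export(name = ".adamUpdate")]]
void adam_update_cpp(NumericVector val, NumericVector grad, NumericVector m,
                     NumericVector v, int t, double lr, double beta1,
                     double beta2, double eps, double gradScale) {
  const R_xlen_t n = val.size();
  const double c1 = 1.0 - std::pow(beta1, t), c2 = 1.0 - std::pow(beta2, t);
  double *pv = val.begin(), *pm = m.begin(), *pvv = v.begin();
  const double *pg = grad.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double g = pg[i] / gradScale;
    pm[i] = beta1 * pm[i] + (1.0 - beta1) * g;
    pvv[i] = beta2 * pvv[i] + (1.0 - beta2) * g * g;
    pv[i] -= lr * (pm[i] / c1) / (std::sqrt(pvv[i] / c2) + eps);
  }
}
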