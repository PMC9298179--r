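// 2-D convolution kernels for the generator/discriminator stacks.
// Tensor layout follows R column-major arrays dimensioned (H, W, C, B):
// element (h, w, c, b) sits at h + H*(w + W*(c + C*b)).
// Zero padding; im2col (patch-major) + GEMM via Armadillo:
//   At  : (Ho*Wo) x (Cin*k*k), row index ho + Ho*wo, col index kh + k*(kw + k*c)
//   Wt  : (Cin*k*k) x Cout
//   Y   = At * Wt : (Ho*Wo) x Cout  — exactly the (Ho, Wo, Cout) output layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// valid output range [lo, hi) for which in = out*stride - pad + koff lies in [0, n)
static inline void valid_range(int n, int stride, int pad, int koff,
                               int nout, int& lo, int& hi) {
  lo = (pad - koff + stride - 1) / stride;   // ceil((pad - koff)/stride)
  if (lo < 0) lo = 0;
  hi = (n - 1 + pad - koff) / stride + 1;    // floor((n-1+pad-koff)/stride) + 1
  if (hi > nout) hi = nout;
  if (hi < lo) hi = lo;
}

// Patch-major im2col for one batch item.
static void im2col_t(const double* x, int H, int W, int C,
                     int k, int stride, int pad, arma::mat& At) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  At.zeros((arma::uword)Ho * Wo, (arma::uword)C * k * k);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (arma::uword)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      int wlo, whi;
      valid_range(W, stride, pad, kw, Wo, wlo, whi);
      for (int kh = 0; kh < k; ++kh) {
        const arma::uword r = (arma::uword)kh + k * ((arma::uword)kw + k * c);
        double* col = At.colptr(r);
        int hlo, hhi;
        valid_range(H, stride, pad, kh, Ho, hlo, hhi);
        for (int wo = wlo; wo < whi; ++wo) {
          const int w = wo * stride - pad + kw;
          const double* src = xc + (arma::uword)H * w + (hlo * stride - pad + kh);
          double* dst = col + (arma::uword)Ho * wo + hlo;
          const int nrun = hhi - hlo;
          if (stride == 1) {
            std::copy(src, src + nrun, dst);
          } else {
            for (int i = 0; i < nrun; ++i) dst[i] = src[(arma::uword)i * stride];
          }
        }
      }
    }
  }
}

// Transpose of im2col_t: scatter-add patch-major columns back into x.
static void col2im_t(const arma::mat& At, int H, int W, int C,
                     int k, int stride, int pad, double* x) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (arma::uword)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      int wlo, whi;
      valid_range(W, stride, pad, kw, Wo, wlo, whi);
      for (int kh = 0; kh < k; ++kh) {
        const arma::uword r = (arma::uword)kh + k * ((arma::uword)kw + k * c);
        const double* col = At.colptr(r);
        int hlo, hhi;
        valid_range(H, stride, pad, kh, Ho, hlo, hhi);
        for (int wo = wlo; wo < whi; ++wo) {
          const int w = wo * stride - pad + kw;
          double* dst = xc + (arma::uword)H * w + (hlo * stride - pad + kh);
          const double* src = col + (arma::uword)Ho * wo + hlo;
          const int nrun = hhi - hlo;
          if (stride == 1) {
            for (int i = 0; i < nrun; ++i) dst[i] += src[i];
          } else {
            for (int i = 0; i < nrun; ++i) dst[(arma::uword)i * stride] += src[i];
          }
        }
      }
    }
  }
}

// Weights (k, k, Cin, Cout) -> Wt (Cin*k*k) x Cout. The R array layout
// kh + k*(kw + k*(ci + Cin*co)) already matches the patch row order, so
// Wt is just a reshape (no copy needed beyond the view).
static arma::mat weight_t(const NumericVector& w, int k, int Cin, int Cout) {
  return arma::mat(const_cast<double*>(w.begin()),
                   (arma::uword)k * k * Cin, (arma::uword)Cout,
                   false, true);
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector y((R_xlen_t)Ho * Wo * Cout * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  arma::mat Wt = weight_t(w, k, Cin, Cout);
  arma::rowvec bias(b.begin(), Cout);
  arma::mat At;
  for (int bi = 0; bi < B; ++bi) {
    im2col_t(x.begin() + (R_xlen_t)H * W * C * bi, H, W, C, k, stride, pad, At);
    arma::mat Y(y.begin() + (R_xlen_t)Ho * Wo * Cout * bi,
                (arma::uword)Ho * Wo, (arma::uword)Cout, false, true);
    Y = At * Wt;
    Y.each_row() += bias;
  }
  return y;
}

// Returns list(gx, gw, gb). gy has dim (Ho, Wo, Cout, B).
// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  arma::mat Wt = weight_t(w, k, Cin, Cout);

  NumericVector gx((R_xlen_t)H * W * C * B);
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  arma::mat GW((arma::uword)k * k * Cin, (arma::uword)Cout, arma::fill::zeros);
  arma::rowvec GB((arma::uword)Cout, arma::fill::zeros);

  arma::mat At, Gcol;
  for (int bi = 0; bi < B; ++bi) {
    const arma::mat Gy(const_cast<double*>(gy.begin()) + (R_xlen_t)Ho * Wo * Cout * bi,
                       (arma::uword)Ho * Wo, (arma::uword)Cout, false, true);
    im2col_t(x.begin() + (R_xlen_t)H * W * C * bi, H, W, C, k, stride, pad, At);
    GW += At.t() * Gy;
    GB += arma::sum(Gy, 0);
    Gcol = Gy * Wt.t();                      // (Ho*Wo) x (Cin*k*k)
    col2im_t(Gcol, H, W, C, k, stride, pad,
             gx.begin() + (R_xlen_t)H * W * C * bi);
  }

  NumericVector gwv((R_xlen_t)k * k * Cin * Cout);
  gwv.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  std::copy(GW.begin(), GW.end(), gwv.begin());
  NumericVector gbv(Cout);
  std::copy(GB.begin(), GB.end(), gbv.begin());
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

// Gradient w.r.t. input only (frozen weights: the perceptual extractor and
// the generator's adversarial path through the discriminator).
// [[Rcpp::export(name = ".conv2d_bwd_input")]]
NumericVector conv2d_bwd_input(NumericVector w, NumericVector gy,
                               int stride, int pad, int H, int W) {
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1], B = gd[3];
  arma::mat Wt = weight_t(w, k, Cin, Cout);
  NumericVector gx((R_xlen_t)H * W * Cin * B);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, B);
  arma::mat Gcol;
  for (int bi = 0; bi < B; ++bi) {
    const arma::mat Gy(const_cast<double*>(gy.begin()) + (R_xlen_t)Ho * Wo * Cout * bi,
                       (arma::uword)Ho * Wo, (arma::uword)Cout, false, true);
    Gcol = Gy * Wt.t();
    col2im_t(Gcol, H, W, Cin, k, stride, pad,
             gx.begin() + (R_xlen_t)H * W * Cin * bi);
  }
  return gx;
}
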