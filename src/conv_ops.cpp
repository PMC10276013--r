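// Batched 2-D convolution kernels (im2col + GEMM) used by the autodiff layer.
//
// Array layout follows R's column-major convention throughout:
//   feature maps  x : (H, W, Cin, N)
//   kernels       w : (kh, kw, Cin, Cout)
//   outputs       y : (Ho, Wo, Cout, N)
// The im2col matrix is M x K with M = Ho*Wo and K = kh*kw*Cin, the column
// index being ki + kh*(kj + kw*ci). That matches the flattening of w, so the
// forward pass is the single GEMM y_n = col * Wmat, and the inner im2col /
// col2im loops run down contiguous memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int Cin,
                   int kh, int kw, int dil, int stride, int ph, int pw,
                   int Ho, int Wo, arma::mat& col) {
  const arma::uword M = col.n_rows;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const arma::uword k = ki + kh * (kj + kw * ci);
        double* colk = col.memptr() + M * k;
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride - pw + kj * dil;
          double* dst = colk + (size_t)Ho * oj;
          if (ij < 0 || ij >= W) {
            std::fill(dst, dst + Ho, 0.0);
            continue;
          }
          const double* src = xc + (size_t)H * ij;
          const int base = -ph + ki * dil;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride + base;
            dst[oi] = (ii >= 0 && ii < H) ? src[ii] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, double* dx, int H, int W, int Cin,
                       int kh, int kw, int dil, int stride, int ph, int pw,
                       int Ho, int Wo) {
  const arma::uword M = col.n_rows;
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = dx + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const arma::uword k = ki + kh * (kj + kw * ci);
        const double* colk = col.memptr() + M * k;
        for (int oj = 0; oj < Wo; ++oj) {
          const int ij = oj * stride - pw + kj * dil;
          if (ij < 0 || ij >= W) continue;
          const double* src = colk + (size_t)Ho * oj;
          double* dst = xc + (size_t)H * ij;
          const int base = -ph + ki * dil;
          for (int oi = 0; oi < Ho; ++oi) {
            const int ii = oi * stride + base;
            if (ii >= 0 && ii < H) dst[ii] += src[oi];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(const NumericVector& x, const NumericVector& w,
                             const NumericVector& b, int stride, int dilation,
                             int ph, int pw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: kernel expects %d input channels, got %d", wd[2], Cin);
  const int eh = (kh - 1) * dilation + 1, ew = (kw - 1) * dilation + 1;
  const int Ho = (H + 2 * ph - eh) / stride + 1;
  const int Wo = (W + 2 * pw - ew) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: input smaller than effective kernel");

  const arma::uword K = (arma::uword)kh * kw * Cin;
  const arma::uword M = (arma::uword)Ho * Wo;
  arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  NumericVector y((R_xlen_t)M * Cout * N);
  arma::mat col(M, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
           kh, kw, dilation, stride, ph, pw, Ho, Wo, col);
    arma::mat Y(y.begin() + (size_t)n * M * Cout, M, Cout, false, true);
    Y = col * Wmat;
    Y.each_row() += bv;
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(const NumericVector& x, const NumericVector& w,
                    const NumericVector& dy, int stride, int dilation,
                    int ph, int pw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];

  const arma::uword K = (arma::uword)kh * kw * Cin;
  const arma::uword M = (arma::uword)Ho * Wo;
  arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dx((R_xlen_t)x.size()), dw((R_xlen_t)w.size());
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat col(M, K), dcol(M, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
           kh, kw, dilation, stride, ph, pw, Ho, Wo, col);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)n * M * Cout,
                 M, Cout, false, true);
    dWm += col.t() * dY;
    dbv += arma::sum(dY, 0).t();
    dcol = dY * Wmat.t();
    col2im_add(dcol, dx.begin() + (size_t)n * H * W * Cin, H, W, Cin,
               kh, kw, dilation, stride, ph, pw, Ho, Wo);
  }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
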