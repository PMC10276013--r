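// Elementwise / normalization kernels kept out of R for speed: ReLU,
// channelwise reductions and the batch-norm forward/backward passes over
// (H, W, C, N) arrays.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(const NumericVector& x) {
  NumericVector y(x.size());
  const double* xi = x.begin();
  double* yi = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yi[i] = xi[i] > 0 ? xi[i] : 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(const NumericVector& x, const NumericVector& dy) {
  NumericVector dx(x.size());
  const double* xi = x.begin();
  const double* di = dy.begin();
  double* o = dx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) o[i] = xi[i] > 0 ? di[i] : 0;
  dx.attr("dim") = x.attr("dim");
  return dx;
}

static void get_dims(const NumericVector& x, R_xlen_t& hw, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  hw = (R_xlen_t)d[0] * d[1];
  C = d[2];
  N = d[3];
}

// [[Rcpp::export]]
List bn_fwd_cpp(const NumericVector& x, const NumericVector& gamma,
                const NumericVector& beta, double eps) {
  R_xlen_t hw; int C, N;
  get_dims(x, hw, C, N);
  const double m = (double)hw * N;
  NumericVector mu(C), va(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + hw * (c + (R_xlen_t)C * n);
      double s = 0, s2 = 0;
      for (R_xlen_t i = 0; i < hw; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      mu[c] += s;
      va[c] += s2;
    }
  }
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    va[c] = va[c] / m - mu[c] * mu[c];
    if (va[c] < 0) va[c] = 0;
  }
  NumericVector xhat(x.size()), y(x.size());
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = hw * (c + (R_xlen_t)C * n);
      const double* xc = x.begin() + off;
      double* xh = xhat.begin() + off;
      double* yc = y.begin() + off;
      const double inv = 1.0 / std::sqrt(va[c] + eps);
      const double g = gamma[c], b = beta[c], mc = mu[c];
      for (R_xlen_t i = 0; i < hw; ++i) {
        xh[i] = (xc[i] - mc) * inv;
        yc[i] = xh[i] * g + b;
      }
    }
  }
  xhat.attr("dim") = x.attr("dim");
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mu,
                      _["var"] = va);
}

// [[Rcpp::export]]
List bn_bwd_cpp(const NumericVector& xhat, const NumericVector& dy,
                const NumericVector& gamma, const NumericVector& var,
                double eps) {
  R_xlen_t hw; int C, N;
  get_dims(xhat, hw, C, N);
  const double m = (double)hw * N;
  NumericVector s1(C), s2(C), dgamma(C), dbeta(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = hw * (c + (R_xlen_t)C * n);
      const double* xh = xhat.begin() + off;
      const double* d = dy.begin() + off;
      double a = 0, b = 0;
      for (R_xlen_t i = 0; i < hw; ++i) { a += d[i]; b += d[i] * xh[i]; }
      s1[c] += a;
      s2[c] += b;
    }
  }
  for (int c = 0; c < C; ++c) { dbeta[c] = s1[c]; dgamma[c] = s2[c]; }
  NumericVector dx(xhat.size());
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = hw * (c + (R_xlen_t)C * n);
      const double* xh = xhat.begin() + off;
      const double* d = dy.begin() + off;
      double* o = dx.begin() + off;
      const double inv = gamma[c] / std::sqrt(var[c] + eps);
      const double a = s1[c] * gamma[c] / m, b = s2[c] * gamma[c] / m;
      const double invg = 1.0 / std::sqrt(var[c] + eps);
      for (R_xlen_t i = 0; i < hw; ++i) {
        o[i] = invg * (gamma[c] * d[i] - a - xh[i] * b);
      }
      (void)inv;
    }
  }
  dx.attr("dim") = xhat.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// inference-mode normalization with running statistics
// [[Rcpp::export]]
NumericVector bn_inf_cpp(const NumericVector& x, const NumericVector& gamma,
                         const NumericVector& beta, const NumericVector& mean,
                         const NumericVector& var, double eps) {
  R_xlen_t hw; int C, N;
  get_dims(x, hw, C, N);
  NumericVector y(x.size());
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = hw * (c + (R_xlen_t)C * n);
      const double* xc = x.begin() + off;
      double* yc = y.begin() + off;
      const double inv = 1.0 / std::sqrt(var[c] + eps);
      const double g = gamma[c], b = beta[c], mc = mean[c];
      for (R_xlen_t i = 0; i < hw; ++i) yc[i] = (xc[i] - mc) * inv * g + b;
    }
  }
  y.attr("dim") = x.attr("dim");
  return y;
}
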