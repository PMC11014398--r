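// Fused element-wise kernels: batch norm, per-channel scaling, ReLU backward.
// These avoid the large broadcast temporaries an R-level implementation needs
// on 128x128 feature maps.

#include <RcppArmadillo.h>
using namespace Rcpp;

// Per-channel mean and variance over (H, W, N) of an (H, W, C, N) array.
// [[Rcpp::export(name = ".bn_stats")]]
List bn_stats(NumericVector x) {
  IntegerVector d = x.attr("dim");
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  NumericVector mu(C), var(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    double m = s / (HW * N);
    mu[c] = m;
    var[c] = s2 / (HW * N) - m * m;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// y = (x - mu[c]) * inv[c] * gamma[c] + beta[c]
// [[Rcpp::export(name = ".bn_apply")]]
NumericVector bn_apply(NumericVector x, NumericVector mu, NumericVector inv,
                       NumericVector gamma, NumericVector beta) {
  IntegerVector d = x.attr("dim");
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double a = inv[c] * gamma[c];
      double b = beta[c] - mu[c] * a;
      size_t off = HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yp[off + i] = xp[off + i] * a + b;
    }
  return y;
}

// Batch-norm backward. xhat is recomputed from the cached input in-pass.
// training = true includes the batch-statistics terms.
// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector x, NumericVector gy, NumericVector mu,
            NumericVector inv, NumericVector gamma, bool training) {
  IntegerVector d = x.attr("dim");
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  double m = (double)HW * N;
  NumericVector ggamma(C), gbeta(C);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      size_t off = HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        double xh = (xp[off + i] - mu[c]) * inv[c];
        sg += gp[off + i];
        sgx += gp[off + i] * xh;
      }
    }
    gbeta[c] = sg;
    ggamma[c] = sgx;
  }
  NumericVector gx(x.size());
  gx.attr("dim") = d;
  double* op = gx.begin();
  for (int c = 0; c < C; ++c) {
    double coef = gamma[c] * inv[c];
    double mg = training ? gbeta[c] / m : 0.0;
    double mgx = training ? ggamma[c] / m : 0.0;
    for (int n = 0; n < N; ++n) {
      size_t off = HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        double xh = (xp[off + i] - mu[c]) * inv[c];
        op[off + i] = coef * (gp[off + i] - mg - xh * mgx);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// y[,,c,n] = x[,,c,n] * g[c,n]  (SE gating, GAP backward)
// [[Rcpp::export(name = ".mul_channels")]]
NumericVector mul_channels(NumericVector x, NumericMatrix g) {
  IntegerVector d = x.attr("dim");
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double gc = g(c, n);
      size_t off = HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yp[off + i] = xp[off + i] * gc;
    }
  return y;
}

// s[c,n] = sum over the spatial plane of x*y (SE gate gradient)
// [[Rcpp::export(name = ".sum_channels_xy")]]
NumericMatrix sum_channels_xy(NumericVector x, NumericVector y) {
  IntegerVector d = x.attr("dim");
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  NumericMatrix s(C, N);
  const double* xp = x.begin();
  const double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = HW * (c + (size_t)C * n);
      double acc = 0;
      for (size_t i = 0; i < HW; ++i) acc += xp[off + i] * yp[off + i];
      s(c, n) = acc;
    }
  return s;
}

// ReLU forward / backward (mask recomputed from the cached output)
// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  size_t n = x.size();
  for (size_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(NumericVector gy, NumericVector out) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  const double* gp = gy.begin();
  const double* op = out.begin();
  double* xp = gx.begin();
  size_t n = gy.size();
  for (size_t i = 0; i < n; ++i) xp[i] = op[i] > 0 ? gp[i] : 0.0;
  return gx;
}

// y[,,c,n] = s[c,n]  broadcast to a full (H, W, C, N) array
// [[Rcpp::export(name = ".bcast_channels")]]
NumericVector bcast_channels(IntegerVector d, NumericMatrix s) {
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  NumericVector y(HW * C * N);
  y.attr("dim") = d;
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double v = s(c, n);
      size_t off = HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yp[off + i] = v;
    }
  return y;
}

// y = x + s[c,n] broadcast
// [[Rcpp::export(name = ".add_channels")]]
NumericVector add_channels(NumericVector x, NumericMatrix s) {
  IntegerVector d = x.attr("dim");
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double v = s(c, n);
      size_t off = HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yp[off + i] = xp[off + i] + v;
    }
  return y;
}
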