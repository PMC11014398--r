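// Convolution and pooling kernels for the mini CNN framework.
// Tensor layout everywhere: column-major R arrays dim = (H, W, C, N).
// Weight layout: (k, k, C_in/groups, C_out).
// Convolutions are computed group-wise via im2col + GEMM (Armadillo/BLAS),
// chunked over samples so the patch matrix stays cache/RAM friendly.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Patch matrix for channels [c0, c0+cg) of samples [n0, n1).
// Result: (cg*k*k) x (Ho*Wo*(n1-n0)), column index = ho + Ho*(wo + Wo*(n-n0)).
static void im2col_group(const double* x, int H, int W, int C, int N,
                         int c0, int cg, int k, int stride, int pad,
                         int Ho, int Wo, int n0, int n1, arma::mat& M) {
  const size_t planeHW = (size_t)H * W;
  const size_t sampleSz = planeHW * C;
  for (int n = n0; n < n1; ++n) {
    const double* xs = x + (size_t)n * sampleSz;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (n - n0));
        double* dst = M.colptr(col);
        int hi0 = ho * stride - pad;
        int wi0 = wo * stride - pad;
        int kh_lo = hi0 < 0 ? -hi0 : 0;
        int kh_hi = hi0 + k > H ? H - hi0 : k;
        for (int c = 0; c < cg; ++c) {
          const double* xc = xs + (size_t)(c0 + c) * planeHW;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wi0 + kw;
            double* d = dst + k * (kw + k * c);   // row index = kh + k*(kw + k*c)
            if (wi < 0 || wi >= W || kh_lo >= kh_hi) {
              std::memset(d, 0, k * sizeof(double));
              continue;
            }
            if (kh_lo > 0) std::memset(d, 0, kh_lo * sizeof(double));
            if (kh_hi < k) std::memset(d + kh_hi, 0, (k - kh_hi) * sizeof(double));
            std::memcpy(d + kh_lo, xc + (size_t)(hi0 + kh_lo) + (size_t)H * wi,
                        (kh_hi - kh_lo) * sizeof(double));
          }
        }
      }
    }
  }
}

// Scatter-add the patch-matrix gradient back onto the input gradient.
static void col2im_group(const arma::mat& M, double* gx, int H, int W, int C,
                         int N, int c0, int cg, int k, int stride, int pad,
                         int Ho, int Wo, int n0, int n1) {
  const size_t planeHW = (size_t)H * W;
  const size_t sampleSz = planeHW * C;
  for (int n = n0; n < n1; ++n) {
    double* gs = gx + (size_t)n * sampleSz;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (n - n0));
        const double* src = M.colptr(col);
        int hi0 = ho * stride - pad;
        int wi0 = wo * stride - pad;
        int kh_lo = hi0 < 0 ? -hi0 : 0;
        int kh_hi = hi0 + k > H ? H - hi0 : k;
        if (kh_lo >= kh_hi) continue;
        for (int c = 0; c < cg; ++c) {
          double* gc = gs + (size_t)(c0 + c) * planeHW;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wi0 + kw;
            if (wi < 0 || wi >= W) continue;
            const double* s = src + k * (kw + k * c);
            double* gcol = gc + (size_t)H * wi + hi0;
            for (int kh = kh_lo; kh < kh_hi; ++kh) gcol[kh] += s[kh];
          }
        }
      }
    }
  }
}

// Samples per chunk so the patch matrix stays under ~32 MB.
static int chunk_samples(size_t rows, size_t oplane, int N) {
  size_t budget = (size_t)32 * 1024 * 1024 / sizeof(double);
  int n = (int)(budget / (rows * oplane));
  if (n < 1) n = 1;
  if (n > N) n = N;
  return n;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         Nullable<NumericVector> bias, int stride, int pad,
                         int groups) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int k = dw[0], cg = dw[2], Cout = dw[3];
  int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  int cout_g = Cout / groups;
  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), (size_t)k * k * cg, Cout, false);
  const size_t oplane = (size_t)Ho * Wo;
  const size_t rows = (size_t)cg * k * k;
  int step = chunk_samples(rows, oplane, N);
  arma::mat M(rows, oplane * step);
  arma::mat Y(oplane * step, cout_g);
  for (int g = 0; g < groups; ++g) {
    const arma::mat Wg(const_cast<double*>(Wm.colptr(g * cout_g)), rows, cout_g,
                       false);
    for (int n0 = 0; n0 < N; n0 += step) {
      int n1 = std::min(n0 + step, N);
      size_t ncols = oplane * (n1 - n0);
      arma::mat Mv(M.memptr(), rows, ncols, false, true);
      im2col_group(x.begin(), H, W, C, N, g * cg, cg, k, stride, pad, Ho, Wo,
                   n0, n1, Mv);
      arma::mat Yv(Y.memptr(), ncols, cout_g, false, true);
      Yv = arma::trans(Mv) * Wg;
      for (int co = 0; co < cout_g; ++co) {
        int c = g * cout_g + co;
        const double* src = Yv.colptr(co);
        for (int n = n0; n < n1; ++n)
          std::memcpy(out.begin() + oplane * (c + (size_t)Cout * n),
                      src + (size_t)(n - n0) * oplane, oplane * sizeof(double));
      }
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        double bc = b[c];
        double* dst = out.begin() + oplane * (c + (size_t)Cout * n);
        for (size_t i = 0; i < oplane; ++i) dst[i] += bc;
      }
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy, int stride,
                int pad, int groups, bool has_bias) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  IntegerVector dy = gy.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int k = dw[0], cg = dw[2], Cout = dw[3];
  int Ho = dy[0], Wo = dy[1];
  int cout_g = Cout / groups;
  const size_t oplane = (size_t)Ho * Wo;
  const size_t rows = (size_t)cg * k * k;

  NumericVector gxv((size_t)H * W * C * N);
  gxv.attr("dim") = dx;
  NumericVector gwv(w.size());
  gwv.attr("dim") = dw;
  NumericVector gbv(has_bias ? Cout : 0);

  arma::mat Wm(w.begin(), rows, Cout, false);
  arma::mat GWm(gwv.begin(), rows, Cout, false);

  int step = chunk_samples(rows, oplane, N);
  arma::mat M(rows, oplane * step);
  arma::mat GY(oplane * step, cout_g);
  for (int g = 0; g < groups; ++g) {
    const arma::mat Wg(const_cast<double*>(Wm.colptr(g * cout_g)), rows, cout_g,
                       false);
    arma::mat GWg(GWm.colptr(g * cout_g), rows, cout_g, false, true);
    for (int n0 = 0; n0 < N; n0 += step) {
      int n1 = std::min(n0 + step, N);
      size_t ncols = oplane * (n1 - n0);
      arma::mat GYv(GY.memptr(), ncols, cout_g, false, true);
      for (int co = 0; co < cout_g; ++co) {
        int c = g * cout_g + co;
        double* dst = GYv.colptr(co);
        for (int n = n0; n < n1; ++n)
          std::memcpy(dst + (size_t)(n - n0) * oplane,
                      gy.begin() + oplane * (c + (size_t)Cout * n),
                      oplane * sizeof(double));
        if (has_bias) gbv[c] += arma::accu(GYv.col(co));
      }
      arma::mat Mv(M.memptr(), rows, ncols, false, true);
      im2col_group(x.begin(), H, W, C, N, g * cg, cg, k, stride, pad, Ho, Wo,
                   n0, n1, Mv);
      GWg += Mv * GYv;                        // (cg k k) x cout_g
      arma::mat GM = Wg * arma::trans(GYv);   // (cg k k) x (Ho Wo chunk)
      col2im_group(GM, gxv.begin(), H, W, C, N, g * cg, cg, k, stride, pad,
                   Ho, Wo, n0, n1);
    }
  }
  return List::create(_["gx"] = gxv, _["gw"] = gwv, _["gb"] = gbv);
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based argmax indices
// into the flattened input array (for the backward pass).
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector dx = x.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector idx(out.size());
  const double* xp = x.begin();
  double* op = out.begin();
  double* ip = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t i00 = base + (size_t)(2 * ho) + (size_t)H * (2 * wo);
          size_t cand[4] = {i00, i00 + 1, i00 + (size_t)H, i00 + (size_t)H + 1};
          size_t best = cand[0];
          for (int j = 1; j < 4; ++j)
            if (xp[cand[j]] > xp[best]) best = cand[j];
          size_t oi = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n));
          op[oi] = xp[best];
          ip[oi] = (double)(best + 1);
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector gy, NumericVector idx,
                           IntegerVector in_dim) {
  size_t n_in = (size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector gx(n_in);
  gx.attr("dim") = in_dim;
  const double* gp = gy.begin();
  const double* ip = idx.begin();
  double* xp = gx.begin();
  size_t n = gy.size();
  for (size_t i = 0; i < n; ++i) xp[(size_t)ip[i] - 1] += gp[i];
  return gx;
}

// ---- direct depthwise 3x3 path (groups == channels) -------------------------
// The im2col/GEMM route degenerates into per-channel micro-GEMMs for
// depthwise convolutions; these direct stencil kernels are memory-bound.

// [[Rcpp::export(name = ".dwconv2d_fwd")]]
NumericVector dwconv2d_fwd(NumericVector x, NumericVector w, int stride, int pad) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int k = dw[0];
  int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const size_t planeHW = (size_t)H * W;
  const size_t oplane = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + planeHW * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)k * k * c;
      double* oc = out.begin() + oplane * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        int wi0 = wo * stride - pad;
        for (int ho = 0; ho < Ho; ++ho) {
          int hi0 = ho * stride - pad;
          double acc = 0;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wi0 + kw;
            if (wi < 0 || wi >= W) continue;
            const double* col = xc + (size_t)H * wi;
            const double* wk = wc + (size_t)k * kw;
            int lo = hi0 < 0 ? -hi0 : 0;
            int hi = hi0 + k > H ? H - hi0 : k;
            for (int kh = lo; kh < hi; ++kh) acc += col[hi0 + kh] * wk[kh];
          }
          oc[(size_t)ho + (size_t)Ho * wo] = acc;
        }
      }
    }
  return out;
}

// [[Rcpp::export(name = ".dwconv2d_bwd")]]
List dwconv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                  int stride, int pad) {
  IntegerVector dx = x.attr("dim");
  IntegerVector dw = w.attr("dim");
  IntegerVector dy = gy.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int k = dw[0];
  int Ho = dy[0], Wo = dy[1];
  NumericVector gxv(x.size());
  gxv.attr("dim") = dx;
  NumericVector gwv(w.size());
  gwv.attr("dim") = dw;
  const size_t planeHW = (size_t)H * W;
  const size_t oplane = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + planeHW * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)k * k * c;
      double* gwc = gwv.begin() + (size_t)k * k * c;
      double* gxc = gxv.begin() + planeHW * (c + (size_t)C * n);
      const double* gc = gy.begin() + oplane * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        int wi0 = wo * stride - pad;
        for (int ho = 0; ho < Ho; ++ho) {
          int hi0 = ho * stride - pad;
          double g = gc[(size_t)ho + (size_t)Ho * wo];
          if (g == 0) continue;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wi0 + kw;
            if (wi < 0 || wi >= W) continue;
            double* gcol = gxc + (size_t)H * wi;
            const double* col = xc + (size_t)H * wi;
            const double* wk = wc + (size_t)k * kw;
            double* gwk = gwc + (size_t)k * kw;
            int lo = hi0 < 0 ? -hi0 : 0;
            int hi = hi0 + k > H ? H - hi0 : k;
            for (int kh = lo; kh < hi; ++kh) {
              gcol[hi0 + kh] += g * wk[kh];
              gwk[kh] += g * col[hi0 + kh];
            }
          }
        }
      }
    }
  return List::create(_["gx"] = gxv, _["gw"] = gwv);
}
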