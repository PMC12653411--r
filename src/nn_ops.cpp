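// Dense numeric kernels for the autograd engine: same-padded stride-1
// convolution (arbitrary dilation), 2x2 max pooling, and 2x bilinear
// upsampling.  Feature maps are R arrays with dim = c(H, W, C, N)
// (column-major), convolution weights dim = c(K, K, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Unfold a band of image columns [w0, w1) of one sample into a
// (H*(w1-w0)) x (K*K*C) patch matrix; patch-column ordering matches the
// column-major flattening of a (K, K, C) weight slice.  Banding keeps the
// buffer small at large image sizes.
static void im2col(const double* xs, int H, int W, int C, int K, int dil,
                   int w0, int w1, arma::mat& col) {
  const int HW = H * W;
  const int half = (K - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const double* plane = xs + (std::size_t)c * HW;
    for (int kw = 0; kw < K; ++kw) {
      const int dw = (kw - half) * dil;
      for (int kh = 0; kh < K; ++kh) {
        const int dh = (kh - half) * dil;
        double* dst = col.colptr((std::size_t)c * K * K + (std::size_t)kw * K + kh);
        for (int w = w0; w < w1; ++w) {
          const int sw = w + dw;
          double* d2 = dst + (std::size_t)(w - w0) * H;
          if (sw < 0 || sw >= W) {
            std::fill(d2, d2 + H, 0.0);
            continue;
          }
          const double* src = plane + (std::size_t)sw * H;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dh;
            d2[h] = (sh >= 0 && sh < H) ? src[sh] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the patch-matrix gradient of a column band back onto the
// input gradient.
static void col2im(const arma::mat& gcol, int H, int W, int C, int K, int dil,
                   int w0, int w1, double* gxs) {
  const int HW = H * W;
  const int half = (K - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* plane = gxs + (std::size_t)c * HW;
    for (int kw = 0; kw < K; ++kw) {
      const int dw = (kw - half) * dil;
      for (int kh = 0; kh < K; ++kh) {
        const int dh = (kh - half) * dil;
        const double* src = gcol.colptr((std::size_t)c * K * K + (std::size_t)kw * K + kh);
        for (int w = w0; w < w1; ++w) {
          const int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          const double* s2 = src + (std::size_t)(w - w0) * H;
          double* d2 = plane + (std::size_t)sw * H;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dh;
            if (sh >= 0 && sh < H) d2[sh] += s2[h];
          }
        }
      }
    }
  }
}

// Column-band width keeping the patch buffer near 64 MB.
static int conv_band(int H, int W, int C, int K) {
  const double budget = 8e6;  // doubles
  int bw = (int)(budget / ((double)H * K * K * C));
  if (bw < 1) bw = 1;
  if (bw > W) bw = W;
  return bw;
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                           int dil) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: input has %d channels, weights expect %d", C, wd[2]);
  const int HW = H * W;
  NumericVector y((std::size_t)HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)K * K * C, Cout, false, true);
  const int bw = conv_band(H, W, C, K);
  arma::mat col;
  if (K > 1) col.set_size((std::size_t)H * bw, (std::size_t)K * K * C);
  for (int n = 0; n < N; ++n) {
    arma::mat Y(y.begin() + (std::size_t)n * HW * Cout, HW, Cout, false, true);
    if (K == 1) {  // 1x1 convolution: plain matrix product, no unfold
      const arma::mat X(const_cast<double*>(x.begin()) + (std::size_t)n * HW * C,
                        HW, C, false, true);
      Y = X * Wm;
    } else {
      for (int w0 = 0; w0 < W; w0 += bw) {
        const int w1 = std::min(W, w0 + bw);
        im2col(x.begin() + (std::size_t)n * HW * C, H, W, C, K, dil, w0, w1, col);
        Y.rows((std::size_t)w0 * H, (std::size_t)w1 * H - 1) =
          col.rows(0, (std::size_t)(w1 - w0) * H - 1) * Wm;
      }
    }
    for (int c = 0; c < Cout; ++c) Y.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy, int dil) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  const int HW = H * W;
  const arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)K * K * C, Cout, false, true);
  NumericVector gx((std::size_t)HW * C * N);
  gx.attr("dim") = xd;
  NumericVector gw((std::size_t)K * K * C * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat GW(gw.begin(), (std::size_t)K * K * C, Cout, false, true);
  const int bw = conv_band(H, W, C, K);
  arma::mat col, gcol;
  if (K > 1) {
    col.set_size((std::size_t)H * bw, (std::size_t)K * K * C);
    gcol.set_size((std::size_t)H * bw, (std::size_t)K * K * C);
  }
  for (int n = 0; n < N; ++n) {
    const arma::mat GY(const_cast<double*>(gy.begin()) + (std::size_t)n * HW * Cout,
                       HW, Cout, false, true);
    for (int c = 0; c < Cout; ++c) gb[c] += arma::accu(GY.col(c));
    if (K == 1) {
      const arma::mat X(const_cast<double*>(x.begin()) + (std::size_t)n * HW * C,
                        HW, C, false, true);
      arma::mat GX(gx.begin() + (std::size_t)n * HW * C, HW, C, false, true);
      GW += X.t() * GY;
      GX = GY * Wm.t();
    } else {
      for (int w0 = 0; w0 < W; w0 += bw) {
        const int w1 = std::min(W, w0 + bw);
        const std::size_t nr = (std::size_t)(w1 - w0) * H;
        im2col(x.begin() + (std::size_t)n * HW * C, H, W, C, K, dil, w0, w1, col);
        const arma::mat GYb = GY.rows((std::size_t)w0 * H, (std::size_t)w1 * H - 1);
        GW += col.rows(0, nr - 1).t() * GYb;
        gcol.rows(0, nr - 1) = GYb * Wm.t();
        col2im(gcol, H, W, C, K, dil, w0, w1,
               gx.begin() + (std::size_t)n * HW * C);
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List nn_maxpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even, got %dx%d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((std::size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  std::size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const std::size_t base = ((std::size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          const std::size_t i00 = base + (std::size_t)(2 * w) * H + 2 * h;
          std::size_t best = i00;
          double bv = xp[i00];
          const std::size_t cand[3] = {i00 + 1, i00 + H, i00 + H + 1};
          for (int k = 0; k < 3; ++k)
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
          yp[o] = bv;
          ip[o] = (int)best;
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool2_bw(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  std::size_t n = 1;
  for (int k = 0; k < xdim.size(); ++k) n *= xdim[k];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  double* gp = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) gp[idx[i]] += gy[i];
  return gx;
}

// Precompute 1-D source indices/weights for scale-2 bilinear resampling
// (half-pixel centers, clamped at the border).
static void lin_weights(int Hin, std::vector<int>& i0, std::vector<int>& i1,
                        std::vector<double>& w1) {
  const int Hout = 2 * Hin;
  i0.resize(Hout); i1.resize(Hout); w1.resize(Hout);
  for (int i = 0; i < Hout; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > Hin - 1) s = Hin - 1;
    int a = (int)std::floor(s);
    int b = std::min(a + 1, Hin - 1);
    i0[i] = a; i1[i] = b; w1[i] = s - a;
  }
}

// [[Rcpp::export]]
NumericVector nn_upsample2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((std::size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rw, cw;
  lin_weights(H, r0, r1, rw);
  lin_weights(W, c0, c1, cw);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* pl = xp + ((std::size_t)n * C + c) * H * W;
      double* po = yp + ((std::size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w) {
        const double* s0 = pl + (std::size_t)c0[w] * H;
        const double* s1 = pl + (std::size_t)c1[w] * H;
        const double wc = cw[w];
        double* d = po + (std::size_t)w * Ho;
        for (int h = 0; h < Ho; ++h) {
          const double a = s0[r0[h]] * (1 - rw[h]) + s0[r1[h]] * rw[h];
          const double b = s1[r0[h]] * (1 - rw[h]) + s1[r1[h]] * rw[h];
          d[h] = a * (1 - wc) + b * wc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_upsample2_bw(NumericVector gy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx((std::size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rw, cw;
  lin_weights(H, r0, r1, rw);
  lin_weights(W, c0, c1, cw);
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* pl = gxp + ((std::size_t)n * C + c) * H * W;
      const double* po = gp + ((std::size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w) {
        double* s0 = pl + (std::size_t)c0[w] * H;
        double* s1 = pl + (std::size_t)c1[w] * H;
        const double wc = cw[w];
        const double* d = po + (std::size_t)w * Ho;
        for (int h = 0; h < Ho; ++h) {
          const double g = d[h];
          s0[r0[h]] += g * (1 - rw[h]) * (1 - wc);
          s0[r1[h]] += g * rw[h] * (1 - wc);
          s1[r0[h]] += g * (1 - rw[h]) * wc;
          s1[r1[h]] += g * rw[h] * wc;
        }
      }
    }
  }
  return gx;
}

// Per-channel moments over (H, W, N) of a (H, W, C, N) map.
// [[Rcpp::export]]
List nn_bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const std::size_t HW = (std::size_t)H * W;
  NumericVector mu(C), va(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((std::size_t)n * C + c) * HW;
      for (std::size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / (HW * N);
    mu[c] = m;
    va[c] = s2 / (HW * N) - m * m;
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// [[Rcpp::export]]
NumericVector nn_bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
                       NumericVector mu, NumericVector va, double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const std::size_t HW = (std::size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double ivar = 1.0 / std::sqrt(va[c] + eps);
    const double a = gamma[c] * ivar;
    const double b = beta[c] - a * mu[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((std::size_t)n * C + c) * HW;
      double* q = y.begin() + ((std::size_t)n * C + c) * HW;
      for (std::size_t i = 0; i < HW; ++i) q[i] = a * p[i] + b;
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_bn_bw(NumericVector x, NumericVector gamma, NumericVector g,
              NumericVector mu, NumericVector va, double eps, bool training) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const std::size_t HW = (std::size_t)H * W;
  const double m = (double)HW * N;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const double ivar = 1.0 / std::sqrt(va[c] + eps);
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      const std::size_t off = ((std::size_t)n * C + c) * HW;
      const double* xp = x.begin() + off;
      const double* gp = g.begin() + off;
      for (std::size_t i = 0; i < HW; ++i) {
        sg += gp[i];
        sgx += gp[i] * (xp[i] - mu[c]) * ivar;
      }
    }
    gbeta[c] = sg;
    ggamma[c] = sgx;
    const double t1 = sg / m, t2 = sgx / m;
    for (int n = 0; n < N; ++n) {
      const std::size_t off = ((std::size_t)n * C + c) * HW;
      const double* xp = x.begin() + off;
      const double* gp = g.begin() + off;
      double* op = gx.begin() + off;
      if (training) {
        for (std::size_t i = 0; i < HW; ++i) {
          const double xhat = (xp[i] - mu[c]) * ivar;
          op[i] = gamma[c] * ivar * (gp[i] - t1 - xhat * t2);
        }
      } else {
        for (std::size_t i = 0; i < HW; ++i) op[i] = gamma[c] * ivar * gp[i];
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector nn_relu_fw(NumericVector x) {
  NumericVector y = clone(x);
  for (R_xlen_t i = 0; i < y.size(); ++i) if (y[i] < 0) y[i] = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector nn_relu_bw(NumericVector x, NumericVector g) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) gx[i] = x[i] > 0 ? g[i] : 0.0;
  return gx;
}
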