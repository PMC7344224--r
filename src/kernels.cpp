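// Numeric kernels for the 2D U-Net and the image-geometry operations.
// Array layout throughout: column-major R arrays dim (H, W, C, N) so that a
// single sample's (H*W) x C view is contiguous and GEMM-friendly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col for a 3x3 same-padding convolution: one sample, channels C.
// Column index r = (c*3 + (dw+1))*3 + (dh+1); rows enumerate output pixels
// in (h, w) column-major order. Out-of-image taps are zero. The column
// matrix is single precision: convolution GEMMs run in float32 (ample for
// network activations/gradients) at half the memory traffic.
static void im2col3x3(const double* xc0, int H, int W, int C, arma::fmat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = xc0 + (size_t)c * H * W;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        int r = (c * 3 + (dw + 1)) * 3 + (dh + 1);
        float* colp = col.colptr(r);
        for (int wj = 0; wj < W; ++wj) {
          float* dst = colp + (size_t)wj * H;
          int wsrc = wj + dw;
          if (wsrc < 0 || wsrc >= W) {
            std::fill(dst, dst + H, 0.0f);
            continue;
          }
          const double* src = xc + (size_t)wsrc * H;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int hi = 0; hi < h0; ++hi) dst[hi] = 0.0f;
          for (int hi = h0; hi < h1; ++hi) dst[hi] = (float)src[hi + dh];
          for (int hi = h1; hi < H; ++hi) dst[hi] = 0.0f;
        }
      }
    }
  }
}

// scatter-add transpose of im2col3x3 (float gradient columns into double dx)
static void col2im3x3(const arma::fmat& dcol, int H, int W, int C, double* dx0) {
  for (int c = 0; c < C; ++c) {
    double* dxc = dx0 + (size_t)c * H * W;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        int r = (c * 3 + (dw + 1)) * 3 + (dh + 1);
        const float* colp = dcol.colptr(r);
        for (int wj = 0; wj < W; ++wj) {
          int wsrc = wj + dw;
          if (wsrc < 0 || wsrc >= W) continue;
          double* dst = dxc + (size_t)wsrc * H;
          const float* src = colp + (size_t)wj * H;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int hi = h0; hi < h1; ++hi) dst[hi + dh] += src[hi];
        }
      }
    }
  }
}

static arma::fmat toF(const double* p, size_t n, size_t m) {
  arma::fmat f(n, m);
  float* q = f.memptr();
  for (size_t k = 0; k < n * m; ++k) q[k] = (float)p[k];
  return f;
}

// [[Rcpp::export]]
NumericVector cpp_conv3x3_forward(NumericVector x, NumericMatrix w) {
  int H, W, C, N; dims4(x, H, W, C, N);
  if (w.nrow() != 9 * C) stop("weight rows must equal 9*C_in");
  int Cout = w.ncol();
  arma::fmat Wf = toF(w.begin(), w.nrow(), Cout);
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::fmat col((size_t)H * W, (size_t)9 * C);
  arma::fmat Y((size_t)H * W, Cout);
  for (int n = 0; n < N; ++n) {
    im2col3x3(x.begin() + (size_t)n * C * H * W, H, W, C, col);
    Y = col * Wf;
    double* yp = y.begin() + (size_t)n * Cout * H * W;
    const float* fp = Y.memptr();
    for (size_t k = 0; k < (size_t)H * W * Cout; ++k) yp[k] = fp[k];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3x3_backward(NumericVector x, NumericMatrix w, NumericVector dy) {
  int H, W, C, N; dims4(x, H, W, C, N);
  int Cout = w.ncol();
  arma::fmat Wf = toF(w.begin(), w.nrow(), Cout);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericMatrix dw(w.nrow(), Cout);
  arma::fmat dWf(w.nrow(), Cout, arma::fill::zeros);
  arma::fmat col((size_t)H * W, (size_t)9 * C);
  arma::fmat dcol((size_t)H * W, (size_t)9 * C);
  for (int n = 0; n < N; ++n) {
    im2col3x3(x.begin() + (size_t)n * C * H * W, H, W, C, col);
    arma::fmat dY = toF(dy.begin() + (size_t)n * Cout * H * W, (size_t)H * W, Cout);
    dWf += col.t() * dY;
    dcol = dY * Wf.t();
    col2im3x3(dcol, H, W, C, dx.begin() + (size_t)n * C * H * W);
  }
  for (int k = 0; k < w.nrow() * Cout; ++k) dw[k] = dWf.memptr()[k];
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export]]
NumericVector cpp_conv1x1_forward(NumericVector x, NumericMatrix w, NumericVector b) {
  int H, W, C, N; dims4(x, H, W, C, N);
  if (w.nrow() != C) stop("weight rows must equal C_in");
  int Cout = w.ncol();
  arma::mat Wm(w.begin(), C, Cout, false);
  arma::rowvec bv(b.begin(), Cout);
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X(x.begin() + (size_t)n * C * H * W, (size_t)H * W, C, false, true);
    arma::mat Y(y.begin() + (size_t)n * Cout * H * W, (size_t)H * W, Cout, false, true);
    Y = X * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv1x1_backward(NumericVector x, NumericMatrix w, NumericVector dy) {
  int H, W, C, N; dims4(x, H, W, C, N);
  int Cout = w.ncol();
  arma::mat Wm(w.begin(), C, Cout, false);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericMatrix dw(C, Cout);
  arma::mat dWm(dw.begin(), C, Cout, false);
  NumericVector db(Cout);
  arma::rowvec dbv(db.begin(), Cout, false);
  for (int n = 0; n < N; ++n) {
    arma::mat X(x.begin() + (size_t)n * C * H * W, (size_t)H * W, C, false, true);
    arma::mat dY(dy.begin() + (size_t)n * Cout * H * W, (size_t)H * W, Cout, false, true);
    arma::mat dX(dx.begin() + (size_t)n * C * H * W, (size_t)H * W, C, false, true);
    dWm += X.t() * dY;
    dbv += arma::sum(dY, 0);
    dX = dY * Wm.t();
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Records argmax position (dh + 2*dw) for backprop.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  int H, W, C, N; dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("max-pool input must have even height and width");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t planes = (size_t)C * N;
  for (size_t pl = 0; pl < planes; ++pl) {
    const double* xpl = xp + pl * H * W;
    double* ypl = yp + pl * Ho * Wo;
    int* ipl = ip + pl * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int h = 2 * ho, w = 2 * wo;
        double best = xpl[(size_t)w * H + h];
        int bi = 0;
        double v = xpl[(size_t)w * H + h + 1];
        if (v > best) { best = v; bi = 1; }
        v = xpl[(size_t)(w + 1) * H + h];
        if (v > best) { best = v; bi = 2; }
        v = xpl[(size_t)(w + 1) * H + h + 1];
        if (v > best) { best = v; bi = 3; }
        ypl[(size_t)wo * Ho + ho] = best;
        ipl[(size_t)wo * Ho + ho] = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector idx) {
  int Ho, Wo, C, N; dims4(dy, Ho, Wo, C, N);
  int H = 2 * Ho, W = 2 * Wo;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  size_t planes = (size_t)C * N;
  for (size_t pl = 0; pl < planes; ++pl) {
    const double* dypl = dyp + pl * Ho * Wo;
    const int* ipl = ip + pl * Ho * Wo;
    double* dxpl = dxp + pl * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int bi = ipl[(size_t)wo * Ho + ho];
        int h = 2 * ho + (bi & 1), w = 2 * wo + (bi >> 1);
        dxpl[(size_t)w * H + h] += dypl[(size_t)wo * Ho + ho];
      }
    }
  }
  return dx;
}

// pixel-center-aligned source coordinates for a 2x bilinear upsample
static void up2_weights(int Hin, std::vector<int>& i0, std::vector<double>& t) {
  int Hout = 2 * Hin;
  i0.resize(Hout); t.resize(Hout);
  for (int i = 0; i < Hout; ++i) {
    double f = 0.5 * i - 0.25;
    int j = (int)std::floor(f);
    double u = f - j;
    if (j < 0) { j = 0; u = 0.0; }
    if (j >= Hin - 1) { j = std::max(0, Hin - 2); u = (Hin > 1) ? 1.0 : 0.0; }
    i0[i] = j; t[i] = u;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_forward(NumericVector x) {
  int H, W, C, N; dims4(x, H, W, C, N);
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> hi0, wi0; std::vector<double> ht, wt;
  up2_weights(H, hi0, ht);
  up2_weights(W, wi0, wt);
  size_t planes = (size_t)C * N;
  for (size_t pl = 0; pl < planes; ++pl) {
    const double* xpl = x.begin() + pl * H * W;
    double* ypl = y.begin() + pl * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const double* c0 = xpl + (size_t)wi0[wo] * H;
      const double* c1 = xpl + (size_t)std::min(wi0[wo] + 1, W - 1) * H;
      double uw = wt[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        int h0 = hi0[ho], h1 = std::min(h0 + 1, H - 1);
        double uh = ht[ho];
        double a = c0[h0] * (1 - uh) + c0[h1] * uh;
        double b = c1[h0] * (1 - uh) + c1[h1] * uh;
        ypl[(size_t)wo * Ho + ho] = a * (1 - uw) + b * uw;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector dy) {
  int Ho, Wo, C, N; dims4(dy, Ho, Wo, C, N);
  int H = Ho / 2, W = Wo / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> hi0, wi0; std::vector<double> ht, wt;
  up2_weights(H, hi0, ht);
  up2_weights(W, wi0, wt);
  size_t planes = (size_t)C * N;
  for (size_t pl = 0; pl < planes; ++pl) {
    const double* dypl = dy.begin() + pl * Ho * Wo;
    double* dxpl = dx.begin() + pl * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      int w0 = wi0[wo], w1 = std::min(w0 + 1, W - 1);
      double uw = wt[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        int h0 = hi0[ho], h1 = std::min(h0 + 1, H - 1);
        double uh = ht[ho];
        double g = dypl[(size_t)wo * Ho + ho];
        dxpl[(size_t)w0 * H + h0] += g * (1 - uh) * (1 - uw);
        dxpl[(size_t)w0 * H + h1] += g * uh * (1 - uw);
        dxpl[(size_t)w1 * H + h0] += g * (1 - uh) * uw;
        dxpl[(size_t)w1 * H + h1] += g * uh * uw;
      }
    }
  }
  return dx;
}

// general bilinear resize of one 2D plane, pixel-center alignment, edge clamp
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix x, int ho, int wo) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix y(ho, wo);
  double sh = (double)H / ho, sw = (double)W / wo;
  for (int j = 0; j < wo; ++j) {
    double fw = (j + 0.5) * sw - 0.5;
    int w0 = (int)std::floor(fw);
    double uw = fw - w0;
    if (w0 < 0) { w0 = 0; uw = 0.0; }
    if (w0 >= W - 1) { w0 = std::max(0, W - 2); uw = (W > 1) ? 1.0 : 0.0; }
    int w1 = std::min(w0 + 1, W - 1);
    for (int i = 0; i < ho; ++i) {
      double fh = (i + 0.5) * sh - 0.5;
      int h0 = (int)std::floor(fh);
      double uh = fh - h0;
      if (h0 < 0) { h0 = 0; uh = 0.0; }
      if (h0 >= H - 1) { h0 = std::max(0, H - 2); uh = (H > 1) ? 1.0 : 0.0; }
      int h1 = std::min(h0 + 1, H - 1);
      double a = x(h0, w0) * (1 - uh) + x(h1, w0) * uh;
      double b = x(h0, w1) * (1 - uh) + x(h1, w1) * uh;
      y(i, j) = a * (1 - uw) + b * uw;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_nearest(NumericMatrix x, int ho, int wo) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix y(ho, wo);
  double sh = (double)H / ho, sw = (double)W / wo;
  for (int j = 0; j < wo; ++j) {
    int w0 = (int)std::floor((j + 0.5) * sw);
    if (w0 < 0) w0 = 0;
    if (w0 >= W) w0 = W - 1;
    for (int i = 0; i < ho; ++i) {
      int h0 = (int)std::floor((i + 0.5) * sh);
      if (h0 < 0) h0 = 0;
      if (h0 >= H) h0 = H - 1;
      y(i, j) = x(h0, w0);
    }
  }
  return y;
}

// inverse-mapped affine warp: for output pixel (row i, col j), source coords
// (0-based) are  src_r = a11*i + a12*j + b1,  src_c = a21*i + a22*j + b2.
// bilinear = true samples bilinearly with `fill` outside; otherwise nearest.
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(NumericMatrix x, int ho, int wo,
                              NumericVector coef, bool bilinear, double fill) {
  int H = x.nrow(), W = x.ncol();
  double a11 = coef[0], a12 = coef[1], b1 = coef[2];
  double a21 = coef[3], a22 = coef[4], b2 = coef[5];
  NumericMatrix y(ho, wo);
  for (int j = 0; j < wo; ++j) {
    for (int i = 0; i < ho; ++i) {
      double sr = a11 * i + a12 * j + b1;
      double sc = a21 * i + a22 * j + b2;
      if (bilinear) {
        int h0 = (int)std::floor(sr), w0 = (int)std::floor(sc);
        double uh = sr - h0, uw = sc - w0;
        double acc = 0.0;
        for (int dh = 0; dh <= 1; ++dh) {
          for (int dw = 0; dw <= 1; ++dw) {
            int h = h0 + dh, w = w0 + dw;
            double wgt = (dh ? uh : 1 - uh) * (dw ? uw : 1 - uw);
            double v = (h >= 0 && h < H && w >= 0 && w < W) ? x(h, w) : fill;
            acc += wgt * v;
          }
        }
        y(i, j) = acc;
      } else {
        int h = (int)std::lround(sr), w = (int)std::lround(sc);
        y(i, j) = (h >= 0 && h < H && w >= 0 && w < W) ? x(h, w) : fill;
      }
    }
  }
  return y;
}

// per-channel sum and sum of squares over (H, W, N) — batch-norm statistics
// [[Rcpp::export]]
List cpp_channel_stats(NumericVector x) {
  int H, W, C, N; dims4(x, H, W, C, N);
  NumericVector s(C), ss(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)n * C + c) * H * W;
      double a = 0.0, b = 0.0;
      for (size_t k = 0; k < (size_t)H * W; ++k) { a += p[k]; b += p[k] * p[k]; }
      s[c] += a; ss[c] += b;
    }
  }
  return List::create(_["sum"] = s, _["sumsq"] = ss, _["count"] = (double)H * W * N);
}

// per-channel sum of x*y over (H, W, N)
// [[Rcpp::export]]
NumericVector cpp_channel_dot(NumericVector x, NumericVector y) {
  int H, W, C, N; dims4(x, H, W, C, N);
  NumericVector s(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)n * C + c) * H * W;
      const double* q = y.begin() + ((size_t)n * C + c) * H * W;
      double a = 0.0;
      for (size_t k = 0; k < (size_t)H * W; ++k) a += p[k] * q[k];
      s[c] += a;
    }
  }
  return s;
}

// y[., c, .] = x[., c, .] * a[c] + b[c]
// [[Rcpp::export]]
NumericVector cpp_channel_scale_shift(NumericVector x, NumericVector a, NumericVector b) {
  int H, W, C, N; dims4(x, H, W, C, N);
  NumericVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)n * C + c) * H * W;
      double* q = y.begin() + ((size_t)n * C + c) * H * W;
      double ac = a[c], bc = b[c];
      for (size_t k = 0; k < (size_t)H * W; ++k) q[k] = p[k] * ac + bc;
    }
  }
  return y;
}

// fused batch-norm + ReLU, training mode: computes batch statistics,
// normalizes, scales/shifts and rectifies in two passes
// [[Rcpp::export]]
List cpp_bn_relu_train(NumericVector x, NumericVector gamma, NumericVector beta) {
  int H, W, C, N; dims4(x, H, W, C, N);
  size_t plane = (size_t)H * W;
  double m = (double)plane * N;
  std::vector<double> s(C, 0.0), ss(C, 0.0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)n * C + c) * plane;
      double a = 0.0, b = 0.0;
      for (size_t k = 0; k < plane; ++k) { a += p[k]; b += p[k] * p[k]; }
      s[c] += a; ss[c] += b;
    }
  NumericVector mean(C), invstd(C), var(C);
  for (int c = 0; c < C; ++c) {
    mean[c] = s[c] / m;
    double v = ss[c] / m - mean[c] * mean[c];
    if (v < 0) v = 0;
    var[c] = v;
    invstd[c] = 1.0 / std::sqrt(v + 1e-5);
  }
  NumericVector y((R_xlen_t)plane * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)n * C + c) * plane;
      double* q = y.begin() + ((size_t)n * C + c) * plane;
      double a = gamma[c] * invstd[c], b = beta[c] - gamma[c] * mean[c] * invstd[c];
      for (size_t k = 0; k < plane; ++k) {
        double v = p[k] * a + b;
        q[k] = v > 0 ? v : 0.0;
      }
    }
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd,
                      _["var"] = var);
}

// fused batch-norm + ReLU, evaluation mode (running statistics)
// [[Rcpp::export]]
NumericVector cpp_bn_relu_eval(NumericVector x, NumericVector gamma,
                               NumericVector beta, NumericVector rmean,
                               NumericVector rvar) {
  int H, W, C, N; dims4(x, H, W, C, N);
  size_t plane = (size_t)H * W;
  NumericVector y((R_xlen_t)plane * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)n * C + c) * plane;
      double* q = y.begin() + ((size_t)n * C + c) * plane;
      double is = 1.0 / std::sqrt(rvar[c] + 1e-5);
      double a = gamma[c] * is, b = beta[c] - gamma[c] * rmean[c] * is;
      for (size_t k = 0; k < plane; ++k) {
        double v = p[k] * a + b;
        q[k] = v > 0 ? v : 0.0;
      }
    }
  return y;
}

// backward of the fused BN+ReLU block. x: conv output (BN input); y: fused
// block output (its zeros mark rectified positions); dy: upstream gradient.
// [[Rcpp::export]]
List cpp_bn_relu_backward(NumericVector x, NumericVector y, NumericVector dy,
                          NumericVector gamma, NumericVector mean,
                          NumericVector invstd) {
  int H, W, C, N; dims4(x, H, W, C, N);
  size_t plane = (size_t)H * W;
  double m = (double)plane * N;
  NumericVector dgamma(C), dbeta(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* px = x.begin() + ((size_t)n * C + c) * plane;
      const double* py = y.begin() + ((size_t)n * C + c) * plane;
      const double* pd = dy.begin() + ((size_t)n * C + c) * plane;
      double mu = mean[c], is = invstd[c], dg = 0.0, db = 0.0;
      for (size_t k = 0; k < plane; ++k) {
        if (py[k] > 0) {
          double g = pd[k];
          db += g;
          dg += g * (px[k] - mu) * is;
        }
      }
      dgamma[c] += dg; dbeta[c] += db;
    }
  NumericVector dx((R_xlen_t)plane * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* px = x.begin() + ((size_t)n * C + c) * plane;
      const double* py = y.begin() + ((size_t)n * C + c) * plane;
      const double* pd = dy.begin() + ((size_t)n * C + c) * plane;
      double* q = dx.begin() + ((size_t)n * C + c) * plane;
      double mu = mean[c], is = invstd[c];
      double a = gamma[c] * is;
      double t1 = dbeta[c] / m, t2 = dgamma[c] / m;
      for (size_t k = 0; k < plane; ++k) {
        double g = (py[k] > 0) ? pd[k] : 0.0;
        double xh = (px[k] - mu) * is;
        q[k] = a * (g - t1 - xh * t2);
      }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// inverted dropout using R's RNG (keeps runs reproducible under set.seed);
// returns the dropped activations and the scaled mask for backprop
// [[Rcpp::export]]
List cpp_dropout_forward(NumericVector x, double rate) {
  int H, W, C, N; dims4(x, H, W, C, N);
  R_xlen_t len = x.size();
  NumericVector y(len), mask(len);
  y.attr("dim") = x.attr("dim");
  mask.attr("dim") = x.attr("dim");
  double keep = 1.0 - rate, inv = 1.0 / keep;
  GetRNGstate();
  for (R_xlen_t k = 0; k < len; ++k) {
    double u = unif_rand();
    double mk = (u >= rate) ? inv : 0.0;
    mask[k] = mk;
    y[k] = x[k] * mk;
  }
  PutRNGstate();
  return List::create(_["y"] = y, _["mask"] = mask);
}

// [[Rcpp::export]]
NumericVector cpp_elemwise_mul(NumericVector a, NumericVector b) {
  NumericVector y(a.size());
  y.attr("dim") = a.attr("dim");
  for (R_xlen_t k = 0; k < a.size(); ++k) y[k] = a[k] * b[k];
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_concat_channels(NumericVector a, NumericVector b) {
  int H, W, Ca, N; dims4(a, H, W, Ca, N);
  int H2, W2, Cb, N2; dims4(b, H2, W2, Cb, N2);
  if (H != H2 || W != W2 || N != N2) stop("concat: mismatched grids");
  size_t plane = (size_t)H * W;
  NumericVector y((R_xlen_t)plane * (Ca + Cb) * N);
  y.attr("dim") = IntegerVector::create(H, W, Ca + Cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(a.begin() + (size_t)n * Ca * plane,
              a.begin() + (size_t)(n + 1) * Ca * plane,
              y.begin() + (size_t)n * (Ca + Cb) * plane);
    std::copy(b.begin() + (size_t)n * Cb * plane,
              b.begin() + (size_t)(n + 1) * Cb * plane,
              y.begin() + ((size_t)n * (Ca + Cb) + Ca) * plane);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_split_channels(NumericVector x, int ca) {
  int H, W, C, N; dims4(x, H, W, C, N);
  int cb = C - ca;
  size_t plane = (size_t)H * W;
  NumericVector a((R_xlen_t)plane * ca * N), b((R_xlen_t)plane * cb * N);
  a.attr("dim") = IntegerVector::create(H, W, ca, N);
  b.attr("dim") = IntegerVector::create(H, W, cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(x.begin() + (size_t)n * C * plane,
              x.begin() + ((size_t)n * C + ca) * plane,
              a.begin() + (size_t)n * ca * plane);
    std::copy(x.begin() + ((size_t)n * C + ca) * plane,
              x.begin() + (size_t)(n + 1) * C * plane,
              b.begin() + (size_t)n * cb * plane);
  }
  return List::create(_["a"] = a, _["b"] = b);
}

// mean 4-class pixelwise softmax cross-entropy and its logit gradient
// labels: (H, W, N) integer array of class codes 0..C-1
// [[Rcpp::export]]
List cpp_softmax_xent(NumericVector logits, IntegerVector labels) {
  int H, W, C, N; dims4(logits, H, W, C, N);
  size_t plane = (size_t)H * W;
  double npix = (double)plane * N;
  NumericVector dl((R_xlen_t)plane * C * N);
  dl.attr("dim") = logits.attr("dim");
  double total = 0.0;
  std::vector<double> p(C);
  for (int n = 0; n < N; ++n) {
    const double* L = logits.begin() + (size_t)n * C * plane;
    double* G = dl.begin() + (size_t)n * C * plane;
    const int* Y = labels.begin() + (size_t)n * plane;
    for (size_t k = 0; k < plane; ++k) {
      double mx = L[k];
      for (int c = 1; c < C; ++c) mx = std::max(mx, L[c * plane + k]);
      double s = 0.0;
      for (int c = 0; c < C; ++c) { p[c] = std::exp(L[c * plane + k] - mx); s += p[c]; }
      int yk = Y[k];
      total -= std::log(std::max(p[yk] / s, 1e-300));
      for (int c = 0; c < C; ++c)
        G[c * plane + k] = (p[c] / s - (c == yk ? 1.0 : 0.0)) / npix;
    }
  }
  return List::create(_["loss"] = total / npix, _["dlogits"] = dl);
}

// forward convolution that also returns the (single-precision) im2col
// matrices, packed in a raw vector, so the backward pass can reuse them
// [[Rcpp::export]]
List cpp_conv3x3_forward_cache(NumericVector x, NumericMatrix w) {
  int H, W, C, N; dims4(x, H, W, C, N);
  if (w.nrow() != 9 * C) stop("weight rows must equal 9*C_in");
  int Cout = w.ncol();
  arma::fmat Wf = toF(w.begin(), w.nrow(), Cout);
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  RawVector col((R_xlen_t)H * W * 9 * C * N * sizeof(float));
  float* colp = reinterpret_cast<float*>(RAW(col));
  arma::fmat Y((size_t)H * W, Cout);
  for (int n = 0; n < N; ++n) {
    arma::fmat Cn(colp + (size_t)n * 9 * C * H * W, (size_t)H * W,
                  (size_t)9 * C, false, true);
    im2col3x3(x.begin() + (size_t)n * C * H * W, H, W, C, Cn);
    Y = Cn * Wf;
    double* yp = y.begin() + (size_t)n * Cout * H * W;
    const float* fp = Y.memptr();
    for (size_t k = 0; k < (size_t)H * W * Cout; ++k) yp[k] = fp[k];
  }
  return List::create(_["y"] = y, _["col"] = col);
}

// backward using cached im2col matrices; dx computation can be skipped for
// the first layer (its input gradient is never used)
// [[Rcpp::export]]
List cpp_conv3x3_backward_cached(RawVector col, NumericMatrix w,
                                 NumericVector dy, bool computeDx) {
  int H, W, Cout, N; dims4(dy, H, W, Cout, N);
  int K = w.nrow();      // 9 * C_in
  int C = K / 9;
  arma::fmat Wf = toF(w.begin(), K, Cout);
  NumericMatrix dw(K, Cout);
  arma::fmat dWf(K, Cout, arma::fill::zeros);
  NumericVector dx;
  if (computeDx) {
    dx = NumericVector((R_xlen_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  float* colp = reinterpret_cast<float*>(RAW(col));
  arma::fmat dcol((size_t)H * W, (size_t)K);
  for (int n = 0; n < N; ++n) {
    arma::fmat Cn(colp + (size_t)n * K * H * W, (size_t)H * W, (size_t)K,
                  false, true);
    arma::fmat dY = toF(dy.begin() + (size_t)n * Cout * H * W, (size_t)H * W, Cout);
    dWf += Cn.t() * dY;
    if (computeDx) {
      dcol = dY * Wf.t();
      col2im3x3(dcol, H, W, C, dx.begin() + (size_t)n * C * H * W);
    }
  }
  for (int k = 0; k < K * Cout; ++k) dw[k] = dWf.memptr()[k];
  return List::create(_["dx"] = dx, _["dw"] = dw);
}
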