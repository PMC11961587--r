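// Convolution / pooling / resampling kernels for the autodiff core.
// Array layout everywhere: [H, W, C, B] column-major (H fastest), matching R.
// Conv weights: [kh, kw, Cin, Cout]; depthwise weights: [kh, kw, C].

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((size_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static NumericVector alloc3(int a, int b, int c) {
  NumericVector v((size_t)a * b * c);
  v.attr("dim") = IntegerVector::create(a, b, c);
  return v;
}

// im2col for one sample: x is [H, W, C] (flat), columns indexed by output
// pixel (ho + Ho*wo), rows by (i + kh*j + kh*kw*c). Zero padding.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   arma::mat& cols) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      double* dst = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          const int w = wo * stride - pad + j;
          for (int i = 0; i < kh; ++i) {
            const int h = ho * stride - pad + i;
            const int row = i + kh * j + kh * kw * c;
            dst[row] = (h >= 0 && h < H && w >= 0 && w < W)
                       ? xc[h + (size_t)H * w] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int H, int W, int C,
                   int kh, int kw, int stride, int pad, double* gx) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const double* src = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        double* gc = gx + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          const int w = wo * stride - pad + j;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int h = ho * stride - pad + i;
            if (h < 0 || h >= H) continue;
            gc[h + (size_t)H * w] += src[i + kh * j + kh * kw * c];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector bias,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  arma::mat wmat(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false);
  NumericVector y = alloc4(Ho, Wo, Cout, B);
  arma::mat cols((size_t)kh * kw * C, (size_t)Ho * Wo);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)H * W * C * b, H, W, C, kh, kw, stride, pad, cols);
    arma::mat out = cols.t() * wmat;  // [HoWo, Cout]
    double* yb = y.begin() + (size_t)Ho * Wo * Cout * b;
    for (int c = 0; c < Cout; ++c) {
      const double bc = bias[c];
      const double* oc = out.colptr(c);
      double* yc = yb + (size_t)Ho * Wo * c;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) yc[p] = oc[p] + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  arma::mat wmat(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout, false);
  NumericVector gx = alloc4(H, W, C, B);
  NumericVector gw = alloc4(kh, kw, Cin, Cout);
  NumericVector gb(Cout);
  arma::mat gwmat(gw.begin(), (size_t)kh * kw * Cin, Cout, false);
  arma::mat cols((size_t)kh * kw * C, (size_t)Ho * Wo);
  for (int b = 0; b < B; ++b) {
    const double* gyb = gy.begin() + (size_t)Ho * Wo * Cout * b;
    arma::mat gmat(const_cast<double*>(gyb), (size_t)Ho * Wo, Cout, false);
    im2col(x.begin() + (size_t)H * W * C * b, H, W, C, kh, kw, stride, pad, cols);
    gwmat += cols * gmat;
    arma::mat gcols = wmat * gmat.t();  // [khkwC, HoWo]
    col2im(gcols, H, W, C, kh, kw, stride, pad,
           gx.begin() + (size_t)H * W * C * b);
    for (int c = 0; c < Cout; ++c) {
      const double* gc = gmat.colptr(c);
      double s = 0.0;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) s += gc[p];
      gb[c] += s;
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Depthwise 3x3-style conv: weights [kh, kw, C].
// [[Rcpp::export]]
NumericVector dwconv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector bias,
                               int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  NumericVector y = alloc4(Ho, Wo, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * b);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double s = bias[c];
          for (int j = 0; j < kw; ++j) {
            const int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              s += wc[i + kh * j] * xc[hi + (size_t)H * wi];
            }
          }
          yc[ho + (size_t)Ho * wo] = s;
        }
    }
  return y;
}

// [[Rcpp::export]]
List dwconv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                      int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = gd[0], Wo = gd[1];
  NumericVector gx = alloc4(H, W, C, B);
  NumericVector gw = alloc3(kh, kw, C);
  NumericVector gb(C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * b);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      const double* gc = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      double* gxc = gx.begin() + (size_t)H * W * (c + (size_t)C * b);
      double* gwc = gw.begin() + (size_t)kh * kw * c;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gc[ho + (size_t)Ho * wo];
          gb[c] += g;
          for (int j = 0; j < kw; ++j) {
            const int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              gwc[i + kh * j] += g * xc[hi + (size_t)H * wi];
              gxc[hi + (size_t)H * wi] += g * wc[i + kh * j];
            }
          }
        }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Average pooling, no padding; H, W need not divide exactly (trailing cells
// dropped as usual when (in - k) %% stride != 0).
// [[Rcpp::export]]
NumericVector avgpool_fwd_cpp(NumericVector x, int kh, int kw, int sh, int sw) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = (H - kh) / sh + 1, Wo = (W - kw) / sw + 1;
  NumericVector y = alloc4(Ho, Wo, C, B);
  const double inv = 1.0 / (kh * kw);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * b);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double s = 0.0;
          for (int j = 0; j < kw; ++j)
            for (int i = 0; i < kh; ++i)
              s += xc[(ho * sh + i) + (size_t)H * (wo * sw + j)];
          yc[ho + (size_t)Ho * wo] = s * inv;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool_bwd_cpp(NumericVector gy, int H, int W,
                              int kh, int kw, int sh, int sw) {
  IntegerVector gd = gy.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2], B = gd[3];
  NumericVector gx = alloc4(H, W, C, B);
  const double inv = 1.0 / (kh * kw);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* gc = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      double* gxc = gx.begin() + (size_t)H * W * (c + (size_t)C * b);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gc[ho + (size_t)Ho * wo] * inv;
          for (int j = 0; j < kw; ++j)
            for (int i = 0; i < kh; ++i)
              gxc[(ho * sh + i) + (size_t)H * (wo * sw + j)] += g;
        }
    }
  return gx;
}

// Bilinear resize to (Ho, Wo), half-pixel centers (align_corners = FALSE).
// [[Rcpp::export]]
NumericVector bilinear_fwd_cpp(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  NumericVector y = alloc4(Ho, Wo, C, B);
  const double fh = (double)H / Ho, fw = (double)W / Wo;
  std::vector<int> h0(Ho), h1(Ho); std::vector<double> wh(Ho);
  std::vector<int> w0(Wo), w1(Wo); std::vector<double> ww(Wo);
  for (int o = 0; o < Ho; ++o) {
    double src = (o + 0.5) * fh - 0.5;
    if (src < 0) src = 0;
    int lo = (int)std::floor(src);
    if (lo > H - 1) lo = H - 1;
    h0[o] = lo; h1[o] = std::min(lo + 1, H - 1); wh[o] = src - lo;
  }
  for (int o = 0; o < Wo; ++o) {
    double src = (o + 0.5) * fw - 0.5;
    if (src < 0) src = 0;
    int lo = (int)std::floor(src);
    if (lo > W - 1) lo = W - 1;
    w0[o] = lo; w1[o] = std::min(lo + 1, W - 1); ww[o] = src - lo;
  }
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * b);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io) {
          const double a = wh[io], bwt = ww[jo];
          const double v00 = xc[h0[io] + (size_t)H * w0[jo]];
          const double v10 = xc[h1[io] + (size_t)H * w0[jo]];
          const double v01 = xc[h0[io] + (size_t)H * w1[jo]];
          const double v11 = xc[h1[io] + (size_t)H * w1[jo]];
          yc[io + (size_t)Ho * jo] =
            (1 - a) * (1 - bwt) * v00 + a * (1 - bwt) * v10 +
            (1 - a) * bwt * v01 + a * bwt * v11;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector bilinear_bwd_cpp(NumericVector gy, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2], B = gd[3];
  NumericVector gx = alloc4(H, W, C, B);
  const double fh = (double)H / Ho, fw = (double)W / Wo;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* gc = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      double* gxc = gx.begin() + (size_t)H * W * (c + (size_t)C * b);
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io) {
          double sh = (io + 0.5) * fh - 0.5; if (sh < 0) sh = 0;
          int h0 = (int)std::floor(sh); if (h0 > H - 1) h0 = H - 1;
          int h1 = std::min(h0 + 1, H - 1);
          double a = sh - h0;
          double sw = (jo + 0.5) * fw - 0.5; if (sw < 0) sw = 0;
          int w0 = (int)std::floor(sw); if (w0 > W - 1) w0 = W - 1;
          int w1 = std::min(w0 + 1, W - 1);
          double bwt = sw - w0;
          const double g = gc[io + (size_t)Ho * jo];
          gxc[h0 + (size_t)H * w0] += (1 - a) * (1 - bwt) * g;
          gxc[h1 + (size_t)H * w0] += a * (1 - bwt) * g;
          gxc[h0 + (size_t)H * w1] += (1 - a) * bwt * g;
          gxc[h1 + (size_t)H * w1] += a * bwt * g;
        }
    }
  return gx;
}

// Nearest-neighbour upsample by integer factors (token broadcast).
// [[Rcpp::export]]
NumericVector nearest_up_fwd_cpp(NumericVector x, int fh, int fw) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = H * fh, Wo = W * fw;
  NumericVector y = alloc4(Ho, Wo, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * b);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io)
          yc[io + (size_t)Ho * jo] = xc[(io / fh) + (size_t)H * (jo / fw)];
    }
  return y;
}

// [[Rcpp::export]]
NumericVector nearest_up_bwd_cpp(NumericVector gy, int fh, int fw) {
  IntegerVector gd = gy.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2], B = gd[3];
  const int H = Ho / fh, W = Wo / fw;
  NumericVector gx = alloc4(H, W, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* gc = gy.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      double* gxc = gx.begin() + (size_t)H * W * (c + (size_t)C * b);
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io)
          gxc[(io / fh) + (size_t)H * (jo / fw)] += gc[io + (size_t)Ho * jo];
    }
  return gx;
}
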