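// Minimal batched tensor primitives for the attention U-Net stack.
// Layout convention everywhere: column-major R arrays dim (H, W, C, N).
// Convolutions go through im2col + GEMM in single precision (the usual
// arithmetic for convolutional networks; halves memory traffic and GEMM
// time relative to double); results return as R doubles. Backward passes
// rebuild the column matrix instead of caching it, keeping peak memory
// proportional to one layer.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword out_side(int in, int k, int stride, int pad) {
  return (arma::uword)((in + 2 * pad - k) / stride + 1);
}

// Fill the per-sample transposed column matrix Kt (Ho*Wo x kh*kw*C) from
// one sample plane set x_n (H,W,C). Column r = ki + kh*kj + kh*kw*c holds
// the shifted image; for unit stride each (ow, c, kj, ki) slice is a
// contiguous run over oh, so the fill is a clipped strided copy rather
// than a per-element branch.
static void im2col_t_fill(const double* xn, int H, int W, int C,
                          int kh, int kw, int stride, int pad,
                          int Ho, int Wo, arma::fmat& Kt) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = xn + HW * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        float* col = Kt.colptr((arma::uword)ki + (arma::uword)kh * kj +
                               (arma::uword)kh * kw * c);
        for (int ow = 0; ow < Wo; ++ow) {
          int w = ow * stride - pad + kj;
          float* dst = col + (size_t)Ho * ow;
          if (w < 0 || w >= W) {
            std::fill(dst, dst + Ho, 0.0f);
            continue;
          }
          const double* src = xc + (size_t)H * w;
          // valid oh range: 0 <= oh*stride - pad + ki <= H-1
          int lo = 0;
          while (lo < Ho && lo * stride - pad + ki < 0) ++lo;
          int hi = Ho;
          while (hi > lo && (hi - 1) * stride - pad + ki >= H) --hi;
          for (int oh = 0; oh < lo; ++oh) dst[oh] = 0.0f;
          for (int oh = lo; oh < hi; ++oh)
            dst[oh] = (float)src[oh * stride - pad + ki];
          for (int oh = hi; oh < Ho; ++oh) dst[oh] = 0.0f;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch (%d vs %d)", Cin, C);
  int Ho = (int)out_side(H, kh, stride, pad);
  int Wo = (int)out_side(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  const arma::uword kk = (arma::uword)kh * kw * C;
  const size_t HoWo = (size_t)Ho * Wo;

  arma::fmat Wm(kk, (arma::uword)Cout);
  { float* o = Wm.memptr();
    for (arma::uword i = 0; i < kk * Cout; ++i) o[i] = (float)w[i]; }

  NumericVector y((R_xlen_t)HoWo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::fmat Kt((arma::uword)HoWo, kk);
  const bool has_b = b.size() > 0;
  for (int n = 0; n < N; ++n) {
    im2col_t_fill(x.begin() + (size_t)H * W * C * n, H, W, C,
                  kh, kw, stride, pad, Ho, Wo, Kt);
    arma::fmat Yn = Kt * Wm;  // (Ho*Wo) x Cout
    double* dst = y.begin() + HoWo * (size_t)Cout * n;
    const float* src = Yn.memptr();
    for (int c = 0; c < Cout; ++c) {
      const double bias = has_b ? b[c] : 0.0;
      for (size_t p = 0; p < HoWo; ++p)
        dst[p + HoWo * c] = (double)src[p + HoWo * c] + bias;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, bool want_gx, bool want_gb,
                    bool want_gw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  const arma::uword kk = (arma::uword)kh * kw * C;
  const size_t HoWo = (size_t)Ho * Wo;

  arma::fmat GW(kk, (arma::uword)Cout, arma::fill::zeros);
  arma::fvec GB((arma::uword)Cout, arma::fill::zeros);
  arma::fmat Wm;
  if (want_gx) {
    Wm.set_size(kk, (arma::uword)Cout);
    float* o = Wm.memptr();
    for (arma::uword i = 0; i < kk * Cout; ++i) o[i] = (float)w[i];
  }
  NumericVector gx;
  if (want_gx) {
    gx = NumericVector((R_xlen_t)H * W * C * N);
    gx.attr("dim") = IntegerVector::create(H, W, C, N);
  }

  arma::fmat Kt, Gn((arma::uword)HoWo, (arma::uword)Cout);
  if (want_gw) Kt.set_size((arma::uword)HoWo, kk);
  for (int n = 0; n < N; ++n) {
    const double* gsrc = gy.begin() + HoWo * (size_t)Cout * n;
    float* gdst = Gn.memptr();
    for (size_t i = 0; i < HoWo * (size_t)Cout; ++i) gdst[i] = (float)gsrc[i];
    if (want_gb) GB += arma::sum(Gn, 0).t();
    if (want_gw) {
      im2col_t_fill(x.begin() + (size_t)H * W * C * n, H, W, C,
                    kh, kw, stride, pad, Ho, Wo, Kt);
      GW += Kt.t() * Gn;
    }
    if (want_gx) {
      arma::fmat Gc = Gn * Wm.t();  // (Ho*Wo) x (kh*kw*C), col2im adjoint
      double* xn = gx.begin() + (size_t)H * W * C * n;
      for (int c = 0; c < C; ++c) {
        double* xc = xn + (size_t)H * W * c;
        for (int kj = 0; kj < kw; ++kj)
          for (int ki = 0; ki < kh; ++ki) {
            const float* col = Gc.colptr((arma::uword)ki +
                                         (arma::uword)kh * kj +
                                         (arma::uword)kh * kw * c);
            for (int ow = 0; ow < Wo; ++ow) {
              int wcol = ow * stride - pad + kj;
              if (wcol < 0 || wcol >= W) continue;
              double* dst = xc + (size_t)H * wcol;
              const float* src = col + (size_t)Ho * ow;
              int lo = 0;
              while (lo < Ho && lo * stride - pad + ki < 0) ++lo;
              int hi = Ho;
              while (hi > lo && (hi - 1) * stride - pad + ki >= H) --hi;
              for (int oh = lo; oh < hi; ++oh)
                dst[oh * stride - pad + ki] += (double)src[oh];
            }
          }
      }
    }
  }

  NumericVector gw, gb;
  if (want_gw) {
    gw = NumericVector((R_xlen_t)kk * Cout);
    std::copy(GW.begin(), GW.end(), gw.begin());
    gw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  }
  if (want_gb) {
    gb = NumericVector(GB.size());
    std::copy(GB.begin(), GB.end(), gb.begin());
  }
  return List::create(_["gw"] = gw, _["gb"] = gb, _["gx"] = gx);
}

// Per-channel batch normalization over (H, W, N), double precision
// (memory-bound; done here to avoid R-side array permutations).
// [[Rcpp::export(name = ".cpp_bn_fwd")]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector mu_in, NumericVector var_in, bool train,
                double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W, plane = HW, stride_n = HW * C;
  NumericVector mu(C), var(C);
  const double* xp = x.begin();
  if (train) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = xp + stride_n * n + plane * c;
        for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      double m = s / (HW * N);
      double v = s2 / (HW * N) - m * m;
      mu[c] = m;
      var[c] = v > 0 ? v : 0;
    }
  } else {
    mu = mu_in;
    var = var_in;
  }
  NumericVector y((R_xlen_t)x.size()), xhat((R_xlen_t)x.size());
  y.attr("dim") = xd;
  xhat.attr("dim") = xd;
  double* yp = y.begin();
  double* hp = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], b = beta[c], m = mu[c];
    for (int n = 0; n < N; ++n) {
      const double* p = xp + stride_n * n + plane * c;
      double* yo = yp + stride_n * n + plane * c;
      double* ho = hp + stride_n * n + plane * c;
      for (size_t i = 0; i < HW; ++i) {
        double h = (p[i] - m) * inv;
        ho[i] = h;
        yo[i] = g * h + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var);
}

// [[Rcpp::export(name = ".cpp_bn_bwd")]]
List cpp_bn_bwd(NumericVector gy, NumericVector xhat, NumericVector gamma,
                NumericVector var, bool train, double eps) {
  IntegerVector xd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W, plane = HW, stride_n = HW * C;
  const double m_count = (double)HW * N;
  NumericVector ggamma(C), gbeta(C);
  NumericVector gx((R_xlen_t)gy.size());
  gx.attr("dim") = xd;
  const double* gp = gy.begin();
  const double* hp = xhat.begin();
  double* op = gx.begin();
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgh = 0;
    for (int n = 0; n < N; ++n) {
      const double* g = gp + stride_n * n + plane * c;
      const double* h = hp + stride_n * n + plane * c;
      for (size_t i = 0; i < HW; ++i) { sg += g[i]; sgh += g[i] * h[i]; }
    }
    ggamma[c] = sgh;
    gbeta[c] = sg;
    const double scale = gamma[c] / std::sqrt(var[c] + eps);
    const double mg = sg / m_count, mgh = sgh / m_count;
    for (int n = 0; n < N; ++n) {
      const double* g = gp + stride_n * n + plane * c;
      const double* h = hp + stride_n * n + plane * c;
      double* o = op + stride_n * n + plane * c;
      if (train)
        for (size_t i = 0; i < HW; ++i)
          o[i] = scale * (g[i] - mg - h[i] * mgh);
      else
        for (size_t i = 0; i < HW; ++i) o[i] = scale * g[i];
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// 2x2 max pooling, stride 2. Returns pooled values and the argmax code
// (0..3 = di + 2*dj) needed for the backward scatter.
// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t q = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* plane = xp + (size_t)H * W * cn;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh) {
        const double* base = plane + (size_t)H * (2 * ow) + 2 * oh;
        double best = base[0]; int code = 0;
        if (base[1] > best) { best = base[1]; code = 1; }
        if (base[H] > best) { best = base[H]; code = 2; }
        if (base[H + 1] > best) { best = base[H + 1]; code = 3; }
        yp[(size_t)oh + (size_t)Ho * ow + (size_t)Ho * Wo * cn] = best;
        ip[(size_t)oh + (size_t)Ho * ow + (size_t)Ho * Wo * cn] = code;
        (void)q;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx,
                               int H, int W) {
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = gy.begin();
  const int* ip = idx.begin();
  double* xp = gx.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    double* plane = xp + (size_t)H * W * cn;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh) {
        size_t o = (size_t)oh + (size_t)Ho * ow + (size_t)Ho * Wo * cn;
        int code = ip[o];
        int di = code & 1, dj = code >> 1;
        plane[(size_t)H * (2 * ow + dj) + 2 * oh + di] += gp[o];
      }
  }
  return gx;
}

// Bilinear resize with the half-pixel convention; clamped at borders.
// [[Rcpp::export(name = ".cpp_bilinear_fwd")]]
NumericVector cpp_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> y0(Ho), y1(Ho), x0(Wo), x1(Wo);
  std::vector<double> wy(Ho), wx(Wo);
  for (int oh = 0; oh < Ho; ++oh) {
    double s = (oh + 0.5) * (double)H / Ho - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    y0[oh] = (int)std::floor(s);
    y1[oh] = std::min(y0[oh] + 1, H - 1);
    wy[oh] = s - y0[oh];
  }
  for (int ow = 0; ow < Wo; ++ow) {
    double s = (ow + 0.5) * (double)W / Wo - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    x0[ow] = (int)std::floor(s);
    x1[ow] = std::min(x0[ow] + 1, W - 1);
    wx[ow] = s - x0[ow];
  }
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* plane = xp + (size_t)H * W * cn;
    double* out = yp + (size_t)Ho * Wo * cn;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh) {
        const double a = (1 - wy[oh]) * (1 - wx[ow]);
        const double b = wy[oh] * (1 - wx[ow]);
        const double c = (1 - wy[oh]) * wx[ow];
        const double d = wy[oh] * wx[ow];
        out[(size_t)oh + (size_t)Ho * ow] =
            a * plane[(size_t)H * x0[ow] + y0[oh]] +
            b * plane[(size_t)H * x0[ow] + y1[oh]] +
            c * plane[(size_t)H * x1[ow] + y0[oh]] +
            d * plane[(size_t)H * x1[ow] + y1[oh]];
      }
  }
  return y;
}

// Adjoint of cpp_bilinear_fwd (scatter-add with identical weights).
// [[Rcpp::export(name = ".cpp_bilinear_bwd")]]
NumericVector cpp_bilinear_bwd(NumericVector gy, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> y0(Ho), y1(Ho), x0(Wo), x1(Wo);
  std::vector<double> wy(Ho), wx(Wo);
  for (int oh = 0; oh < Ho; ++oh) {
    double s = (oh + 0.5) * (double)H / Ho - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    y0[oh] = (int)std::floor(s);
    y1[oh] = std::min(y0[oh] + 1, H - 1);
    wy[oh] = s - y0[oh];
  }
  for (int ow = 0; ow < Wo; ++ow) {
    double s = (ow + 0.5) * (double)W / Wo - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    x0[ow] = (int)std::floor(s);
    x1[ow] = std::min(x0[ow] + 1, W - 1);
    wx[ow] = s - x0[ow];
  }
  const double* gp = gy.begin();
  double* xp = gx.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    double* plane = xp + (size_t)H * W * cn;
    const double* in = gp + (size_t)Ho * Wo * cn;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh) {
        const double g = in[(size_t)oh + (size_t)Ho * ow];
        plane[(size_t)H * x0[ow] + y0[oh]] += g * (1 - wy[oh]) * (1 - wx[ow]);
        plane[(size_t)H * x0[ow] + y1[oh]] += g * wy[oh] * (1 - wx[ow]);
        plane[(size_t)H * x1[ow] + y0[oh]] += g * (1 - wy[oh]) * wx[ow];
        plane[(size_t)H * x1[ow] + y1[oh]] += g * wy[oh] * wx[ow];
      }
  }
  return gx;
}

// 2x2 average pooling (used to build the multi-level attention targets).
// [[Rcpp::export(name = ".cpp_avgpool2")]]
NumericVector cpp_avgpool2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int cn = 0; cn < C * N; ++cn) {
    const double* plane = xp + (size_t)H * W * cn;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh) {
        const double* base = plane + (size_t)H * (2 * ow) + 2 * oh;
        yp[(size_t)oh + (size_t)Ho * ow + (size_t)Ho * Wo * cn] =
            0.25 * (base[0] + base[1] + base[H] + base[H + 1]);
      }
  }
  return y;
}

// ---- cheap elementwise kernels (single pass, no temporaries) ----------

// [[Rcpp::export(name = ".cpp_relu_fwd")]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export(name = ".cpp_relu_bwd")]]
NumericVector cpp_relu_bwd(NumericVector gy, NumericVector x) {
  NumericVector g(gy.size());
  g.attr("dim") = gy.attr("dim");
  const double* gp = gy.begin();
  const double* xp = x.begin();
  double* op = g.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) op[i] = xp[i] > 0 ? gp[i] : 0.0;
  return g;
}

// [[Rcpp::export(name = ".cpp_lrelu_fwd")]]
NumericVector cpp_lrelu_fwd(NumericVector x, double alpha) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    yp[i] = xp[i] > 0 ? xp[i] : alpha * xp[i];
  return y;
}

// [[Rcpp::export(name = ".cpp_lrelu_bwd")]]
NumericVector cpp_lrelu_bwd(NumericVector gy, NumericVector x, double alpha) {
  NumericVector g(gy.size());
  g.attr("dim") = gy.attr("dim");
  const double* gp = gy.begin();
  const double* xp = x.begin();
  double* op = g.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    op[i] = xp[i] > 0 ? gp[i] : alpha * gp[i];
  return g;
}

// Broadcast-multiply a (H,W,1,N) gate over the channels of (H,W,C,N).
// [[Rcpp::export(name = ".cpp_gate_mul")]]
NumericVector cpp_gate_mul(NumericVector x, NumericVector g) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* gn = gp + HW * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + HW * ((size_t)c + (size_t)C * n);
      double* yc = yp + HW * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yc[i] = xc[i] * gn[i];
    }
  }
  return y;
}

// Sum (H,W,C,N) over the channel axis -> (H,W,1,N).
// [[Rcpp::export(name = ".cpp_sum_ch")]]
NumericVector cpp_sum_ch(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector y((R_xlen_t)HW * N);
  y.attr("dim") = IntegerVector::create(H, W, 1, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  std::fill(yp, yp + HW * N, 0.0);
  for (int n = 0; n < N; ++n) {
    double* yn = yp + HW * n;
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + HW * ((size_t)c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) yn[i] += xc[i];
    }
  }
  return y;
}

// Channel-axis max and mean pooling with argmax channel (1-based).
// [[Rcpp::export(name = ".cpp_chanpool_fwd")]]
List cpp_chanpool_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector mp((R_xlen_t)HW * N), ap((R_xlen_t)HW * N);
  IntegerVector idx((R_xlen_t)HW * N);
  mp.attr("dim") = IntegerVector::create(H, W, 1, N);
  ap.attr("dim") = IntegerVector::create(H, W, 1, N);
  idx.attr("dim") = IntegerVector::create(H, W, 1, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    double* m = mp.begin() + HW * n;
    double* a = ap.begin() + HW * n;
    int* id = idx.begin() + HW * n;
    const double* x0 = xp + HW * (size_t)C * n;
    for (size_t i = 0; i < HW; ++i) { m[i] = x0[i]; a[i] = x0[i]; id[i] = 1; }
    for (int c = 1; c < C; ++c) {
      const double* xc = x0 + HW * c;
      for (size_t i = 0; i < HW; ++i) {
        a[i] += xc[i];
        if (xc[i] > m[i]) { m[i] = xc[i]; id[i] = c + 1; }
      }
    }
    for (size_t i = 0; i < HW; ++i) a[i] /= C;
  }
  return List::create(_["mp"] = mp, _["ap"] = ap, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_chanpool_bwd")]]
NumericVector cpp_chanpool_bwd(NumericVector gmp, NumericVector gap,
                               IntegerVector idx, int C) {
  IntegerVector gd = gmp.attr("dim");
  int H = gd[0], W = gd[1], N = gd[3];
  const size_t HW = (size_t)H * W;
  NumericVector gx((R_xlen_t)HW * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  double* gp = gx.begin();
  for (int n = 0; n < N; ++n) {
    const double* gm = gmp.begin() + HW * n;
    const double* ga = gap.begin() + HW * n;
    const int* id = idx.begin() + HW * n;
    double* g0 = gp + HW * (size_t)C * n;
    for (int c = 0; c < C; ++c) {
      double* gc = g0 + HW * c;
      for (size_t i = 0; i < HW; ++i)
        gc[i] = ga[i] / C + (id[i] == c + 1 ? gm[i] : 0.0);
    }
  }
  return gx;
}
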