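// Low-level numeric kernels for clemosaic.
//
// Tensor layout convention: dense feature maps are R arrays with
// dim = c(H, W, C, N) (column-major), i.e. element (h, w, c, n) sits at
// h + H*(w + W*(c + C*n)), all indices 0-based. Single images are plain
// H x W matrices. Pixel coordinates in the geometry kernels are 0-based
// (x = column, y = row).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int reflect_idx(int p, int n) {
  // reflect-101 (mirror about the edge pixel): -1 -> 1, n -> n-2
  if (n == 1) return 0;
  while (p < 0 || p >= n) {
    if (p < 0) p = -p;
    if (p >= n) p = 2 * n - 2 - p;
  }
  return p;
}

// ---------------------------------------------------------------------------
// conv2d, stride 1, same zero padding
// x: (H,W,Cin,N), w: (kh,kw,Cin,Cout), b: length Cout
// ---------------------------------------------------------------------------

static void im2col(const double* x, int H, int W, int Cin,
                   int kh, int kw, arma::mat& col) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  // col: (Cin*kh*kw) x (H*W); row r = ki + kh*(kj + kw*ci)
  col.zeros();
  const size_t R = col.n_rows;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)H * W * ci;
    for (int kj = 0; kj < kw; ++kj) {
      const int w_lo = std::max(0, pw - kj);
      const int w_hi = std::min(W, W + pw - kj);
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ci);
        const int h_lo = std::max(0, ph - ki);
        const int h_hi = std::min(H, H + ph - ki);
        double* crow = col.memptr() + r; // stride = col.n_rows
        for (int w0 = w_lo; w0 < w_hi; ++w0) {
          const double* xcol = xc + (size_t)H * (w0 + kj - pw) + (ki - ph);
          double* cc = crow + R * (size_t)H * w0;
          for (int h0 = h_lo; h0 < h_hi; ++h0) {
            cc[R * (size_t)h0] = xcol[h0];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int H, int W, int Cin,
                       int kh, int kw, double* dx) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const size_t R = col.n_rows;
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = dx + (size_t)H * W * ci;
    for (int kj = 0; kj < kw; ++kj) {
      const int w_lo = std::max(0, pw - kj);
      const int w_hi = std::min(W, W + pw - kj);
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ci);
        const int h_lo = std::max(0, ph - ki);
        const int h_hi = std::min(H, H + ph - ki);
        const double* crow = col.memptr() + r;
        for (int w0 = w_lo; w0 < w_hi; ++w0) {
          double* xcol = xc + (size_t)H * (w0 + kj - pw) + (ki - ph);
          const double* cc = crow + R * (size_t)H * w0;
          for (int h0 = h_lo; h0 < h_hi; ++h0) {
            xcol[h0] += cc[R * (size_t)h0];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: channel mismatch");
  NumericVector y((size_t)H * W * (size_t)Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);

  // weight matrix: Cout x (Cin*kh*kw)
  arma::mat Wm(Cout, (size_t)Cin * kh * kw);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          Wm(co, ki + kh * (kj + kw * ci)) =
            w[ki + (size_t)kh * (kj + (size_t)kw * (ci + (size_t)Cin * co))];

  arma::mat col((size_t)Cin * kh * kw, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, kh, kw, col);
    arma::mat ym = Wm * col; // Cout x HW
    double* yp = y.begin() + (size_t)H * W * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double bb = b[co];
      double* ypc = yp + (size_t)H * W * co;
      for (size_t p = 0; p < (size_t)H * W; ++p) ypc[p] = ym(co, p) + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];

  arma::mat Wm(Cout, (size_t)Cin * kh * kw);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          Wm(co, ki + kh * (kj + kw * ci)) =
            w[ki + (size_t)kh * (kj + (size_t)kw * (ci + (size_t)Cin * co))];

  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat dWm(Cout, (size_t)Cin * kh * kw, arma::fill::zeros);
  NumericVector db(Cout);

  arma::mat col((size_t)Cin * kh * kw, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, kh, kw, col);
    // dy as Cout x HW
    arma::mat dym(Cout, (size_t)H * W);
    const double* dyp = dy.begin() + (size_t)H * W * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double* dypc = dyp + (size_t)H * W * co;
      for (size_t p = 0; p < (size_t)H * W; ++p) dym(co, p) = dypc[p];
      db[co] += arma::accu(dym.row(co));
    }
    dWm += dym * col.t();
    arma::mat dcol = Wm.t() * dym; // (Cin*kh*kw) x HW
    col2im_add(dcol, H, W, Cin, kh, kw, dx.begin() + (size_t)H * W * Cin * n);
  }

  NumericVector dw((size_t)kh * kw * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          dw[ki + (size_t)kh * (kj + (size_t)kw * (ci + (size_t)Cin * co))] =
            dWm(co, ki + kh * (kj + kw * ci));

  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// depthwise correlation with a single shared kernel, reflect-101 padding
// (used for the fixed Gaussian layers and for classical-pipeline blurs)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, NumericMatrix k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = k.nrow(), kw = k.ncol();
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector y((size_t)H * W * C * N);
  y.attr("dim") = xd;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xc = x.begin() + (size_t)H * W * cn;
    double* yc = y.begin() + (size_t)H * W * cn;
    for (int w0 = 0; w0 < W; ++w0) {
      for (int h0 = 0; h0 < H; ++h0) {
        double acc = 0.0;
        for (int kj = 0; kj < kw; ++kj) {
          const int ws = reflect_idx(w0 + kj - pw, W);
          const double* xcol = xc + (size_t)H * ws;
          for (int ki = 0; ki < kh; ++ki)
            acc += k(ki, kj) * xcol[reflect_idx(h0 + ki - ph, H)];
        }
        yc[h0 + (size_t)H * w0] = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector dwconv_bwd_cpp(NumericVector dy, NumericMatrix k) {
  // adjoint of dwconv_fwd (kernel fixed): scatter-add through the
  // reflect-101 index map
  IntegerVector xd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = k.nrow(), kw = k.ncol();
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* dyc = dy.begin() + (size_t)H * W * cn;
    double* dxc = dx.begin() + (size_t)H * W * cn;
    for (int w0 = 0; w0 < W; ++w0) {
      for (int h0 = 0; h0 < H; ++h0) {
        const double g = dyc[h0 + (size_t)H * w0];
        if (g == 0.0) continue;
        for (int kj = 0; kj < kw; ++kj) {
          const int ws = reflect_idx(w0 + kj - pw, W);
          double* dxcol = dxc + (size_t)H * ws;
          for (int ki = 0; ki < kh; ++ki)
            dxcol[reflect_idx(h0 + ki - ph, H)] += k(ki, kj) * g;
        }
      }
    }
  }
  return dx;
}

// ---------------------------------------------------------------------------
// 2x2 max pooling, stride 2
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // linear index into x
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xc = x.begin() + (size_t)H * W * cn;
    double* yc = y.begin() + (size_t)Ho * Wo * cn;
    int* ic = idx.begin() + (size_t)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -HUGE_VAL; int bi = 0;
        for (int dw = 0; dw < 2; ++dw) {
          for (int dh = 0; dh < 2; ++dh) {
            const int hh = 2 * ho + dh, ww = 2 * wo + dw;
            const double v = xc[hh + (size_t)H * ww];
            if (v > best) { best = v; bi = hh + H * ww; }
          }
        }
        yc[ho + (size_t)Ho * wo] = best;
        ic[ho + (size_t)Ho * wo] = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector idx,
                               int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* dyc = dy.begin() + (size_t)Ho * Wo * cn;
    const int* ic = idx.begin() + (size_t)Ho * Wo * cn;
    double* dxc = dx.begin() + (size_t)H * W * cn;
    for (size_t p = 0; p < (size_t)Ho * Wo; ++p) dxc[ic[p]] += dyc[p];
  }
  return dx;
}

// ---------------------------------------------------------------------------
// 2x bilinear upsampling (align_corners = FALSE convention)
// ---------------------------------------------------------------------------

static inline void up2_coef(int i, int n, int& i0, int& i1, double& a) {
  double s = (i + 0.5) / 2.0 - 0.5;
  if (s < 0) s = 0;
  if (s > n - 1) s = n - 1;
  i0 = (int)std::floor(s);
  i1 = i0 + 1 < n ? i0 + 1 : i0;
  a = s - i0;
}

// [[Rcpp::export]]
NumericVector up2_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ah(Ho), aw(Wo);
  for (int i = 0; i < Ho; ++i) up2_coef(i, H, h0[i], h1[i], ah[i]);
  for (int j = 0; j < Wo; ++j) up2_coef(j, W, w0[j], w1[j], aw[j]);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xc = x.begin() + (size_t)H * W * cn;
    double* yc = y.begin() + (size_t)Ho * Wo * cn;
    for (int j = 0; j < Wo; ++j) {
      const double* c0 = xc + (size_t)H * w0[j];
      const double* c1 = xc + (size_t)H * w1[j];
      for (int i = 0; i < Ho; ++i) {
        const double top = (1 - aw[j]) * c0[h0[i]] + aw[j] * c1[h0[i]];
        const double bot = (1 - aw[j]) * c0[h1[i]] + aw[j] * c1[h1[i]];
        yc[i + (size_t)Ho * j] = (1 - ah[i]) * top + ah[i] * bot;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector up2_bwd_cpp(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ah(Ho), aw(Wo);
  for (int i = 0; i < Ho; ++i) up2_coef(i, H, h0[i], h1[i], ah[i]);
  for (int j = 0; j < Wo; ++j) up2_coef(j, W, w0[j], w1[j], aw[j]);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* dyc = dy.begin() + (size_t)Ho * Wo * cn;
    double* dxc = dx.begin() + (size_t)H * W * cn;
    for (int j = 0; j < Wo; ++j) {
      double* c0 = dxc + (size_t)H * w0[j];
      double* c1 = dxc + (size_t)H * w1[j];
      for (int i = 0; i < Ho; ++i) {
        const double g = dyc[i + (size_t)Ho * j];
        c0[h0[i]] += (1 - aw[j]) * (1 - ah[i]) * g;
        c1[h0[i]] += aw[j] * (1 - ah[i]) * g;
        c0[h1[i]] += (1 - aw[j]) * ah[i] * g;
        c1[h1[i]] += aw[j] * ah[i] * g;
      }
    }
  }
  return dx;
}

// ---------------------------------------------------------------------------
// batch normalization helpers (per-channel over H, W, N)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector m(C), v(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double mu = s / (HW * N);
    m[c] = mu;
    double vv = s2 / (HW * N) - mu * mu;
    v[c] = vv > 0 ? vv : 0;
  }
  return List::create(_["mean"] = m, _["var"] = v);
}

// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, NumericVector m, NumericVector inv_sd,
                NumericVector gamma, NumericVector beta) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = xd;
  xhat.attr("dim") = xd;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = HW * (c + (size_t)C * n);
      const double mc = m[c], ic = inv_sd[c], gc = gamma[c], bc = beta[c];
      const double* px = x.begin() + off;
      double* ph = xhat.begin() + off;
      double* py = y.begin() + off;
      for (size_t i = 0; i < HW; ++i) {
        const double h = (px[i] - mc) * ic;
        ph[i] = h;
        py[i] = h * gc + bc;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dy, NumericVector xhat, NumericVector gamma,
                NumericVector inv_sd, bool training) {
  IntegerVector xd = dy.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  const double nred = (double)HW * N;
  NumericVector dgamma(C), dbeta(C), s1(C), s2(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = HW * (c + (size_t)C * n);
      const double* pd = dy.begin() + off;
      const double* ph = xhat.begin() + off;
      double a = 0, b = 0;
      for (size_t i = 0; i < HW; ++i) { a += pd[i] * ph[i]; b += pd[i]; }
      dgamma[c] += a;
      dbeta[c] += b;
    }
  }
  for (int c = 0; c < C; ++c) {
    s1[c] = dbeta[c] * gamma[c];      // sum of dxhat
    s2[c] = dgamma[c] * gamma[c];     // sum of dxhat * xhat
  }
  NumericVector dx(dy.size());
  dx.attr("dim") = xd;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = HW * (c + (size_t)C * n);
      const double* pd = dy.begin() + off;
      const double* ph = xhat.begin() + off;
      double* px = dx.begin() + off;
      const double gc = gamma[c], ic = inv_sd[c];
      if (training) {
        const double a1 = s1[c] / nred, a2 = s2[c] / nred;
        for (size_t i = 0; i < HW; ++i) {
          px[i] = ic * (pd[i] * gc - a1 - ph[i] * a2);
        }
      } else {
        for (size_t i = 0; i < HW; ++i) px[i] = pd[i] * gc * ic;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---------------------------------------------------------------------------
// geometry: inverse-mapped bilinear homography warp and flow remap
// img: H x W matrix; coordinates 0-based (x = col, y = row)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix warp_homography_cpp(NumericMatrix img, NumericMatrix hinv,
                                  int out_h, int out_w, double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  const double a = hinv(0, 0), b = hinv(0, 1), c = hinv(0, 2);
  const double d = hinv(1, 0), e = hinv(1, 1), f = hinv(1, 2);
  const double g = hinv(2, 0), h = hinv(2, 1), i = hinv(2, 2);
  for (int x = 0; x < out_w; ++x) {
    for (int y = 0; y < out_h; ++y) {
      const double wz = g * x + h * y + i;
      if (wz == 0.0) { out(y, x) = fill; continue; }
      const double xs = (a * x + b * y + c) / wz;
      const double ys = (d * x + e * y + f) / wz;
      if (xs < 0 || xs > W - 1 || ys < 0 || ys > H - 1) { out(y, x) = fill; continue; }
      const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      const int x1 = x0 + 1 < W ? x0 + 1 : x0;
      const int y1 = y0 + 1 < H ? y0 + 1 : y0;
      const double ax = xs - x0, ay = ys - y0;
      out(y, x) = (1 - ay) * ((1 - ax) * img(y0, x0) + ax * img(y0, x1)) +
                  ay * ((1 - ax) * img(y1, x0) + ax * img(y1, x1));
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// keypoint description: dominant orientation + 4x4x8 gradient-histogram
// descriptor, computed from an octave-level gradient field.
// pts: n x 3 (x, y, sigma) in 0-based octave pixel coordinates.
// ---------------------------------------------------------------------------

static inline double sample_clamped(const NumericMatrix& m, double x, double y) {
  const int H = m.nrow(), W = m.ncol();
  if (x < 0 || x > W - 1 || y < 0 || y > H - 1) return 0.0;
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  const int x1 = x0 + 1 < W ? x0 + 1 : x0;
  const int y1 = y0 + 1 < H ? y0 + 1 : y0;
  const double ax = x - x0, ay = y - y0;
  return (1 - ay) * ((1 - ax) * m(y0, x0) + ax * m(y0, x1)) +
         ay * ((1 - ax) * m(y1, x0) + ax * m(y1, x1));
}

// [[Rcpp::export]]
List sift_describe_cpp(NumericMatrix gx, NumericMatrix gy, NumericMatrix pts) {
  const int n = pts.nrow();
  const int H = gx.nrow(), W = gx.ncol();
  NumericVector ori(n);
  NumericMatrix desc(n, 128);
  const double two_pi = 2.0 * M_PI;
  for (int p = 0; p < n; ++p) {
    const double x = pts(p, 0), y = pts(p, 1), sigma = pts(p, 2);
    // --- dominant orientation: 36-bin Gaussian-weighted histogram ---
    const int r = std::max(2, (int)std::lround(4.5 * sigma));
    const int cx = (int)std::lround(x), cy = (int)std::lround(y);
    double hist[36] = {0};
    const double wdenom = 2.0 * (1.5 * sigma) * (1.5 * sigma);
    for (int dy = -r; dy <= r; ++dy) {
      const int yy = cy + dy;
      if (yy < 0 || yy >= H) continue;
      for (int dx = -r; dx <= r; ++dx) {
        const int xx = cx + dx;
        if (xx < 0 || xx >= W) continue;
        const double vx = gx(yy, xx), vy = gy(yy, xx);
        const double mag = std::sqrt(vx * vx + vy * vy);
        if (mag == 0) continue;
        double ang = std::atan2(vy, vx);
        if (ang < 0) ang += two_pi;
        const double ddx = xx - x, ddy = yy - y;
        const double wgt = mag * std::exp(-(ddx * ddx + ddy * ddy) / wdenom);
        int b = (int)(ang / two_pi * 36.0);
        if (b > 35) b = 35;
        hist[b] += wgt;
      }
    }
    double hs[36];
    int bmax = 0;
    for (int b = 0; b < 36; ++b) {
      hs[b] = (hist[b] + hist[(b + 1) % 36] + hist[(b + 35) % 36]) / 3.0;
      if (hs[b] > hs[bmax]) bmax = b;
    }
    const double theta = (bmax + 0.5) / 36.0 * two_pi;
    ori[p] = theta;
    // --- descriptor: 16x16 samples -> 4x4 cells x 8 orientation bins ---
    const double spacing = (sigma > 1 ? sigma : 1.0) * 0.5;
    const double co = std::cos(theta), so = std::sin(theta);
    const double wsig = 8.0 * spacing;
    double d[128] = {0};
    for (int gj = 0; gj < 16; ++gj) {
      const double u = (gj - 7.5) * spacing; // along rotated x
      for (int gi = 0; gi < 16; ++gi) {
        const double v = (gi - 7.5) * spacing; // along rotated y
        const double sx = x + u * co - v * so;
        const double sy = y + u * so + v * co;
        const double vx = sample_clamped(gx, sx, sy);
        const double vy = sample_clamped(gy, sx, sy);
        double mag = std::sqrt(vx * vx + vy * vy);
        if (mag == 0) continue;
        mag *= std::exp(-(u * u + v * v) / (2.0 * wsig * wsig));
        double ang = std::atan2(vy, vx) - theta;
        ang -= std::floor(ang / two_pi) * two_pi;
        int ob = (int)(ang / two_pi * 8.0);
        if (ob > 7) ob = 7;
        const int cell_r = gi / 4, cell_c = gj / 4;
        d[cell_r * 8 + cell_c * 32 + ob] += mag;
      }
    }
    double nrm = 0;
    for (int k = 0; k < 128; ++k) nrm += d[k] * d[k];
    nrm = std::sqrt(nrm);
    if (nrm > 0) for (int k = 0; k < 128; ++k) d[k] /= nrm;
    nrm = 0;
    for (int k = 0; k < 128; ++k) {
      if (d[k] > 0.2) d[k] = 0.2;
      nrm += d[k] * d[k];
    }
    nrm = std::sqrt(nrm);
    for (int k = 0; k < 128; ++k) desc(p, k) = nrm > 0 ? d[k] / nrm : 0;
  }
  return List::create(_["orientation"] = ori, _["desc"] = desc);
}

// [[Rcpp::export]]
NumericMatrix remap_cpp(NumericMatrix img, NumericMatrix mapx,
                        NumericMatrix mapy, double fill) {
  const int H = img.nrow(), W = img.ncol();
  const int Ho = mapx.nrow(), Wo = mapx.ncol();
  NumericMatrix out(Ho, Wo);
  for (int x = 0; x < Wo; ++x) {
    for (int y = 0; y < Ho; ++y) {
      const double xs = mapx(y, x), ys = mapy(y, x);
      if (!(xs >= 0) || !(xs <= W - 1) || !(ys >= 0) || !(ys <= H - 1)) {
        out(y, x) = fill; continue;
      }
      const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      const int x1 = x0 + 1 < W ? x0 + 1 : x0;
      const int y1 = y0 + 1 < H ? y0 + 1 : y0;
      const double ax = xs - x0, ay = ys - y0;
      out(y, x) = (1 - ay) * ((1 - ax) * img(y0, x0) + ax * img(y0, x1)) +
                  ay * ((1 - ax) * img(y1, x0) + ax * img(y1, x1));
    }
  }
  return out;
}
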