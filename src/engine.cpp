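// Low-level numerical kernels for the U-Net engine and the raster geometry
// used by the balancing / inference modules. Array layout follows R:
// feature tensors are numeric arrays with dim = c(H, W, C, N), column-major,
// so index(h,w,c,n) = h + H*(w + W*(c + C*n)). Convolutions are im2col +
// GEMM (Armadillo); bilinear resizing uses the half-pixel (align_corners =
// FALSE) convention throughout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int L, int k, int stride, int pad) {
  return (L + 2 * pad - k) / stride + 1;
}

static void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// fill the im2col matrix (K x P) for one sample; x points at (H,W,C) block
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  const int P = Ho * Wo;
  col.zeros();
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const int p = io + Ho * jo;
      double* cp = col.colptr(p);
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = x + (size_t)H * W * ci;
        for (int kj = 0; kj < kw; ++kj) {
          const int w = jo * stride - pad + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int h = io * stride - pad + ki;
            const int r = ki + kh * (kj + kw * ci);
            if (h >= 0 && h < H && w >= 0 && w < W)
              cp[r] = xc[h + (size_t)H * w];
          }
        }
      }
    }
  }
  (void)P;
}

// scatter-add the columns back into the (padded) input gradient
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const int p = io + Ho * jo;
      const double* cp = col.colptr(p);
      for (int ci = 0; ci < C; ++ci) {
        double* dxc = dx + (size_t)H * W * ci;
        for (int kj = 0; kj < kw; ++kj) {
          const int w = jo * stride - pad + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int h = io * stride - pad + ki;
            const int r = ki + kh * (kj + kw * ci);
            if (h >= 0 && h < H && w >= 0 && w < W)
              dxc[h + (size_t)H * w] += cp[r];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must be (kh, kw, Cin, Cout)");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and weights");
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("non-positive output size");
  const int K = kh * kw * Cin, P = Ho * Wo;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);

  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat Ym(y.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    Ym = col.t() * Wm;
    Ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, NumericVector w, NumericVector dy,
                 int stride, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  const int K = kh * kw * Cin, P = Ho * Wo;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((size_t)kh * kw * Cin * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);

  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat dYm(const_cast<double*>(dy.begin()) + (size_t)P * Cout * n, P, Cout, false, true);
    dWm += col * dYm;
    dbv += arma::sum(dYm, 0);
    arma::mat dcol = Wm * dYm.t();
    col2im(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
           dx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int kernel, int stride, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Ho = out_size(H, kernel, stride, pad), Wo = out_size(W, kernel, stride, pad);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector am((size_t)Ho * Wo * C * N);  // linear h + H*w index of the max
  am.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kj = 0; kj < kernel; ++kj) {
            const int w = jo * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < kernel; ++ki) {
              const int h = io * stride - pad + ki;
              if (h < 0 || h >= H) continue;
              const double v = xc[h + (size_t)H * w];
              if (v > best) { best = v; besti = h + H * w; }
            }
          }
          // y is laid out (Ho,Wo) within each (c,n) slab, column-major
          const size_t oi = (size_t)io + (size_t)Ho * jo +
                            (size_t)Ho * Wo * (c + (size_t)C * n);
          y[oi] = best;
          am[oi] = besti;
          (void)o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector argmax,
                             int H, int W) {
  int Ho, Wo, C, N;
  get_dims4(dy, Ho, Wo, C, N);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t slab_in = (size_t)H * W * (c + (size_t)C * n);
      const size_t slab_out = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) {
        const int idx = argmax[slab_out + p];
        if (idx >= 0) dx[slab_in + idx] += dy[slab_out + p];
      }
    }
  }
  return dx;
}

struct LinTab { std::vector<int> i0, i1; std::vector<double> t; };

static LinTab lin_table(int Lout, int Lin) {
  LinTab tab;
  tab.i0.resize(Lout); tab.i1.resize(Lout); tab.t.resize(Lout);
  const double scale = (double)Lin / Lout;
  for (int o = 0; o < Lout; ++o) {
    double src = (o + 0.5) * scale - 0.5;
    double f = std::floor(src);
    double t = src - f;
    int i0 = (int)f, i1 = (int)f + 1;
    if (i0 < 0) { i0 = 0; }
    if (i0 > Lin - 1) i0 = Lin - 1;
    if (i1 < 0) i1 = 0;
    if (i1 > Lin - 1) i1 = Lin - 1;
    tab.i0[o] = i0; tab.i1[o] = i1; tab.t[o] = t < 0 ? 0 : (t > 1 ? 1 : t);
  }
  return tab;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_fw(NumericVector x, int Ho, int Wo) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  LinTab th = lin_table(Ho, H), tw = lin_table(Wo, W);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int jo = 0; jo < Wo; ++jo) {
        const int w0 = tw.i0[jo], w1 = tw.i1[jo];
        const double tj = tw.t[jo];
        for (int io = 0; io < Ho; ++io) {
          const int h0 = th.i0[io], h1 = th.i1[io];
          const double ti = th.t[io];
          const double v =
            (1 - ti) * (1 - tj) * xc[h0 + (size_t)H * w0] +
            ti * (1 - tj) * xc[h1 + (size_t)H * w0] +
            (1 - ti) * tj * xc[h0 + (size_t)H * w1] +
            ti * tj * xc[h1 + (size_t)H * w1];
          yc[io + (size_t)Ho * jo] = v;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bw(NumericVector dy, int H, int W) {
  int Ho, Wo, C, N;
  get_dims4(dy, Ho, Wo, C, N);
  LinTab th = lin_table(Ho, H), tw = lin_table(Wo, W);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* dyc = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int jo = 0; jo < Wo; ++jo) {
        const int w0 = tw.i0[jo], w1 = tw.i1[jo];
        const double tj = tw.t[jo];
        for (int io = 0; io < Ho; ++io) {
          const int h0 = th.i0[io], h1 = th.i1[io];
          const double ti = th.t[io];
          const double g = dyc[io + (size_t)Ho * jo];
          dxc[h0 + (size_t)H * w0] += (1 - ti) * (1 - tj) * g;
          dxc[h1 + (size_t)H * w0] += ti * (1 - tj) * g;
          dxc[h0 + (size_t)H * w1] += (1 - ti) * tj * g;
          dxc[h1 + (size_t)H * w1] += ti * tj * g;
        }
      }
    }
  }
  return dx;
}

// Connected components of a logical mask; rows index y, cols index x.
// Returns an integer matrix, 0 = background, components numbered from 1 in
// scan order. connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int n8 = 8;
  const int dh[n8] = { -1, 1, 0, 0, -1, -1, 1, 1 };
  const int dw[n8] = { 0, 0, -1, 1, -1, 1, -1, 1 };
  const int nn = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  int next = 0;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w) || lab(h, w) != 0) continue;
      ++next;
      lab(h, w) = next;
      stack.clear();
      stack.push_back(h + H * w);
      while (!stack.empty()) {
        const int cur = stack.back(); stack.pop_back();
        const int ch = cur % H, cw = cur / H;
        for (int k = 0; k < nn; ++k) {
          const int nh = ch + dh[k], nw = cw + dw[k];
          if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
          if (mask(nh, nw) && lab(nh, nw) == 0) {
            lab(nh, nw) = next;
            stack.push_back(nh + H * nw);
          }
        }
      }
    }
  }
  return lab;
}

// Scanline polygon rasterization at pixel centers (even-odd rule per
// polygon, union across polygons). Polygons are n x 2 matrices of (x, y)
// vertices in continuous pixel coordinates: pixel (ix, iy) covers
// [ix, ix+1) x [iy, iy+1) and its center is (ix + 0.5, iy + 0.5).
// The result is a logical matrix with rows = y, cols = x.
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize_polygons(List polys, int H, int W) {
  LogicalMatrix out(H, W);
  for (int pi = 0; pi < polys.size(); ++pi) {
    NumericMatrix P = polys[pi];
    const int nv = P.nrow();
    if (nv < 3) continue;
    double ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < nv; ++i) {
      ymin = std::min(ymin, P(i, 1));
      ymax = std::max(ymax, P(i, 1));
    }
    const int y0 = std::max(0, (int)std::floor(ymin - 0.5));
    const int y1 = std::min(H - 1, (int)std::ceil(ymax));
    std::vector<double> xs;
    for (int y = y0; y <= y1; ++y) {
      const double yc = y + 0.5;
      xs.clear();
      for (int i = 0; i < nv; ++i) {
        const int j = (i + 1) % nv;
        const double ya = P(i, 1), yb = P(j, 1);
        if ((ya <= yc) != (yb <= yc)) {
          const double xint = P(i, 0) + (yc - ya) * (P(j, 0) - P(i, 0)) / (yb - ya);
          xs.push_back(xint);
        }
      }
      std::sort(xs.begin(), xs.end());
      for (size_t k = 0; k + 1 < xs.size(); k += 2) {
        int xa = (int)std::ceil(xs[k] - 0.5);
        int xb = (int)std::ceil(xs[k + 1] - 0.5) - 1;
        if (xa < 0) xa = 0;
        if (xb > W - 1) xb = W - 1;
        for (int x = xa; x <= xb; ++x) out(y, x) = true;
      }
    }
  }
  return out;
}

// Backward warp of an (H, W, C) image: output(h, w) samples the input at
// continuous position (mapy(h,w), mapx(h,w)) in pixel-index space (integer
// positions hit pixel h exactly). Out-of-range samples take `fill`.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector img, NumericMatrix mapy, NumericMatrix mapx,
                       bool bilinear, double fill) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3) stop("image must be (H, W, C)");
  const int H = d[0], W = d[1], C = d[2];
  NumericVector out((size_t)H * W * C);
  out.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    const double* xc = img.begin() + (size_t)H * W * c;
    double* oc = out.begin() + (size_t)H * W * c;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double sy = mapy(h, w), sx = mapx(h, w);
        double v;
        if (bilinear) {
          const int h0 = (int)std::floor(sy), w0 = (int)std::floor(sx);
          const double ty = sy - h0, tx = sx - w0;
          double acc = 0, wacc = 0;
          for (int dj = 0; dj <= 1; ++dj) {
            for (int di = 0; di <= 1; ++di) {
              const int hh = h0 + di, ww = w0 + dj;
              const double wt = (di ? ty : 1 - ty) * (dj ? tx : 1 - tx);
              if (hh >= 0 && hh < H && ww >= 0 && ww < W) {
                acc += wt * xc[hh + (size_t)H * ww];
                wacc += wt;
              } else {
                acc += wt * fill;
                wacc += wt;
              }
            }
          }
          v = wacc > 0 ? acc / wacc : fill;
        } else {
          const int hh = (int)std::lround(sy), ww = (int)std::lround(sx);
          v = (hh >= 0 && hh < H && ww >= 0 && ww < W) ? xc[hh + (size_t)H * ww] : fill;
        }
        oc[h + (size_t)H * w] = v;
      }
    }
  }
  return out;
}
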