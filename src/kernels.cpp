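#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Feature arrays are numeric vectors, column-major (row index fastest),
// with dim c(H, W, C) for a single image or c(H, W, B, C) for a batch
// (channels last, so channel-matrix reshapes are contiguous). Spatial
// positions are linearised as i + j*H.

static inline void read_dims(const RObject& x, int& H, int& W, int& B,
                             int& C) {
  IntegerVector d = x.attr("dim");
  H = d[0]; W = d[1];
  if (d.size() == 4) { B = d[2]; C = d[3]; }
  else { B = 1; C = (d.size() > 2) ? d[2] : 1; }
}

static inline IntegerVector make_dims(int H, int W, int B, int C,
                                      bool batched) {
  if (batched) return IntegerVector::create(H, W, B, C);
  return IntegerVector::create(H, W, C);
}

// [[Rcpp::export(name = ".im2col")]]
NumericMatrix im2col_cpp(NumericVector x, int K, int stride, int pad) {
  int H, W, B, C;
  read_dims(x, H, W, B, C);
  int Ho = (H + 2 * pad - K) / stride + 1;
  int Wo = (W + 2 * pad - K) / stride + 1;
  int HWB = H * W * B;
  NumericMatrix cols(Ho * Wo * B, K * K * C);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < K; ++dj) {
      for (int di = 0; di < K; ++di) {
        int col = di + dj * K + c * K * K;
        for (int b = 0; b < B; ++b) {
          const double* xs = &x[b * H * W + c * HWB];
          double* out = &cols(b * Ho * Wo, col);
          for (int jo = 0; jo < Wo; ++jo) {
            int j = jo * stride + dj - pad;
            bool jok = (j >= 0 && j < W);
            for (int io = 0; io < Ho; ++io) {
              int i = io * stride + di - pad;
              double v = 0.0;
              if (jok && i >= 0 && i < H) v = xs[i + j * H];
              out[io + jo * Ho] = v;
            }
          }
        }
      }
    }
  }
  cols.attr("out_dim") = IntegerVector::create(Ho, Wo, B);
  return cols;
}

// Scatter-add of column gradients back onto the input grid.
// [[Rcpp::export(name = ".col2im")]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int B, int C,
                         int K, int stride, int pad, bool batched) {
  int Ho = (H + 2 * pad - K) / stride + 1;
  int Wo = (W + 2 * pad - K) / stride + 1;
  int HWB = H * W * B;
  NumericVector gx(HWB * C);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < K; ++dj) {
      for (int di = 0; di < K; ++di) {
        int col = di + dj * K + c * K * K;
        for (int b = 0; b < B; ++b) {
          const double* in = &cols(b * Ho * Wo, col);
          double* gs = &gx[b * H * W + c * HWB];
          for (int jo = 0; jo < Wo; ++jo) {
            int j = jo * stride + dj - pad;
            if (j < 0 || j >= W) continue;
            for (int io = 0; io < Ho; ++io) {
              int i = io * stride + di - pad;
              if (i < 0 || i >= H) continue;
              gs[i + j * H] += in[io + jo * Ho];
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = make_dims(H, W, B, C, batched);
  return gx;
}

// Depthwise KxK convolution, one filter per channel, shared across the
// batch. w has dim c(K, K, C).
// [[Rcpp::export(name = ".dwconv_fwd")]]
NumericVector dwconv_fwd_cpp(NumericVector x, NumericVector w, int stride, int pad) {
  IntegerVector dw = w.attr("dim");
  int H, W, B, C;
  read_dims(x, H, W, B, C);
  int K = dw[0];
  int Ho = (H + 2 * pad - K) / stride + 1;
  int Wo = (W + 2 * pad - K) / stride + 1;
  bool batched = Rf_length(x.attr("dim")) == 4;
  NumericVector y(Ho * Wo * B * C);
  for (int c = 0; c < C; ++c) {
    const double* wc = &w[c * K * K];
    for (int b = 0; b < B; ++b) {
      const double* xs = &x[(b + c * B) * H * W];
      double* ys = &y[(b + c * B) * Ho * Wo];
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          double acc = 0.0;
          for (int dj = 0; dj < K; ++dj) {
            int j = jo * stride + dj - pad;
            if (j < 0 || j >= W) continue;
            for (int di = 0; di < K; ++di) {
              int i = io * stride + di - pad;
              if (i < 0 || i >= H) continue;
              acc += xs[i + j * H] * wc[di + dj * K];
            }
          }
          ys[io + jo * Ho] = acc;
        }
      }
    }
  }
  y.attr("dim") = make_dims(Ho, Wo, B, C, batched);
  return y;
}

// [[Rcpp::export(name = ".dwconv_bwd")]]
List dwconv_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad) {
  IntegerVector dw = w.attr("dim");
  int H, W, B, C;
  read_dims(x, H, W, B, C);
  int K = dw[0];
  IntegerVector dy = gy.attr("dim");
  int Ho = dy[0], Wo = dy[1];
  bool batched = Rf_length(x.attr("dim")) == 4;
  NumericVector gx(H * W * B * C), gw(K * K * C);
  for (int c = 0; c < C; ++c) {
    const double* wc = &w[c * K * K];
    double* gwc = &gw[c * K * K];
    for (int b = 0; b < B; ++b) {
      const double* xs = &x[(b + c * B) * H * W];
      const double* gys = &gy[(b + c * B) * Ho * Wo];
      double* gxs = &gx[(b + c * B) * H * W];
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          double g = gys[io + jo * Ho];
          if (g == 0.0) continue;
          for (int dj = 0; dj < K; ++dj) {
            int j = jo * stride + dj - pad;
            if (j < 0 || j >= W) continue;
            for (int di = 0; di < K; ++di) {
              int i = io * stride + di - pad;
              if (i < 0 || i >= H) continue;
              gxs[i + j * H] += g * wc[di + dj * K];
              gwc[di + dj * K] += g * xs[i + j * H];
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = make_dims(H, W, B, C, batched);
  gw.attr("dim") = IntegerVector::create(K, K, C);
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// Bilinear resize with half-pixel centre alignment, per batch and channel.
// [[Rcpp::export(name = ".bilinear_fwd")]]
NumericVector bilinear_fwd_cpp(NumericVector x, int Ho, int Wo) {
  int H, W, B, C;
  read_dims(x, H, W, B, C);
  bool batched = Rf_length(x.attr("dim")) == 4;
  int BC = B * C;
  NumericVector y(Ho * Wo * BC);
  double sr = (double)H / Ho, sc = (double)W / Wo;
  for (int jo = 0; jo < Wo; ++jo) {
    double fc = (jo + 0.5) * sc - 0.5;
    int j0 = (int)std::floor(fc);
    double wc = fc - j0;
    int j0c = std::min(std::max(j0, 0), W - 1);
    int j1c = std::min(std::max(j0 + 1, 0), W - 1);
    for (int io = 0; io < Ho; ++io) {
      double fr = (io + 0.5) * sr - 0.5;
      int i0 = (int)std::floor(fr);
      double wr = fr - i0;
      int i0c = std::min(std::max(i0, 0), H - 1);
      int i1c = std::min(std::max(i0 + 1, 0), H - 1);
      for (int c = 0; c < BC; ++c) {
        const double* xc = &x[c * H * W];
        double v = (1 - wr) * (1 - wc) * xc[i0c + j0c * H]
                 + wr * (1 - wc) * xc[i1c + j0c * H]
                 + (1 - wr) * wc * xc[i0c + j1c * H]
                 + wr * wc * xc[i1c + j1c * H];
        y[io + jo * Ho + c * Ho * Wo] = v;
      }
    }
  }
  y.attr("dim") = make_dims(Ho, Wo, B, C, batched);
  return y;
}

// Transpose of bilinear_fwd: scatter output gradients to the input grid.
// [[Rcpp::export(name = ".bilinear_bwd")]]
NumericVector bilinear_bwd_cpp(NumericVector gy, int H, int W) {
  int Ho, Wo, B, C;
  read_dims(gy, Ho, Wo, B, C);
  bool batched = Rf_length(gy.attr("dim")) == 4;
  int BC = B * C;
  NumericVector gx(H * W * BC);
  double sr = (double)H / Ho, sc = (double)W / Wo;
  for (int jo = 0; jo < Wo; ++jo) {
    double fc = (jo + 0.5) * sc - 0.5;
    int j0 = (int)std::floor(fc);
    double wc = fc - j0;
    int j0c = std::min(std::max(j0, 0), W - 1);
    int j1c = std::min(std::max(j0 + 1, 0), W - 1);
    for (int io = 0; io < Ho; ++io) {
      double fr = (io + 0.5) * sr - 0.5;
      int i0 = (int)std::floor(fr);
      double wr = fr - i0;
      int i0c = std::min(std::max(i0, 0), H - 1);
      int i1c = std::min(std::max(i0 + 1, 0), H - 1);
      for (int c = 0; c < BC; ++c) {
        double g = gy[io + jo * Ho + c * Ho * Wo];
        if (g == 0.0) continue;
        double* gxc = &gx[c * H * W];
        gxc[i0c + j0c * H] += (1 - wr) * (1 - wc) * g;
        gxc[i1c + j0c * H] += wr * (1 - wc) * g;
        gxc[i0c + j1c * H] += (1 - wr) * wc * g;
        gxc[i1c + j1c * H] += wr * wc * g;
      }
    }
  }
  gx.attr("dim") = make_dims(H, W, B, C, batched);
  return gx;
}

// 3x3 min pool (stride 1, replicate-free: window clipped at borders),
// returning pooled values and the argmin linear index for gradient routing.
// [[Rcpp::export(name = ".minpool3")]]
List minpool3_cpp(NumericMatrix x) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix y(H, W);
  IntegerMatrix arg(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double best = R_PosInf; int bidx = i + j * H;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= W) continue;
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= H) continue;
          double v = x(ii, jj);
          if (v < best) { best = v; bidx = ii + jj * H; }
        }
      }
      y(i, j) = best;
      arg(i, j) = bidx;  // 0-based linear index
    }
  }
  return List::create(_["value"] = y, _["argmin"] = arg);
}

// 8-connected component labelling; labels assigned in row-major order of
// each component's first (top-left-most) pixel, starting at 1.
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8_cpp(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<int> q;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(i + j * H);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = pi + di, jj = pj + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push(ii + jj * H);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Y = X + b[col], column-major N x C matrix.
// [[Rcpp::export(name = ".addcol")]]
NumericMatrix addcol_cpp(NumericMatrix x, NumericVector b) {
  int n = x.nrow(), c = x.ncol();
  NumericMatrix y(n, c);
  for (int j = 0; j < c; ++j) {
    double bj = b[j];
    const double* xi = &x(0, j);
    double* yi = &y(0, j);
    for (int i = 0; i < n; ++i) yi[i] = xi[i] + bj;
  }
  return y;
}

// Batch-norm training forward over rows (spatial positions) per column
// (channel): returns y, xhat, mean, var (population).
// [[Rcpp::export(name = ".bn_train")]]
List bn_train_cpp(NumericMatrix x, NumericVector g, NumericVector b,
                  double eps) {
  int n = x.nrow(), c = x.ncol();
  NumericMatrix y(n, c), xhat(n, c);
  NumericVector mu(c), va(c), invstd(c);
  for (int j = 0; j < c; ++j) {
    const double* xi = &x(0, j);
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) s += xi[i];
    double m = s / n;
    for (int i = 0; i < n; ++i) { double d = xi[i] - m; s2 += d * d; }
    double v = s2 / n;
    double is = 1.0 / std::sqrt(v + eps);
    mu[j] = m; va[j] = v; invstd[j] = is;
    double gj = g[j], bj = b[j];
    double* xh = &xhat(0, j);
    double* yi = &y(0, j);
    for (int i = 0; i < n; ++i) {
      double h = (xi[i] - m) * is;
      xh[i] = h;
      yi[i] = gj * h + bj;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mu,
                      _["var"] = va, _["invstd"] = invstd);
}

// Batch-norm eval forward with running statistics.
// [[Rcpp::export(name = ".bn_eval")]]
NumericMatrix bn_eval_cpp(NumericMatrix x, NumericVector g, NumericVector b,
                          NumericVector mu, NumericVector va, double eps) {
  int n = x.nrow(), c = x.ncol();
  NumericMatrix y(n, c);
  for (int j = 0; j < c; ++j) {
    double is = 1.0 / std::sqrt(va[j] + eps);
    double gj = g[j] * is, bj = b[j] - g[j] * is * mu[j];
    const double* xi = &x(0, j);
    double* yi = &y(0, j);
    for (int i = 0; i < n; ++i) yi[i] = gj * xi[i] + bj;
  }
  return y;
}

// Batch-norm training backward.
// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(NumericMatrix gy, NumericMatrix xhat, NumericVector g,
                NumericVector invstd) {
  int n = gy.nrow(), c = gy.ncol();
  NumericMatrix gx(n, c);
  NumericVector gg(c), gb(c);
  for (int j = 0; j < c; ++j) {
    const double* gyi = &gy(0, j);
    const double* xh = &xhat(0, j);
    double s1 = 0.0, s2 = 0.0, sb = 0.0;
    for (int i = 0; i < n; ++i) {
      sb += gyi[i];
      s2 += gyi[i] * xh[i];
    }
    gg[j] = s2; gb[j] = sb;
    double m1 = g[j] * sb / n, m2 = g[j] * s2 / n;
    double gj = g[j], is = invstd[j];
    double* gxi = &gx(0, j);
    for (int i = 0; i < n; ++i)
      gxi[i] = is * (gj * gyi[i] - m1 - xh[i] * m2);
  }
  return List::create(_["gx"] = gx, _["ggamma"] = gg, _["gbeta"] = gb);
}

// ReLU6 forward; returns y and the active mask.
// [[Rcpp::export(name = ".relu6")]]
List relu6_cpp(NumericVector x) {
  int n = x.size();
  NumericVector y(n);
  LogicalVector mask(n);
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    bool act = (v > 0.0 && v < 6.0);
    mask[i] = act;
    y[i] = v < 0.0 ? 0.0 : (v > 6.0 ? 6.0 : v);
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["mask"] = mask);
}

// gy masked by the ReLU6 active set.
// [[Rcpp::export(name = ".maskmul")]]
NumericVector maskmul_cpp(NumericVector gy, LogicalVector mask) {
  int n = gy.size();
  NumericVector g(n);
  for (int i = 0; i < n; ++i) g[i] = mask[i] ? gy[i] : 0.0;
  g.attr("dim") = gy.attr("dim");
  return g;
}

// Grouped batch-norm forward: statistics per (image, channel) group. Rows
// of x are ordered spatial-then-image within each channel column, so image
// b occupies the contiguous block [b*ng, (b+1)*ng). Running statistics are
// reported as the per-channel average over images.
// [[Rcpp::export(name = ".bn_train_g")]]
List bn_train_g_cpp(NumericMatrix x, NumericVector g, NumericVector b,
                    double eps, int ng, int B) {
  int c = x.ncol();
  NumericMatrix y(x.nrow(), c), xhat(x.nrow(), c), invstd(B, c);
  NumericVector mu_avg(c), va_avg(c);
  for (int j = 0; j < c; ++j) {
    double gj = g[j], bj = b[j];
    for (int bb = 0; bb < B; ++bb) {
      const double* xi = &x(bb * ng, j);
      double* xh = &xhat(bb * ng, j);
      double* yi = &y(bb * ng, j);
      double s = 0.0, s2 = 0.0;
      for (int i = 0; i < ng; ++i) s += xi[i];
      double m = s / ng;
      for (int i = 0; i < ng; ++i) { double d = xi[i] - m; s2 += d * d; }
      double v = s2 / ng;
      double is = 1.0 / std::sqrt(v + eps);
      invstd(bb, j) = is;
      mu_avg[j] += m / B;
      va_avg[j] += v / B;
      for (int i = 0; i < ng; ++i) {
        double h = (xi[i] - m) * is;
        xh[i] = h;
        yi[i] = gj * h + bj;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["mean"] = mu_avg, _["var"] = va_avg);
}

// Grouped batch-norm backward.
// [[Rcpp::export(name = ".bn_bwd_g")]]
List bn_bwd_g_cpp(NumericMatrix gy, NumericMatrix xhat, NumericVector g,
                  NumericMatrix invstd, int ng, int B) {
  int c = gy.ncol();
  NumericMatrix gx(gy.nrow(), c);
  NumericVector gg(c), gb(c);
  for (int j = 0; j < c; ++j) {
    double gj = g[j];
    for (int bb = 0; bb < B; ++bb) {
      const double* gyi = &gy(bb * ng, j);
      const double* xh = &xhat(bb * ng, j);
      double* gxi = &gx(bb * ng, j);
      double s1 = 0.0, s2 = 0.0;
      for (int i = 0; i < ng; ++i) {
        s1 += gyi[i];
        s2 += gyi[i] * xh[i];
      }
      gb[j] += s1; gg[j] += s2;
      double m1 = gj * s1 / ng, m2 = gj * s2 / ng;
      double is = invstd(bb, j);
      for (int i = 0; i < ng; ++i)
        gxi[i] = is * (gj * gyi[i] - m1 - xh[i] * m2);
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = gg, _["gbeta"] = gb);
}
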