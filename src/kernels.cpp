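// Dense and depthwise 3D convolution kernels over [C, D, H, W] column-major
// volumes (channel index fastest).  Dense convolutions go through a chunked
// im2col + GEMM; the depthwise path is a direct loop vectorised over the
// contiguous channel axis.  Bias addition and reductions live on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct ConvGeom {
  int C, D, H, W;      // input
  int k, s, p;         // kernel, stride, pad (same on all axes)
  int oD, oH, oW;      // output spatial
  int K;               // C * k^3 patch rows
  long N;              // output columns
};

ConvGeom geom(const IntegerVector &xd, int k, int s, int p) {
  ConvGeom g;
  g.C = xd[0]; g.D = xd[1]; g.H = xd[2]; g.W = xd[3];
  g.k = k; g.s = s; g.p = p;
  g.oD = (g.D + 2 * p - k) / s + 1;
  g.oH = (g.H + 2 * p - k) / s + 1;
  g.oW = (g.W + 2 * p - k) / s + 1;
  g.K = g.C * k * k * k;
  g.N = (long)g.oD * g.oH * g.oW;
  return g;
}

// Fill patch matrix (K x n) for output columns [col0, col0 + n).
void im2col_chunk(const double *x, const ConvGeom &g, long col0, long n,
                  arma::mat &P) {
  P.zeros();
  const long planeD = g.oD;
  const long planeDH = (long)g.oD * g.oH;
  for (long j = 0; j < n; ++j) {
    long col = col0 + j;
    int ow = (int)(col / planeDH);
    int rem = (int)(col % planeDH);
    int oh = rem / planeD;
    int od = rem % planeD;
    double *pcol = P.colptr(j);
    for (int kw = 0; kw < g.k; ++kw) {
      int iw = ow * g.s - g.p + kw;
      if (iw < 0 || iw >= g.W) continue;
      for (int kh = 0; kh < g.k; ++kh) {
        int ih = oh * g.s - g.p + kh;
        if (ih < 0 || ih >= g.H) continue;
        for (int kd = 0; kd < g.k; ++kd) {
          int id = od * g.s - g.p + kd;
          if (id < 0 || id >= g.D) continue;
          const double *src =
              x + (long)g.C * (id + (long)g.D * (ih + (long)g.H * iw));
          double *dst = pcol + (long)g.C * (kd + g.k * (kh + g.k * kw));
          std::copy(src, src + g.C, dst);
        }
      }
    }
  }
}

// Scatter-add patch matrix back into the input gradient (col2im transpose).
void col2im_chunk(const arma::mat &P, const ConvGeom &g, long col0, long n,
                  double *dx) {
  const long planeD = g.oD;
  const long planeDH = (long)g.oD * g.oH;
  for (long j = 0; j < n; ++j) {
    long col = col0 + j;
    int ow = (int)(col / planeDH);
    int rem = (int)(col % planeDH);
    int oh = rem / planeD;
    int od = rem % planeD;
    const double *pcol = P.colptr(j);
    for (int kw = 0; kw < g.k; ++kw) {
      int iw = ow * g.s - g.p + kw;
      if (iw < 0 || iw >= g.W) continue;
      for (int kh = 0; kh < g.k; ++kh) {
        int ih = oh * g.s - g.p + kh;
        if (ih < 0 || ih >= g.H) continue;
        for (int kd = 0; kd < g.k; ++kd) {
          int id = od * g.s - g.p + kd;
          if (id < 0 || id >= g.D) continue;
          double *dst =
              dx + (long)g.C * (id + (long)g.D * (ih + (long)g.H * iw));
          const double *src = pcol + (long)g.C * (kd + g.k * (kh + g.k * kw));
          for (int c = 0; c < g.C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

long chunk_cols(const ConvGeom &g) {
  long n = 4194304L / std::max(g.K, 1);  // ~32 MB patch buffer
  if (n < 64) n = 64;
  if (n > g.N) n = g.N;
  return n;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, int cout, int k, int stride,
                             int pad) {
  ConvGeom g = geom(xd, k, stride, pad);
  NumericVector y((long)cout * g.N);
  arma::mat Wm(const_cast<double *>(w.begin()), cout, g.K, false, true);
  long nc = chunk_cols(g);
  arma::mat P(g.K, nc);
  for (long col0 = 0; col0 < g.N; col0 += nc) {
    long n = std::min(nc, g.N - col0);
    arma::mat Pv = P.cols(0, n - 1);
    im2col_chunk(x.begin(), g, col0, n, Pv);
    arma::mat Ym(y.begin() + (long)cout * col0, cout, n, false, true);
    Ym = Wm * Pv;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_input(NumericVector gy, IntegerVector xd,
                                   NumericVector w, int cout, int k,
                                   int stride, int pad) {
  ConvGeom g = geom(xd, k, stride, pad);
  NumericVector dx((long)g.C * g.D * g.H * g.W);
  arma::mat Wm(const_cast<double *>(w.begin()), cout, g.K, false, true);
  long nc = chunk_cols(g);
  for (long col0 = 0; col0 < g.N; col0 += nc) {
    long n = std::min(nc, g.N - col0);
    arma::mat Gy(const_cast<double *>(gy.begin()) + (long)cout * col0, cout, n,
                 false, true);
    arma::mat P = Wm.t() * Gy;  // K x n
    col2im_chunk(P, g, col0, n, dx.begin());
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_weight(NumericVector gy, NumericVector x,
                                    IntegerVector xd, int cout, int k,
                                    int stride, int pad) {
  ConvGeom g = geom(xd, k, stride, pad);
  arma::mat dW(cout, g.K, arma::fill::zeros);
  long nc = chunk_cols(g);
  arma::mat P(g.K, nc);
  for (long col0 = 0; col0 < g.N; col0 += nc) {
    long n = std::min(nc, g.N - col0);
    arma::mat Pv = P.cols(0, n - 1);
    im2col_chunk(x.begin(), g, col0, n, Pv);
    arma::mat Gy(const_cast<double *>(gy.begin()) + (long)cout * col0, cout, n,
                 false, true);
    dW += Gy * Pv.t();
  }
  NumericVector out(dW.begin(), dW.end());
  return out;
}

// Depthwise 3D convolution, stride 1, symmetric "same" padding (odd k).
// Weights: [C, k^3] with tap index t = kd + k*(kh + k*kw).

// [[Rcpp::export]]
NumericVector cpp_dwconv3d_fwd(NumericVector x, IntegerVector xd,
                               NumericVector w, int k) {
  const int C = xd[0], D = xd[1], H = xd[2], W = xd[3];
  const int p = (k - 1) / 2;
  NumericVector y((long)C * D * H * W);
  const double *xp = x.begin();
  const double *wp = w.begin();
  double *yp = y.begin();
  for (int ow = 0; ow < W; ++ow)
    for (int oh = 0; oh < H; ++oh)
      for (int od = 0; od < D; ++od) {
        double *yv = yp + (long)C * (od + (long)D * (oh + (long)H * ow));
        for (int kw = 0; kw < k; ++kw) {
          int iw = ow - p + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int ih = oh - p + kh;
            if (ih < 0 || ih >= H) continue;
            for (int kd = 0; kd < k; ++kd) {
              int id = od - p + kd;
              if (id < 0 || id >= D) continue;
              const double *xv =
                  xp + (long)C * (id + (long)D * (ih + (long)H * iw));
              const double *wv = wp + (long)C * (kd + k * (kh + k * kw));
              for (int c = 0; c < C; ++c) yv[c] += wv[c] * xv[c];
            }
          }
        }
      }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_dwconv3d_bwd_input(NumericVector gy, IntegerVector xd,
                                     NumericVector w, int k) {
  const int C = xd[0], D = xd[1], H = xd[2], W = xd[3];
  const int p = (k - 1) / 2;
  NumericVector dx((long)C * D * H * W);
  const double *gp = gy.begin();
  const double *wp = w.begin();
  double *dp = dx.begin();
  for (int ow = 0; ow < W; ++ow)
    for (int oh = 0; oh < H; ++oh)
      for (int od = 0; od < D; ++od) {
        const double *gv = gp + (long)C * (od + (long)D * (oh + (long)H * ow));
        for (int kw = 0; kw < k; ++kw) {
          int iw = ow - p + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int ih = oh - p + kh;
            if (ih < 0 || ih >= H) continue;
            for (int kd = 0; kd < k; ++kd) {
              int id = od - p + kd;
              if (id < 0 || id >= D) continue;
              double *dv = dp + (long)C * (id + (long)D * (ih + (long)H * iw));
              const double *wv = wp + (long)C * (kd + k * (kh + k * kw));
              for (int c = 0; c < C; ++c) dv[c] += wv[c] * gv[c];
            }
          }
        }
      }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_dwconv3d_bwd_weight(NumericVector gy, NumericVector x,
                                      IntegerVector xd, int k) {
  const int C = xd[0], D = xd[1], H = xd[2], W = xd[3];
  const int p = (k - 1) / 2;
  NumericVector dw((long)C * k * k * k);
  const double *gp = gy.begin();
  const double *xp = x.begin();
  double *dp = dw.begin();
  for (int ow = 0; ow < W; ++ow)
    for (int oh = 0; oh < H; ++oh)
      for (int od = 0; od < D; ++od) {
        const double *gv = gp + (long)C * (od + (long)D * (oh + (long)H * ow));
        for (int kw = 0; kw < k; ++kw) {
          int iw = ow - p + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int ih = oh - p + kh;
            if (ih < 0 || ih >= H) continue;
            for (int kd = 0; kd < k; ++kd) {
              int id = od - p + kd;
              if (id < 0 || id >= D) continue;
              const double *xv =
                  xp + (long)C * (id + (long)D * (ih + (long)H * iw));
              double *dv = dp + (long)C * (kd + k * (kh + k * kw));
              for (int c = 0; c < C; ++c) dv[c] += gv[c] * xv[c];
            }
          }
        }
      }
  return dw;
}

// Trilinear x2 upsampling, half-pixel convention: output o samples input at
// o/2 - 0.25, neighbours clamped at the boundary.  Vectorised over the
// contiguous channel axis.

namespace {
void up2_axis_weights(int L, std::vector<int> &lo, std::vector<int> &hi,
                      std::vector<double> &wlo, std::vector<double> &whi) {
  lo.resize(2 * L); hi.resize(2 * L); wlo.resize(2 * L); whi.resize(2 * L);
  for (int m = 0; m < L; ++m) {
    int e = 2 * m, o = 2 * m + 1;
    lo[e] = std::max(m - 1, 0); hi[e] = m; wlo[e] = 0.25; whi[e] = 0.75;
    lo[o] = m; hi[o] = std::min(m + 1, L - 1); wlo[o] = 0.75; whi[o] = 0.25;
  }
}
}  // namespace

// [[Rcpp::export]]
NumericVector cpp_up2_fwd(NumericVector x, IntegerVector xd) {
  const int C = xd[0], D = xd[1], H = xd[2], W = xd[3];
  const int oD = 2 * D, oH = 2 * H, oW = 2 * W;
  NumericVector y((long)C * oD * oH * oW);
  std::vector<int> ld, hd, lh, hh, lw, hw;
  std::vector<double> wld, whd, wlh, whh, wlw, whw;
  up2_axis_weights(D, ld, hd, wld, whd);
  up2_axis_weights(H, lh, hh, wlh, whh);
  up2_axis_weights(W, lw, hw, wlw, whw);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int ow = 0; ow < oW; ++ow)
    for (int oh = 0; oh < oH; ++oh)
      for (int od = 0; od < oD; ++od) {
        double *yv = yp + (long)C * (od + (long)oD * (oh + (long)oH * ow));
        for (int cw = 0; cw < 2; ++cw) {
          int iw = cw ? hw[ow] : lw[ow];
          double fw = cw ? whw[ow] : wlw[ow];
          for (int ch = 0; ch < 2; ++ch) {
            int ih = ch ? hh[oh] : lh[oh];
            double fh = ch ? whh[oh] : wlh[oh];
            for (int cd = 0; cd < 2; ++cd) {
              int id = cd ? hd[od] : ld[od];
              double f = fw * fh * (cd ? whd[od] : wld[od]);
              const double *xv =
                  xp + (long)C * (id + (long)D * (ih + (long)H * iw));
              for (int c = 0; c < C; ++c) yv[c] += f * xv[c];
            }
          }
        }
      }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_up2_bwd(NumericVector gy, IntegerVector xd) {
  const int C = xd[0], D = xd[1], H = xd[2], W = xd[3];
  const int oD = 2 * D, oH = 2 * H, oW = 2 * W;
  NumericVector dx((long)C * D * H * W);
  std::vector<int> ld, hd, lh, hh, lw, hw;
  std::vector<double> wld, whd, wlh, whh, wlw, whw;
  up2_axis_weights(D, ld, hd, wld, whd);
  up2_axis_weights(H, lh, hh, wlh, whh);
  up2_axis_weights(W, lw, hw, wlw, whw);
  const double *gp = gy.begin();
  double *dp = dx.begin();
  for (int ow = 0; ow < oW; ++ow)
    for (int oh = 0; oh < oH; ++oh)
      for (int od = 0; od < oD; ++od) {
        const double *gv = gp + (long)C * (od + (long)oD * (oh + (long)oH * ow));
        for (int cw = 0; cw < 2; ++cw) {
          int iw = cw ? hw[ow] : lw[ow];
          double fw = cw ? whw[ow] : wlw[ow];
          for (int ch = 0; ch < 2; ++ch) {
            int ih = ch ? hh[oh] : lh[oh];
            double fh = ch ? whh[oh] : wlh[oh];
            for (int cd = 0; cd < 2; ++cd) {
              int id = cd ? hd[od] : ld[od];
              double f = fw * fh * (cd ? whd[od] : wld[od]);
              double *dv = dp + (long)C * (id + (long)D * (ih + (long)H * iw));
              for (int c = 0; c < C; ++c) dv[c] += f * gv[c];
            }
          }
        }
      }
  return dx;
}

// Exact GELU x * Phi(x) and its derivative Phi(x) + x * phi(x).

// [[Rcpp::export]]
NumericVector cpp_gelu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double isq2 = 0.7071067811865475244;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    y[i] = x[i] * 0.5 * (1.0 + std::erf(x[i] * isq2));
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_gelu_bwd(NumericVector g, NumericVector x) {
  NumericVector dx(x.size());
  const double isq2 = 0.7071067811865475244;
  const double is2pi = 0.3989422804014326779;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double phi = 0.5 * (1.0 + std::erf(x[i] * isq2));
    double dens = is2pi * std::exp(-0.5 * x[i] * x[i]);
    dx[i] = g[i] * (phi + x[i] * dens);
  }
  return dx;
}
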