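// Low-level tensor operations for the U-Net channel regressors.
// Layout convention: image batches are R arrays dim (H, W, C, N),
// convolution kernels dim (k, k, C_in, C_out). All convolutions are
// zero-padded "same" with stride 1; pooling and upsampling act by
// factors of 2.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::cube cube_view(const NumericVector& x, int H, int W, int C,
                                   int n) {
  // copy-free would need const_cast; a copy of one sample is cheap
  arma::cube out(H, W, C);
  const double* p = x.begin() + (size_t)n * H * W * C;
  std::copy(p, p + (size_t)H * W * C, out.memptr());
  return out;
}

// im2col for k x k same-padded convolution: rows index output pixels
// (column-major over H then W), columns index (ki, kj, c).
static arma::mat im2col(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  arma::mat col(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int idx = c * k * k + kj * k + ki;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - pad;
            if (si < 0 || si >= H) continue;
            col(j * H + i, idx) = x(si, sj, c);
          }
        }
      }
    }
  }
  return col;
}

// adjoint of im2col
static void col2im_acc(const arma::mat& col, int H, int W, int C, int k,
                       arma::cube& out) {
  const int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int idx = c * k * k + kj * k + ki;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - pad;
            if (si < 0 || si >= H) continue;
            out(si, sj, c) += col(j * H + i, idx);
          }
        }
      }
    }
  }
}

// samples per im2col block, keeping the stacked matrix near 32 MB
static int conv_group(int H, int W, int kkC, int N) {
  double per = (double)H * W * kkC;
  int g = (int)std::max(1.0, std::floor(4.0e6 / per));
  return std::min(g, N);
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  if (wd[2] != C) stop("conv2d_fwd: channel mismatch");
  arma::mat wm(const_cast<double*>(w.begin()), k * k * C, F, false, true);
  NumericVector y((size_t)H * W * F * N);
  y.attr("dim") = IntegerVector::create(H, W, F, N);
  const int G = conv_group(H, W, k * k * C, N);
  arma::mat col;
  for (int n0 = 0; n0 < N; n0 += G) {
    const int g = std::min(G, N - n0);
    col.set_size((size_t)H * W * g, k * k * C);
    for (int n = 0; n < g; ++n) {
      arma::cube xc = cube_view(x, H, W, C, n0 + n);
      col.rows((size_t)n * H * W, (size_t)(n + 1) * H * W - 1) = im2col(xc, k);
    }
    arma::mat out = col * wm;  // (gHW) x F
    for (int f = 0; f < F; ++f) out.col(f) += b[f];
    for (int n = 0; n < g; ++n)
      for (int f = 0; f < F; ++f)
        std::copy(out.colptr(f) + (size_t)n * H * W,
                  out.colptr(f) + (size_t)(n + 1) * H * W,
                  y.begin() + ((size_t)(n0 + n) * F + f) * H * W);
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  arma::mat wm(const_cast<double*>(w.begin()), k * k * C, F, false, true);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat dw(k * k * C, F, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  const int G = conv_group(H, W, k * k * C, N);
  arma::mat col, dyg;
  for (int n0 = 0; n0 < N; n0 += G) {
    const int g = std::min(G, N - n0);
    col.set_size((size_t)H * W * g, k * k * C);
    dyg.set_size((size_t)H * W * g, F);
    for (int n = 0; n < g; ++n) {
      arma::cube xc = cube_view(x, H, W, C, n0 + n);
      col.rows((size_t)n * H * W, (size_t)(n + 1) * H * W - 1) = im2col(xc, k);
      for (int f = 0; f < F; ++f)
        std::copy(dy.begin() + ((size_t)(n0 + n) * F + f) * H * W,
                  dy.begin() + ((size_t)(n0 + n) * F + f + 1) * H * W,
                  dyg.colptr(f) + (size_t)n * H * W);
    }
    dw += col.t() * dyg;
    db += arma::sum(dyg, 0).t();
    arma::mat dcol = dyg * wm.t();  // (gHW) x (kkC)
    for (int n = 0; n < g; ++n) {
      arma::cube dxc(H, W, C, arma::fill::zeros);
      col2im_acc(dcol.rows((size_t)n * H * W, (size_t)(n + 1) * H * W - 1),
                 H, W, C, k, dxc);
      std::copy(dxc.memptr(), dxc.memptr() + (size_t)H * W * C,
                dx.begin() + (size_t)(n0 + n) * H * W * C);
    }
  }
  NumericVector dwr(dw.memptr(), dw.memptr() + dw.n_elem);
  dwr.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2; returns pooled values and flat argmax
// indices (1-based into the (H, W) plane of each channel/sample).
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++o) {
          double best = -1e300;
          int bi = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              int ii = 2 * i + di, jj = 2 * j + dj;
              double v = plane[jj * H + ii];
              if (v > best) { best = v; bi = jj * H + ii; }
            }
          y[o] = best;
          idx[o] = bi + 1;
        }
    }
  // arrays filled in (i, j) inner order per (c, n): matches column-major dim
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* plane = dx.begin() + ((size_t)n * C + c) * H * W;
      for (size_t t = 0; t < (size_t)Ho * Wo; ++t, ++o)
        plane[idx[o] - 1] += dy[o];
    }
  return dx;
}

// Bilinear 2x upsampling with half-pixel centers (output pixel i maps to
// input coordinate (i + 0.5)/2 - 0.5, clamped at the borders).
static void up2_weights(int Ho, int H, arma::ivec& i0, arma::ivec& i1,
                        arma::vec& w1) {
  i0.set_size(Ho); i1.set_size(Ho); w1.set_size(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    int lo = (int)std::floor(s);
    int hi = std::min(lo + 1, H - 1);
    i0[i] = lo; i1[i] = hi; w1[i] = s - lo;
  }
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  arma::ivec i0, i1, j0, j1; arma::vec wi, wj;
  up2_weights(Ho, H, i0, i1, wi);
  up2_weights(Wo, W, j0, j1, wj);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* in = x.begin() + ((size_t)n * C + c) * H * W;
      double* out = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double a = in[j0[j] * H + i0[i]], b = in[j0[j] * H + i1[i]];
          double cc = in[j1[j] * H + i0[i]], d = in[j1[j] * H + i1[i]];
          double top = a * (1 - wi[i]) + b * wi[i];
          double bot = cc * (1 - wi[i]) + d * wi[i];
          out[j * Ho + i] = top * (1 - wj[j]) + bot * wj[j];
        }
    }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  arma::ivec i0, i1, j0, j1; arma::vec wi, wj;
  up2_weights(Ho, H, i0, i1, wi);
  up2_weights(Wo, W, j0, j1, wj);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* out = dx.begin() + ((size_t)n * C + c) * H * W;
      const double* g = dy.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double v = g[j * Ho + i];
          out[j0[j] * H + i0[i]] += v * (1 - wi[i]) * (1 - wj[j]);
          out[j0[j] * H + i1[i]] += v * wi[i] * (1 - wj[j]);
          out[j1[j] * H + i0[i]] += v * (1 - wi[i]) * wj[j];
          out[j1[j] * H + i1[i]] += v * wi[i] * wj[j];
        }
    }
  return dx;
}
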