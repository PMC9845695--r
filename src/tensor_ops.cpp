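// Dense tensor primitives for the segmentation network.
//
// Layout convention: batched feature tensors are R arrays [H, W, C, N]
// (column-major), so the (.,.,c,n) plane is contiguous. Convolution weights
// are matrices of shape (Cin*k*k) x Cout with row index c*k*k + dh*k + dw.
// All convolutions are stride 1 with "same" zero padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array [H, W, C, N]");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col for one image: fills K (Cin*k*k x H*W), zero padding.
static void im2col(const double* x, int H, int W, int Cin, int k,
                   arma::mat& K) {
  const int pad = (k - 1) / 2;
  K.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dh = 0; dh < k; ++dh) {
      for (int dw = 0; dw < k; ++dw) {
        const int row = c * k * k + dh * k + dw;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dw - pad;
          if (sj < 0 || sj >= W) continue;
          const double* col_src = xc + (size_t)sj * H;
          double* Kcol = K.memptr() + (size_t)row; // stride = K.n_rows
          const int i0 = std::max(0, pad - dh);
          const int i1 = std::min(H, H + pad - dh);
          for (int i = i0; i < i1; ++i) {
            K((size_t)row, (size_t)(i + (size_t)H * j)) = col_src[i + dh - pad];
          }
          (void)Kcol;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericMatrix w, NumericVector b,
                        int ksize) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  const int Cout = w.ncol();
  if ((int)w.nrow() != Cin * ksize * ksize)
    stop("weight rows (%d) != Cin*k*k (%d)", (int)w.nrow(), Cin * ksize * ksize);
  NumericVector out((size_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat K(Cin * ksize * ksize, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, ksize, K);
    arma::mat Y = wm.t() * K; // Cout x HW
    double* op = out.begin() + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double bias = b[co];
      for (size_t j = 0; j < (size_t)H * W; ++j)
        op[(size_t)co * H * W + j] = Y(co, j) + bias;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericMatrix w, NumericVector gy, int ksize) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  const int Cout = w.ncol();
  const int pad = (ksize - 1) / 2;
  NumericVector gx((size_t)H * W * Cin * N);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat gw(w.nrow(), Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::mat K(Cin * ksize * ksize, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, ksize, K);
    // gy for this image as Cout x HW (needs transpose of plane layout)
    arma::mat gym(Cout, (size_t)H * W);
    const double* gp = gy.begin() + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; ++co)
      for (size_t j = 0; j < (size_t)H * W; ++j)
        gym(co, j) = gp[(size_t)co * H * W + j];
    gw += K * gym.t();
    gb += arma::sum(gym, 1);
    arma::mat G = wm * gym; // (Cin*k*k) x HW
    // col2im scatter
    double* gxp = gx.begin() + (size_t)n * H * W * Cin;
    for (int c = 0; c < Cin; ++c) {
      double* gxc = gxp + (size_t)c * H * W;
      for (int dh = 0; dh < ksize; ++dh) {
        for (int dw = 0; dw < ksize; ++dw) {
          const int row = c * ksize * ksize + dh * ksize + dw;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dw - pad;
            if (sj < 0 || sj >= W) continue;
            const int i0 = std::max(0, pad - dh);
            const int i1 = std::min(H, H + pad - dh);
            for (int i = i0; i < i1; ++i)
              gxc[(size_t)sj * H + (i + dh - pad)] += G(row, (size_t)H * j + i);
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx,
                      _["gw"] = NumericMatrix(w.nrow(), Cout, gw.memptr()),
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// 2x2 max pooling, stride 2. Returns pooled values and the flat within-window
// argmax (0..3, column-major within the window) for the backward pass.
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2: odd spatial dims (%d x %d)", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* plane = xp + p * H * W;
    double* yp = y.begin() + p * Ho * Wo;
    int* ip = idx.begin() + p * Ho * Wo;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const int i = 2 * io, j = 2 * jo;
        double best = plane[(size_t)j * H + i];
        int arg = 0;
        const double v10 = plane[(size_t)j * H + i + 1];
        if (v10 > best) { best = v10; arg = 1; }
        const double v01 = plane[(size_t)(j + 1) * H + i];
        if (v01 > best) { best = v01; arg = 2; }
        const double v11 = plane[(size_t)(j + 1) * H + i + 1];
        if (v11 > best) { best = v11; arg = 3; }
        yp[(size_t)jo * Ho + io] = best;
        ip[(size_t)jo * Ho + io] = arg;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(IntegerVector idx, NumericVector gy, int H, int W) {
  int Ho, Wo, C, N;
  get_dims4(gy, Ho, Wo, C, N);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* gp = gy.begin() + p * Ho * Wo;
    const int* ip = idx.begin() + p * Ho * Wo;
    double* gxp = gx.begin() + p * H * W;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const int a = ip[(size_t)jo * Ho + io];
        const int i = 2 * io + (a & 1), j = 2 * jo + (a >> 1);
        gxp[(size_t)j * H + i] += gp[(size_t)jo * Ho + io];
      }
    }
  }
  return gx;
}

struct BilinWeights {
  std::vector<int> lo, hi;
  std::vector<double> frac;
};

// Pixel-center (half-pixel) alignment: src = (dst + 0.5) * in/out - 0.5,
// clamped to the valid range (corners are NOT aligned).
static BilinWeights bilin_axis(int in, int out) {
  BilinWeights w;
  w.lo.resize(out); w.hi.resize(out); w.frac.resize(out);
  const double scale = (double)in / out;
  for (int d = 0; d < out; ++d) {
    double s = (d + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > in - 1) s = in - 1;
    int l = (int)std::floor(s);
    if (l > in - 1) l = in - 1;
    int h = std::min(l + 1, in - 1);
    w.lo[d] = l; w.hi[d] = h; w.frac[d] = s - l;
  }
  return w;
}

// [[Rcpp::export(name = ".bilinear_resize_fw")]]
NumericVector bilinear_resize_fw(NumericVector x, int Hout, int Wout) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  NumericVector y((size_t)Hout * Wout * C * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, C, N);
  BilinWeights wr = bilin_axis(H, Hout), wc = bilin_axis(W, Wout);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* xp = x.begin() + p * H * W;
    double* yp = y.begin() + p * Hout * Wout;
    for (int j = 0; j < Wout; ++j) {
      const int c0 = wc.lo[j], c1 = wc.hi[j];
      const double fc = wc.frac[j];
      const double* colA = xp + (size_t)c0 * H;
      const double* colB = xp + (size_t)c1 * H;
      for (int i = 0; i < Hout; ++i) {
        const int r0 = wr.lo[i], r1 = wr.hi[i];
        const double fr = wr.frac[i];
        const double top = colA[r0] * (1 - fc) + colB[r0] * fc;
        const double bot = colA[r1] * (1 - fc) + colB[r1] * fc;
        yp[(size_t)j * Hout + i] = top * (1 - fr) + bot * fr;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".bilinear_resize_bw")]]
NumericVector bilinear_resize_bw(NumericVector gy, int Hin, int Win) {
  int Ho, Wo, C, N;
  get_dims4(gy, Ho, Wo, C, N);
  NumericVector gx((size_t)Hin * Win * C * N);
  gx.attr("dim") = IntegerVector::create(Hin, Win, C, N);
  BilinWeights wr = bilin_axis(Hin, Ho), wc = bilin_axis(Win, Wo);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* gp = gy.begin() + p * Ho * Wo;
    double* gxp = gx.begin() + p * Hin * Win;
    for (int j = 0; j < Wo; ++j) {
      const int c0 = wc.lo[j], c1 = wc.hi[j];
      const double fc = wc.frac[j];
      for (int i = 0; i < Ho; ++i) {
        const int r0 = wr.lo[i], r1 = wr.hi[i];
        const double fr = wr.frac[i];
        const double g = gp[(size_t)j * Ho + i];
        gxp[(size_t)c0 * Hin + r0] += g * (1 - fc) * (1 - fr);
        gxp[(size_t)c1 * Hin + r0] += g * fc * (1 - fr);
        gxp[(size_t)c0 * Hin + r1] += g * (1 - fc) * fr;
        gxp[(size_t)c1 * Hin + r1] += g * fc * fr;
      }
    }
  }
  return gx;
}

// Bilinear interpolation of a [h, w, C] feature map at full-resolution pixel
// centers (rows/cols are 0-based indices on an H x W grid). Equivalent to
// upsampling the map to H x W with .bilinear_resize_fw and gathering.
// [[Rcpp::export(name = ".point_sample_fw")]]
NumericMatrix point_sample_fw(NumericVector x, IntegerVector rows,
                              IntegerVector cols, int H, int W) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d feature map [h, w, C]");
  const int h = d[0], w = d[1], C = d[2];
  const int k = rows.size();
  NumericMatrix out(k, C);
  const double sr = (double)h / H, sc = (double)w / W;
  for (int q = 0; q < k; ++q) {
    if (rows[q] < 0 || rows[q] >= H || cols[q] < 0 || cols[q] >= W)
      stop("point index out of range: (%d, %d)", rows[q], cols[q]);
    double si = (rows[q] + 0.5) * sr - 0.5, sj = (cols[q] + 0.5) * sc - 0.5;
    si = std::min(std::max(si, 0.0), (double)h - 1);
    sj = std::min(std::max(sj, 0.0), (double)w - 1);
    const int r0 = (int)std::floor(si), c0 = (int)std::floor(sj);
    const int r1 = std::min(r0 + 1, h - 1), c1 = std::min(c0 + 1, w - 1);
    const double fr = si - r0, fc = sj - c0;
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)c * h * w;
      const double top = xp[(size_t)c0 * h + r0] * (1 - fc) + xp[(size_t)c1 * h + r0] * fc;
      const double bot = xp[(size_t)c0 * h + r1] * (1 - fc) + xp[(size_t)c1 * h + r1] * fc;
      out(q, c) = top * (1 - fr) + bot * fr;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".point_sample_bw")]]
NumericVector point_sample_bw(NumericMatrix g, IntegerVector rows,
                              IntegerVector cols, int h, int w, int H, int W) {
  const int C = g.ncol(), k = rows.size();
  NumericVector gx((size_t)h * w * C);
  gx.attr("dim") = IntegerVector::create(h, w, C);
  const double sr = (double)h / H, sc = (double)w / W;
  for (int q = 0; q < k; ++q) {
    double si = (rows[q] + 0.5) * sr - 0.5, sj = (cols[q] + 0.5) * sc - 0.5;
    si = std::min(std::max(si, 0.0), (double)h - 1);
    sj = std::min(std::max(sj, 0.0), (double)w - 1);
    const int r0 = (int)std::floor(si), c0 = (int)std::floor(sj);
    const int r1 = std::min(r0 + 1, h - 1), c1 = std::min(c0 + 1, w - 1);
    const double fr = si - r0, fc = sj - c0;
    for (int c = 0; c < C; ++c) {
      double* gp = gx.begin() + (size_t)c * h * w;
      const double gv = g(q, c);
      gp[(size_t)c0 * h + r0] += gv * (1 - fc) * (1 - fr);
      gp[(size_t)c1 * h + r0] += gv * fc * (1 - fr);
      gp[(size_t)c0 * h + r1] += gv * (1 - fc) * fr;
      gp[(size_t)c1 * h + r1] += gv * fc * fr;
    }
  }
  return gx;
}
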