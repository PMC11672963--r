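// Low-level numerical kernels for the encoder-decoder networks and the
// morphological post-processing.  Tensors are plain R arrays in (H, W, C, N)
// layout (column-major); convolution weights are (k, k, Cin, Cout).
//
// Convolutions are implemented as im2col + GEMM so the heavy lifting goes
// through BLAS; pooling records per-window argmax positions so the decoder
// can unpool by index, placing each retained maximum back at its original
// location.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void check_dim4(const NumericVector& x, const char* what) {
  if (x.attr("dim") == R_NilValue)
    stop("%s must be a 4-d array (H, W, C, N)", what);
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("%s must be a 4-d array (H, W, C, N)", what);
}

// Fill the patch matrix (H*W x k*k*C) for the sample pointed to by xp.
// Column index r = di + k*dj + k*k*c matches column-major flattening of
// the (k, k, Cin, Cout) weight array, so y = cols * Wm directly.  Zero
// padding of width k/2 keeps "same" output size.  Both the input reads
// and the matrix writes are contiguous runs.
static void im2col(const double* xp, int H, int W, int C, int k,
                   arma::mat& cols) {
  const int p = k / 2, kk = k * k;
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = di + k * dj + kk * c;
        double* colr = cols.colptr(r);
        const int i0 = std::max(0, p - di);
        const int i1 = std::min(H, H + p - di);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          std::memcpy(colr + i0 + (size_t)H * j,
                      xc + (size_t)sj * H + (i0 + di - p),
                      (size_t)(i1 - i0) * sizeof(double));
        }
      }
    }
  }
}

// Scatter-add of the patch-matrix gradient back to image space (transpose
// of im2col).
static void col2im(const arma::mat& dcols, int H, int W, int C, int k,
                   double* dxp) {
  const int p = k / 2, kk = k * k;
  for (int c = 0; c < C; ++c) {
    double* dxc = dxp + (size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = di + k * dj + kk * c;
        const double* colr = dcols.colptr(r);
        const int i0 = std::max(0, p - di);
        const int i1 = std::min(H, H + p - di);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          double* dst = dxc + (size_t)sj * H + (i0 + di - p);
          const double* src = colr + i0 + (size_t)H * j;
          for (int i = i0; i < i1; ++i) *dst++ += *src++;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b) {
  check_dim4(x, "x");
  check_dim4(w, "w");
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k) stop("convolution kernel must be square");
  if (wd[2] != C) stop("weight Cin (%d) does not match input C (%d)",
                       (int)wd[2], C);
  if (b.size() != Cout) stop("bias length must equal Cout");
  if (k != 1 && k % 2 == 0) stop("kernel size must be odd");

  arma::mat Wm(w.begin(), (size_t)k * k * C, Cout, false, true);
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);

  arma::mat cols((size_t)H * W, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    // (H*W x Cout) is exactly the column-major layout of one output sample
    arma::mat ym(y.begin() + (size_t)n * H * W * Cout, (size_t)H * W, Cout,
                 false, true);
    ym = cols * Wm;
    for (int c = 0; c < Cout; ++c) ym.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  check_dim4(x, "x");
  check_dim4(dy, "dy");
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];

  arma::mat Wm(w.begin(), (size_t)k * k * C, Cout, false, true);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  arma::mat dW((size_t)k * k * C, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);

  arma::mat cols((size_t)H * W, (size_t)k * k * C);
  arma::mat dcols((size_t)H * W, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    arma::mat dym((double*)dy.begin() + (size_t)n * H * W * Cout,
                  (size_t)H * W, Cout, false, true);
    dW += cols.t() * dym;
    db += arma::sum(dym, 0).t();
    dcols = dym * Wm.t();
    col2im(dcols, H, W, C, k, dx.begin() + (size_t)n * H * W * C);
  }

  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Batch normalization over (H, W, N) per channel, fused with the leaky
// ReLU.  Forward returns the activation output plus the normalized field
// xhat and the per-channel inverse sd needed by the backward pass.
// [[Rcpp::export]]
List cpp_bn_lrelu_fwd(NumericVector x, NumericVector gamma,
                      NumericVector beta, NumericVector use_mean,
                      NumericVector use_var, double slope, double eps) {
  check_dim4(x, "x");
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;

  NumericVector batch_mean(C), batch_var(C);
  bool train = use_mean.size() == 0;
  if (train) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((size_t)n * C + c) * hw;
        for (size_t i = 0; i < hw; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      }
      const double m = s / (hw * N);
      batch_mean[c] = m;
      batch_var[c] = s2 / (hw * N) - m * m;
    }
  } else {
    batch_mean = clone(use_mean);
    batch_var = clone(use_var);
  }

  NumericVector y(x.size()), xhat(x.size()), inv_sd(C);
  y.attr("dim") = d;
  xhat.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    const double m = batch_mean[c];
    const double isd = 1.0 / std::sqrt(batch_var[c] + eps);
    inv_sd[c] = isd;
    const double g = gamma[c], be = beta[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* xc = x.begin() + off;
      double* xh = xhat.begin() + off;
      double* yc = y.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        const double h = (xc[i] - m) * isd;
        xh[i] = h;
        const double v = g * h + be;
        yc[i] = v >= 0 ? v : slope * v;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv_sd"] = inv_sd,
                      _["mean"] = batch_mean, _["var"] = batch_var);
}

// Backward of the fused block.  y is the forward output (its sign equals
// the pre-activation sign since slope > 0).  train toggles the full BN
// jacobian vs the frozen-statistics (inference) one.
// [[Rcpp::export]]
List cpp_bn_lrelu_bwd(NumericVector dy, NumericVector y,
                      NumericVector xhat, NumericVector gamma,
                      NumericVector inv_sd, double slope, bool train) {
  IntegerVector d = dy.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  const double cnt = (double)hw * N;

  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    double s_dy = 0, s_dyx = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* dyc = dy.begin() + off;
      const double* yc = y.begin() + off;
      const double* xh = xhat.begin() + off;
      double* dxc = dx.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        const double g = yc[i] >= 0 ? dyc[i] : slope * dyc[i];
        dxc[i] = g;  // temporarily: gradient after the activation
        s_dy += g;
        s_dyx += g * xh[i];
      }
    }
    dgamma[c] = s_dyx;
    dbeta[c] = s_dy;
    const double gi = gamma[c] * inv_sd[c];
    const double m_dy = s_dy / cnt, m_dyx = s_dyx / cnt;
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* xh = xhat.begin() + off;
      double* dxc = dx.begin() + off;
      if (train) {
        for (size_t i = 0; i < hw; ++i)
          dxc[i] = gi * (dxc[i] - m_dy - xh[i] * m_dyx);
      } else {
        for (size_t i = 0; i < hw; ++i) dxc[i] = gi * dxc[i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// 2x2 max pooling, stride 2.  idx codes the argmax position within each
// window as di + 2*dj (di row offset, dj column offset); ties are broken by
// the first maximal element in row-major window order (0,0), (0,1), (1,0),
// (1,1).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  check_dim4(x, "x");
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2)
    stop("max pooling requires even spatial size, got %d x %d", H, W);
  const int H2 = H / 2, W2 = W / 2;

  NumericVector y((size_t)H2 * W2 * C * N);
  IntegerVector idx((size_t)H2 * W2 * C * N);
  IntegerVector od = IntegerVector::create(H2, W2, C, N);
  y.attr("dim") = od;
  idx.attr("dim") = od;

  // row-major scan order of the 2x2 window positions
  const int scan_di[4] = {0, 0, 1, 1};
  const int scan_dj[4] = {0, 1, 0, 1};

  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i, ++o) {
          double best = R_NegInf;
          int besti = 0;
          for (int s = 0; s < 4; ++s) {
            const double v =
                xc[(2 * i + scan_di[s]) + (size_t)H * (2 * j + scan_dj[s])];
            if (v > best) {
              best = v;
              besti = scan_di[s] + 2 * scan_dj[s];
            }
          }
          y[o] = best;
          idx[o] = besti;
        }
    }
  // output is iterated (i fastest, then j, c, n) but written sequentially in
  // (j, i) order per (c, n); fix ordering: we wrote o in i-fastest within
  // j loop which matches column-major (H2 fastest) only if i inner.  It is.
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx, int H,
                               int W) {
  IntegerVector d = dy.attr("dim");
  const int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  if (H2 * 2 != H || W2 * 2 != W) stop("pooled size does not match H, W");
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dxc = dx.begin() + ((size_t)n * C + c) * H * W;
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i, ++o) {
          const int di = idx[o] % 2, dj = idx[o] / 2;
          dxc[(2 * i + di) + (size_t)H * (2 * j + dj)] += dy[o];
        }
    }
  return dx;
}

// Index-preserving unpooling: each pooled value is inserted at its recorded
// argmax position; every other output position is zero.
// [[Rcpp::export]]
NumericVector cpp_maxunpool_fwd(NumericVector y, IntegerVector idx, int H,
                                int W) {
  IntegerVector d = y.attr("dim");
  const int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  if (H2 * 2 != H || W2 * 2 != W)
    stop("unpool target size (%d x %d) does not match pooled input", H, W);
  NumericVector x((size_t)H * W * C * N);
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i, ++o) {
          const int di = idx[o] % 2, dj = idx[o] / 2;
          xc[(2 * i + di) + (size_t)H * (2 * j + dj)] = y[o];
        }
    }
  return x;
}

// [[Rcpp::export]]
NumericVector cpp_maxunpool_bwd(NumericVector dout, IntegerVector idx) {
  IntegerVector d = idx.attr("dim");
  const int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  IntegerVector dd = dout.attr("dim");
  const int H = dd[0], W = dd[1];
  NumericVector dy((size_t)H2 * W2 * C * N);
  dy.attr("dim") = d;
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* dc = dout.begin() + ((size_t)n * C + c) * H * W;
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i, ++o) {
          const int di = idx[o] % 2, dj = idx[o] / 2;
          dy[o] = dc[(2 * i + di) + (size_t)H * (2 * j + dj)];
        }
    }
  return dy;
}

// Connected-component labelling of a binary mask by breadth-first search.
// Components are numbered 1, 2, ... in order of first encounter scanning
// rows first (row-major).  connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int s = 0; s < nn; ++s) {
          const int ii = p.first + di8[s], jj = p.second + dj8[s];
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          if (!mask(ii, jj) || lab(ii, jj)) continue;
          lab(ii, jj) = next;
          q.push(std::make_pair(ii, jj));
        }
      }
    }
  return lab;
}
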