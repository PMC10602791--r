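// Minimal CNN kernels: 3x3 'same' convolution and 2x2 max pooling, forward
// and backward, over batches stored as (H, W, C, N) column-major arrays, plus
// the subsample/bootstrap slope resampler. All randomness comes from R's RNG
// so results are reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;


static NumericVector num4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector int4(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector dims_of(const NumericVector& a) {
  if (!a.hasAttribute("dim")) stop("expected an array with a dim attribute");
  return a.attr("dim");
}

// im2col for one (H, W, C) image with 3x3 kernel, zero padding 1.
// Output: (H*W) x (9*C); column r = c*9 + kj*3 + ki holds pixel
// x(i + ki - 1, j + kj - 1, c) for output site q = j*H + i.
static void im2col3(const double* x, int H, int W, int C, arma::mat& Pt) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        int r = c * 9 + kj * 3 + ki;
        double* col = Pt.colptr(r);
        for (int j = 0; j < W; ++j) {
          int sj = j + kj - 1;
          double* dst = col + (size_t)j * H;
          if (sj < 0 || sj >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)sj * H;
          int si0 = ki - 1; // source row for output row 0
          for (int i = 0; i < H; ++i) {
            int si = i + si0;
            dst[i] = (si < 0 || si >= H) ? 0.0 : src[si];
          }
        }
      }
    }
  }
}

// Forward 3x3 same-padding convolution. w has dim (3, 3, Cin, Cout).
// [[Rcpp::export]]
NumericVector cnn_conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (wd[0] != 3 || wd[1] != 3 || wd[2] != C) stop("weight/input channel mismatch");
  int F = wd[3];
  if (b.size() != F) stop("bias length mismatch");

  arma::mat Wm(const_cast<double*>(w.begin()), 9 * C, F, false, true);
  NumericVector y = num4(H, W, F, N);
  arma::mat Pt(H * W, 9 * C);
  arma::rowvec bias(const_cast<double*>(b.begin()), F, false, true);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    im2col3(xn, H, W, C, Pt);
    arma::mat Y(y.begin() + (size_t)n * H * W * F, H * W, F, false, true);
    Y = Pt * Wm;
    Y.each_row() += bias;
  }
  return y;
}

// Backward pass: returns grads wrt input, weights, bias.
// [[Rcpp::export]]
List cnn_conv_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int F = wd[3];

  arma::mat Wm(const_cast<double*>(w.begin()), 9 * C, F, false, true);
  NumericVector gx = num4(H, W, C, N);
  NumericVector gw = num4(3, 3, C, F);
  NumericVector gb(F);
  arma::mat gWm(gw.begin(), 9 * C, F, false, true);
  arma::vec gB(gb.begin(), F, false, true);

  arma::mat Pt(H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    im2col3(xn, H, W, C, Pt);
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)n * H * W * F,
                 H * W, F, false, true);
    gWm += Pt.t() * Gy;
    gB += arma::sum(Gy, 0).t();
    arma::mat Gcol = Gy * Wm.t(); // (H*W) x (9*C)
    // col2im: scatter-add each shifted column back into the input grad.
    double* gxn = gx.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      double* gxc = gxn + (size_t)c * H * W;
      for (int kj = 0; kj < 3; ++kj) {
        for (int ki = 0; ki < 3; ++ki) {
          int r = c * 9 + kj * 3 + ki;
          const double* col = Gcol.colptr(r);
          for (int j = 0; j < W; ++j) {
            int sj = j + kj - 1;
            if (sj < 0 || sj >= W) continue;
            double* dst = gxc + (size_t)sj * H;
            const double* src = col + (size_t)j * H;
            int si0 = ki - 1;
            int i_lo = std::max(0, -si0), i_hi = std::min(H, H - si0);
            for (int i = i_lo; i < i_hi; ++i) dst[i + si0] += src[i];
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2 (floor on odd sizes). Returns pooled batch and
// the 1-based linear index (into the full input array) of each max.
// [[Rcpp::export]]
List cnn_pool_fwd(NumericVector x) {
  IntegerVector xd = dims_of(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y = num4(Ho, Wo, C, N);
  IntegerVector idx = int4(Ho, Wo, C, N);
  size_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * H * W;
      size_t base = ((size_t)n * C + c) * H * W;
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          int i = 2 * io, j = 2 * jo;
          size_t k00 = base + (size_t)j * H + i;
          size_t best = k00;
          double v = x[k00];
          size_t cand[3] = {k00 + 1, k00 + H, k00 + H + 1};
          for (int t = 0; t < 3; ++t) {
            if (x[cand[t]] > v) { v = x[cand[t]]; best = cand[t]; }
          }
          y[q] = v;
          idx[q] = (int)(best + 1);
          ++q;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cnn_pool_bwd(NumericVector gy, IntegerVector idx, IntegerVector in_dim) {
  NumericVector gx = num4(in_dim[0], in_dim[1], in_dim[2], in_dim[3]);
  size_t m = gy.size();
  for (size_t q = 0; q < m; ++q) gx[idx[q] - 1] += gy[q];
  return gx;
}

// Through-origin slopes for n_boot random subsamples of k points.
// Sampling uses R's RNG (partial Fisher-Yates when without replacement).
// [[Rcpp::export]]
NumericVector boot_slopes_cpp(NumericVector x, NumericVector y, int k,
                              int n_boot, bool replace) {
  int n = x.size();
  if (y.size() != n) stop("x and y lengths differ");
  if (k < 2 || k > n) stop("resample size k must be in [2, n]");
  NumericVector out(n_boot);
  std::vector<int> base(n), idx(n);
  for (int i = 0; i < n; ++i) base[i] = i;
  for (int bt = 0; bt < n_boot; ++bt) {
    double sxy = 0.0, sxx = 0.0;
    if (replace) {
      for (int t = 0; t < k; ++t) {
        int j = (int)(unif_rand() * n);
        if (j == n) j = n - 1;
        sxy += x[j] * y[j];
        sxx += x[j] * x[j];
      }
    } else {
      idx = base;
      int m = n;
      for (int t = 0; t < k; ++t) {
        int j = (int)(unif_rand() * m);
        if (j == m) j = m - 1;
        int p = idx[j];
        idx[j] = idx[--m];
        sxy += x[p] * y[p];
        sxx += x[p] * x[p];
      }
    }
    out[bt] = sxy / sxx;
  }
  return out;
}
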