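// Low-level tensor kernels for the U-Net: same-padding 2-D convolution,
// 2x2 max pooling and 2x2 stride-2 transposed convolution, each with the
// matching gradient. Tensors are R arrays in (H, W, C, N) layout; kernels
// are (k, k, Cin, Cout). Convolution is im2col + GEMM; the patch matrix is
// laid out (H*W, k*k*Cin) so that both the im2col writes and the GEMM run
// over contiguous memory.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims4(const NumericVector& x, int d[4], const char* what) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("%s must be a 4-d array", what);
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Row j*H+i of cols holds the k*k*Cin receptive field of output pixel
// (i, j); column order matches the R flattening of a (k, k, Cin) array.
// For fixed (di, dj, c) the entries over i are a contiguous run of the
// input column, shifted by di.
static void im2col_same(const double* x, int H, int W, int C, int k,
                        arma::mat& cols) {
  const int r = k / 2;
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        double* col = cols.colptr(di + k * dj + k * k * c);
        const int lo = std::max(0, r - di), hi = H - 1 - std::max(0, di - r);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - r;
          if (sj < 0 || sj >= W) continue;
          const double* src = xc + (size_t)sj * H + (di - r);
          double* dst = col + (size_t)j * H;
          for (int i = lo; i <= hi; ++i) dst[i] = src[i];
        }
      }
  }
}

static void col2im_same(const arma::mat& cols, int H, int W, int C, int k,
                        double* dx) {
  const int r = k / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const double* col = cols.colptr(di + k * dj + k * k * c);
        const int lo = std::max(0, r - di), hi = H - 1 - std::max(0, di - r);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - r;
          if (sj < 0 || sj >= W) continue;
          double* dst = xc + (size_t)sj * H + (di - r);
          const double* src = col + (size_t)j * H;
          for (int i = lo; i <= hi; ++i) dst[i] += src[i];
        }
      }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, NumericVector w, NumericVector b) {
  int dx4[4], dw4[4];
  get_dims4(x, dx4, "x"); get_dims4(w, dw4, "w");
  const int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  const int k = dw4[0], Cout = dw4[3];
  if (dw4[1] != k) stop("kernel must be square");
  if (dw4[2] != C) stop("kernel expects %d input channels, got %d", dw4[2], C);
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false);
  const arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false);
  arma::mat cols((size_t)H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    arma::mat ym(y.begin() + (size_t)n * H * W * Cout, (size_t)H * W, Cout,
                 false, true);
    ym = cols * Wm;
    ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, NumericVector w, NumericVector dy) {
  int dx4[4], dw4[4], dy4[4];
  get_dims4(x, dx4, "x"); get_dims4(w, dw4, "w"); get_dims4(dy, dy4, "dy");
  const int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  const int k = dw4[0], Cout = dw4[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  NumericVector db(Cout);
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false);
  arma::mat dWm(dw.begin(), k * k * C, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat cols((size_t)H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (size_t)n * H * W * C, H, W, C, k, cols);
    const arma::mat dym(const_cast<double*>(dy.begin()) + (size_t)n * H * W * Cout,
                        (size_t)H * W, Cout, false);
    dWm += cols.t() * dym;
    dbv += arma::sum(dym, 0);
    arma::mat dcols = dym * Wm.t();
    col2im_same(dcols, H, W, C, k, dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x) {
  int d4[4];
  get_dims4(x, d4, "x");
  const int H = d4[0], W = d4[1], C = d4[2], N = d4[3];
  if (H % 2 || W % 2) stop("max pool needs even spatial dimensions");
  const int H2 = H / 2, W2 = W / 2;
  NumericVector y((size_t)H2 * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  IntegerVector idx(y.size());
  idx.attr("dim") = y.attr("dim");
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i, ++o) {
          double best = -1e300; int arg = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const double v = xc[(size_t)(2 * j + dj) * H + 2 * i + di];
              if (v > best) { best = v; arg = di + 2 * dj; }
            }
          y[o] = best; idx[o] = arg;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector idx,
                             int H, int W) {
  int d4[4];
  NumericVector dyv = dy;
  get_dims4(dyv, d4, "dy");
  const int H2 = d4[0], W2 = d4[1], C = d4[2], N = d4[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + ((size_t)n * C + c) * H * W;
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i, ++o) {
          const int di = idx[o] % 2, dj = idx[o] / 2;
          xc[(size_t)(2 * j + dj) * H + 2 * i + di] += dy[o];
        }
    }
  return dx;
}

// Transposed convolution, kernel 2x2, stride 2: each input pixel paints a
// 2x2 output block, so output pixel (2i+di, 2j+dj) receives exactly one
// contribution and the bias is added during the scatter.
// [[Rcpp::export]]
NumericVector cpp_upconv_fw(NumericVector x, NumericVector w,
                            NumericVector b) {
  int dx4[4], dw4[4];
  get_dims4(x, dx4, "x"); get_dims4(w, dw4, "w");
  const int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  const int Cout = dw4[3];
  if (dw4[0] != 2 || dw4[1] != 2 || dw4[2] != C)
    stop("transposed-conv kernel must be (2, 2, Cin, Cout)");
  const int H2 = 2 * H, W2 = 2 * W;
  NumericVector y((size_t)H2 * W2 * Cout * N);
  y.attr("dim") = IntegerVector::create(H2, W2, Cout, N);
  arma::mat Wsub(C, Cout);
  for (int dj = 0; dj < 2; ++dj)
    for (int di = 0; di < 2; ++di) {
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < C; ++c)
          Wsub(c, o) = w[di + 2 * dj + 4 * c + (size_t)4 * C * o];
      for (int n = 0; n < N; ++n) {
        const arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                           (size_t)H * W, C, false);
        arma::mat Ys = Xm * Wsub;
        double* yn = y.begin() + (size_t)n * H2 * W2 * Cout;
        for (int o = 0; o < Cout; ++o) {
          double* yo = yn + (size_t)o * H2 * W2;
          for (int j = 0; j < W; ++j) {
            const double* src = Ys.colptr(o) + (size_t)j * H;
            double* dst = yo + (size_t)(2 * j + dj) * H2 + di;
            for (int i = 0; i < H; ++i) dst[2 * i] = src[i] + b[o];
          }
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_upconv_bw(NumericVector x, NumericVector w, NumericVector dy) {
  int dx4[4], dw4[4], dy4[4];
  get_dims4(x, dx4, "x"); get_dims4(w, dw4, "w"); get_dims4(dy, dy4, "dy");
  const int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  const int Cout = dw4[3];
  const int H2 = dy4[0], W2 = dy4[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  NumericVector db(Cout);
  arma::mat Wsub(C, Cout), dYs((size_t)H * W, Cout);
  for (int dj = 0; dj < 2; ++dj)
    for (int di = 0; di < 2; ++di) {
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < C; ++c)
          Wsub(c, o) = w[di + 2 * dj + 4 * c + (size_t)4 * C * o];
      arma::mat dWsub(C, Cout, arma::fill::zeros);
      for (int n = 0; n < N; ++n) {
        const double* dyn = dy.begin() + (size_t)n * H2 * W2 * Cout;
        for (int o = 0; o < Cout; ++o) {
          const double* dyo = dyn + (size_t)o * H2 * W2;
          for (int j = 0; j < W; ++j) {
            double* dst = dYs.colptr(o) + (size_t)j * H;
            const double* src = dyo + (size_t)(2 * j + dj) * H2 + di;
            for (int i = 0; i < H; ++i) dst[i] = src[2 * i];
          }
        }
        const arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                           (size_t)H * W, C, false);
        arma::mat dXm(dx.begin() + (size_t)n * H * W * C, (size_t)H * W, C,
                      false, true);
        dWsub += Xm.t() * dYs;
        dXm += dYs * Wsub.t();
        for (int o = 0; o < Cout; ++o) db[o] += arma::accu(dYs.col(o));
      }
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < C; ++c)
          dw[di + 2 * dj + 4 * c + (size_t)4 * C * o] = dWsub(c, o);
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
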