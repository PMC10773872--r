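// Low-level numeric kernels: same-padded 2D convolution (forward and
// backward via im2col + GEMM), 2x2 max pooling with recorded argmax,
// batch normalization, ReLU, and an even-odd scanline polygon
// rasterizer.
//
// Array convention (column-major, as stored by R):
//   feature tensors  dim = (H, W, C, N)
//   conv weights     dim = (k, k, Cin, Cout), k odd (1 or 3 in practice)
// so linear index = h + H*(w + W*(c + C*n)).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline arma::uvec dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return arma::uvec{(unsigned)d[0], (unsigned)d[1], (unsigned)d[2], (unsigned)d[3]};
}

// Build the patch matrix (H*W x k*k*Cin) for one image with zero
// padding pad = (k-1)/2.  Column r = (kh, kw, c) holds, contiguously
// over output pixels, the input value at offset (kh-pad, kw-pad) in
// channel c, so writes are long contiguous runs along h.
static void im2col(const double* x, int H, int W, int C, int k,
                   arma::mat& col) {
  const int pad = (k - 1) / 2;
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)HW * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * c);
        double* dst = col.colptr(r);
        const int dh = kh - pad, dw = kw - pad;
        const int lo = std::max(0, -dh), hi = std::min(H, H - dh);
        for (int w = 0; w < W; ++w) {
          double* d = dst + (size_t)H * w;
          const int ws = w + dw;
          if (ws < 0 || ws >= W) {
            std::memset(d, 0, sizeof(double) * H);
            continue;
          }
          const double* s = xc + (size_t)H * ws + dh;
          if (lo > 0) std::memset(d, 0, sizeof(double) * lo);
          std::memcpy(d + lo, s + lo, sizeof(double) * (hi - lo));
          if (hi < H) std::memset(d + hi, 0, sizeof(double) * (H - hi));
        }
      }
    }
  }
}

// Scatter-add of a patch matrix back to image space (adjoint of im2col).
static void col2im(const arma::mat& col, int H, int W, int C, int k,
                   double* dx) {
  const int pad = (k - 1) / 2;
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)HW * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * c);
        const double* src = col.colptr(r);
        const int dh = kh - pad, dw = kw - pad;
        const int lo = std::max(0, -dh), hi = std::min(H, H - dh);
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          double* d = xc + (size_t)H * ws + dh;
          const double* s = src + (size_t)H * w;
          for (int h = lo; h < hi; ++h) d[h] += s[h];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  arma::uvec dx = dims4(x);
  IntegerVector dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cin = dw[2], Cout = dw[3];
  if (dw[1] != k) stop("non-square kernel");
  if (Cin != C) stop("input channels (%d) do not match weights (%d)", C, Cin);
  if (b.size() != Cout) stop("bias length must equal output channels");
  const int HW = H * W;

  NumericVector out = alloc4(H, W, Cout, N);
  arma::mat Wm(w.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::rowvec bias(b.begin(), Cout);

  if (k == 1) {
    for (int n = 0; n < N; ++n) {
      arma::mat X(x.begin() + (size_t)HW * C * n, HW, C, false, true);
      arma::mat Y(out.begin() + (size_t)HW * Cout * n, HW, Cout, false, true);
      Y = X * Wm;
      Y.each_row() += bias;
    }
    return out;
  }

  arma::mat col(HW, (size_t)k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)HW * C * n, H, W, C, k, col);
    arma::mat Y(out.begin() + (size_t)HW * Cout * n, HW, Cout, false, true);
    Y = col * Wm;
    Y.each_row() += bias;
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy) {
  arma::uvec dx4 = dims4(x);
  IntegerVector dw = w.attr("dim");
  const int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  const int k = dw[0], Cin = dw[2], Cout = dw[3];
  const int HW = H * W;

  NumericVector dxv = alloc4(H, W, C, N);
  NumericVector dwv = alloc4(k, k, Cin, Cout);
  NumericVector dbv(Cout);
  arma::mat Wm(w.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::mat dWm(dwv.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::rowvec dB(dbv.begin(), Cout, false, true);

  if (k == 1) {
    for (int n = 0; n < N; ++n) {
      arma::mat X(x.begin() + (size_t)HW * C * n, HW, C, false, true);
      arma::mat dY(dy.begin() + (size_t)HW * Cout * n, HW, Cout, false, true);
      arma::mat dX(dxv.begin() + (size_t)HW * C * n, HW, C, false, true);
      dX = dY * Wm.t();
      dWm += X.t() * dY;
      dB += arma::sum(dY, 0);
    }
    return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
  }

  arma::mat col(HW, (size_t)k * k * Cin);
  arma::mat dcol(HW, (size_t)k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)HW * C * n, H, W, C, k, col);
    arma::mat dY(dy.begin() + (size_t)HW * Cout * n, HW, Cout, false, true);
    dWm += col.t() * dY;
    dB += arma::sum(dY, 0);
    dcol = dY * Wm.t();
    col2im(dcol, H, W, C, k, dxv.begin() + (size_t)HW * C * n);
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// 2x2 max pooling, stride 2.  Ties resolve to the first element in
// (h, w) scan order so gradients never double-route.
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  arma::uvec d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("spatial dims must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N); // linear index into x
  const double* px = x.begin();
  double* po = out.begin();
  int* pi = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          size_t i00 = base + 2 * h + (size_t)H * (2 * w);
          size_t cand[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
          size_t best = cand[0];
          double bv = px[best];
          for (int t = 1; t < 4; ++t)
            if (px[cand[t]] > bv) { bv = px[cand[t]]; best = cand[t]; }
          po[o] = bv;
          pi[o] = (int)best;
        }
    }
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(IntegerVector idx, NumericVector dy,
                          IntegerVector in_dim) {
  NumericVector dx = alloc4(in_dim[0], in_dim[1], in_dim[2], in_dim[3]);
  const int* pi = idx.begin();
  const double* pd = dy.begin();
  double* px = dx.begin();
  const size_t n = dy.size();
  for (size_t i = 0; i < n; ++i) px[pi[i]] += pd[i];
  return dx;
}

// [[Rcpp::export(name = ".relu_fw")]]
NumericVector relu_fw_cpp(NumericVector x) {
  NumericVector y = clone(x);
  double* p = y.begin();
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = 0;
  return y;
}

// [[Rcpp::export(name = ".relu_bw")]]
NumericVector relu_bw_cpp(NumericVector y, NumericVector dy) {
  NumericVector dx = clone(dy);
  const double* py = y.begin();
  double* p = dx.begin();
  const R_xlen_t n = dx.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (py[i] <= 0) p[i] = 0;
  return dx;
}

// Per-channel mean and (population) variance over (H, W, N).
// [[Rcpp::export(name = ".bn_stats")]]
List bn_stats(NumericVector x) {
  arma::uvec d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / (HW * N);
    mean[c] = m;
    var[c] = s2 / (HW * N) - m * m;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = a[c] * x + b[c] per channel (affine form of batch normalization)
// [[Rcpp::export(name = ".bn_apply")]]
NumericVector bn_apply(NumericVector x, NumericVector a, NumericVector b) {
  arma::uvec d = dims4(x);
  const int C = d[2], N = d[3];
  const size_t HW = (size_t)d[0] * d[1];
  NumericVector y = alloc4(d[0], d[1], C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      double* q = y.begin() + HW * (c + (size_t)C * n);
      const double ac = a[c], bc = b[c];
      for (size_t i = 0; i < HW; ++i) q[i] = ac * p[i] + bc;
    }
  return y;
}

// Batch-norm backward.  In training mode the batch statistics depend on
// x, giving the usual three-term gradient; in inference mode the
// normalization is a fixed affine map.
// [[Rcpp::export(name = ".bn_bw")]]
List bn_bw_cpp(NumericVector x, NumericVector dy, NumericVector gamma,
               NumericVector mu, NumericVector istd, bool training) {
  arma::uvec d = dims4(x);
  const int C = d[2], N = d[3];
  const size_t HW = (size_t)d[0] * d[1];
  const double m = (double)HW * N;
  NumericVector dx = alloc4(d[0], d[1], C, N);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + HW * (c + (size_t)C * n);
      const double* pd = dy.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        s1 += pd[i];
        s2 += pd[i] * (px[i] - mu[c]) * istd[c];
      }
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double gc = gamma[c] * istd[c];
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + HW * (c + (size_t)C * n);
      const double* pd = dy.begin() + HW * (c + (size_t)C * n);
      double* pq = dx.begin() + HW * (c + (size_t)C * n);
      if (training) {
        for (size_t i = 0; i < HW; ++i) {
          const double xh = (px[i] - mu[c]) * istd[c];
          pq[i] = gc * (pd[i] - s1 / m - xh * s2 / m);
        }
      } else {
        for (size_t i = 0; i < HW; ++i) pq[i] = gc * pd[i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Even-odd scanline polygon fill on pixel centers.  Vertices in pixel
// coordinates with origin at the centre of pixel (row 1, col 1) = (1, 1);
// a pixel (r, c) is inside if its centre point (c, r) is inside the
// polygon by the even-odd rule.  Returns a logical matrix (nrow x ncol).
// [[Rcpp::export(name = ".poly_fill")]]
LogicalMatrix poly_fill(int nrow, int ncol, NumericVector px, NumericVector py) {
  const int nv = px.size();
  if (nv != py.size()) stop("coordinate vectors differ in length");
  LogicalMatrix out(nrow, ncol);
  if (nv < 3) return out;
  std::vector<double> xs;
  xs.reserve(nv);
  for (int r = 0; r < nrow; ++r) {
    const double yc = (double)(r + 1);
    xs.clear();
    for (int i = 0, j = nv - 1; i < nv; j = i++) {
      const double yi = py[i], yj = py[j];
      if ((yi > yc) != (yj > yc)) {
        const double t = (yc - yi) / (yj - yi);
        xs.push_back(px[i] + t * (px[j] - px[i]));
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (size_t s = 0; s + 1 < xs.size(); s += 2) {
      int c0 = (int)std::ceil(xs[s] - 1.0);      // first col with centre >= x0
      int c1 = (int)std::floor(xs[s + 1] - 1.0); // last col with centre <= x1
      if (c0 < 0) c0 = 0;
      if (c1 >= ncol) c1 = ncol - 1;
      for (int c = c0; c <= c1; ++c) out(r, c) = true;
    }
  }
  return out;
}
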