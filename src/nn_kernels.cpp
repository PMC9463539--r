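// Minimal dense conv-net primitives used by the TOY_CNN backbone.
// Arrays follow R's column-major layout with dim = (H, W, C, N).
// Convolutions are fixed 3x3, stride 1, zero padding 1, implemented as
// im2col + GEMM; pooling is 2x2 max with stride 2.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dim4(const NumericVector& x, int* d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Fill the valid (in-bounds) entries of the im2col matrix for image n.
// col is HW x 9*Cin; out-of-bounds entries must already be zero and are
// never written, so a single zeroing before the image loop suffices.
static void im2col_fill(const double* x, arma::mat& col,
                        int H, int W, int Cin, int n) {
  const long imoff = (long)H * W * Cin * n;
  for (int c = 0; c < Cin; ++c) {
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const int k = kh + 3 * kw + 9 * c;
        double* cp = col.colptr(k);
        for (int ow = 0; ow < W; ++ow) {
          const int iw = ow + kw - 1;
          if (iw < 0 || iw >= W) continue;
          const int oh0 = (kh == 0) ? 1 : 0;
          const int oh1 = (kh == 2) ? (H - 2) : (H - 1);
          const int len = oh1 - oh0 + 1;
          if (len <= 0) continue;
          const long src = imoff + (oh0 + kh - 1) + (long)H * (iw + (long)W * c);
          std::memcpy(cp + oh0 + (long)H * ow, x + src, len * sizeof(double));
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  int dx[4], dw[4];
  get_dim4(x, dx);
  get_dim4(w, dw);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  if (dw[0] != 3 || dw[1] != 3 || dw[2] != Cin)
    stop("weight array must be 3 x 3 x Cin x Cout");
  const int Cout = dw[3];
  if ((int)b.size() != Cout) stop("bias length must equal Cout");
  const int HW = H * W;

  NumericVector y = alloc4(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), 9 * Cin, Cout, false, true);
  arma::mat col(HW, 9 * Cin, arma::fill::zeros);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);

  for (int n = 0; n < N; ++n) {
    im2col_fill(x.begin(), col, H, W, Cin, n);
    arma::mat ys(y.begin() + (long)HW * Cout * n, HW, Cout, false, true);
    ys = col * Wm;
    ys.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy) {
  int dx_[4], dw_[4];
  get_dim4(x, dx_);
  get_dim4(w, dw_);
  const int H = dx_[0], W = dx_[1], Cin = dx_[2], N = dx_[3];
  const int Cout = dw_[3];
  const int HW = H * W;

  NumericVector dx = alloc4(H, W, Cin, N);
  NumericVector dwv = alloc4(3, 3, Cin, Cout);
  NumericVector dbv(Cout);

  arma::mat Wm(const_cast<double*>(w.begin()), 9 * Cin, Cout, false, true);
  arma::mat dW(dwv.begin(), 9 * Cin, Cout, false, true);
  arma::vec db(dbv.begin(), Cout, false, true);
  arma::mat col(HW, 9 * Cin, arma::fill::zeros);
  arma::mat dcol(HW, 9 * Cin);

  for (int n = 0; n < N; ++n) {
    im2col_fill(x.begin(), col, H, W, Cin, n);
    arma::mat dys(const_cast<double*>(dy.begin()) + (long)HW * Cout * n,
                  HW, Cout, false, true);
    dW += col.t() * dys;
    db += arma::sum(dys, 0).t();
    dcol = dys * Wm.t();
    // col2im: scatter-add dcol back onto the padded input grid
    double* dxp = dx.begin() + (long)HW * Cin * n;
    for (int c = 0; c < Cin; ++c) {
      for (int kw = 0; kw < 3; ++kw) {
        for (int kh = 0; kh < 3; ++kh) {
          const int k = kh + 3 * kw + 9 * c;
          const double* cp = dcol.colptr(k);
          for (int ow = 0; ow < W; ++ow) {
            const int iw = ow + kw - 1;
            if (iw < 0 || iw >= W) continue;
            const int oh0 = (kh == 0) ? 1 : 0;
            const int oh1 = (kh == 2) ? (H - 2) : (H - 1);
            double* dst = dxp + (oh0 + kh - 1) + (long)H * (iw + (long)W * c);
            const double* src = cp + oh0 + (long)H * ow;
            for (int i = 0; i <= oh1 - oh0; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List maxpool2_fw(NumericVector x) {
  int d[4];
  get_dim4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dimensions");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  long o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long base = (long)H * W * (c + (long)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh, ++o) {
          const long p00 = base + 2 * oh + (long)H * (2 * ow);
          long best = p00;
          double bv = xp[p00];
          const long cand[3] = {p00 + 1, p00 + H, p00 + H + 1};
          for (int k = 0; k < 3; ++k)
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
          yp[o] = bv;
          ip[o] = (int)best;  // first occurrence wins ties: deterministic
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(NumericVector dy, IntegerVector idx,
                          IntegerVector xdim) {
  if (xdim.size() != 4) stop("xdim must have length 4");
  NumericVector dx = alloc4(xdim[0], xdim[1], xdim[2], xdim[3]);
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  const long n = dy.size();
  for (long i = 0; i < n; ++i) dxp[ip[i]] += dyp[i];
  return dx;
}
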