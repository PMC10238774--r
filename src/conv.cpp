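// Real-valued 2-D convolution (cross-correlation) primitives used by the
// quaternion layers: a quaternion convolution is lowered in R to a real
// convolution whose per-pair 4x4 weight block is the Hamilton-product matrix.
// Layout (column-major, R order): x[H, W, C, N], w[kh, kw, Cin, Cout],
// y[Ho, Wo, Cout, N]. Padding is symmetric zero padding of `pad` pixels;
// Ho = (H + 2*pad - kh)/stride + 1.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void dims4(const NumericVector& a, int d[4]) {
  IntegerVector dm = a.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// fill the im2col matrix for one sample: rows = Ho*Wo (i fastest),
// cols = kh*kw*Cin in (ki, kj, c) order — matching R's column-major flatten
// of w[kh, kw, Cin, .] so that y = col * Wmat.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int cc = ki + kh * kj + kh * kw * c;
        double* dst = col.colptr(cc);
        for (int j = 0; j < Wo; ++j) {
          int xj = j * stride + kj - pad;
          if (xj < 0 || xj >= W) {
            for (int i = 0; i < Ho; ++i) dst[i + (size_t)Ho * j] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)xj * H;
          for (int i = 0; i < Ho; ++i) {
            int xi = i * stride + ki - pad;
            dst[i + (size_t)Ho * j] =
              (xi < 0 || xi >= H) ? 0.0 : xcol[xi];
          }
        }
      }
    }
  }
}

// scatter-add of a col-matrix back to image space (adjoint of im2col)
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int cc = ki + kh * kj + kh * kw * c;
        const double* src = col.colptr(cc);
        for (int j = 0; j < Wo; ++j) {
          int xj = j * stride + kj - pad;
          if (xj < 0 || xj >= W) continue;
          double* xcol = xc + (size_t)xj * H;
          for (int i = 0; i < Ho; ++i) {
            int xi = i * stride + ki - pad;
            if (xi >= 0 && xi < H) xcol[xi] += src[i + (size_t)Ho * j];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector bias, int stride, int pad) {
  int dx[4], dw[4];
  dims4(x, dx); dims4(w, dw);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("input channels (%d) do not match kernel channels (%d)", C, Cin);
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wmat(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout,
                 false, true);
  arma::mat col(Ho * Wo, (size_t)kh * kw * Cin);
  bool has_bias = bias.size() == Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    arma::mat ymat(y.begin() + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout,
                   false, true);
    ymat = col * Wmat;
    if (has_bias) ymat.each_row() += arma::rowvec(bias.begin(), Cout, false);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, bool need_gx) {
  int dx[4], dw[4], dy[4];
  dims4(x, dx); dims4(w, dw); dims4(gy, dy);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], Cin = dw[2], Cout = dw[3];
  int Ho = dy[0], Wo = dy[1];
  arma::mat Wmat(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout,
                 false, true);
  NumericVector gw((size_t)kh * kw * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  arma::mat Gw(gw.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  NumericVector gb(Cout);
  arma::rowvec Gb(gb.begin(), Cout, false, true);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector((size_t)H * W * C * N);
    gx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  arma::mat col(Ho * Wo, (size_t)kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)n * Ho * Wo * Cout,
                 Ho * Wo, Cout, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    Gw += col.t() * Gy;
    Gb += arma::sum(Gy, 0);
    if (need_gx) {
      arma::mat gcol = Gy * Wmat.t();
      col2im(gcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
             gx.begin() + (size_t)n * H * W * C);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
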