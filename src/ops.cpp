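// Broadcast / reduction helpers over (H, W, C, N) arrays, used by batch
// normalization and the attention gates. "chan" variants broadcast or
// reduce per channel c; "cn" variants per (channel, sample); "pn" variants
// per (pixel, sample). All return fresh arrays; nothing mutates its input.
#include <Rcpp.h>
using namespace Rcpp;

static void get_dims(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// [[Rcpp::export]]
List chan_stats_cpp(NumericVector x) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  size_t hw = (size_t)H * W;
  NumericVector mean(C), var(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      double s = 0, s2 = 0;
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      mean[c] += s; var[c] += s2;
    }
  double M = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    mean[c] /= M;
    var[c] = var[c] / M - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector chan_affine_cpp(NumericVector x, NumericVector scale,
                              NumericVector shift) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  size_t hw = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      double* q = y.begin() + hw * (c + (size_t)C * n);
      double a = scale[c], b = shift.size() ? shift[c] : 0.0;
      for (size_t i = 0; i < hw; ++i) q[i] = a * p[i] + b;
    }
  return y;
}

// [[Rcpp::export]]
NumericVector chan_dot_cpp(NumericVector a, NumericVector b) {
  int H, W, C, N; get_dims(a, H, W, C, N);
  size_t hw = (size_t)H * W;
  NumericVector out(C);
  bool hasb = b.size() == a.size();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = hw * (c + (size_t)C * n);
      const double* p = a.begin() + off;
      double s = 0;
      if (hasb) {
        const double* q = b.begin() + off;
        for (size_t i = 0; i < hw; ++i) s += p[i] * q[i];
      } else {
        for (size_t i = 0; i < hw; ++i) s += p[i];
      }
      out[c] += s;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cn_mean_cpp(NumericVector x) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  size_t hw = (size_t)H * W;
  NumericMatrix out(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      double s = 0;
      for (size_t i = 0; i < hw; ++i) s += p[i];
      out(c, n) = s / hw;
    }
  return out;
}

// [[Rcpp::export]]
List cn_max_cpp(NumericVector x) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  size_t hw = (size_t)H * W;
  NumericMatrix mx(C, N);
  IntegerMatrix arg(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      double best = p[0]; int bi = 0;
      for (size_t i = 1; i < hw; ++i)
        if (p[i] > best) { best = p[i]; bi = (int)i; }
      mx(c, n) = best;
      arg(c, n) = bi + 1; // 1-based spatial index
    }
  return List::create(_["max"] = mx, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cn_scale_cpp(NumericVector x, NumericMatrix s) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  size_t hw = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = hw * (c + (size_t)C * n);
      const double* p = x.begin() + off;
      double* q = y.begin() + off;
      double a = s(c, n);
      for (size_t i = 0; i < hw; ++i) q[i] = a * p[i];
    }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cn_dot_cpp(NumericVector a, NumericVector b) {
  int H, W, C, N; get_dims(a, H, W, C, N);
  size_t hw = (size_t)H * W;
  NumericMatrix out(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = hw * (c + (size_t)C * n);
      const double* p = a.begin() + off;
      const double* q = b.begin() + off;
      double s = 0;
      for (size_t i = 0; i < hw; ++i) s += p[i] * q[i];
      out(c, n) = s;
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cn_addconst_cpp(NumericVector x, NumericMatrix t) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  size_t hw = (size_t)H * W;
  NumericVector y = clone(x);
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* q = y.begin() + hw * (c + (size_t)C * n);
      double a = t(c, n);
      for (size_t i = 0; i < hw; ++i) q[i] += a;
    }
  return y;
}

// mean / max / argmax along the channel axis: outputs (H, W, N)
// [[Rcpp::export]]
List pn_meanmax_cpp(NumericVector x) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  size_t hw = (size_t)H * W;
  NumericVector mean(hw * N), mx(hw * N);
  IntegerVector arg(hw * N);
  IntegerVector d3 = IntegerVector::create(H, W, N);
  for (int n = 0; n < N; ++n) {
    double* pm = mean.begin() + hw * n;
    double* px = mx.begin() + hw * n;
    int* pa = arg.begin() + hw * n;
    const double* p0 = x.begin() + hw * (size_t)C * n;
    for (size_t i = 0; i < hw; ++i) { pm[i] = p0[i]; px[i] = p0[i]; pa[i] = 1; }
    for (int c = 1; c < C; ++c) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) {
        pm[i] += p[i];
        if (p[i] > px[i]) { px[i] = p[i]; pa[i] = c + 1; }
      }
    }
    for (size_t i = 0; i < hw; ++i) pm[i] /= C;
  }
  mean.attr("dim") = d3; mx.attr("dim") = d3; arg.attr("dim") = d3;
  return List::create(_["mean"] = mean, _["max"] = mx, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector pn_scale_cpp(NumericVector x, NumericVector g) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  size_t hw = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n) {
    const double* pg = g.begin() + hw * n;
    for (int c = 0; c < C; ++c) {
      size_t off = hw * (c + (size_t)C * n);
      const double* p = x.begin() + off;
      double* q = y.begin() + off;
      for (size_t i = 0; i < hw; ++i) q[i] = p[i] * pg[i];
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector pn_dot_cpp(NumericVector a, NumericVector b) {
  int H, W, C, N; get_dims(a, H, W, C, N);
  size_t hw = (size_t)H * W;
  NumericVector out(hw * N);
  for (int n = 0; n < N; ++n) {
    double* po = out.begin() + hw * n;
    for (int c = 0; c < C; ++c) {
      size_t off = hw * (c + (size_t)C * n);
      const double* p = a.begin() + off;
      const double* q = b.begin() + off;
      for (size_t i = 0; i < hw; ++i) po[i] += p[i] * q[i];
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, N);
  return out;
}

// [[Rcpp::export]]
NumericVector pn_addconst_cpp(NumericVector x, NumericVector t) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  size_t hw = (size_t)H * W;
  NumericVector y = clone(x);
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n) {
    const double* pt = t.begin() + hw * n;
    for (int c = 0; c < C; ++c) {
      double* q = y.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) q[i] += pt[i];
    }
  }
  return y;
}
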