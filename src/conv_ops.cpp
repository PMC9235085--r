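// 2D convolution forward/backward via im2col + GEMM (Armadillo).
// Tensor layout follows the R side: x is [H, W, C, N] (column-major),
// weights are [kh, kw, C, F], outputs [Ho, Wo, F, N]. Stride `s`,
// symmetric zero padding `p`.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static void im2col(const double *x, int H, int W, int C, int kh, int kw,
                   int s, int p, int Ho, int Wo, arma::mat &col) {
  // col is (kh*kw*C) x (Ho*Wo); row index r = ki + kh*(kj + kw*c)
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * s - p + kj;
          double *dst = col.colptr(0) + r; // will index manually
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              col(r, ho + Ho * wo) = 0.0;
            continue;
          }
          const double *xcol = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * s - p + ki;
            col(r, ho + Ho * wo) =
                (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
          }
          (void)dst;
        }
      }
  }
}

static void col2im_add(const arma::mat &col, int H, int W, int C, int kh,
                       int kw, int s, int p, int Ho, int Wo, double *dx) {
  for (int c = 0; c < C; ++c) {
    double *xc = dx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * s - p + kj;
          if (wi < 0 || wi >= W) continue;
          double *xcol = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * s - p + ki;
            if (hi < 0 || hi >= H) continue;
            xcol[hi] += col(r, ho + Ho * wo);
          }
        }
      }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  if (xd.size() != 4 || wd.size() != 4) stop("x and w must be 4D");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cw = wd[2], F = wd[3];
  if (C != Cw) stop("channel mismatch");
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("output size would be empty");

  NumericVector y(Ho * Wo * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);

  arma::mat Wm(const_cast<double *>(w.begin()), kh * kw * C, F, false, true);
  arma::mat col(kh * kw * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + (size_t)H * W * C * n;
    im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat ymat = Wm.t() * col; // F x (Ho*Wo)
    double *yn = y.begin() + (size_t)Ho * Wo * F * n;
    for (int f = 0; f < F; ++f) {
      double bf = b[f];
      double *yf = yn + (size_t)Ho * Wo * f;
      for (int o = 0; o < Ho * Wo; ++o) yf[o] = ymat(f, o) + bf;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  int Ho = yd[0], Wo = yd[1];

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(F);

  arma::mat Wm(const_cast<double *>(w.begin()), kh * kw * C, F, false, true);
  arma::mat dWm(dw.begin(), kh * kw * C, F, false, true);
  arma::mat col(kh * kw * C, Ho * Wo);
  arma::mat dymat(F, Ho * Wo);

  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + (size_t)H * W * C * n;
    const double *dyn = dy.begin() + (size_t)Ho * Wo * F * n;
    for (int f = 0; f < F; ++f) {
      const double *dyf = dyn + (size_t)Ho * Wo * f;
      double acc = 0;
      for (int o = 0; o < Ho * Wo; ++o) {
        dymat(f, o) = dyf[o];
        acc += dyf[o];
      }
      db[f] += acc;
    }
    im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    dWm += col * dymat.t();
    arma::mat dcol = Wm * dymat; // (kh*kw*C) x (Ho*Wo)
    double *dxn = dx.begin() + (size_t)H * W * C * n;
    col2im_add(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo, dxn);
  }
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}
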