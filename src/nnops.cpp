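// Low-level kernels for the 3D convolutional clip classifier.
//
// Tensor layout: dense double vector with dims (C, H, W, T, N),
// channel fastest. Convolution weights arrive as a K x Cout matrix
// with K = Cin*kh*kw*kt, rows ordered (Cin, kh, kw, kt) nested
// channel-fastest (i.e. an R array dim c(Cin,kh,kw,kt,Cout) flattened).
// "Same" padding keeps out = ceil(in/stride) on every axis; pooling can
// optionally run unpadded ("valid") on the temporal axis, which the
// architecture needs once to land on its printed pre-avgpool extent.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Ax { int out, pad_beg; };

Ax same_axis(int in, int k, int s) {
  int out = (in + s - 1) / s;
  int pad = std::max((out - 1) * s + k - in, 0);
  return {out, pad / 2};
}
Ax valid_axis(int in, int k, int s) {
  return {(in - k) / s + 1, 0};
}

inline size_t idx5(int c, int h, int w, int t, int n,
                   int C, int H, int W, int T) {
  return (size_t)c + (size_t)C * (h + (size_t)H * (w + (size_t)W *
         (t + (size_t)T * n)));
}

// gather one (n, t_out) chunk into col (K x Ho*Wo); the (C, kh) block
// is contiguous in both source and destination, so each in-bounds
// kernel column is a single memcpy of C*len doubles
void im2col_chunk(const double* x, int C, int H, int W, int T,
                  int n, int to, int kh, int kw, int kt,
                  int sh, int sw, int st,
                  int ph, int pw, int pt, int Ho, int Wo,
                  double* col) {
  const int K = C * kh * kw * kt;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* dst = col + (size_t)K * (ho + (size_t)Ho * wo);
      int h0 = ho * sh - ph, w0 = wo * sw - pw, t0 = to * st - pt;
      int hlo = std::max(0, -h0), hhi = std::min(kh, H - h0);
      for (int it = 0; it < kt; ++it) {
        int t = t0 + it;
        for (int iw = 0; iw < kw; ++iw) {
          int w = w0 + iw;
          double* d = dst + (size_t)C * kh * (iw + (size_t)kw * it);
          if (t < 0 || t >= T || w < 0 || w >= W || hlo >= hhi) {
            std::fill(d, d + (size_t)C * kh, 0.0);
            continue;
          }
          if (hlo > 0) std::fill(d, d + (size_t)C * hlo, 0.0);
          const double* s = x + idx5(0, h0 + hlo, w, t, n, C, H, W, T);
          std::copy(s, s + (size_t)C * (hhi - hlo), d + (size_t)C * hlo);
          if (hhi < kh)
            std::fill(d + (size_t)C * hhi, d + (size_t)C * kh, 0.0);
        }
      }
    }
  }
}

// scatter-add a col chunk back into dx; the (C, kh) run is added in
// one contiguous sweep
void col2im_chunk(const double* col, int C, int H, int W, int T,
                  int n, int to, int kh, int kw, int kt,
                  int sh, int sw, int st,
                  int ph, int pw, int pt, int Ho, int Wo,
                  double* dx) {
  const int K = C * kh * kw * kt;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* src = col + (size_t)K * (ho + (size_t)Ho * wo);
      int h0 = ho * sh - ph, w0 = wo * sw - pw, t0 = to * st - pt;
      int hlo = std::max(0, -h0), hhi = std::min(kh, H - h0);
      if (hlo >= hhi) continue;
      const size_t run = (size_t)C * (hhi - hlo);
      for (int it = 0; it < kt; ++it) {
        int t = t0 + it;
        if (t < 0 || t >= T) continue;
        for (int iw = 0; iw < kw; ++iw) {
          int w = w0 + iw;
          if (w < 0 || w >= W) continue;
          const double* s = src + (size_t)C * (hlo + kh * (iw + (size_t)kw * it));
          double* d = dx + idx5(0, h0 + hlo, w, t, n, C, H, W, T);
          for (size_t q = 0; q < run; ++q) d[q] += s[q];
        }
      }
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".conv3d_forward_cpp")]]
Rcpp::List conv3d_forward_cpp(const Rcpp::NumericVector& x,
                              const Rcpp::IntegerVector& dims,
                              const arma::mat& wmat,
                              const Rcpp::NumericVector& bias,
                              const Rcpp::IntegerVector& kern,
                              const Rcpp::IntegerVector& stride) {
  const int C = dims[0], H = dims[1], W = dims[2], T = dims[3], N = dims[4];
  const int kh = kern[0], kw = kern[1], kt = kern[2];
  const int sh = stride[0], sw = stride[1], st = stride[2];
  const int Cout = wmat.n_cols;
  Ax ah = same_axis(H, kh, sh), aw = same_axis(W, kw, sw),
     at = same_axis(T, kt, st);
  const int Ho = ah.out, Wo = aw.out, To = at.out;
  const int K = C * kh * kw * kt, P = Ho * Wo;

  Rcpp::NumericVector y((size_t)Cout * Ho * Wo * To * N);
  mat col(K, P);
  const mat wt = wmat.t();  // Cout x K
  vec b(bias.begin(), Cout);
  for (int n = 0; n < N; ++n)
    for (int to = 0; to < To; ++to) {
      im2col_chunk(x.begin(), C, H, W, T, n, to, kh, kw, kt,
                   sh, sw, st, ah.pad_beg, aw.pad_beg, at.pad_beg,
                   Ho, Wo, col.memptr());
      mat out = wt * col;              // Cout x P
      out.each_col() += b;
      std::copy(out.memptr(), out.memptr() + (size_t)Cout * P,
                y.begin() + idx5(0, 0, 0, to, n, Cout, Ho, Wo, To));
    }
  return Rcpp::List::create(
      Rcpp::Named("y") = y,
      Rcpp::Named("dims") = Rcpp::IntegerVector::create(Cout, Ho, Wo, To, N));
}

// [[Rcpp::export(name = ".conv3d_backward_cpp")]]
Rcpp::List conv3d_backward_cpp(const Rcpp::NumericVector& dy,
                               const Rcpp::NumericVector& x,
                               const Rcpp::IntegerVector& dims,
                               const arma::mat& wmat,
                               const Rcpp::IntegerVector& kern,
                               const Rcpp::IntegerVector& stride) {
  const int C = dims[0], H = dims[1], W = dims[2], T = dims[3], N = dims[4];
  const int kh = kern[0], kw = kern[1], kt = kern[2];
  const int sh = stride[0], sw = stride[1], st = stride[2];
  const int Cout = wmat.n_cols;
  Ax ah = same_axis(H, kh, sh), aw = same_axis(W, kw, sw),
     at = same_axis(T, kt, st);
  const int Ho = ah.out, Wo = aw.out, To = at.out;
  const int K = C * kh * kw * kt, P = Ho * Wo;

  Rcpp::NumericVector dx(x.size());
  mat dW(K, Cout, fill::zeros);
  vec db(Cout, fill::zeros);
  mat col(K, P), dyc(Cout, P), dcol;
  for (int n = 0; n < N; ++n)
    for (int to = 0; to < To; ++to) {
      const double* src = dy.begin() + idx5(0, 0, 0, to, n, Cout, Ho, Wo, To);
      std::copy(src, src + (size_t)Cout * P, dyc.memptr());
      im2col_chunk(x.begin(), C, H, W, T, n, to, kh, kw, kt,
                   sh, sw, st, ah.pad_beg, aw.pad_beg, at.pad_beg,
                   Ho, Wo, col.memptr());
      dW += col * dyc.t();
      db += sum(dyc, 1);
      dcol = wmat * dyc;               // K x P
      col2im_chunk(dcol.memptr(), C, H, W, T, n, to, kh, kw, kt,
                   sh, sw, st, ah.pad_beg, aw.pad_beg, at.pad_beg,
                   Ho, Wo, dx.begin());
    }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = Rcpp::wrap(db));
}

// [[Rcpp::export(name = ".maxpool3d_forward_cpp")]]
Rcpp::List maxpool3d_forward_cpp(const Rcpp::NumericVector& x,
                                 const Rcpp::IntegerVector& dims,
                                 const Rcpp::IntegerVector& kern,
                                 const Rcpp::IntegerVector& stride,
                                 bool valid_t) {
  const int C = dims[0], H = dims[1], W = dims[2], T = dims[3], N = dims[4];
  const int kh = kern[0], kw = kern[1], kt = kern[2];
  const int sh = stride[0], sw = stride[1], st = stride[2];
  Ax ah = same_axis(H, kh, sh), aw = same_axis(W, kw, sw);
  Ax at = valid_t ? valid_axis(T, kt, st) : same_axis(T, kt, st);
  const int Ho = ah.out, Wo = aw.out, To = at.out;

  Rcpp::NumericVector y((size_t)C * Ho * Wo * To * N);
  Rcpp::NumericVector arg(y.size());   // flat source index (0-based), as double
  const double* px = x.begin();
  double* py = y.begin();
  double* pa = arg.begin();
  for (int n = 0; n < N; ++n)
    for (int to = 0; to < To; ++to)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double* yo = py + idx5(0, ho, wo, to, n, C, Ho, Wo, To);
          double* ao = pa + idx5(0, ho, wo, to, n, C, Ho, Wo, To);
          for (int c = 0; c < C; ++c)
            yo[c] = -std::numeric_limits<double>::infinity();
          int h0 = ho * sh - ah.pad_beg, w0 = wo * sw - aw.pad_beg,
              t0 = to * st - at.pad_beg;
          for (int it = 0; it < kt; ++it) {
            int t = t0 + it; if (t < 0 || t >= T) continue;
            for (int iw = 0; iw < kw; ++iw) {
              int w = w0 + iw; if (w < 0 || w >= W) continue;
              for (int ih = 0; ih < kh; ++ih) {
                int h = h0 + ih; if (h < 0 || h >= H) continue;
                size_t base = idx5(0, h, w, t, n, C, H, W, T);
                const double* xs = px + base;
                for (int c = 0; c < C; ++c)
                  if (xs[c] > yo[c]) { yo[c] = xs[c]; ao[c] = (double)(base + c); }
              }
            }
          }
        }
  return Rcpp::List::create(
      Rcpp::Named("y") = y, Rcpp::Named("arg") = arg,
      Rcpp::Named("dims") = Rcpp::IntegerVector::create(C, Ho, Wo, To, N));
}

// [[Rcpp::export(name = ".maxpool3d_backward_cpp")]]
Rcpp::NumericVector maxpool3d_backward_cpp(const Rcpp::NumericVector& dy,
                                           const Rcpp::NumericVector& arg,
                                           double xlen) {
  Rcpp::NumericVector dx((size_t)xlen);
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[(size_t)arg[i]] += dy[i];
  return dx;
}

// [[Rcpp::export(name = ".bn_forward_cpp")]]
Rcpp::List bn_forward_cpp(const Rcpp::NumericVector& x, int C,
                          const Rcpp::NumericVector& gamma,
                          const Rcpp::NumericVector& beta,
                          const Rcpp::NumericVector& mean_in,
                          const Rcpp::NumericVector& var_in,
                          bool training, double eps) {
  const R_xlen_t n = x.size();
  const R_xlen_t M = n / C;
  const double* px = x.begin();
  Rcpp::NumericVector mean(C), var(C);
  if (training) {
    std::vector<double> s(C, 0.0), s2(C, 0.0);
    for (R_xlen_t m = 0; m < M; ++m) {
      const double* xm = px + m * C;
      for (int c = 0; c < C; ++c) {
        s[c] += xm[c]; s2[c] += xm[c] * xm[c];
      }
    }
    for (int c = 0; c < C; ++c) {
      mean[c] = s[c] / M;
      var[c] = s2[c] / M - mean[c] * mean[c];
      if (var[c] < 0) var[c] = 0;
    }
  } else {
    mean = Rcpp::clone(mean_in); var = Rcpp::clone(var_in);
  }
  Rcpp::NumericVector y(n);
  double* py = y.begin();
  std::vector<double> a(C), b(C);
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    a[c] = gamma[c] * inv;
    b[c] = beta[c] - gamma[c] * inv * mean[c];
  }
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* xm = px + m * C;
    double* ym = py + m * C;
    for (int c = 0; c < C; ++c) ym[c] = a[c] * xm[c] + b[c];
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("mean") = mean,
                            Rcpp::Named("var") = var);
}

// [[Rcpp::export(name = ".bn_backward_cpp")]]
Rcpp::List bn_backward_cpp(const Rcpp::NumericVector& dy,
                           const Rcpp::NumericVector& x, int C,
                           const Rcpp::NumericVector& gamma,
                           const Rcpp::NumericVector& mean,
                           const Rcpp::NumericVector& var, double eps) {
  const R_xlen_t n = x.size();
  const R_xlen_t M = n / C;
  const double* px = x.begin();
  const double* pdy = dy.begin();
  std::vector<double> dg(C, 0.0), db(C, 0.0), inv(C);
  for (int c = 0; c < C; ++c) inv[c] = 1.0 / std::sqrt(var[c] + eps);
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* xm = px + m * C;
    const double* dm = pdy + m * C;
    for (int c = 0; c < C; ++c) {
      dg[c] += dm[c] * (xm[c] - mean[c]) * inv[c];
      db[c] += dm[c];
    }
  }
  Rcpp::NumericVector dx(n);
  double* pdx = dx.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* xm = px + m * C;
    const double* dm = pdy + m * C;
    double* om = pdx + m * C;
    for (int c = 0; c < C; ++c) {
      double xh = (xm[c] - mean[c]) * inv[c];
      om[c] = gamma[c] * inv[c] * (dm[c] - db[c] / M - xh * dg[c] / M);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = Rcpp::NumericVector(dg.begin(), dg.end()),
                            Rcpp::Named("dbeta") = Rcpp::NumericVector(db.begin(), db.end()));
}
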