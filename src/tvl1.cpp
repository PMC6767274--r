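// Dense TV-L1 optical flow (duality-based primal-dual scheme with
// coarse-to-fine pyramid and iterative warping).
//
// Images are H x W matrices; the returned flow maps a pixel x in the
// first image to x + u in the second, so an object moving DOWN the
// image (increasing row index) between the two frames produces a
// positive vertical (v) component.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// bilinear sample with border clamp
inline double sample(const mat& I, double r, double c) {
  const int H = I.n_rows, W = I.n_cols;
  if (r < 0) r = 0; if (r > H - 1) r = H - 1;
  if (c < 0) c = 0; if (c > W - 1) c = W - 1;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * ((1 - fc) * I(r0, c0) + fc * I(r0, c1)) +
         fr * ((1 - fc) * I(r1, c0) + fc * I(r1, c1));
}

// warp I by flow (u = horizontal/col displacement, v = vertical/row)
mat warp_image(const mat& I, const mat& u, const mat& v) {
  mat out(I.n_rows, I.n_cols);
  for (uword c = 0; c < I.n_cols; ++c)
    for (uword r = 0; r < I.n_rows; ++r)
      out(r, c) = sample(I, r + v(r, c), c + u(r, c));
  return out;
}

void centered_gradient(const mat& I, mat& gx, mat& gy) {
  const int H = I.n_rows, W = I.n_cols;
  gx.set_size(H, W); gy.set_size(H, W);
  for (int c = 0; c < W; ++c) {
    int cl = std::max(c - 1, 0), cr = std::min(c + 1, W - 1);
    for (int r = 0; r < H; ++r) {
      int ru = std::max(r - 1, 0), rd = std::min(r + 1, H - 1);
      gx(r, c) = 0.5 * (I(r, cr) - I(r, cl));
      gy(r, c) = 0.5 * (I(rd, c) - I(ru, c));
    }
  }
}

// forward differences (Neumann at the far border)
void forward_gradient(const mat& f, mat& fx, mat& fy) {
  const int H = f.n_rows, W = f.n_cols;
  fx.zeros(H, W); fy.zeros(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (c < W - 1) fx(r, c) = f(r, c + 1) - f(r, c);
      if (r < H - 1) fy(r, c) = f(r + 1, c) - f(r, c);
    }
}

// divergence, adjoint of the forward gradient
mat divergence(const mat& p1, const mat& p2) {
  const int H = p1.n_rows, W = p1.n_cols;
  mat d(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double dx = (c == 0) ? p1(r, 0) : (c == W - 1 ? -p1(r, c - 1)
                                                    : p1(r, c) - p1(r, c - 1));
      double dy = (r == 0) ? p2(0, c) : (r == H - 1 ? -p2(r - 1, c)
                                                    : p2(r, c) - p2(r - 1, c));
      d(r, c) = dx + dy;
    }
  return d;
}

// gaussian blur (separable, reflecting border)
mat gaussian_blur(const mat& I, double sigma) {
  if (sigma <= 0) return I;
  int rad = std::max(1, (int)std::ceil(2.5 * sigma));
  vec k(2 * rad + 1);
  for (int i = -rad; i <= rad; ++i)
    k(i + rad) = std::exp(-0.5 * i * i / (sigma * sigma));
  k /= accu(k);
  const int H = I.n_rows, W = I.n_cols;
  mat tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = std::abs(r + i); if (rr > H - 1) rr = 2 * (H - 1) - rr;
        s += k(i + rad) * I(rr, c);
      }
      tmp(r, c) = s;
    }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = std::abs(c + i); if (cc > W - 1) cc = 2 * (W - 1) - cc;
        s += k(i + rad) * tmp(r, cc);
      }
      out(r, c) = s;
    }
  return out;
}

mat zoom_size(const mat& I, int H2, int W2) {
  mat out(H2, W2);
  double sr = (double)I.n_rows / H2, sc = (double)I.n_cols / W2;
  for (int c = 0; c < W2; ++c)
    for (int r = 0; r < H2; ++r)
      out(r, c) = sample(I, (r + 0.5) * sr - 0.5, (c + 0.5) * sc - 0.5);
  return out;
}

// anti-aliased downscale by factor `zoom` (< 1)
mat zoom_out(const mat& I, double zoom, int H2, int W2) {
  double sigma = 0.6 * std::sqrt(1.0 / (zoom * zoom) - 1.0);
  return zoom_size(gaussian_blur(I, sigma), H2, W2);
}

// One pyramid level. Hot path: fused single-precision passes over
// column-major H x W buffers, early exit on the mean-squared update,
// and an outer exit when a whole warp no longer moves the flow.
void tvl1_one_scale(const mat& I0d, const mat& I1d, mat& ud, mat& vd,
                    double tau, double lambda, double theta,
                    int warps, double epsilon, int maxiter) {
  const int H = I0d.n_rows, W = I0d.n_cols;
  const size_t n = (size_t)H * W;
  const float l_t = (float)(lambda * theta), th = (float)theta;
  const float taut = (float)(tau / theta);
  const float eps2 = (float)(epsilon * epsilon);

  mat I1x, I1y;
  centered_gradient(I1d, I1x, I1y);

  std::vector<float> u(n), v(n), p11(n, 0.f), p12(n, 0.f), p21(n, 0.f),
      p22(n, 0.f), wI(n), wx(n), wy(n), g2(n), rc(n), v1(n), v2(n);
  for (size_t i = 0; i < n; ++i) { u[i] = (float)ud(i); v[i] = (float)vd(i); }

  for (int w = 0; w < warps; ++w) {
    // warp I1 and its gradients to x + (u, v)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        size_t i = (size_t)r + (size_t)H * c;
        double rr = r + v[i], cc = c + u[i];
        wI[i] = (float)sample(I1d, rr, cc);
        wx[i] = (float)sample(I1x, rr, cc);
        wy[i] = (float)sample(I1y, rr, cc);
        g2[i] = wx[i] * wx[i] + wy[i] * wy[i];
        rc[i] = wI[i] - wx[i] * u[i] - wy[i] * v[i] - (float)I0d(i);
      }
    float warp_change = 0.f;
    for (int it = 0; it < maxiter; ++it) {
      // pass A: thresholding step + proximal update of (u, v) using
      // the divergence of the current dual field
      float err = 0.f;
      for (int c = 0; c < W; ++c) {
        const size_t col = (size_t)H * c;
        for (int r = 0; r < H; ++r) {
          size_t i = r + col;
          float rho = rc[i] + wx[i] * u[i] + wy[i] * v[i];
          float d1, d2;
          if (rho < -l_t * g2[i])     { d1 =  l_t * wx[i]; d2 =  l_t * wy[i]; }
          else if (rho > l_t * g2[i]) { d1 = -l_t * wx[i]; d2 = -l_t * wy[i]; }
          else if (g2[i] > 1e-10f)    { float s = -rho / g2[i];
                                        d1 = s * wx[i]; d2 = s * wy[i]; }
          else                        { d1 = 0.f; d2 = 0.f; }
          // divergence of p at (r, c), backward differences
          float div1 = (c == 0 ? p11[i] : (c == W - 1 ? -p11[i - H]
                        : p11[i] - p11[i - H])) +
                       (r == 0 ? p12[i] : (r == H - 1 ? -p12[i - 1]
                        : p12[i] - p12[i - 1]));
          float div2 = (c == 0 ? p21[i] : (c == W - 1 ? -p21[i - H]
                        : p21[i] - p21[i - H])) +
                       (r == 0 ? p22[i] : (r == H - 1 ? -p22[i - 1]
                        : p22[i] - p22[i - 1]));
          float un = u[i] + d1 + th * div1;
          float vn = v[i] + d2 + th * div2;
          err += (un - u[i]) * (un - u[i]) + (vn - v[i]) * (vn - v[i]);
          u[i] = un; v[i] = vn;
        }
      }
      err /= (float)n;
      // pass B: dual ascent with forward gradients of the new (u, v)
      for (int c = 0; c < W; ++c) {
        const size_t col = (size_t)H * c;
        for (int r = 0; r < H; ++r) {
          size_t i = r + col;
          float ux = (c < W - 1) ? u[i + H] - u[i] : 0.f;
          float uy = (r < H - 1) ? u[i + 1] - u[i] : 0.f;
          float vx = (c < W - 1) ? v[i + H] - v[i] : 0.f;
          float vy = (r < H - 1) ? v[i + 1] - v[i] : 0.f;
          float ng1 = 1.f + taut * std::sqrt(ux * ux + uy * uy);
          float ng2 = 1.f + taut * std::sqrt(vx * vx + vy * vy);
          p11[i] = (p11[i] + taut * ux) / ng1;
          p12[i] = (p12[i] + taut * uy) / ng1;
          p21[i] = (p21[i] + taut * vx) / ng2;
          p22[i] = (p22[i] + taut * vy) / ng2;
        }
      }
      warp_change += err;
      if (err < eps2) break;
    }
    if (warp_change < eps2) break;  // this warp no longer moved the flow
  }
  for (size_t i = 0; i < n; ++i) { ud(i) = u[i]; vd(i) = v[i]; }
}

} // namespace

// [[Rcpp::export(name = ".tvl1_flow_cpp")]]
Rcpp::List tvl1_flow_cpp(const arma::mat& im0, const arma::mat& im1,
                         double tau, double lambda, double theta,
                         int nscales, double zoom, int warps,
                         double epsilon, int maxiter) {
  // joint normalization to a 0..255 intensity scale (the scale the
  // default lambda is calibrated for)
  double mn = std::min(im0.min(), im1.min());
  double mx = std::max(im0.max(), im1.max());
  double den = (mx - mn) > 1e-12 ? (mx - mn) : 1.0;
  mat I0 = (im0 - mn) * (255.0 / den);
  mat I1 = (im1 - mn) * (255.0 / den);

  const int H = I0.n_rows, W = I0.n_cols;
  // cap the pyramid so the coarsest level keeps some structure
  int ns = nscales;
  while (ns > 1 &&
         std::min(H, W) * std::pow(zoom, ns - 1) < 16.0) --ns;

  std::vector<mat> P0(ns), P1(ns);
  std::vector<int> Hs(ns), Ws(ns);
  P0[0] = I0; P1[0] = I1; Hs[0] = H; Ws[0] = W;
  for (int s = 1; s < ns; ++s) {
    Hs[s] = (int)std::lround(Hs[s - 1] * zoom);
    Ws[s] = (int)std::lround(Ws[s - 1] * zoom);
    P0[s] = zoom_out(P0[s - 1], zoom, Hs[s], Ws[s]);
    P1[s] = zoom_out(P1[s - 1], zoom, Hs[s], Ws[s]);
  }

  mat u(Hs[ns - 1], Ws[ns - 1], fill::zeros);
  mat v(Hs[ns - 1], Ws[ns - 1], fill::zeros);
  for (int s = ns - 1; s >= 0; --s) {
    tvl1_one_scale(P0[s], P1[s], u, v, tau, lambda, theta,
                   warps, epsilon, maxiter);
    if (s > 0) {
      double fr = (double)Hs[s - 1] / Hs[s];
      double fc = (double)Ws[s - 1] / Ws[s];
      u = zoom_size(u, Hs[s - 1], Ws[s - 1]) * fc;
      v = zoom_size(v, Hs[s - 1], Ws[s - 1]) * fr;
    }
  }
  return Rcpp::List::create(Rcpp::Named("u") = u, Rcpp::Named("v") = v);
}
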