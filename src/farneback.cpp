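// Dense optical flow by polynomial expansion: each neighbourhood is
// approximated by a quadratic f(x) = x^T A x + b^T x + c over a 5x5
// window with Gaussian applicability, and displacement is estimated from
// paired expansion coefficients, coarse-to-fine over an image pyramid
// with iterative refinement and spatial averaging of the normal
// equations. Implemented in C++ because a 60 s session means ~1,500
// frame pairs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;

struct PolyExp {
  mat c, bx, by, axx, ayy, axy;
};

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// polynomial expansion with window half-size 2 (5x5), Gaussian weights
static PolyExp poly_expansion(const mat& img, double sigma) {
  const int h = img.n_rows, w = img.n_cols, n = 2;
  arma::vec g(2 * n + 1);
  for (int u = -n; u <= n; ++u) g(u + n) = std::exp(-0.5 * u * u / (sigma * sigma));

  // G = sum w(u)w(v) B B^T, basis (1, x, y, x^2, y^2, xy), x = col offset
  arma::mat66 G;
  G.zeros();
  for (int v = -n; v <= n; ++v) {
    for (int u = -n; u <= n; ++u) {
      double wgt = g(u + n) * g(v + n);
      arma::vec6 B = {1.0, (double)u, (double)v,
                      (double)u * u, (double)v * v, (double)u * v};
      G += wgt * B * B.t();
    }
  }
  arma::mat66 Ginv = arma::inv(G);

  // horizontal pass: h0 = sum_u w f, h1 = sum_u w u f, h2 = sum_u w u^2 f
  mat h0(h, w), h1(h, w), h2(h, w);
  const double w0 = g(0), w1 = g(1), w2 = g(2), w3 = g(3), w4 = g(4);
  for (int j = 0; j < w; ++j) {
    const double* ca = img.colptr(clampi(j - 2, 0, w - 1));
    const double* cb = img.colptr(clampi(j - 1, 0, w - 1));
    const double* cc = img.colptr(j);
    const double* cd = img.colptr(clampi(j + 1, 0, w - 1));
    const double* ce = img.colptr(clampi(j + 2, 0, w - 1));
    double* o0 = h0.colptr(j);
    double* o1 = h1.colptr(j);
    double* o2 = h2.colptr(j);
    for (int i = 0; i < h; ++i) {
      double a = ca[i], b2 = cb[i], c2 = cc[i], d2 = cd[i], e2 = ce[i];
      o0[i] = w0 * a + w1 * b2 + w2 * c2 + w3 * d2 + w4 * e2;
      o1[i] = -2 * w0 * a - w1 * b2 + w3 * d2 + 2 * w4 * e2;
      o2[i] = 4 * w0 * a + w1 * b2 + w3 * d2 + 4 * w4 * e2;
    }
  }
  // vertical pass assembles the six projections; Ginv is applied with its
  // known sparsity (1/x^2/y^2 block, lone x, lone y, lone xy)
  const double I00 = Ginv(0, 0), I03 = Ginv(0, 3), I04 = Ginv(0, 4);
  const double I11 = Ginv(1, 1), I22 = Ginv(2, 2);
  const double I30 = Ginv(3, 0), I33 = Ginv(3, 3), I34 = Ginv(3, 4);
  const double I40 = Ginv(4, 0), I43 = Ginv(4, 3), I44 = Ginv(4, 4);
  const double I55 = Ginv(5, 5);
  PolyExp pe;
  pe.c.set_size(h, w); pe.bx.set_size(h, w); pe.by.set_size(h, w);
  pe.axx.set_size(h, w); pe.ayy.set_size(h, w); pe.axy.set_size(h, w);
  const double g0 = g(0), g1 = g(1), g2 = g(2), g3 = g(3), g4 = g(4);
  for (int j = 0; j < w; ++j) {
    const double* p0 = h0.colptr(j);
    const double* p1 = h1.colptr(j);
    const double* p2 = h2.colptr(j);
    for (int i = 0; i < h; ++i) {
      int im2 = clampi(i - 2, 0, h - 1), im1 = clampi(i - 1, 0, h - 1);
      int ip1 = clampi(i + 1, 0, h - 1), ip2 = clampi(i + 2, 0, h - 1);
      double a = p0[im2], b2v = p0[im1], cv = p0[i], dv = p0[ip1], ev = p0[ip2];
      double v1 = g0 * a + g1 * b2v + g2 * cv + g3 * dv + g4 * ev;
      double vy = -2 * g0 * a - g1 * b2v + g3 * dv + 2 * g4 * ev;
      double vyy = 4 * g0 * a + g1 * b2v + g3 * dv + 4 * g4 * ev;
      double q_a = p1[im2], q_b = p1[im1], q_c = p1[i], q_d = p1[ip1], q_e = p1[ip2];
      double vx = g0 * q_a + g1 * q_b + g2 * q_c + g3 * q_d + g4 * q_e;
      double vxy = -2 * g0 * q_a - g1 * q_b + g3 * q_d + 2 * g4 * q_e;
      double vxx = g0 * p2[im2] + g1 * p2[im1] + g2 * p2[i] + g3 * p2[ip1] +
                   g4 * p2[ip2];
      pe.c(i, j) = I00 * v1 + I03 * vxx + I04 * vyy;
      pe.bx(i, j) = I11 * vx;
      pe.by(i, j) = I22 * vy;
      pe.axx(i, j) = I30 * v1 + I33 * vxx + I34 * vyy;
      pe.ayy(i, j) = I40 * v1 + I43 * vxx + I44 * vyy;
      pe.axy(i, j) = 0.5 * I55 * vxy;
    }
  }
  return pe;
}

// box filter (win x win, odd), truncated at borders with count renorm;
// result written into out, tmp is caller-provided workspace
static void box_smooth(const mat& x, int win, mat& tmp, mat& out) {
  const int h = x.n_rows, w = x.n_cols, r = win / 2;
  // vertical pass first (column-major friendly)
  for (int j = 0; j < w; ++j) {
    const double* xc = x.colptr(j);
    double* tc = tmp.colptr(j);
    double s = 0; int cnt = 0;
    int lim = std::min(r, h - 1);
    for (int i = 0; i <= lim; ++i) { s += xc[i]; ++cnt; }
    for (int i = 0; i < h; ++i) {
      tc[i] = s / cnt;
      int add = i + r + 1, rem = i - r;
      if (add < h) { s += xc[add]; ++cnt; }
      if (rem >= 0) { s -= xc[rem]; --cnt; }
    }
  }
  // horizontal pass with running column sum
  arma::vec acc(h, arma::fill::zeros);
  int cnt = 0;
  int lim = std::min(r, w - 1);
  for (int j = 0; j <= lim; ++j) { acc += tmp.col(j); ++cnt; }
  for (int j = 0; j < w; ++j) {
    double* oc = out.colptr(j);
    const double inv = 1.0 / cnt;
    const double* av = acc.memptr();
    for (int i = 0; i < h; ++i) oc[i] = av[i] * inv;
    int add = j + r + 1, rem = j - r;
    if (add < w) { acc += tmp.col(add); ++cnt; }
    if (rem >= 0) { acc -= tmp.col(rem); --cnt; }
  }
}

// downscale by 2 with 1-4-6-4-1 binomial anti-aliasing
static mat pyr_down(const mat& x) {
  const int h = x.n_rows, w = x.n_cols;
  static const double k[5] = {1.0 / 16, 4.0 / 16, 6.0 / 16, 4.0 / 16, 1.0 / 16};
  mat tmp(h, w, arma::fill::zeros);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double s = 0;
      for (int u = -2; u <= 2; ++u) s += k[u + 2] * x(i, clampi(j + u, 0, w - 1));
      tmp(i, j) = s;
    }
  const int h2 = (h + 1) / 2, w2 = (w + 1) / 2;
  mat out(h2, w2);
  for (int j2 = 0; j2 < w2; ++j2)
    for (int i2 = 0; i2 < h2; ++i2) {
      int i = 2 * i2, j = 2 * j2;
      double s = 0;
      for (int u = -2; u <= 2; ++u) s += k[u + 2] * tmp(clampi(i + u, 0, h - 1), j);
      out(i2, j2) = s;
    }
  return out;
}

// bilinear upsample of a flow component to (h, w), values scaled by 2
static mat up_flow(const mat& x, int h, int w) {
  const int hs = x.n_rows, ws = x.n_cols;
  mat out(h, w);
  for (int j = 0; j < w; ++j) {
    double xj = (double)j * ws / w;
    int j0 = clampi((int)std::floor(xj), 0, ws - 1);
    int j1 = clampi(j0 + 1, 0, ws - 1);
    double fj = xj - j0;
    for (int i = 0; i < h; ++i) {
      double yi = (double)i * hs / h;
      int i0 = clampi((int)std::floor(yi), 0, hs - 1);
      int i1 = clampi(i0 + 1, 0, hs - 1);
      double fi = yi - i0;
      double v = (1 - fi) * ((1 - fj) * x(i0, j0) + fj * x(i0, j1)) +
                 fi * ((1 - fj) * x(i1, j0) + fj * x(i1, j1));
      out(i, j) = 2.0 * v;
    }
  }
  return out;
}

// one refinement pass at a fixed scale
static void flow_iterate(const PolyExp& p1, const PolyExp& p2,
                         mat& dx, mat& dy, int iters, int smooth_win) {
  const int h = p1.c.n_rows, w = p1.c.n_cols;
  mat g11(h, w), g12(h, w), g22(h, w), h1(h, w), h2(h, w);
  mat s11(h, w), s12(h, w), s22(h, w), t1(h, w), t2(h, w), tmp(h, w);
  for (int it = 0; it < iters; ++it) {
    for (int j = 0; j < w; ++j) {
      const double* paxx = p1.axx.colptr(j);
      const double* paxy = p1.axy.colptr(j);
      const double* payy = p1.ayy.colptr(j);
      const double* pbx = p1.bx.colptr(j);
      const double* pby = p1.by.colptr(j);
      const double* dxc = dx.colptr(j);
      const double* dyc = dy.colptr(j);
      double* c11 = g11.colptr(j); double* c12 = g12.colptr(j);
      double* c22 = g22.colptr(j); double* ch1 = h1.colptr(j);
      double* ch2 = h2.colptr(j);
      for (int i = 0; i < h; ++i) {
        double dxe = dxc[i], dye = dyc[i];
        int j2 = clampi((int)std::lround(j + dxe), 0, w - 1);
        int i2 = clampi((int)std::lround(i + dye), 0, h - 1);
        // the compensation term must use the INTEGER offset actually used
        // to fetch the second expansion, or sub-pixel estimates are biased
        double joff = (double)(j2 - j), ioff = (double)(i2 - i);
        double a11 = 0.5 * (paxx[i] + p2.axx(i2, j2));
        double a12 = 0.5 * (paxy[i] + p2.axy(i2, j2));
        double a22 = 0.5 * (payy[i] + p2.ayy(i2, j2));
        double db1 = -0.5 * (p2.bx(i2, j2) - pbx[i]) + (a11 * joff + a12 * ioff);
        double db2 = -0.5 * (p2.by(i2, j2) - pby[i]) + (a12 * joff + a22 * ioff);
        c11[i] = a11 * a11 + a12 * a12;
        c12[i] = a12 * (a11 + a22);
        c22[i] = a12 * a12 + a22 * a22;
        ch1[i] = a11 * db1 + a12 * db2;
        ch2[i] = a12 * db1 + a22 * db2;
      }
    }
    box_smooth(g11, smooth_win, tmp, s11);
    box_smooth(g12, smooth_win, tmp, s12);
    box_smooth(g22, smooth_win, tmp, s22);
    box_smooth(h1, smooth_win, tmp, t1);
    box_smooth(h2, smooth_win, tmp, t2);
    const double reg = 1e-9;
    for (int j = 0; j < w; ++j) {
      const double* a = s11.colptr(j); const double* b = s12.colptr(j);
      const double* c = s22.colptr(j); const double* u = t1.colptr(j);
      const double* v = t2.colptr(j);
      double* ox = dx.colptr(j); double* oy = dy.colptr(j);
      for (int i = 0; i < h; ++i) {
        double det = (a[i] + reg) * (c[i] + reg) - b[i] * b[i];
        if (std::fabs(det) < 1e-30) { ox[i] = 0; oy[i] = 0; continue; }
        ox[i] = ((c[i] + reg) * u[i] - b[i] * v[i]) / det;
        oy[i] = ((a[i] + reg) * v[i] - b[i] * u[i]) / det;
      }
    }
  }
}

// [[Rcpp::export(name = ".poly_exp_cpp")]]
List poly_exp_cpp(const arma::mat& img, double sigma = 1.1) {
  PolyExp pe = poly_expansion(img, sigma);
  return List::create(_["c"] = pe.c, _["bx"] = pe.bx, _["by"] = pe.by,
                      _["axx"] = pe.axx, _["ayy"] = pe.ayy,
                      _["axy"] = pe.axy);
}

// [[Rcpp::export(name = ".fb_flow_cpp")]]
List fb_flow_cpp(const arma::mat& a, const arma::mat& b, int levels = 5,
                 int iters = 10, double sigma = 1.1, int smooth_win = 25) {
  if (a.n_rows != b.n_rows || a.n_cols != b.n_cols)
    stop("frames must have identical size");
  if ((int)std::min(a.n_rows, a.n_cols) < 8)
    stop("frames too small for the pyramid (minimum side: 8 px)");
  std::vector<mat> pyr_a, pyr_b;
  pyr_a.push_back(a); pyr_b.push_back(b);
  for (int l = 1; l < levels; ++l) {
    const mat& pa = pyr_a.back();
    if ((int)std::min(pa.n_rows, pa.n_cols) / 2 < 8) break;
    pyr_a.push_back(pyr_down(pyr_a.back()));
    pyr_b.push_back(pyr_down(pyr_b.back()));
  }
  int top = (int)pyr_a.size() - 1;
  mat dx(pyr_a[top].n_rows, pyr_a[top].n_cols, arma::fill::zeros);
  mat dy = dx;
  for (int l = top; l >= 0; --l) {
    int sw = std::max(5, (int)std::lround(smooth_win / std::pow(2.0, l)));
    if (sw % 2 == 0) ++sw;
    PolyExp p1 = poly_expansion(pyr_a[l], sigma);
    PolyExp p2 = poly_expansion(pyr_b[l], sigma);
    flow_iterate(p1, p2, dx, dy, iters, sw);
    if (l > 0) {
      dx = up_flow(dx, pyr_a[l - 1].n_rows, pyr_a[l - 1].n_cols);
      dy = up_flow(dy, pyr_a[l - 1].n_rows, pyr_a[l - 1].n_cols);
    }
  }
  return List::create(_["dx"] = dx, _["dy"] = dy,
                      _["levels"] = top + 1, _["iters"] = iters);
}
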