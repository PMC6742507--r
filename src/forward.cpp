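#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Oriented-Gaussian PSF slice operator kernels.
//
// Geometry conventions (all world units in mm, voxel indices 0-based):
//   HR grid:  world = G %*% index + o,  G = direction %*% diag(spacing)
//   slice:    world centre of pixel (i, j) = p0 + i * e1 + j * e2
// The PSF is a 3D Gaussian with covariance `cov` expressed in world
// coordinates (already rotated into the frame of the posed slice).  Weights
// are truncated at Mahalanobis distance `radius` and, when `normalize` is
// true, renormalized to sum to one per slice pixel so the operator
// reproduces constants.

struct PsfGeom {
  NumericMatrix G, Ginv, covinv;
  NumericVector o, p0, e1, e2, hw;
  IntegerVector gdim;
  double r2;
  PsfGeom(NumericMatrix G_, NumericMatrix Ginv_, NumericVector o_,
          IntegerVector gdim_, NumericVector p0_, NumericVector e1_,
          NumericVector e2_, NumericMatrix covinv_, double r2_,
          NumericVector hw_)
      : G(G_), Ginv(Ginv_), covinv(covinv_), o(o_), p0(p0_), e1(e1_), e2(e2_),
        hw(hw_), gdim(gdim_), r2(r2_) {}
};

// Iterate the truncation box of pixel (i, j); call f(linear_voxel, weight).
template <typename F>
inline void psf_visit(const PsfGeom& g, int i, int j, F f) {
  double c[3], v[3];
  for (int a = 0; a < 3; ++a) c[a] = g.p0[a] + i * g.e1[a] + j * g.e2[a];
  for (int a = 0; a < 3; ++a) {
    v[a] = 0.0;
    for (int b = 0; b < 3; ++b) v[a] += g.Ginv(a, b) * (c[b] - g.o[b]);
  }
  int lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = (int)std::ceil(v[a] - g.hw[a]);
    hi[a] = (int)std::floor(v[a] + g.hw[a]);
    if (lo[a] < 0) lo[a] = 0;
    if (hi[a] > g.gdim[a] - 1) hi[a] = g.gdim[a] - 1;
  }
  if (lo[0] > hi[0] || lo[1] > hi[1] || lo[2] > hi[2]) return;
  const int n1 = g.gdim[0], n12 = g.gdim[0] * g.gdim[1];
  for (int u3 = lo[2]; u3 <= hi[2]; ++u3) {
    for (int u2 = lo[1]; u2 <= hi[1]; ++u2) {
      // world offset of voxel (lo[0], u2, u3) relative to pixel centre
      double d0 = g.G(0,0)*lo[0] + g.G(0,1)*u2 + g.G(0,2)*u3 + g.o[0] - c[0];
      double d1 = g.G(1,0)*lo[0] + g.G(1,1)*u2 + g.G(1,2)*u3 + g.o[1] - c[1];
      double d2 = g.G(2,0)*lo[0] + g.G(2,1)*u2 + g.G(2,2)*u3 + g.o[2] - c[2];
      int base = lo[0] + n1 * u2 + n12 * u3;
      for (int u1 = lo[0]; u1 <= hi[0]; ++u1) {
        double q0 = g.covinv(0,0)*d0 + g.covinv(0,1)*d1 + g.covinv(0,2)*d2;
        double q1 = g.covinv(1,0)*d0 + g.covinv(1,1)*d1 + g.covinv(1,2)*d2;
        double q2 = g.covinv(2,0)*d0 + g.covinv(2,1)*d1 + g.covinv(2,2)*d2;
        double m = d0*q0 + d1*q1 + d2*q2;
        if (m <= g.r2) f(base, std::exp(-0.5 * m));
        d0 += g.G(0,0); d1 += g.G(1,0); d2 += g.G(2,0);
        ++base;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_forward_project(NumericVector x, IntegerVector gdim, NumericMatrix G,
                         NumericMatrix Ginv, NumericVector o,
                         NumericVector p0, NumericVector e1, NumericVector e2,
                         int n1, int n2, NumericMatrix covinv, double r2,
                         NumericVector hw, bool normalize) {
  PsfGeom g(G, Ginv, o, gdim, p0, e1, e2, covinv, r2, hw);
  NumericVector y(n1 * n2), wsum(n1 * n2);
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      double acc = 0.0, ws = 0.0;
      psf_visit(g, i, j, [&](int vox, double w) {
        acc += w * x[vox];
        ws += w;
      });
      int p = i + n1 * j;
      wsum[p] = ws;
      y[p] = (normalize && ws > 0.0) ? acc / ws : acc;
    }
  }
  return List::create(_["y"] = y, _["wsum"] = wsum);
}

// [[Rcpp::export]]
NumericVector cpp_adjoint_project(NumericVector y, IntegerVector gdim,
                                  NumericMatrix G, NumericMatrix Ginv,
                                  NumericVector o, NumericVector p0,
                                  NumericVector e1, NumericVector e2, int n1,
                                  int n2, NumericMatrix covinv, double r2,
                                  NumericVector hw, bool normalize) {
  PsfGeom g(G, Ginv, o, gdim, p0, e1, e2, covinv, r2, hw);
  NumericVector x((double)gdim[0] * gdim[1] * gdim[2]);
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      double yi = y[i + n1 * j];
      double ws = 0.0;
      if (normalize) {
        psf_visit(g, i, j, [&](int, double w) { ws += w; });
        if (ws <= 0.0) continue;
        yi /= ws;
      }
      psf_visit(g, i, j, [&](int vox, double w) { x[vox] += w * yi; });
    }
  }
  return x;
}

// [[Rcpp::export]]
List cpp_operator_triplets(IntegerVector gdim, NumericMatrix G,
                           NumericMatrix Ginv, NumericVector o,
                           NumericVector p0, NumericVector e1,
                           NumericVector e2, int n1, int n2,
                           NumericMatrix covinv, double r2, NumericVector hw,
                           bool normalize) {
  PsfGeom g(G, Ginv, o, gdim, p0, e1, e2, covinv, r2, hw);
  std::vector<int> ri, ci;
  std::vector<double> wv;
  NumericVector wsum(n1 * n2);
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      int p = i + n1 * j;
      size_t first = wv.size();
      double ws = 0.0;
      psf_visit(g, i, j, [&](int vox, double w) {
        ri.push_back(p);
        ci.push_back(vox);
        wv.push_back(w);
        ws += w;
      });
      wsum[p] = ws;
      if (normalize && ws > 0.0)
        for (size_t k = first; k < wv.size(); ++k) wv[k] /= ws;
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci),
                      _["w"] = wrap(wv), _["wsum"] = wsum);
}

// Forward projection restricted to a subset of pixels (0-based linear,
// column-major indices into the n1 x n2 slice); used by registration loops
// that only score masked pixels.
// [[Rcpp::export]]
List cpp_forward_project_subset(NumericVector x, IntegerVector gdim,
                                NumericMatrix G, NumericMatrix Ginv,
                                NumericVector o, NumericVector p0,
                                NumericVector e1, NumericVector e2, int n1,
                                IntegerVector pixsel, NumericMatrix covinv,
                                double r2, NumericVector hw) {
  PsfGeom g(G, Ginv, o, gdim, p0, e1, e2, covinv, r2, hw);
  int np = pixsel.size();
  NumericVector y(np), wsum(np);
  for (int k = 0; k < np; ++k) {
    int p = pixsel[k];
    int i = p % n1, j = p / n1;
    double acc = 0.0, ws = 0.0;
    psf_visit(g, i, j, [&](int vox, double w) {
      acc += w * x[vox];
      ws += w;
    });
    wsum[k] = ws;
    y[k] = ws > 0.0 ? acc / ws : 0.0;
  }
  return List::create(_["y"] = y, _["wsum"] = wsum);
}

// ---- 2D cubic B-spline free-form deformation ------------------------------

static inline void bspline_w(double u, double* b) {
  double u2 = u * u, u3 = u2 * u;
  b[0] = (1 - 3 * u + 3 * u2 - u3) / 6.0;
  b[1] = (3 * u3 - 6 * u2 + 4) / 6.0;
  b[2] = (-3 * u3 + 3 * u2 + 3 * u + 1) / 6.0;
  b[3] = u3 / 6.0;
}

// Dense displacement field from control-point displacements.  Control point
// (a, b) (0-based) sits at pixel position ((a - 1) * sp, (b - 1) * sp).
// [[Rcpp::export]]
List cpp_ffd_field(NumericMatrix cx, NumericMatrix cy, double sp, int n1,
                   int n2) {
  NumericMatrix ux(n1, n2), uy(n1, n2);
  int m1 = cx.nrow(), m2 = cx.ncol();
  for (int j = 0; j < n2; ++j) {
    double t2 = j / sp;
    int i2 = (int)std::floor(t2);
    double b2[4];
    bspline_w(t2 - i2, b2);
    for (int i = 0; i < n1; ++i) {
      double t1 = i / sp;
      int i1 = (int)std::floor(t1);
      double b1[4];
      bspline_w(t1 - i1, b1);
      double ax = 0.0, ay = 0.0;
      for (int l2 = 0; l2 < 4; ++l2) {
        int cb = i2 + l2;
        if (cb < 0 || cb >= m2) continue;
        for (int l1 = 0; l1 < 4; ++l1) {
          int ca = i1 + l1;
          if (ca < 0 || ca >= m1) continue;
          double w = b1[l1] * b2[l2];
          ax += w * cx(ca, cb);
          ay += w * cy(ca, cb);
        }
      }
      ux(i, j) = ax;
      uy(i, j) = ay;
    }
  }
  return List::create(_["ux"] = ux, _["uy"] = uy);
}

// Backward-warp img by the displacement field (bilinear, clamped borders).
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(NumericMatrix img, NumericMatrix ux,
                                NumericMatrix uy) {
  int n1 = img.nrow(), n2 = img.ncol();
  NumericMatrix out(n1, n2);
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      double x = i + ux(i, j), y = j + uy(i, j);
      if (x < 0) x = 0; if (x > n1 - 1) x = n1 - 1;
      if (y < 0) y = 0; if (y > n2 - 1) y = n2 - 1;
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
      if (x0 > n1 - 2) x0 = n1 - 2;
      if (y0 > n2 - 2) y0 = n2 - 2;
      if (n1 == 1) x0 = 0;
      if (n2 == 1) y0 = 0;
      double fx = x - x0, fy = y - y0;
      int x1 = (n1 == 1) ? x0 : x0 + 1, y1 = (n2 == 1) ? y0 : y0 + 1;
      out(i, j) = (1 - fx) * (1 - fy) * img(x0, y0) +
                  fx * (1 - fy) * img(x1, y0) +
                  (1 - fx) * fy * img(x0, y1) + fx * fy * img(x1, y1);
    }
  }
  return out;
}
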