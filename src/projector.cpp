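#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Ideal-collimator parallel-beam projector with optional attenuation
// weighting.  Geometry: image n x n, pixel pitch h, physical origin at the
// image center, x rightward along columns, y upward along decreasing rows.
// For angle t the detector lies in direction d = (cos t, sin t); rays are
// sampled at step*h spacing from the detector side inward, and each sample
// gathers (forward) or scatters (adjoint) bilinear pixel weights multiplied
// by exp(-integral of mu from the sample to the detector).  Forward and
// adjoint use the identical weights, so the pair is an exact transpose.

struct Grid {
  int n;
  double h;
  double c0; // (n+1)/2, 1-based center index
};

// Bilinear interpolation helpers: physical (x, y) -> fractional (row, col).
static inline bool toRC(const Grid &g, double x, double y, double &r, double &c) {
  c = x / g.h + g.c0;
  r = g.c0 - y / g.h;
  return (r >= 1.0 && r <= g.n && c >= 1.0 && c <= g.n);
}

static inline double gather(const double *m, const Grid &g, double r, double c) {
  int r0 = (int)std::floor(r); if (r0 > g.n - 1) r0 = g.n - 1; if (r0 < 1) r0 = 1;
  int c0 = (int)std::floor(c); if (c0 > g.n - 1) c0 = g.n - 1; if (c0 < 1) c0 = 1;
  double fr = r - r0, fc = c - c0;
  const double *col0 = m + (size_t)(c0 - 1) * g.n;
  const double *col1 = col0 + g.n;
  double v00 = col0[r0 - 1], v10 = col0[r0], v01 = col1[r0 - 1], v11 = col1[r0];
  return (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
         (1 - fr) * fc * v01 + fr * fc * v11;
}

static inline void corners(const Grid &g, double r, double c,
                           int idx[4], double w[4]) {
  int r0 = (int)std::floor(r); if (r0 > g.n - 1) r0 = g.n - 1; if (r0 < 1) r0 = 1;
  int c0 = (int)std::floor(c); if (c0 > g.n - 1) c0 = g.n - 1; if (c0 < 1) c0 = 1;
  double fr = r - r0, fc = c - c0;
  idx[0] = (c0 - 1) * g.n + (r0 - 1); w[0] = (1 - fr) * (1 - fc);
  idx[1] = (c0 - 1) * g.n + r0;       w[1] = fr * (1 - fc);
  idx[2] = c0 * g.n + (r0 - 1);       w[2] = (1 - fr) * fc;
  idx[3] = c0 * g.n + r0;             w[3] = fr * fc;
}

struct RayGeom {
  double T;      // half-length of the sampled ray segment
  int M;         // number of samples
  double dl;     // sample spacing (mm)
};

static RayGeom rayGeom(const Grid &g, double stepFrac) {
  RayGeom rg;
  rg.dl = stepFrac * g.h;
  rg.T = 0.5 * std::sqrt(2.0) * g.n * g.h + g.h;
  rg.M = (int)std::floor(2.0 * rg.T / rg.dl) + 1;
  return rg;
}

// Restrict the sample index range [m0, m1) to the part of the ray
// intersecting the image square (slab clipping).  Sample positions on the
// fixed tau lattice are unchanged; out-of-grid samples contribute nothing,
// so clipping only skips work.
static void clipRay(const Grid &g, const RayGeom &rg, double ox, double oy,
                    double ct, double st, int &m0, int &m1) {
  double W = 0.5 * g.n * g.h + g.h; // half-width with a safety margin
  double tlo = -rg.T, thi = rg.T;
  // ox + tau*ct in [-W, W]
  if (std::fabs(ct) > 1e-12) {
    double a = (-W - ox) / ct, b = (W - ox) / ct;
    if (a > b) std::swap(a, b);
    if (a > tlo) tlo = a;
    if (b < thi) thi = b;
  } else if (ox < -W || ox > W) { m0 = 0; m1 = 0; return; }
  if (std::fabs(st) > 1e-12) {
    double a = (-W - oy) / st, b = (W - oy) / st;
    if (a > b) std::swap(a, b);
    if (a > tlo) tlo = a;
    if (b < thi) thi = b;
  } else if (oy < -W || oy > W) { m0 = 0; m1 = 0; return; }
  if (tlo > thi) { m0 = 0; m1 = 0; return; }
  // tau_m = T - m*dl decreases with m
  m0 = (int)std::floor((rg.T - thi) / rg.dl) - 1;
  m1 = (int)std::ceil((rg.T - tlo) / rg.dl) + 2;
  if (m0 < 0) m0 = 0;
  if (m1 > rg.M) m1 = rg.M;
}

// [[Rcpp::export]]
NumericMatrix forward_project_cpp(NumericMatrix img, Nullable<NumericMatrix> mu_,
                                  double h, NumericVector anglesRad,
                                  int nbins, double binw, double stepFrac) {
  Grid g; g.n = img.nrow(); g.h = h; g.c0 = (g.n + 1) / 2.0;
  const double *f = img.begin();
  const double *mu = nullptr;
  if (mu_.isNotNull()) mu = NumericMatrix(mu_).begin();
  int na = anglesRad.size();
  RayGeom rg = rayGeom(g, stepFrac);
  NumericMatrix out(na, nbins);
  for (int a = 0; a < na; ++a) {
    double ct = std::cos(anglesRad[a]), st = std::sin(anglesRad[a]);
    for (int k = 0; k < nbins; ++k) {
      double s = (k - (nbins - 1) / 2.0) * binw;
      double ox = s * (-st), oy = s * ct; // offset along detector bin axis
      double cum = 0.0, acc = 0.0;
      int m0 = 0, m1 = rg.M;
      clipRay(g, rg, ox, oy, ct, st, m0, m1);
      for (int m = m0; m < m1; ++m) {
        double tau = rg.T - m * rg.dl; // march from the detector side inward
        double x = ox + tau * ct, y = oy + tau * st;
        double r, c;
        if (!toRC(g, x, y, r, c)) continue;
        double attn = 1.0;
        if (mu) {
          double muv = gather(mu, g, r, c);
          cum += 0.5 * muv * rg.dl;
          attn = std::exp(-cum);
          cum += 0.5 * muv * rg.dl;
        }
        acc += gather(f, g, r, c) * attn;
      }
      out(a, k) = acc * rg.dl;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix back_project_cpp(NumericMatrix sino, Nullable<NumericMatrix> mu_,
                               int n, double h, NumericVector anglesRad,
                               double binw, double stepFrac) {
  Grid g; g.n = n; g.h = h; g.c0 = (n + 1) / 2.0;
  const double *mu = nullptr;
  if (mu_.isNotNull()) mu = NumericMatrix(mu_).begin();
  int na = sino.nrow(), nbins = sino.ncol();
  RayGeom rg = rayGeom(g, stepFrac);
  NumericMatrix out(n, n);
  double *o = out.begin();
  int idx[4]; double w[4];
  for (int a = 0; a < na; ++a) {
    double ct = std::cos(anglesRad[a]), st = std::sin(anglesRad[a]);
    for (int k = 0; k < nbins; ++k) {
      double gval = sino(a, k);
      double s = (k - (nbins - 1) / 2.0) * binw;
      double ox = s * (-st), oy = s * ct;
      double cum = 0.0;
      int m0 = 0, m1 = rg.M;
      clipRay(g, rg, ox, oy, ct, st, m0, m1);
      for (int m = m0; m < m1; ++m) {
        double tau = rg.T - m * rg.dl;
        double x = ox + tau * ct, y = oy + tau * st;
        double r, c;
        if (!toRC(g, x, y, r, c)) continue;
        double attn = 1.0;
        if (mu) {
          double muv = gather(mu, g, r, c);
          cum += 0.5 * muv * rg.dl;
          attn = std::exp(-cum);
          cum += 0.5 * muv * rg.dl;
        }
        if (gval == 0.0) continue; // attenuation state already advanced
        corners(g, r, c, idx, w);
        double wv = gval * attn * rg.dl;
        o[idx[0]] += wv * w[0];
        o[idx[1]] += wv * w[1];
        o[idx[2]] += wv * w[2];
        o[idx[3]] += wv * w[3];
      }
    }
  }
  return out;
}

// One full ART sweep (Kaczmarz row actions) over the rays in rayOrder
// (0-based ray index = angle * nbins + bin).  For each ray the exact row of
// the discretized operator is accumulated pixel-wise, so the unrelaxed
// update annihilates that ray's residual exactly.  Returns the number of
// rays skipped because their row had zero norm.
// [[Rcpp::export]]
int art_sweep_cpp(NumericMatrix f, NumericMatrix sino,
                  Nullable<NumericMatrix> mu_, double h,
                  NumericVector anglesRad, double binw, double stepFrac,
                  double relax, IntegerVector rayOrder) {
  Grid g; g.n = f.nrow(); g.h = h; g.c0 = (g.n + 1) / 2.0;
  const double *mu = nullptr;
  if (mu_.isNotNull()) mu = NumericMatrix(mu_).begin();
  int nbins = sino.ncol();
  RayGeom rg = rayGeom(g, stepFrac);
  double *fp = f.begin();
  std::vector<double> acc((size_t)g.n * g.n, 0.0);
  std::vector<int> touched;
  touched.reserve(8 * rg.M);
  int skipped = 0;
  int idx[4]; double w[4];
  for (int q = 0; q < rayOrder.size(); ++q) {
    int ray = rayOrder[q];
    int a = ray / nbins, k = ray % nbins;
    double ct = std::cos(anglesRad[a]), st = std::sin(anglesRad[a]);
    double s = (k - (nbins - 1) / 2.0) * binw;
    double ox = s * (-st), oy = s * ct;
    double cum = 0.0;
    touched.clear();
    int m0 = 0, m1 = rg.M;
    clipRay(g, rg, ox, oy, ct, st, m0, m1);
    for (int m = m0; m < m1; ++m) {
      double tau = rg.T - m * rg.dl;
      double x = ox + tau * ct, y = oy + tau * st;
      double r, c;
      if (!toRC(g, x, y, r, c)) continue;
      double attn = 1.0;
      if (mu) {
        double muv = gather(mu, g, r, c);
        cum += 0.5 * muv * rg.dl;
        attn = std::exp(-cum);
        cum += 0.5 * muv * rg.dl;
      }
      corners(g, r, c, idx, w);
      for (int j = 0; j < 4; ++j) {
        double wv = attn * rg.dl * w[j];
        if (wv == 0.0) continue;
        if (acc[idx[j]] == 0.0) touched.push_back(idx[j]);
        acc[idx[j]] += wv;
      }
    }
    double Ri = 0.0, denom = 0.0;
    for (size_t j = 0; j < touched.size(); ++j) {
      double wj = acc[touched[j]];
      Ri += wj * fp[touched[j]];
      denom += wj * wj;
    }
    if (denom > 0.0) {
      double corr = relax * (sino(a, k) - Ri) / denom;
      for (size_t j = 0; j < touched.size(); ++j)
        fp[touched[j]] += corr * acc[touched[j]];
    } else {
      ++skipped;
    }
    for (size_t j = 0; j < touched.size(); ++j) acc[touched[j]] = 0.0;
  }
  return skipped;
}

// Angle-averaged attenuation survival probability p(x) in [0, 1]: the mean
// over acquisition angles of exp(-integral of mu from the pixel to the
// detector).  Used to build the "Detector" image.
// [[Rcpp::export]]
NumericMatrix detection_probability_cpp(NumericMatrix mu, double h,
                                        NumericVector anglesRad,
                                        double stepFrac) {
  Grid g; g.n = mu.nrow(); g.h = h; g.c0 = (g.n + 1) / 2.0;
  const double *mp = mu.begin();
  int na = anglesRad.size();
  RayGeom rg = rayGeom(g, stepFrac);
  NumericMatrix out(g.n, g.n);
  for (int a = 0; a < na; ++a) {
    double ct = std::cos(anglesRad[a]), st = std::sin(anglesRad[a]);
    for (int col = 0; col < g.n; ++col) {
      double x0 = (col + 1 - g.c0) * g.h;
      for (int row = 0; row < g.n; ++row) {
        double y0 = (g.c0 - (row + 1)) * g.h;
        // integrate mu from the pixel toward the detector (direction +d)
        double cum = 0.0;
        for (int m = 0; ; ++m) {
          double t = (m + 0.5) * rg.dl;
          if (t > 2.0 * rg.T) break;
          double x = x0 + t * ct, y = y0 + t * st;
          double r, c;
          if (!toRC(g, x, y, r, c)) break; // left the grid: no more material
          cum += gather(mp, g, r, c) * rg.dl;
        }
        out(row, col) += std::exp(-cum);
      }
    }
  }
  for (int i = 0; i < g.n * g.n; ++i) out.begin()[i] /= na;
  return out;
}
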