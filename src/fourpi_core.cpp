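#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Tricubic tensor-spline evaluation and a multi-start Levenberg-Marquardt
// fitter for four-channel emitter images. Coefficients are stored as a
// numeric array with dim = c(64, ncx, ncy, ncz, nch); within a cell the
// coefficient index is m + 4*n + 16*o for the term
//   S * ((x-t_i)/dt)^m * ((y-u_j)/du)^n * ((z-v_k)/dv)^o.

struct Grid {
  const double *S;
  int ncx, ncy, ncz, nch;
  double ox, oy, oz;     // coordinate of first knot center
  double dx, dy, dz;     // knot spacing
};

static inline bool locate(double x, double o, double d, int ncell,
                          int &i, double &t) {
  double u = (x - o) / d;
  if (u < -1e-9 || u > ncell + 1e-9) return false;
  i = (int)std::floor(u);
  if (i < 0) i = 0;
  if (i > ncell - 1) i = ncell - 1;
  t = u - i;
  return true;
}

// value and local-coordinate derivatives of f_S at one point, one channel
static bool eval_point(const Grid &g, double x, double y, double z, int c,
                       double &val, double *grad /* or NULL */) {
  int i, j, k;
  double tx, ty, tz;
  if (!locate(x, g.ox, g.dx, g.ncx, i, tx)) return false;
  if (!locate(y, g.oy, g.dy, g.ncy, j, ty)) return false;
  if (!locate(z, g.oz, g.dz, g.ncz, k, tz)) return false;

  double xm[4] = {1.0, tx, tx * tx, tx * tx * tx};
  double ym[4] = {1.0, ty, ty * ty, ty * ty * ty};
  double zm[4] = {1.0, tz, tz * tz, tz * tz * tz};
  double dxm[4] = {0.0, 1.0, 2.0 * tx, 3.0 * tx * tx};
  double dym[4] = {0.0, 1.0, 2.0 * ty, 3.0 * ty * ty};
  double dzm[4] = {0.0, 1.0, 2.0 * tz, 3.0 * tz * tz};

  const double *cell = g.S +
    (size_t)64 * (i + (size_t)g.ncx * (j + (size_t)g.ncy *
                 (k + (size_t)g.ncz * c)));
  double v = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
  int idx = 0;
  for (int o = 0; o < 4; ++o) {
    for (int n = 0; n < 4; ++n) {
      double yz = ym[n] * zm[o];
      double dy_z = dym[n] * zm[o];
      double y_dz = ym[n] * dzm[o];
      for (int m = 0; m < 4; ++m, ++idx) {
        double s = cell[idx];
        v += s * xm[m] * yz;
        if (grad) {
          gx += s * dxm[m] * yz;
          gy += s * xm[m] * dy_z;
          gz += s * xm[m] * y_dz;
        }
      }
    }
  }
  val = v;
  if (grad) {
    grad[0] = gx / g.dx;
    grad[1] = gy / g.dy;
    grad[2] = gz / g.dz;
  }
  return true;
}

static Grid make_grid(const NumericVector &S, const IntegerVector &dims,
                      const NumericVector &origin,
                      const NumericVector &spacing) {
  Grid g;
  g.S = REAL(S);
  g.ncx = dims[1]; g.ncy = dims[2]; g.ncz = dims[3]; g.nch = dims[4];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.dx = spacing[0]; g.dy = spacing[1]; g.dz = spacing[2];
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_spline_eval(NumericVector S, IntegerVector dims,
                              NumericVector origin, NumericVector spacing,
                              NumericVector x, NumericVector y,
                              NumericVector z, IntegerVector channel) {
  Grid g = make_grid(S, dims, origin, spacing);
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t q = 0; q < n; ++q) {
    double v;
    if (!eval_point(g, x[q], y[q], z[q], channel[q] - 1, v, NULL))
      stop("evaluation point outside spline support");
    out[q] = v;
  }
  return out;
}

// model image mu = b + A * f_S(xp - x0, yp - y0, z, c) on an ROI of
// (2*half+1)^2 pixels per channel; returns value vector and, optionally,
// the Jacobian wrt (x0, y0, z, A, b).
// [[Rcpp::export]]
List cpp_eval_roi(NumericVector S, IntegerVector dims, NumericVector origin,
                  NumericVector spacing, NumericVector theta, int half,
                  double pixel, bool jacobian) {
  Grid g = make_grid(S, dims, origin, spacing);
  double x0 = theta[0], y0 = theta[1], z0 = theta[2];
  double A = theta[3], b = theta[4];
  int w = 2 * half + 1, npx = w * w, ntot = npx * g.nch;
  NumericVector mu(ntot);
  NumericMatrix J;
  if (jacobian) J = NumericMatrix(ntot, 5);
  double gr[3];
  int q = 0;
  for (int c = 0; c < g.nch; ++c)
    for (int py = 0; py < w; ++py)
      for (int px = 0; px < w; ++px, ++q) {
        double xp = (px - half) * pixel - x0;
        double yp = (py - half) * pixel - y0;
        double f;
        if (!eval_point(g, xp, yp, z0, c, f, jacobian ? gr : NULL))
          stop("ROI evaluation outside spline support");
        mu[q] = b + A * f;
        if (jacobian) {
          J(q, 0) = -A * gr[0];
          J(q, 1) = -A * gr[1];
          J(q, 2) = A * gr[2];
          J(q, 3) = f;
          J(q, 4) = 1.0;
        }
      }
  if (jacobian) return List::create(_["mu"] = mu, _["J"] = J);
  return List::create(_["mu"] = mu);
}

static bool solve5(double M[5][5], double v[5], double out[5]) {
  int piv[5] = {0, 1, 2, 3, 4};
  for (int c = 0; c < 5; ++c) {
    int best = c;
    for (int r = c + 1; r < 5; ++r)
      if (std::fabs(M[r][c]) > std::fabs(M[best][c])) best = r;
    if (std::fabs(M[best][c]) < 1e-300) return false;
    if (best != c) {
      for (int k = 0; k < 5; ++k) std::swap(M[c][k], M[best][k]);
      std::swap(v[c], v[best]);
      std::swap(piv[c], piv[best]);
    }
    for (int r = c + 1; r < 5; ++r) {
      double f = M[r][c] / M[c][c];
      for (int k = c; k < 5; ++k) M[r][k] -= f * M[c][k];
      v[r] -= f * v[c];
    }
  }
  for (int r = 4; r >= 0; --r) {
    double s = v[r];
    for (int k = r + 1; k < 5; ++k) s -= M[r][k] * out[k];
    out[r] = s / M[r][r];
  }
  (void)piv;
  return true;
}

static inline double reflect(double p, double lo, double hi) {
  for (int it = 0; it < 8 && (p < lo || p > hi); ++it) {
    if (p < lo) p = lo + (lo - p);
    if (p > hi) p = hi - (p - hi);
  }
  if (p < lo) p = lo;
  if (p > hi) p = hi;
  return p;
}

struct Bounds { double xlo, xhi, ylo, yhi, zlo, zhi; };

// objective per pixel, by weighting mode:
//   0 = unweighted least squares        (d - mu)^2
//   1 = data-weighted least squares     (d - mu)^2 / max(d, 1)
//   2 = Poisson MLE (deviance)          2 [mu - d + d log(d / mu)]
// Mode 2 is fit by Fisher scoring (model-based weights 1/mu), the
// Laurence-Chromy adaptation of Levenberg-Marquardt to Poisson data.
static inline double pix_objective(double d, double mu, int weighting) {
  double r = d - mu;
  switch (weighting) {
  case 0: return r * r;
  case 1: return r * r / std::max(d, 1.0);
  default: {
    double m = std::max(mu, 1e-9);
    if (d <= 0) return 2.0 * m;
    return 2.0 * (m - d + d * std::log(d / m));
  }
  }
}

static inline double pix_weight(double d, double mu, int weighting) {
  switch (weighting) {
  case 0: return 1.0;
  case 1: return 1.0 / std::max(d, 1.0);
  default: return 1.0 / std::max(mu, 1e-3);
  }
}

static double roi_chi2(const Grid &g, const double *y, double *theta, int half,
                       double pixel, const Bounds &bd, int weighting,
                       bool &ok) {
  int w = 2 * half + 1;
  double chi2 = 0.0;
  ok = true;
  int q = 0;
  for (int c = 0; c < g.nch; ++c)
    for (int py = 0; py < w; ++py)
      for (int px = 0; px < w; ++px, ++q) {
        double xp = (px - half) * pixel - theta[0];
        double yp = (py - half) * pixel - theta[1];
        double f;
        if (!eval_point(g, xp, yp, theta[2], c, f, NULL)) { ok = false; return 0.0; }
        double mu = theta[4] + theta[3] * f;
        chi2 += pix_objective(y[q], mu, weighting);
      }
  return chi2;
}

// Levenberg-Marquardt from a single start. Returns chi2, fills theta.
static double lm_fit(const Grid &g, const double *y, double *theta, int half,
                     double pixel, const Bounds &bd, int max_iter,
                     double rel_tol, int weighting, bool &converged,
                     int &niter) {
  int w = 2 * half + 1, npx = w * w, ntot = npx * g.nch;
  std::vector<double> J(ntot * 5), res(ntot), wt(ntot);
  double lambda = 1e-3;
  converged = false;

  bool ok;
  double chi2 = roi_chi2(g, y, theta, half, pixel, bd, weighting, ok);
  if (!ok) return R_PosInf;

  double gr[3];
  for (niter = 0; niter < max_iter; ++niter) {
    // residuals, weights and Jacobian at current theta
    int q = 0;
    for (int c = 0; c < g.nch; ++c)
      for (int py = 0; py < w; ++py)
        for (int px = 0; px < w; ++px, ++q) {
          double xp = (px - half) * pixel - theta[0];
          double yp = (py - half) * pixel - theta[1];
          double f;
          eval_point(g, xp, yp, theta[2], c, f, gr);
          double mu = theta[4] + theta[3] * f;
          res[q] = y[q] - mu;
          wt[q] = pix_weight(y[q], mu, weighting);
          J[q] = -theta[3] * gr[0];
          J[q + ntot] = -theta[3] * gr[1];
          J[q + 2 * (size_t)ntot] = theta[3] * gr[2];
          J[q + 3 * (size_t)ntot] = f;
          J[q + 4 * (size_t)ntot] = 1.0;
        }
    double JTJ[5][5], JTr[5];
    for (int a = 0; a < 5; ++a) {
      JTr[a] = 0.0;
      for (int bcol = a; bcol < 5; ++bcol) JTJ[a][bcol] = 0.0;
    }
    for (int q2 = 0; q2 < ntot; ++q2) {
      for (int a = 0; a < 5; ++a) {
        double ja = J[q2 + a * (size_t)ntot]; // d mu / d theta
        JTr[a] += ja * res[q2] * wt[q2];
        for (int bcol = a; bcol < 5; ++bcol)
          JTJ[a][bcol] += ja * J[q2 + bcol * (size_t)ntot] * wt[q2];
      }
    }
    for (int a = 0; a < 5; ++a)
      for (int bcol = 0; bcol < a; ++bcol) JTJ[a][bcol] = JTJ[bcol][a];

    bool accepted = false;
    for (int tries = 0; tries < 30; ++tries) {
      double M[5][5], v[5], delta[5];
      for (int a = 0; a < 5; ++a) {
        for (int bcol = 0; bcol < 5; ++bcol) M[a][bcol] = JTJ[a][bcol];
        M[a][a] += lambda * std::max(JTJ[a][a], 1e-12);
        v[a] = JTr[a];
      }
      if (!solve5(M, v, delta)) { lambda *= 10.0; continue; }
      double trial[5];
      for (int a = 0; a < 5; ++a) trial[a] = theta[a] + delta[a];
      trial[0] = reflect(trial[0], bd.xlo, bd.xhi);
      trial[1] = reflect(trial[1], bd.ylo, bd.yhi);
      trial[2] = reflect(trial[2], bd.zlo, bd.zhi);
      bool ok2;
      double chi2_t = roi_chi2(g, y, trial, half, pixel, bd, weighting, ok2);
      if (ok2 && chi2_t <= chi2) {
        double dchi = chi2 - chi2_t;
        for (int a = 0; a < 5; ++a) theta[a] = trial[a];
        chi2 = chi2_t;
        lambda = std::max(lambda * 0.3, 1e-12);
        accepted = true;
        if (dchi < rel_tol * std::max(chi2, 1e-30) || chi2 < 1e-20) {
          converged = true;
          return chi2;
        }
        break;
      }
      lambda *= 10.0;
    }
    if (!accepted) { converged = true; return chi2; } // stuck: local minimum
  }
  converged = false;
  return chi2;
}

// Batch multi-start fit of many ROIs.
// data: ntot x nimg matrix (pixel-major: x fastest, then y, then channel)
// zstarts: nst x (1 or nimg) matrix; x0s, y0s, b0s: per image
// [[Rcpp::export]]
NumericMatrix cpp_fit_rois(NumericVector S, IntegerVector dims,
                           NumericVector origin, NumericVector spacing,
                           NumericMatrix data, NumericVector x0s,
                           NumericVector y0s, NumericVector b0s,
                           NumericMatrix zstarts, int half, double pixel,
                           NumericVector bounds, int max_iter,
                           double rel_tol, int weighting) {
  Grid g = make_grid(S, dims, origin, spacing);
  Bounds bd;
  bd.xlo = bounds[0]; bd.xhi = bounds[1];
  bd.ylo = bounds[2]; bd.yhi = bounds[3];
  bd.zlo = bounds[4]; bd.zhi = bounds[5];
  int nimg = data.ncol();
  int ntot = data.nrow();
  int w = 2 * half + 1, npx = w * w;
  if (ntot != npx * g.nch) stop("data row count does not match ROI geometry");
  int nst = zstarts.nrow();
  bool shared_starts = (zstarts.ncol() == 1);
  NumericMatrix out(nimg, 9); // x y z A b chi2 converged nconv niter
  colnames(out) = CharacterVector::create("x", "y", "z", "A", "b", "chi2",
                                          "converged", "n_converged", "iters");
  for (int im = 0; im < nimg; ++im) {
    const double *y = &data(0, im);
    double tot = 0.0;
    for (int q = 0; q < ntot; ++q) tot += y[q];
    double best[5], best_chi2 = R_PosInf;
    int nconv = 0, best_iter = 0;
    bool any = false;
    for (int s = 0; s < nst; ++s) {
      double z0 = shared_starts ? zstarts(s, 0) : zstarts(s, im);
      if (ISNA(z0)) continue;
      z0 = reflect(z0, bd.zlo, bd.zhi);
      // amplitude start from photon budget at this z
      double fs = 0.0, fv;
      bool okf = true;
      for (int c = 0; c < g.nch && okf; ++c)
        for (int py = 0; py < w && okf; ++py)
          for (int px = 0; px < w; ++px) {
            if (!eval_point(g, (px - half) * pixel - x0s[im],
                            (py - half) * pixel - y0s[im], z0, c, fv, NULL)) {
              okf = false; break;
            }
            fs += fv;
          }
      if (!okf) continue;
      double A0 = (tot - ntot * b0s[im]) / std::max(fs, 1e-9);
      if (!(A0 > 0)) A0 = std::max(tot, 1.0) / std::max(fs, 1e-9);
      double theta[5] = {x0s[im], y0s[im], z0, A0, b0s[im]};
      bool conv;
      int niter;
      double chi2 = lm_fit(g, y, theta, half, pixel, bd, max_iter, rel_tol,
                           weighting, conv, niter);
      if (conv) ++nconv;
      if (conv && chi2 < best_chi2) {
        best_chi2 = chi2;
        for (int a = 0; a < 5; ++a) best[a] = theta[a];
        best_iter = niter;
        any = true;
      }
    }
    if (!any) {
      for (int a = 0; a < 5; ++a) out(im, a) = NA_REAL;
      out(im, 5) = NA_REAL;
      out(im, 6) = 0;
      out(im, 7) = 0;
      out(im, 8) = 0;
    } else {
      for (int a = 0; a < 5; ++a) out(im, a) = best[a];
      out(im, 5) = best_chi2;
      out(im, 6) = 1;
      out(im, 7) = nconv;
      out(im, 8) = best_iter;
    }
  }
  return out;
}
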