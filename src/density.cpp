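#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Spread atoms onto a voxel grid as truncated isotropic Gaussians.
// Grid convention: voxel (i,j,k) (0-based here) is centred at
// origin + (i,j,k) * voxel.  Contribution of an atom at x with weight w:
// w * exp(-|r - x|^2 / (2 sigma^2)), truncated at |r - x| > cutoff.
// [[Rcpp::export]]
NumericVector cpp_spread_atoms(NumericMatrix coords, NumericVector weights,
                               IntegerVector dim, NumericVector origin,
                               NumericVector voxel, double sigma,
                               double cutoff) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector grid(static_cast<R_xlen_t>(nx) * ny * nz);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double cut2 = cutoff * cutoff;
  const int natom = coords.nrow();

  for (int a = 0; a < natom; ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    const double w = weights[a];
    // voxel index window covering the truncation sphere
    int i0 = (int)std::ceil((ax - cutoff - origin[0]) / voxel[0]);
    int i1 = (int)std::floor((ax + cutoff - origin[0]) / voxel[0]);
    int j0 = (int)std::ceil((ay - cutoff - origin[1]) / voxel[1]);
    int j1 = (int)std::floor((ay + cutoff - origin[1]) / voxel[1]);
    int k0 = (int)std::ceil((az - cutoff - origin[2]) / voxel[2]);
    int k1 = (int)std::floor((az + cutoff - origin[2]) / voxel[2]);
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    if (i1 > nx - 1) i1 = nx - 1;
    if (j1 > ny - 1) j1 = ny - 1;
    if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * voxel[2] - az;
      const double dz2 = dz * dz;
      if (dz2 > cut2) continue;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * voxel[1] - ay;
        const double dyz2 = dy * dy + dz2;
        if (dyz2 > cut2) continue;
        const R_xlen_t base =
            (static_cast<R_xlen_t>(k) * ny + j) * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * voxel[0] - ax;
          const double d2 = dx * dx + dyz2;
          if (d2 > cut2) continue;
          grid[base + i] += w * std::exp(-d2 * inv2s2);
        }
      }
    }
  }
  grid.attr("dim") = dim;
  return grid;
}

// Spread atoms and return the Pearson correlation (or plain normalised
// inner product) between the simulated grid and a target grid of the
// same shape, without materialising the simulated grid in R.  Used by
// the rigid-body fit objective, which evaluates this thousands of times.
// [[Rcpp::export]]
double cpp_spread_cc(NumericMatrix coords, NumericVector weights,
                     NumericVector target, IntegerVector dim,
                     NumericVector origin, NumericVector voxel,
                     double sigma, double cutoff, bool mean_subtract) {
  NumericVector sim = cpp_spread_atoms(coords, weights, dim, origin,
                                       voxel, sigma, cutoff);
  const R_xlen_t n = sim.size();
  double ss = 0, s = 0, st = 0, t = 0, tt = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double a = sim[i], b = target[i];
    s += a;
    ss += a * a;
    st += a * b;
    t += b;
    tt += b * b;
  }
  if (mean_subtract) {
    const double cov = st - s * t / n;
    const double va = ss - s * s / n;
    const double vb = tt - t * t / n;
    if (va <= 0 || vb <= 0) return 0.0;
    return cov / std::sqrt(va * vb);
  }
  if (ss <= 0 || tt <= 0) return 0.0;
  return st / std::sqrt(ss * tt);
}

// Gradient of the Pearson correlation between the simulated map and a
// target map with respect to every atom position.  The simulated map is
// the Gaussian spread of the atoms; at a perfect match the gradient
// vanishes, making the generating structure a stationary point of the
// bias.  Returns the force matrix with the correlation in attribute "cc".
// [[Rcpp::export]]
NumericMatrix cpp_cc_gradient(NumericMatrix coords, NumericVector weights,
                              NumericVector target, IntegerVector dim,
                              NumericVector origin, NumericVector voxel,
                              double sigma, double cutoff) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector sim = cpp_spread_atoms(coords, weights, dim, origin,
                                       voxel, sigma, cutoff);
  const R_xlen_t n = sim.size();
  double s = 0, ss = 0, st = 0, t = 0, tt = 0;
  for (R_xlen_t v = 0; v < n; ++v) {
    s += sim[v];
    ss += sim[v] * sim[v];
    st += sim[v] * target[v];
    t += target[v];
    tt += target[v] * target[v];
  }
  const double sbar = s / n, tbar = t / n;
  const double A = st - n * sbar * tbar;
  const double Bs = ss - n * sbar * sbar;
  const double Bt = tt - n * tbar * tbar;
  const int natom = coords.nrow();
  NumericMatrix force(natom, 3);
  if (Bs <= 0 || Bt <= 0) {
    force.attr("cc") = 0.0;
    return force;
  }
  const double cc = A / std::sqrt(Bs * Bt);
  const double inv_norm = 1.0 / std::sqrt(Bs * Bt);
  const double ratio = A / Bs;
  // dCC/ds_v = inv_norm * ((t_v - tbar) - ratio * (s_v - sbar))
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double invs2 = 1.0 / (sigma * sigma);
  const double cut2 = cutoff * cutoff;
  for (int a = 0; a < natom; ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    const double w = weights[a];
    int i0 = (int)std::ceil((ax - cutoff - origin[0]) / voxel[0]);
    int i1 = (int)std::floor((ax + cutoff - origin[0]) / voxel[0]);
    int j0 = (int)std::ceil((ay - cutoff - origin[1]) / voxel[1]);
    int j1 = (int)std::floor((ay + cutoff - origin[1]) / voxel[1]);
    int k0 = (int)std::ceil((az - cutoff - origin[2]) / voxel[2]);
    int k1 = (int)std::floor((az + cutoff - origin[2]) / voxel[2]);
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    if (i1 > nx - 1) i1 = nx - 1;
    if (j1 > ny - 1) j1 = ny - 1;
    if (k1 > nz - 1) k1 = nz - 1;
    double fx = 0, fy = 0, fz = 0;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * voxel[2] - az;
      const double dz2 = dz * dz;
      if (dz2 > cut2) continue;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * voxel[1] - ay;
        const double dyz2 = dy * dy + dz2;
        if (dyz2 > cut2) continue;
        const R_xlen_t base = (static_cast<R_xlen_t>(k) * ny + j) * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * voxel[0] - ax;
          const double d2 = dx * dx + dyz2;
          if (d2 > cut2) continue;
          const double g = w * std::exp(-d2 * inv2s2);
          const double e = inv_norm * ((target[base + i] - tbar) -
                                       ratio * (sim[base + i] - sbar));
          // ds_v/dx_a = g * (r_v - x_a) / sigma^2
          const double c = e * g * invs2;
          fx += c * dx;
          fy += c * dy;
          fz += c * dz;
        }
      }
    }
    force(a, 0) = fx;
    force(a, 1) = fy;
    force(a, 2) = fz;
  }
  force.attr("cc") = cc;
  return force;
}

// Trilinear interpolation of map value and its analytic gradient (per
// Angstrom) at arbitrary Cartesian points.  Points must lie within the
// grid (fractional index in [0, n-1]); out-of-range points raise.
// [[Rcpp::export]]
NumericMatrix cpp_trilinear(NumericVector grid, IntegerVector dim,
                            NumericVector origin, NumericVector voxel,
                            NumericMatrix points) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int np = points.nrow();
  NumericMatrix out(np, 4);  // value, d/dx, d/dy, d/dz

  for (int p = 0; p < np; ++p) {
    double fx = (points(p, 0) - origin[0]) / voxel[0];
    double fy = (points(p, 1) - origin[1]) / voxel[1];
    double fz = (points(p, 2) - origin[2]) / voxel[2];
    if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 ||
        fz > nz - 1)
      stop("point %d lies outside the map grid", p + 1);
    int i = (int)std::floor(fx), j = (int)std::floor(fy),
        k = (int)std::floor(fz);
    if (i > nx - 2) i = nx - 2;
    if (j > ny - 2) j = ny - 2;
    if (k > nz - 2) k = nz - 2;
    const double tx = fx - i, ty = fy - j, tz = fz - k;

    double c[2][2][2];
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di)
          c[di][dj][dk] =
              grid[(static_cast<R_xlen_t>(k + dk) * ny + (j + dj)) * nx +
                   (i + di)];

    // collapse z, then y; keep what is needed for the three partials
    double c00 = c[0][0][0] * (1 - tz) + c[0][0][1] * tz;
    double c01 = c[0][1][0] * (1 - tz) + c[0][1][1] * tz;
    double c10 = c[1][0][0] * (1 - tz) + c[1][0][1] * tz;
    double c11 = c[1][1][0] * (1 - tz) + c[1][1][1] * tz;
    double c0 = c00 * (1 - ty) + c01 * ty;
    double c1 = c10 * (1 - ty) + c11 * ty;

    out(p, 0) = c0 * (1 - tx) + c1 * tx;
    out(p, 1) = (c1 - c0) / voxel[0];
    out(p, 2) = ((c01 - c00) * (1 - tx) + (c11 - c10) * tx) / voxel[1];
    double dz00 = c[0][0][1] - c[0][0][0];
    double dz01 = c[0][1][1] - c[0][1][0];
    double dz10 = c[1][0][1] - c[1][0][0];
    double dz11 = c[1][1][1] - c[1][1][0];
    out(p, 3) = ((dz00 * (1 - ty) + dz01 * ty) * (1 - tx) +
                 (dz10 * (1 - ty) + dz11 * ty) * tx) /
                voxel[2];
  }
  return out;
}
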