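#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sampling of a 3D volume at fractional voxel coordinates.
// `pts` is n x 3, 0-based voxel coordinates (x fastest-varying dimension).
// Points outside the support return `fill` and valid = FALSE.
// [[Rcpp::export]]
List cpp_trilinear(NumericVector vol, IntegerVector dim, NumericMatrix pts,
                   double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  LogicalVector valid(n);
  const double *v = vol.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1 ||
        ISNAN(x) || ISNAN(y) || ISNAN(z)) {
      out[i] = fill; valid[i] = false; continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--; if (y0 == ny - 1) y0--; if (z0 == nz - 1) z0--;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    const double *p = v + (size_t)z0 * nx * ny + (size_t)y0 * nx + x0;
    double c00 = p[0] * (1 - fx) + p[1] * fx;
    double c10 = p[nx] * (1 - fx) + p[nx + 1] * fx;
    double c01 = p[(size_t)nx * ny] * (1 - fx) + p[(size_t)nx * ny + 1] * fx;
    double c11 = p[(size_t)nx * ny + nx] * (1 - fx) + p[(size_t)nx * ny + nx + 1] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
    valid[i] = true;
  }
  return List::create(_["values"] = out, _["valid"] = valid);
}

// Trilinear scatter (splatting): distribute each value over the 8 voxels
// surrounding its fractional position, accumulating weighted values and
// weights. Positions outside the grid are dropped.
// [[Rcpp::export]]
List cpp_splat(IntegerVector dim, NumericMatrix pts, NumericVector vals) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector acc((R_xlen_t)nx * ny * nz), wts((R_xlen_t)nx * ny * nz);
  const R_xlen_t n = pts.nrow();
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (ISNAN(x) || x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) continue;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    for (int dz = 0; dz <= 1; ++dz)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          int xi = x0 + dx, yi = y0 + dy, zi = z0 + dz;
          if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz)
            continue;
          double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
          size_t k = (size_t)zi * nx * ny + (size_t)yi * nx + xi;
          acc[k] += w * vals[i];
          wts[k] += w;
        }
  }
  return List::create(_["acc"] = acc, _["wts"] = wts);
}

// Sum anisotropic Gaussian blobs onto a regular grid. Positions and sigmas in
// mm; the grid is described by origin (centre of voxel [1,1,1]) and pitch.
// Support truncated at `cutoff` sigmas.
// [[Rcpp::export]]
NumericVector cpp_render_gaussians(IntegerVector dim, NumericVector origin,
                                   NumericVector pitch, NumericMatrix pos,
                                   NumericVector amp, NumericMatrix sigma,
                                   double cutoff) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector vol((R_xlen_t)nx * ny * nz);
  const R_xlen_t n = pos.nrow();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (amp[i] == 0.0) continue;
    double sx = sigma(i, 0), sy = sigma(i, 1), sz = sigma(i, 2);
    double cx = (pos(i, 0) - origin[0]) / pitch[0];
    double cy = (pos(i, 1) - origin[1]) / pitch[1];
    double cz = (pos(i, 2) - origin[2]) / pitch[2];
    int x0 = (int)std::ceil(cx - cutoff * sx / pitch[0]);
    int x1 = (int)std::floor(cx + cutoff * sx / pitch[0]);
    int y0 = (int)std::ceil(cy - cutoff * sy / pitch[1]);
    int y1 = (int)std::floor(cy + cutoff * sy / pitch[1]);
    int z0 = (int)std::ceil(cz - cutoff * sz / pitch[2]);
    int z1 = (int)std::floor(cz + cutoff * sz / pitch[2]);
    if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0; if (z0 < 0) z0 = 0;
    if (x1 > nx - 1) x1 = nx - 1; if (y1 > ny - 1) y1 = ny - 1;
    if (z1 > nz - 1) z1 = nz - 1;
    if (x0 > x1 || y0 > y1 || z0 > z1) continue;
    for (int zi = z0; zi <= z1; ++zi) {
      double dz = (zi - cz) * pitch[2] / sz;
      double ez = std::exp(-0.5 * dz * dz);
      for (int yi = y0; yi <= y1; ++yi) {
        double dy = (yi - cy) * pitch[1] / sy;
        double ey = std::exp(-0.5 * dy * dy);
        size_t base = (size_t)zi * nx * ny + (size_t)yi * nx;
        for (int xi = x0; xi <= x1; ++xi) {
          double dx = (xi - cx) * pitch[0] / sx;
          vol[base + xi] += amp[i] * ez * ey * std::exp(-0.5 * dx * dx);
        }
      }
    }
  }
  return vol;
}

// Delay-and-sum round trip for point targets: plane-wave transmit along +z,
// per-element analytic (complex) echoes with a Gaussian envelope, coherent
// summation at two-way geometric delays. Returns the envelope magnitude.
// [[Rcpp::export]]
NumericVector cpp_das(IntegerVector dim, NumericVector origin,
                      NumericVector pitch, NumericMatrix elems,
                      NumericMatrix targets, double c_mm_s, double f0_hz,
                      double pulse_sigma_s) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t ne = elems.nrow(), nt = targets.nrow();
  NumericVector vol((R_xlen_t)nx * ny * nz);
  const double two_pi_f = 2 * M_PI * f0_hz;
  // two-way delay per target per element
  std::vector<double> tau((size_t)ne * nt);
  for (R_xlen_t e = 0; e < ne; ++e)
    for (R_xlen_t t = 0; t < nt; ++t) {
      double dx = targets(t, 0) - elems(e, 0);
      double dy = targets(t, 1) - elems(e, 1);
      double dz = targets(t, 2) - elems(e, 2);
      double rx = std::sqrt(dx * dx + dy * dy + dz * dz);
      tau[(size_t)e * nt + t] = (targets(t, 2) + rx) / c_mm_s;
    }
  for (int zi = 0; zi < nz; ++zi) {
    double vz = origin[2] + zi * pitch[2];
    for (int yi = 0; yi < ny; ++yi) {
      double vy = origin[1] + yi * pitch[1];
      for (int xi = 0; xi < nx; ++xi) {
        double vx = origin[0] + xi * pitch[0];
        double re = 0, im = 0;
        for (R_xlen_t e = 0; e < ne; ++e) {
          double dx = vx - elems(e, 0);
          double dy = vy - elems(e, 1);
          double dz = vz - elems(e, 2);
          double rv = std::sqrt(dx * dx + dy * dy + dz * dz);
          double tv = (vz + rv) / c_mm_s;
          for (R_xlen_t t = 0; t < nt; ++t) {
            double dt = tv - tau[(size_t)e * nt + t];
            double env = std::exp(-0.5 * (dt / pulse_sigma_s) * (dt / pulse_sigma_s));
            if (env < 1e-8) continue;
            re += env * std::cos(two_pi_f * dt);
            im += env * std::sin(two_pi_f * dt);
          }
        }
        vol[(size_t)zi * nx * ny + (size_t)yi * nx + xi] = std::sqrt(re * re + im * im);
      }
    }
  }
  return vol;
}

// Strict 26-neighbourhood local maxima above a threshold. NA voxels never
// qualify and never block a neighbour. Returns 1-based voxel indices (n x 3).
// [[Rcpp::export]]
IntegerMatrix cpp_local_maxima(NumericVector vol, IntegerVector dim,
                               double threshold) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> xs, ys, zs;
  const double *v = vol.begin();
  for (int zi = 0; zi < nz; ++zi)
    for (int yi = 0; yi < ny; ++yi)
      for (int xi = 0; xi < nx; ++xi) {
        double val = v[(size_t)zi * nx * ny + (size_t)yi * nx + xi];
        if (ISNAN(val) || val <= threshold) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xn = xi + dx, yn = yi + dy, zn = zi + dz;
              if (xn < 0 || yn < 0 || zn < 0 || xn >= nx || yn >= ny || zn >= nz)
                continue;
              double nv = v[(size_t)zn * nx * ny + (size_t)yn * nx + xn];
              if (!ISNAN(nv) && nv >= val) { ismax = false; break; }
            }
        if (ismax) { xs.push_back(xi + 1); ys.push_back(yi + 1); zs.push_back(zi + 1); }
      }
  IntegerMatrix out(xs.size(), 3);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i]; out(i, 1) = ys[i]; out(i, 2) = zs[i];
  }
  return out;
}
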