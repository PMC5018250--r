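#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <algorithm>
using namespace Rcpp;

// Trilinear sample of a 3D array stored column-major (x fastest).
// x, y, z are 0-based fractional voxel indices; out-of-bounds -> 0.
static inline double tri_sample(const double* v, int nx, int ny, int nz,
                                double x, double y, double z) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2;
  if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2;
  if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2;
  if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const double* p = v + (size_t)z0 * nx * ny + (size_t)y0 * nx + x0;
  size_t sy = nx, sz = (size_t)nx * ny;
  double c00 = p[0]      * (1 - fx) + p[1]           * fx;
  double c10 = p[sy]     * (1 - fx) + p[sy + 1]      * fx;
  double c01 = p[sz]     * (1 - fx) + p[sz + 1]      * fx;
  double c11 = p[sz+sy]  * (1 - fx) + p[sz + sy + 1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double bi_sample(const double* img, int nx, int ny,
                               double x, double y) {
  if (x < 0.0 || y < 0.0 || x > nx - 1.0 || y > ny - 1.0) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 > nx - 2) x0 = nx - 2;
  if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2;
  if (y0 < 0) y0 = 0;
  double fx = x - x0, fy = y - y0;
  const double* p = img + (size_t)y0 * nx + x0;
  double c0 = p[0]  * (1 - fx) + p[1]      * fx;
  double c1 = p[nx] * (1 - fx) + p[nx + 1] * fx;
  return c0 * (1 - fy) + c1 * fy;
}

// out(p) = vol(A (p - c) + b + c), all in 0-based voxel coordinates,
// c = (dim - 1)/2 is the box center.
// [[Rcpp::export]]
NumericVector cpp_affine_sample(NumericVector vol, IntegerVector dim,
                                NumericMatrix A, NumericVector b) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  const double* v = vol.begin();
  double a00 = A(0,0), a01 = A(0,1), a02 = A(0,2);
  double a10 = A(1,0), a11 = A(1,1), a12 = A(1,2);
  double a20 = A(2,0), a21 = A(2,1), a22 = A(2,2);
  size_t idx = 0;
  for (int z = 0; z < nz; ++z) {
    double pz = z - cz;
    for (int y = 0; y < ny; ++y) {
      double py = y - cy;
      for (int x = 0; x < nx; ++x, ++idx) {
        double px = x - cx;
        double sx = a00 * px + a01 * py + a02 * pz + b[0] + cx;
        double sy = a10 * px + a11 * py + a12 * pz + b[1] + cy;
        double sz = a20 * px + a21 * py + a22 * pz + b[2] + cz;
        out[idx] = tri_sample(v, nx, ny, nz, sx, sy, sz);
      }
    }
  }
  return out;
}

// Projection: image(u, w) = sum_t vol(c + R (u, t, w)'), unit steps in t.
// R maps view-frame coordinates into volume coordinates.
// [[Rcpp::export]]
NumericMatrix cpp_project(NumericVector vol, IntegerVector dim, NumericMatrix R) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  NumericMatrix img(nx, nz); // (u, w)
  const double* v = vol.begin();
  double r00 = R(0,0), r01 = R(0,1), r02 = R(0,2);
  double r10 = R(1,0), r11 = R(1,1), r12 = R(1,2);
  double r20 = R(2,0), r21 = R(2,1), r22 = R(2,2);
  for (int iw = 0; iw < nz; ++iw) {
    double w = iw - cz;
    for (int iu = 0; iu < nx; ++iu) {
      double u = iu - cx;
      double acc = 0.0;
      for (int it = 0; it < ny; ++it) {
        double t = it - cy;
        double sx = r00 * u + r01 * t + r02 * w + cx;
        double sy = r10 * u + r11 * t + r12 * w + cy;
        double sz = r20 * u + r21 * t + r22 * w + cz;
        acc += tri_sample(v, nx, ny, nz, sx, sy, sz);
      }
      img(iu, iw) = acc;
    }
  }
  return img;
}

// Rotate image counter-clockwise by psi (deg) about its center, then
// shift by (dx, dy) pixels: out(p) = img(Rot(-psi) (p - c - s) + c).
// [[Rcpp::export]]
NumericMatrix cpp_image_transform(NumericMatrix img, double psi_deg,
                                  double dx, double dy) {
  int nx = img.nrow(), ny = img.ncol();
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double th = -psi_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  NumericMatrix out(nx, ny);
  const double* p = img.begin();
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      double px = x - cx - dx, py = y - cy - dy;
      double sx = ct * px - st * py + cx;
      double sy = st * px + ct * py + cy;
      out(x, y) = bi_sample(p, nx, ny, sx, sy);
    }
  }
  return out;
}

// Add one (already filtered, psi/shift-corrected) segment into the volume:
// vol[x,y,z] += img(u, z) with u = (x-c) cos(az) + (y-c) sin(az) + cu.
// Slice-separable geometry: tilt is taken as exactly 90 degrees here.
// [[Rcpp::export]]
NumericVector cpp_backproject_add(NumericVector vol, IntegerVector dim,
                                  NumericMatrix img, double azimuth_deg) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double th = azimuth_deg * M_PI / 180.0;
  double ca = std::cos(th), sa = std::sin(th);
  double* v = vol.begin();
  const double* im = img.begin();
  int nu = img.nrow();
  double cu = (nu - 1) / 2.0;
  for (int z = 0; z < nz; ++z) {
    const double* col = im + (size_t)z * nu;
    double* slab = v + (size_t)z * nx * ny;
    for (int y = 0; y < ny; ++y) {
      double uy = (y - cy) * sa;
      for (int x = 0; x < nx; ++x) {
        double u = (x - cx) * ca + uy + cu;
        if (u < 0.0 || u > nu - 1.0) continue;
        int u0 = (int)std::floor(u);
        if (u0 > nu - 2) u0 = nu - 2;
        double f = u - u0;
        slab[(size_t)y * nx + x] += col[u0] * (1 - f) + col[u0 + 1] * f;
      }
    }
  }
  return vol;
}

// Average of vol over helical lattice operations T_{i,k}:
// rotate by i*twist + k*360/cn about z, translate i*rise (voxels) along z.
// sym(p) = mean over ops of vol(T^{-1} p); only in-bounds samples counted.
// [[Rcpp::export]]
NumericVector cpp_symmetrize(NumericVector vol, IntegerVector dim,
                             double twist_deg, double rise_vox, int cn,
                             int layer_span) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> acc(n, 0.0);
  std::vector<double> wt(n, 0.0);
  const double* v = vol.begin();
  for (int i = -layer_span; i <= layer_span; ++i) {
    for (int k = 0; k < cn; ++k) {
      double th = -(i * twist_deg + k * 360.0 / cn) * M_PI / 180.0;
      double ct = std::cos(th), st = std::sin(th);
      double dz = i * rise_vox;
      size_t idx = 0;
      for (int z = 0; z < nz; ++z) {
        double pz = z - cz - dz;
        if (pz < 0.0 - cz || pz > nz - 1.0 - cz) { idx += (size_t)nx * ny; continue; }
        for (int y = 0; y < ny; ++y) {
          double py = y - cy;
          for (int x = 0; x < nx; ++x, ++idx) {
            double px = x - cx;
            double sx = ct * px - st * py + cx;
            double sy = st * px + ct * py + cy;
            double sz = pz + cz;
            if (sx < 0.0 || sy < 0.0 || sx > nx - 1.0 || sy > ny - 1.0) continue;
            acc[idx] += tri_sample(v, nx, ny, nz, sx, sy, sz);
            wt[idx] += 1.0;
          }
        }
      }
    }
  }
  NumericVector out(n);
  for (size_t j = 0; j < n; ++j) out[j] = wt[j] > 0 ? acc[j] / wt[j] : 0.0;
  return out;
}

// Mean squared difference between vol and its screw-transformed copy over a
// cylindrical mask (radii in voxels), counting only in-bounds samples.
// Returns c(mse, n_voxels, mean_sq_signal).
// [[Rcpp::export]]
NumericVector cpp_screw_residual(NumericVector vol, IntegerVector dim,
                                 double twist_deg, double rise_vox,
                                 double rmin_vox, double rmax_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  double th = -twist_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  const double* v = vol.begin();
  double ss = 0.0, sig = 0.0;
  long cnt = 0;
  double r2min = rmin_vox * rmin_vox, r2max = rmax_vox * rmax_vox;
  size_t idx = 0;
  for (int z = 0; z < nz; ++z) {
    double sz = z - cz - rise_vox + cz;
    bool zok = (sz >= 0.0 && sz <= nz - 1.0);
    for (int y = 0; y < ny; ++y) {
      double py = y - cy;
      for (int x = 0; x < nx; ++x, ++idx) {
        double px = x - cx;
        double r2 = px * px + py * py;
        if (r2 < r2min || r2 > r2max || !zok) continue;
        double sx = ct * px - st * py + cx;
        double sy = st * px + ct * py + cy;
        if (sx < 0.0 || sy < 0.0 || sx > nx - 1.0 || sy > ny - 1.0) continue;
        double d = v[idx] - tri_sample(v, nx, ny, nz, sx, sy, sz);
        ss += d * d;
        sig += v[idx] * v[idx];
        ++cnt;
      }
    }
  }
  return NumericVector::create(cnt ? ss / cnt : NA_REAL, (double)cnt,
                               cnt ? sig / cnt : NA_REAL);
}

// Sum of isotropic Gaussians rendered on a voxel grid.
// centers in 0-based voxel coords; sigma in voxels; amplitude = integral
// weight (density value amp/( (2 pi)^{3/2} sigma^3 ) at the center).
// [[Rcpp::export]]
NumericVector cpp_render_gauss(IntegerVector dim, NumericMatrix centers,
                               NumericVector amps, NumericVector sigmas) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  double* v = out.begin();
  int na = centers.nrow();
  for (int a = 0; a < na; ++a) {
    double axp = centers(a, 0), ayp = centers(a, 1), azp = centers(a, 2);
    double s = sigmas[a];
    double norm = amps[a] / (std::pow(2.0 * M_PI, 1.5) * s * s * s);
    double inv2s2 = 1.0 / (2.0 * s * s);
    int ext = (int)std::ceil(4.5 * s);
    int x0 = std::max(0, (int)std::floor(axp) - ext);
    int x1 = std::min(nx - 1, (int)std::ceil(axp) + ext);
    int y0 = std::max(0, (int)std::floor(ayp) - ext);
    int y1 = std::min(ny - 1, (int)std::ceil(ayp) + ext);
    int z0 = std::max(0, (int)std::floor(azp) - ext);
    int z1 = std::min(nz - 1, (int)std::ceil(azp) + ext);
    for (int z = z0; z <= z1; ++z) {
      double dz2 = (z - azp) * (z - azp);
      for (int y = y0; y <= y1; ++y) {
        double dy2 = (y - ayp) * (y - ayp);
        double* row = v + (size_t)z * nx * ny + (size_t)y * nx;
        for (int x = x0; x <= x1; ++x) {
          double d2 = (x - axp) * (x - axp) + dy2 + dz2;
          row[x] += norm * std::exp(-d2 * inv2s2);
        }
      }
    }
  }
  return out;
}

// Shrake-Rupley solvent-accessible surface area per atom.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector radii,
                       double probe, int n_points) {
  int n = xyz.nrow();
  NumericVector area(n);
  // quasi-uniform sphere points (golden spiral)
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n_points; ++i) {
    double zz = 1.0 - 2.0 * (i + 0.5) / n_points;
    double rr = std::sqrt(std::max(0.0, 1.0 - zz * zz));
    double th = golden * i;
    px[i] = rr * std::cos(th); py[i] = rr * std::sin(th); pz[i] = zz;
  }
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  double cut = 2.0 * (rmax + probe);
  // neighbor search via sorted-cell grid would be ideal; n is modest, so use
  // a simple spatial hash on a uniform grid with cell size = cut
  double minx = 1e30, miny = 1e30, minz = 1e30;
  for (int i = 0; i < n; ++i) {
    minx = std::min(minx, xyz(i,0)); miny = std::min(miny, xyz(i,1));
    minz = std::min(minz, xyz(i,2));
  }
  auto cellof = [&](double x, double y, double z, int& cx, int& cy, int& cz) {
    cx = (int)std::floor((x - minx) / cut);
    cy = (int)std::floor((y - miny) / cut);
    cz = (int)std::floor((z - minz) / cut);
  };
  std::map<long long, std::vector<int> > cells;
  auto key = [](int cx, int cy, int cz) {
    return ((long long)cx << 42) ^ ((long long)cy << 21) ^ (long long)cz;
  };
  for (int i = 0; i < n; ++i) {
    int cx, cy, cz; cellof(xyz(i,0), xyz(i,1), xyz(i,2), cx, cy, cz);
    cells[key(cx, cy, cz)].push_back(i);
  }
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    double ri = radii[i] + probe;
    double xi = xyz(i,0), yi = xyz(i,1), zi = xyz(i,2);
    nb.clear();
    int cx, cy, cz; cellof(xi, yi, zi, cx, cy, cz);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(key(cx + dx, cy + dy, cz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            if (j == i) continue;
            double rj = radii[j] + probe;
            double ddx = xyz(j,0) - xi, ddy = xyz(j,1) - yi, ddz = xyz(j,2) - zi;
            double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
            double rr = ri + rj;
            if (d2 < rr * rr) nb.push_back(j);
          }
        }
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      double sx = xi + ri * px[p], sy = yi + ri * py[p], sz = zi + ri * pz[p];
      bool buried = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        int j = nb[q];
        double rj = radii[j] + probe;
        double ddx = sx - xyz(j,0), ddy = sy - xyz(j,1), ddz = sz - xyz(j,2);
        if (ddx*ddx + ddy*ddy + ddz*ddz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)acc / n_points;
  }
  return area;
}

// Minimum inter-point distance between two coordinate sets.
// Returns c(min_dist, index_a, index_b) with 1-based indices.
// [[Rcpp::export]]
NumericVector cpp_min_pairdist(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow();
  double best = R_PosInf;
  int bi = 0, bj = 0;
  for (int i = 0; i < na; ++i) {
    double xi = a(i,0), yi = a(i,1), zi = a(i,2);
    for (int j = 0; j < nb; ++j) {
      double dx = b(j,0) - xi, dy = b(j,1) - yi, dz = b(j,2) - zi;
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) { best = d2; bi = i; bj = j; }
    }
  }
  return NumericVector::create(std::sqrt(best), bi + 1.0, bj + 1.0);
}
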