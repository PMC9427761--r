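#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Anisotropic squared Euclidean distance transform (separable lower-envelope
// algorithm, one pass per axis). f holds squared distances in mm^2; INF_VAL
// stands in for "no seed on this line" and stays well inside double range.
// ---------------------------------------------------------------------------

static const double INF_VAL = 1e15;

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w) {
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -INF_VAL;
  z[1] = INF_VAL;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * (double)v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k] && k > 0) {
        k--;
      } else {
        break;
      }
    }
    if (s <= z[k]) { // k == 0
      v[0] = q;
    } else {
      k++;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = INF_VAL;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    const double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// Squared distance (mm^2) from every voxel to the nearest TRUE voxel.
// Voxels are indexed column-major with dims (nx, ny, nz).
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : INF_VAL;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int zi = 0; zi < nz; zi++)
    for (int yi = 0; yi < ny; yi++) {
      R_xlen_t base = (R_xlen_t)zi * nx * ny + (R_xlen_t)yi * nx;
      for (int xi = 0; xi < nx; xi++) f[xi] = out[base + xi];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int xi = 0; xi < nx; xi++) out[base + xi] = d[xi];
    }
  // y pass
  for (int zi = 0; zi < nz; zi++)
    for (int xi = 0; xi < nx; xi++) {
      R_xlen_t base = (R_xlen_t)zi * nx * ny + xi;
      for (int yi = 0; yi < ny; yi++) f[yi] = out[base + (R_xlen_t)yi * nx];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int yi = 0; yi < ny; yi++) out[base + (R_xlen_t)yi * nx] = d[yi];
    }
  // z pass
  for (int yi = 0; yi < ny; yi++)
    for (int xi = 0; xi < nx; xi++) {
      R_xlen_t base = (R_xlen_t)yi * nx + xi;
      for (int zi = 0; zi < nz; zi++) f[zi] = out[base + (R_xlen_t)zi * nx * ny];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int zi = 0; zi < nz; zi++) out[base + (R_xlen_t)zi * nx * ny] = d[zi];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Texture matrices. Levels are 1..nlev inside the ROI; anything outside the
// ROI never pairs, never extends a run and never counts as a neighbour.
// ---------------------------------------------------------------------------

static const int OFFS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline R_xlen_t vidx(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
}

// Symmetric co-occurrence counts merged over the 13 unique 3D offsets.
// [[Rcpp::export(name = ".glcm_counts_cpp")]]
NumericMatrix glcm_counts_cpp(IntegerVector levels, LogicalVector roi,
                              IntegerVector dims, int nlev) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix m(nlev, nlev);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t i = vidx(x, y, z, nx, ny);
        if (!roi[i]) continue;
        int li = levels[i];
        for (int o = 0; o < 13; o++) {
          int x2 = x + OFFS[o][0], y2 = y + OFFS[o][1], z2 = z + OFFS[o][2];
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          R_xlen_t j = vidx(x2, y2, z2, nx, ny);
          if (!roi[j]) continue;
          int lj = levels[j];
          m(li - 1, lj - 1) += 1.0;
          m(lj - 1, li - 1) += 1.0;
        }
      }
  return m;
}

// Run-length counts over the 13 directions, merged by summation.
// Column r holds runs of length r (r = 1..max run length).
// [[Rcpp::export(name = ".glrlm_counts_cpp")]]
NumericMatrix glrlm_counts_cpp(IntegerVector levels, LogicalVector roi,
                               IntegerVector dims, int nlev) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int maxrun = std::max(nx, std::max(ny, nz));
  NumericMatrix m(nlev, maxrun);
  for (int o = 0; o < 13; o++) {
    const int dx = OFFS[o][0], dy = OFFS[o][1], dz = OFFS[o][2];
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
          R_xlen_t i = vidx(x, y, z, nx, ny);
          if (!roi[i]) continue;
          const int li = levels[i];
          // run starts here iff predecessor is absent, out of ROI or differs
          const int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz) {
            R_xlen_t p = vidx(xp, yp, zp, nx, ny);
            if (roi[p] && levels[p] == li) continue;
          }
          int len = 1;
          int xc = x + dx, yc = y + dy, zc = z + dz;
          while (xc >= 0 && xc < nx && yc >= 0 && yc < ny && zc >= 0 && zc < nz) {
            R_xlen_t c = vidx(xc, yc, zc, nx, ny);
            if (!roi[c] || levels[c] != li) break;
            len++;
            xc += dx; yc += dy; zc += dz;
          }
          m(li - 1, len - 1) += 1.0;
        }
  }
  return m;
}

// Neighbourhood gray-tone difference table: per level, the count n_i of ROI
// voxels with >= 1 in-ROI 26-neighbour and the sum s_i of |level - nbhd mean|.
// [[Rcpp::export(name = ".ngtdm_table_cpp")]]
List ngtdm_table_cpp(IntegerVector levels, LogicalVector roi,
                     IntegerVector dims, int nlev) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector ni(nlev), si(nlev);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t i = vidx(x, y, z, nx, ny);
        if (!roi[i]) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; dz++)
          for (int dy = -1; dy <= 1; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                  z2 < 0 || z2 >= nz)
                continue;
              R_xlen_t j = vidx(x2, y2, z2, nx, ny);
              if (!roi[j]) continue;
              sum += levels[j];
              cnt++;
            }
        if (cnt == 0) continue;
        int li = levels[i];
        ni[li - 1] += 1.0;
        si[li - 1] += std::fabs((double)li - sum / cnt);
      }
  return List::create(Named("n") = ni, Named("s") = si);
}

// ---------------------------------------------------------------------------
// Triangulated isosurface area by marching tetrahedra (6-tetrahedron cube
// decomposition, linear interpolation along edges). Corner c of a cell has
// voxel offset (c&1, (c>>1)&1, (c>>2)&1).
// ---------------------------------------------------------------------------

static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

static inline void corner_xyz(int c, double *p) {
  p[0] = (double)(c & 1);
  p[1] = (double)((c >> 1) & 1);
  p[2] = (double)((c >> 2) & 1);
}

static inline double tri_area3(const double *a, const double *b,
                               const double *c) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double w0 = u[1] * v[2] - u[2] * v[1];
  double w1 = u[2] * v[0] - u[0] * v[2];
  double w2 = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(w0 * w0 + w1 * w1 + w2 * w2);
}

// [[Rcpp::export(name = ".surface_area_mt_cpp")]]
double surface_area_mt_cpp(NumericVector field, IntegerVector dims,
                           NumericVector spacing, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double area = 0.0;
  double vals[8], cxyz[8][3];
  for (int c = 0; c < 8; c++) corner_xyz(c, cxyz[c]);

  for (int z = 0; z < nz - 1; z++)
    for (int y = 0; y < ny - 1; y++)
      for (int x = 0; x < nx - 1; x++) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; c++) {
          vals[c] = field[vidx(x + (c & 1), y + ((c >> 1) & 1),
                               z + ((c >> 2) & 1), nx, ny)];
          (vals[c] > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; t++) {
          int ins[4], outs[4], ki = 0, ko = 0;
          for (int j = 0; j < 4; j++) {
            int c = TETS[t][j];
            if (vals[c] > iso) ins[ki++] = c; else outs[ko++] = c;
          }
          if (ki == 0 || ki == 4) continue;
          // interpolated crossing on edge (a in, b out), in mm
          auto ip = [&](int a, int b, double *p) {
            double w = (iso - vals[a]) / (vals[b] - vals[a]);
            for (int k = 0; k < 3; k++)
              p[k] = spacing[k] *
                     ((double)(k == 0 ? x : (k == 1 ? y : z)) +
                      cxyz[a][k] + w * (cxyz[b][k] - cxyz[a][k]));
          };
          if (ki == 1 || ki == 3) {
            int lone = (ki == 1) ? ins[0] : outs[0];
            int *oth = (ki == 1) ? outs : ins;
            double p0[3], p1[3], p2[3];
            ip(lone, oth[0], p0);
            ip(lone, oth[1], p1);
            ip(lone, oth[2], p2);
            area += tri_area3(p0, p1, p2);
          } else { // 2-2 split: quad between the two crossing edge pairs
            double q0[3], q1[3], q2[3], q3[3];
            ip(ins[0], outs[0], q0);
            ip(ins[0], outs[1], q1);
            ip(ins[1], outs[1], q2);
            ip(ins[1], outs[0], q3);
            area += tri_area3(q0, q1, q2) + tri_area3(q0, q2, q3);
          }
        }
      }
  return area;
}

// Maximum pairwise Euclidean distance between points (rows of an n x 3
// matrix of mm coordinates).
// [[Rcpp::export(name = ".max_pairwise_dist_cpp")]]
double max_pairwise_dist_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n - 1; i++)
    for (int j = i + 1; j < n; j++) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
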