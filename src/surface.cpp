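// Surface area of a binary mask by marching tetrahedra.
//
// The mask is optionally smoothed with a separable (1,2,1)/4 kernel to
// anti-alias the staircase boundary, then the 0.5-isosurface is triangulated
// on a grid padded with one layer of zeros (so surfaces touching the array
// edge are closed). Each grid cell is split into 6 tetrahedra around the main
// diagonal (Kuhn subdivision); iso-crossings are linearly interpolated on
// tetrahedron edges in physical (mm) coordinates.

#include <Rcpp.h>
#include <cmath>
#include <vector>

namespace {

struct P3 { double x, y, z; };

inline P3 lerp(const P3& a, const P3& b, double fa, double fb, double iso) {
  double t = (iso - fa) / (fb - fa);
  P3 p;
  p.x = a.x + t * (b.x - a.x);
  p.y = a.y + t * (b.y - a.y);
  p.z = a.z + t * (b.z - a.z);
  return p;
}

inline double tri_area(const P3& a, const P3& b, const P3& c) {
  const double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  const double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  const double cx = uy * vz - uz * vy;
  const double cy = uz * vx - ux * vz;
  const double cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// area contribution of one tetrahedron
double tet_area(const P3 p[4], const double f[4], double iso) {
  bool above[4];
  int na = 0;
  for (int i = 0; i < 4; ++i) { above[i] = f[i] >= iso; na += above[i]; }
  if (na == 0 || na == 4) return 0.0;
  int hi[4], lo[4], nh = 0, nl = 0;
  for (int i = 0; i < 4; ++i) (above[i] ? hi[nh++] : lo[nl++]) = i;
  if (na == 1 || na == 3) {
    const int apex = (na == 1) ? hi[0] : lo[0];
    const int* base = (na == 1) ? lo : hi;
    P3 e0 = lerp(p[apex], p[base[0]], f[apex], f[base[0]], iso);
    P3 e1 = lerp(p[apex], p[base[1]], f[apex], f[base[1]], iso);
    P3 e2 = lerp(p[apex], p[base[2]], f[apex], f[base[2]], iso);
    return tri_area(e0, e1, e2);
  }
  // 2-2: quad on edges (hi0,lo0), (hi0,lo1), (hi1,lo1), (hi1,lo0)
  P3 q0 = lerp(p[hi[0]], p[lo[0]], f[hi[0]], f[lo[0]], iso);
  P3 q1 = lerp(p[hi[0]], p[lo[1]], f[hi[0]], f[lo[1]], iso);
  P3 q2 = lerp(p[hi[1]], p[lo[1]], f[hi[1]], f[lo[1]], iso);
  P3 q3 = lerp(p[hi[1]], p[lo[0]], f[hi[1]], f[lo[0]], iso);
  return tri_area(q0, q1, q2) + tri_area(q0, q2, q3);
}

// corner n of the unit cube: ((n&1), (n>>1)&1, (n>>2)&1)
const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

// separable (1,2,1)/4 smoothing with zero boundary, in place
void smooth3(std::vector<double>& f, int X, int Y, int Z) {
  std::vector<double> tmp(f.size());
  // along x
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        const size_t i = x + (size_t)X * (y + (size_t)Y * z);
        double v = 2.0 * f[i];
        if (x > 0) v += f[i - 1];
        if (x < X - 1) v += f[i + 1];
        tmp[i] = 0.25 * v;
      }
  // along y
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        const size_t i = x + (size_t)X * (y + (size_t)Y * z);
        double v = 2.0 * tmp[i];
        if (y > 0) v += tmp[i - X];
        if (y < Y - 1) v += tmp[i + X];
        f[i] = 0.25 * v;
      }
  // along z
  const size_t XY = (size_t)X * Y;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        const size_t i = x + (size_t)X * (y + (size_t)Y * z);
        double v = 2.0 * f[i];
        if (z > 0) v += f[i - XY];
        if (z < Z - 1) v += f[i + XY];
        tmp[i] = 0.25 * v;
      }
  f.swap(tmp);
}

}  // namespace

// [[Rcpp::export]]
double mt_surface_area(Rcpp::NumericVector mask, Rcpp::IntegerVector dim,
                       Rcpp::NumericVector spacing, int smooth_passes,
                       double iso) {
  if (dim.size() != 3) Rcpp::stop("dim must have 3 elements");
  const int X = dim[0], Y = dim[1], Z = dim[2];
  if ((size_t)mask.size() != (size_t)X * Y * Z) Rcpp::stop("mask length mismatch");
  std::vector<double> f(mask.begin(), mask.end());
  for (int s = 0; s < smooth_passes; ++s) smooth3(f, X, Y, Z);

  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // sample with one-voxel zero padding: corners at (x,y,z) in [-1, X] etc.
  auto sample = [&](int x, int y, int z) -> double {
    if (x < 0 || y < 0 || z < 0 || x >= X || y >= Y || z >= Z) return 0.0;
    return f[x + (size_t)X * (y + (size_t)Y * z)];
  };

  double area = 0.0;
  double fc[8];
  P3 pc[8];
  for (int z = -1; z < Z; ++z)
    for (int y = -1; y < Y; ++y)
      for (int x = -1; x < X; ++x) {
        bool any = false, all = true;
        for (int n = 0; n < 8; ++n) {
          const int cx = x + (n & 1), cy = y + ((n >> 1) & 1), cz = z + ((n >> 2) & 1);
          fc[n] = sample(cx, cy, cz);
          pc[n].x = cx * sx; pc[n].y = cy * sy; pc[n].z = cz * sz;
          if (fc[n] >= iso) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          P3 tp[4]; double tf[4];
          for (int v = 0; v < 4; ++v) { tp[v] = pc[TETS[t][v]]; tf[v] = fc[TETS[t][v]]; }
          area += tet_area(tp, tf, iso);
        }
      }
  return area;
}
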