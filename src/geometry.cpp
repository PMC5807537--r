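#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic quasi-uniform sphere points (Fibonacci / golden-spiral
// lattice). Using a fixed lattice keeps SASA bit-reproducible for a given
// n_points, which the interface-area bookkeeping relies on.
static void fib_sphere(int n, std::vector<double> &px, std::vector<double> &py,
                       std::vector<double> &pz) {
  const double ga = M_PI * (3.0 - std::sqrt(5.0)); // golden angle
  px.resize(n); py.resize(n); pz.resize(n);
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - (2.0 * i + 1.0) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * i;
    px[i] = r * std::cos(th);
    py[i] = r * std::sin(th);
    pz[i] = z;
  }
}

// Shrake-Rupley solvent-accessible surface area, one value per atom (A^2).
// Test points exactly on a neighbouring sphere's surface (within `tol`)
// are shared: their area is split evenly among the coincident spheres, so
// duplicated atoms yield a well-defined half/half split rather than double
// counting.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii, double probe,
                       int n_points) {
  int n = xyz.nrow();
  NumericVector out(n);
  if (n == 0) return out;
  std::vector<double> px, py, pz;
  fib_sphere(n_points, px, py, pz);
  const double tol = 1e-6;

  std::vector<double> R(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    R[i] = radii[i] + probe;
    if (R[i] > rmax) rmax = R[i];
  }

  for (int i = 0; i < n; ++i) {
    // neighbour list: spheres that can bury points of sphere i
    std::vector<int> nb;
    double reach = R[i] + rmax;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0);
      double dy = xyz(j, 1) - xyz(i, 1);
      double dz = xyz(j, 2) - xyz(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double lim = R[i] + R[j];
      if (d2 < lim * lim) nb.push_back(j);
    }
    double acc = 0.0;
    for (int k = 0; k < n_points; ++k) {
      double qx = xyz(i, 0) + R[i] * px[k];
      double qy = xyz(i, 1) + R[i] * py[k];
      double qz = xyz(i, 2) + R[i] * pz[k];
      bool buried = false;
      int ties = 0;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = qx - xyz(j, 0);
        double dy = qy - xyz(j, 1);
        double dz = qz - xyz(j, 2);
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d < R[j] - tol) { buried = true; break; }
        if (std::fabs(d - R[j]) <= tol) ++ties;
      }
      if (!buried) acc += 1.0 / (1.0 + ties);
    }
    out[i] = 4.0 * M_PI * R[i] * R[i] * acc / n_points;
  }
  return out;
}

// Projected shadow area of a union of disks (atoms inflated by the gas
// radius), rasterised on a square grid, for a batch of orientations.
// `rot` is n_orient x 9 (row-major 3x3 rotation matrices); only the first
// two rows of each matrix are needed (projection onto the rotated xy
// plane). `offs` (n_orient x 2, in [0,1)) shifts the raster origin by a
// random sub-cell offset per orientation, which makes the counting
// estimator unbiased for the true shadow area. Returns one area (A^2)
// per orientation.
// [[Rcpp::export]]
NumericVector proj_area_cpp(NumericMatrix xyz, NumericVector radii,
                            NumericMatrix rot, double spacing,
                            NumericMatrix offs) {
  int n = xyz.nrow();
  int no = rot.nrow();
  NumericVector out(no);
  if (n == 0) return out;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) if (radii[i] > rmax) rmax = radii[i];

  std::vector<double> ux(n), uy(n);
  std::vector<char> grid;

  for (int o = 0; o < no; ++o) {
    double r00 = rot(o, 0), r01 = rot(o, 1), r02 = rot(o, 2);
    double r10 = rot(o, 3), r11 = rot(o, 4), r12 = rot(o, 5);
    double xmin = 1e300, xmax = -1e300, ymin = 1e300, ymax = -1e300;
    for (int i = 0; i < n; ++i) {
      double x = r00 * xyz(i, 0) + r01 * xyz(i, 1) + r02 * xyz(i, 2);
      double y = r10 * xyz(i, 0) + r11 * xyz(i, 1) + r12 * xyz(i, 2);
      ux[i] = x; uy[i] = y;
      if (x < xmin) xmin = x;
      if (x > xmax) xmax = x;
      if (y < ymin) ymin = y;
      if (y > ymax) ymax = y;
    }
    xmin -= rmax + spacing + offs(o, 0) * spacing;
    ymin -= rmax + spacing + offs(o, 1) * spacing;
    xmax += rmax + spacing; ymax += rmax + spacing;
    int nx = (int)std::ceil((xmax - xmin) / spacing) + 1;
    int ny = (int)std::ceil((ymax - ymin) / spacing) + 1;
    grid.assign((size_t)nx * ny, 0);
    for (int i = 0; i < n; ++i) {
      double r = radii[i];
      double r2 = r * r;
      int i0 = (int)std::floor((ux[i] - r - xmin) / spacing);
      int i1 = (int)std::ceil((ux[i] + r - xmin) / spacing);
      int j0 = (int)std::floor((uy[i] - r - ymin) / spacing);
      int j1 = (int)std::ceil((uy[i] + r - ymin) / spacing);
      if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0;
      if (i1 >= nx) i1 = nx - 1; if (j1 >= ny) j1 = ny - 1;
      for (int ii = i0; ii <= i1; ++ii) {
        double cx = xmin + ii * spacing;
        double dx = cx - ux[i];
        for (int jj = j0; jj <= j1; ++jj) {
          double cy = ymin + jj * spacing;
          double dy = cy - uy[i];
          if (dx * dx + dy * dy <= r2) grid[(size_t)ii * ny + jj] = 1;
        }
      }
    }
    size_t cnt = 0;
    for (size_t k = 0; k < grid.size(); ++k) cnt += grid[k];
    out[o] = (double)cnt * spacing * spacing;
  }
  return out;
}

// Minimum inter-atomic distance between two coordinate sets; used for
// clash screening in probe scoring and rigid-body model building.
// [[Rcpp::export]]
double min_dist_cpp(NumericMatrix a, NumericMatrix b) {
  double best = R_PosInf;
  for (int i = 0; i < a.nrow(); ++i)
    for (int j = 0; j < b.nrow(); ++j) {
      double dx = a(i, 0) - b(j, 0);
      double dy = a(i, 1) - b(j, 1);
      double dz = a(i, 2) - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}

// Count of pairs closer than `cutoff` between two coordinate sets.
// [[Rcpp::export]]
int clash_count_cpp(NumericMatrix a, NumericMatrix b, double cutoff) {
  double c2 = cutoff * cutoff;
  int n = 0;
  for (int i = 0; i < a.nrow(); ++i)
    for (int j = 0; j < b.nrow(); ++j) {
      double dx = a(i, 0) - b(j, 0);
      double dy = a(i, 1) - b(j, 1);
      double dz = a(i, 2) - b(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) ++n;
    }
  return n;
}
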