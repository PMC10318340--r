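#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Half-sample symmetric reflection: ... x1 x0 | x0 x1 ... xn-1 | xn-1 ...
// Conserves total mass under a normalised kernel (Neumann boundary).
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Separable 3D Gaussian convolution; sigma in voxel units per axis.
// Kernel truncated at ceil(4*sigma) taps each side and renormalised.
// Each line is gathered into a contiguous buffer padded by reflection,
// so the inner convolution runs without bounds checks.
// [[Rcpp::export]]
NumericVector smooth3d_cpp(NumericVector x, IntegerVector dim,
                           NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<double> src(x.begin(), x.end());

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0.0) continue;
    int r = (int)std::ceil(4.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0.0;
    for (int t = -r; t <= r; ++t) {
      k[t + r] = std::exp(-0.5 * (double)t * t / (s * s));
      ksum += k[t + r];
    }
    for (double &kv : k) kv /= ksum;

    const int n = (ax == 0) ? nx : (ax == 1 ? ny : nz);
    const R_xlen_t stride =
        (ax == 0) ? 1 : (ax == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
    std::vector<double> buf(n + 2 * r);
    const R_xlen_t nlines = nvox / n;
    for (R_xlen_t line = 0; line < nlines; ++line) {
      // base offset of this line in the 3D array
      R_xlen_t base;
      if (ax == 0) {
        base = line * nx;
      } else if (ax == 1) {
        R_xlen_t zi = line / nx, xi = line % nx;
        base = zi * (R_xlen_t)nx * ny + xi;
      } else {
        base = line;  // lines over the z axis are indexed by (x, y)
      }
      for (int i = 0; i < n; ++i) buf[r + i] = src[base + (R_xlen_t)i * stride];
      for (int i = 0; i < r; ++i) {
        buf[r - 1 - i] = buf[r + reflect_idx(-1 - i, n)];
        buf[r + n + i] = buf[r + reflect_idx(n + i, n)];
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        const double *b = &buf[i];
        for (int t = 0; t <= 2 * r; ++t) acc += k[t] * b[t];
        src[base + (R_xlen_t)i * stride] = acc;
      }
    }
  }

  NumericVector out(nvox);
  std::copy(src.begin(), src.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

static void neighbour_offsets(int connectivity, const IntegerVector &dim,
                              std::vector<int> &di, std::vector<int> &dj,
                              std::vector<int> &dk) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
}

// Label connected components of a logical 3D array (6/18/26 connectivity).
// Returns integer labels 1..n_components, 0 for background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(nvox, 0);
  std::vector<int> di, dj, dk;
  neighbour_offsets(connectivity, dim, di, dj, dk);
  const int nn = (int)di.size();

  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t v = 0; v < nvox; ++v) {
    if (!mask[v] || labels[v] != 0) continue;
    ++current;
    labels[v] = current;
    stack.clear();
    stack.push_back(v);
    while (!stack.empty()) {
      R_xlen_t u = stack.back();
      stack.pop_back();
      int ui = (int)(u % nx);
      int uj = (int)((u / nx) % ny);
      int uk = (int)(u / ((R_xlen_t)nx * ny));
      for (int t = 0; t < nn; ++t) {
        int i = ui + di[t], j = uj + dj[t], kk = uk + dk[t];
        if (i < 0 || i >= nx || j < 0 || j >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)kk * nx * ny + (R_xlen_t)j * nx + i;
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// Largest connected suprathreshold component of x > cut within mask.
// [[Rcpp::export]]
int max_suprathreshold_cluster_cpp(NumericVector x, IntegerVector dim,
                                   LogicalVector mask, double cut,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<char> supra(nvox), seen(nvox, 0);
  for (R_xlen_t v = 0; v < nvox; ++v)
    supra[v] = (mask[v] && x[v] > cut) ? 1 : 0;
  std::vector<int> di, dj, dk;
  neighbour_offsets(connectivity, dim, di, dj, dk);
  const int nn = (int)di.size();

  int best = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t v = 0; v < nvox; ++v) {
    if (!supra[v] || seen[v]) continue;
    int size = 0;
    seen[v] = 1;
    stack.clear();
    stack.push_back(v);
    while (!stack.empty()) {
      R_xlen_t u = stack.back();
      stack.pop_back();
      ++size;
      int ui = (int)(u % nx);
      int uj = (int)((u / nx) % ny);
      int uk = (int)(u / ((R_xlen_t)nx * ny));
      for (int t = 0; t < nn; ++t) {
        int i = ui + di[t], j = uj + dj[t], kk = uk + dk[t];
        if (i < 0 || i >= nx || j < 0 || j >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)kk * nx * ny + (R_xlen_t)j * nx + i;
        if (supra[w] && !seen[w]) {
          seen[w] = 1;
          stack.push_back(w);
        }
      }
    }
    if (size > best) best = size;
  }
  return best;
}

// --- spin permutation null ---------------------------------------------
// Uniform-cell spatial hash over the unit sphere embedded in [-1,1]^3.
struct SphereGrid {
  int ncell;          // cells per axis
  double h;           // cell edge
  std::vector<std::vector<int> > cells;
  int n;
  const double *X;    // n x 3, column-major

  SphereGrid(const NumericMatrix &coords, int ncell_) : ncell(ncell_) {
    h = 2.0 / ncell;
    n = coords.nrow();
    X = coords.begin();
    cells.assign((size_t)ncell * ncell * ncell, std::vector<int>());
    for (int i = 0; i < n; ++i)
      cells[cell_of(X[i], X[i + n], X[i + 2 * n])].push_back(i);
  }
  inline int clampc(int c) const {
    return c < 0 ? 0 : (c >= ncell ? ncell - 1 : c);
  }
  inline size_t cell_of(double x, double y, double z) const {
    int cx = clampc((int)std::floor((x + 1.0) / h));
    int cy = clampc((int)std::floor((y + 1.0) / h));
    int cz = clampc((int)std::floor((z + 1.0) / h));
    return ((size_t)cz * ncell + cy) * ncell + cx;
  }
  // Nearest vertex to query point q (Euclidean == monotone in great-circle
  // distance on the unit sphere). Ties broken by lowest vertex index.
  int nearest(double qx, double qy, double qz) const {
    int cx = clampc((int)std::floor((qx + 1.0) / h));
    int cy = clampc((int)std::floor((qy + 1.0) / h));
    int cz = clampc((int)std::floor((qz + 1.0) / h));
    double best = 1e300;
    int bestj = -1;
    for (int ring = 0; ring < ncell; ++ring) {
      bool any = false;
      for (int a = cx - ring; a <= cx + ring; ++a) {
        if (a < 0 || a >= ncell) continue;
        for (int b = cy - ring; b <= cy + ring; ++b) {
          if (b < 0 || b >= ncell) continue;
          for (int c = cz - ring; c <= cz + ring; ++c) {
            if (c < 0 || c >= ncell) continue;
            // only the shell of Chebyshev radius `ring`
            if (std::max(std::abs(a - cx),
                         std::max(std::abs(b - cy), std::abs(c - cz))) != ring)
              continue;
            any = true;
            const std::vector<int> &cell =
                cells[((size_t)c * ncell + b) * ncell + a];
            for (size_t t = 0; t < cell.size(); ++t) {
              int j = cell[t];
              double dx = X[j] - qx, dy = X[j + n] - qy, dz = X[j + 2 * n] - qz;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best - 1e-12 ||
                  (std::fabs(d2 - best) <= 1e-12 && j < bestj)) {
                best = d2;
                bestj = j;
              }
            }
          }
        }
      }
      // Unvisited shells lie at Euclidean distance >= ring*h from q.
      if (bestj >= 0 && best <= (double)ring * h * (double)ring * h) break;
      if (!any && bestj >= 0) break;
    }
    return bestj;
  }
};

// Null Pearson correlations for the spin test. For permutation p with
// rotation R (3x3, column-major slab of `rotations`), the permuted map B
// value at vertex i is map_b[j], j = argmin_j angle(v_i, R v_j), i.e. the
// nearest original vertex to R^T v_i. Pairs where either map is invalid
// are dropped per permutation.
// [[Rcpp::export]]
NumericVector spin_null_r_cpp(NumericMatrix coords, NumericVector map_a,
                              LogicalVector valid_a, NumericVector map_b,
                              LogicalVector valid_b, NumericVector rotations,
                              int n_perm) {
  const int n = coords.nrow();
  int ncell = (int)std::floor(2.0 / std::sqrt(12.56637 / std::max(n, 100)));
  if (ncell < 4) ncell = 4;
  if (ncell > 64) ncell = 64;
  SphereGrid grid(coords, ncell);
  NumericVector out(n_perm);
  const double *X = coords.begin();

  for (int p = 0; p < n_perm; ++p) {
    const double *R = &rotations[(R_xlen_t)p * 9];  // column-major 3x3
    double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
    int m = 0;
    for (int i = 0; i < n; ++i) {
      if (!valid_a[i]) continue;
      double vx = X[i], vy = X[i + n], vz = X[i + 2 * n];
      // q = R^T v
      double qx = R[0] * vx + R[1] * vy + R[2] * vz;
      double qy = R[3] * vx + R[4] * vy + R[5] * vz;
      double qz = R[6] * vx + R[7] * vy + R[8] * vz;
      int j = grid.nearest(qx, qy, qz);
      if (j < 0 || !valid_b[j]) continue;
      double a = map_a[i], b = map_b[j];
      sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
      ++m;
    }
    if (m < 3) {
      out[p] = NA_REAL;
      continue;
    }
    double va = saa - sa * sa / m, vb = sbb - sb * sb / m;
    double cab = sab - sa * sb / m;
    out[p] = (va > 0 && vb > 0) ? cab / std::sqrt(va * vb) : NA_REAL;
  }
  return out;
}
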