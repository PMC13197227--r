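#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Column-major 3D indexing; voxel (i,j,k) <-> data[i + nx*(j + ny*k)], 0-based.
// All coordinates below are in voxel units, 0-based, origin at first-voxel centre.

static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double x, double y, double z) {
  // zero outside the grid
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return 0.0;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  const double* p = v + (size_t)i0 + (size_t)nx * ((size_t)j0 + (size_t)ny * k0);
  size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  double c000 = p[0], c100 = p[sx], c010 = p[sy], c110 = p[sx + sy];
  double c001 = p[sz], c101 = p[sx + sz], c011 = p[sy + sz], c111 = p[sx + sy + sz];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_interp(NumericVector vol, IntegerVector dims, NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  for (int i = 0; i < n; i++)
    out[i] = trilinear(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// out(p) = vol(A %*% p + b), p the 0-based voxel coordinate of the output grid
// [[Rcpp::export]]
NumericVector cpp_affine(NumericVector vol, IntegerVector dims,
                         IntegerVector out_dims, NumericMatrix A, NumericVector b) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  NumericVector out((size_t)ox * oy * oz);
  const double* v = vol.begin();
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2);
  size_t idx = 0;
  for (int k = 0; k < oz; k++)
    for (int j = 0; j < oy; j++) {
      double x0 = a01 * j + a02 * k + b[0];
      double y0 = a11 * j + a12 * k + b[1];
      double z0 = a21 * j + a22 * k + b[2];
      for (int i = 0; i < ox; i++, idx++)
        out[idx] = trilinear(v, nx, ny, nz,
                             a00 * i + x0, a10 * i + y0, a20 * i + z0);
    }
  return out;
}

// canvas(p) += patch(A %*% p + b) for p in [lo, hi] (0-based, inclusive); in place
// [[Rcpp::export]]
void cpp_add_transformed(NumericVector canvas, IntegerVector cdims,
                         NumericVector patch, IntegerVector pdims,
                         NumericMatrix A, NumericVector b,
                         IntegerVector lo, IntegerVector hi) {
  int nx = cdims[0], ny = cdims[1], nz = cdims[2];
  int px = pdims[0], py = pdims[1], pz = pdims[2];
  const double* pp = patch.begin();
  double* cv = canvas.begin();
  int i0 = std::max(0, (int)lo[0]), i1 = std::min(nx - 1, (int)hi[0]);
  int j0 = std::max(0, (int)lo[1]), j1 = std::min(ny - 1, (int)hi[1]);
  int k0 = std::max(0, (int)lo[2]), k1 = std::min(nz - 1, (int)hi[2]);
  for (int k = k0; k <= k1; k++)
    for (int j = j0; j <= j1; j++)
      for (int i = i0; i <= i1; i++) {
        double x = A(0, 0) * i + A(0, 1) * j + A(0, 2) * k + b[0];
        double y = A(1, 0) * i + A(1, 1) * j + A(1, 2) * k + b[1];
        double z = A(2, 0) * i + A(2, 1) * j + A(2, 2) * k + b[2];
        cv[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] +=
          trilinear(pp, px, py, pz, x, y, z);
      }
}

// Sum of isotropic Gaussians: dens += w * exp(-d^2 / (2 sigma^2)), truncated at
// cutoff_sigma; pts in voxel units, sigma per point in voxel units.
// [[Rcpp::export]]
void cpp_splat(NumericVector dens, IntegerVector dims, NumericMatrix pts,
               NumericVector w, NumericVector sigma, double cutoff_sigma,
               bool normalise) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double* v = dens.begin();
  for (int p = 0; p < pts.nrow(); p++) {
    double cx = pts(p, 0), cy = pts(p, 1), cz = pts(p, 2);
    double s = sigma[p], r = cutoff_sigma * s;
    double inv2s2 = 1.0 / (2.0 * s * s);
    // normalised: integral over voxels ~ w (unit voxel volume)
    double amp = normalise ? w[p] / std::pow(2.0 * M_PI * s * s, 1.5) : w[p];
    int i0 = std::max(0, (int)std::ceil(cx - r)), i1 = std::min(nx - 1, (int)std::floor(cx + r));
    int j0 = std::max(0, (int)std::ceil(cy - r)), j1 = std::min(ny - 1, (int)std::floor(cy + r));
    int k0 = std::max(0, (int)std::ceil(cz - r)), k1 = std::min(nz - 1, (int)std::floor(cz + r));
    for (int k = k0; k <= k1; k++) {
      double dz2 = (k - cz) * (k - cz);
      for (int j = j0; j <= j1; j++) {
        double dyz2 = (j - cy) * (j - cy) + dz2;
        for (int i = i0; i <= i1; i++) {
          double d2 = (i - cx) * (i - cx) + dyz2;
          v[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] +=
            amp * std::exp(-d2 * inv2s2);
        }
      }
    }
  }
}

// 26-connected reachability from seed voxels within a logical mask.
// seeds are 0-based linear indices. Returns logical vector: reachable.
// [[Rcpp::export]]
LogicalVector cpp_flood26(LogicalVector mask, IntegerVector dims, IntegerVector seeds) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> vis(n, 0);
  std::queue<size_t> q;
  for (int s = 0; s < seeds.size(); s++) {
    size_t idx = (size_t)seeds[s];
    if (idx < n && mask[idx] && !vis[idx]) { vis[idx] = 1; q.push(idx); }
  }
  while (!q.empty()) {
    size_t idx = q.front(); q.pop();
    int i = idx % nx, j = (idx / nx) % ny, k = idx / ((size_t)nx * ny);
    for (int dk = -1; dk <= 1; dk++)
      for (int dj = -1; dj <= 1; dj++)
        for (int di = -1; di <= 1; di++) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          size_t nidx = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk);
          if (mask[nidx] && !vis[nidx]) { vis[nidx] = 1; q.push(nidx); }
        }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; i++) out[i] = vis[i] != 0;
  return out;
}

// Bead fit score over a translation grid: score(t) = sum_b w_b * vol(p_b + t).
// pts in voxel units; shifts: m x 3 voxel offsets. Returns m scores.
// [[Rcpp::export]]
NumericVector cpp_bead_scores(NumericVector vol, IntegerVector dims,
                              NumericMatrix pts, NumericVector w,
                              NumericMatrix shifts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = vol.begin();
  int m = shifts.nrow(), nb = pts.nrow();
  NumericVector out(m);
  for (int s = 0; s < m; s++) {
    double acc = 0, sx = shifts(s, 0), sy = shifts(s, 1), sz = shifts(s, 2);
    for (int b = 0; b < nb; b++)
      acc += w[b] * trilinear(v, nx, ny, nz, pts(b, 0) + sx, pts(b, 1) + sy, pts(b, 2) + sz);
    out[s] = acc;
  }
  return out;
}
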