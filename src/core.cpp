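#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Arrays are column-major with dim (nz, ny, nx): linear = z + nz*(y + ny*x).

static inline int lin3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) along a strided
// line, with physical sampling step w.
static void dt1d(std::vector<double> &f, std::vector<double> &d, double w) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double qp = (double)q * w, vp = (double)v[k] * w;
      s = ((f[q] + qp * qp) - (f[v[k]] + vp * vp)) / (2.0 * qp - 2.0 * vp);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qp = (double)q * w;
    while (zb[k + 1] < qp) ++k;
    double vp = (double)v[k] * w;
    d[q] = (qp - vp) * (qp - vp) + f[v[k]];
  }
}

// Euclidean distance (physical units) from each foreground voxel to the
// nearest background voxel. mask: 1 = foreground. spacing: (z,y,x).
// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector mask, IntegerVector dim, NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double BIG = 1e30;
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = mask[i] ? BIG : 0.0;
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < nz; ++z) f[z] = out[lin3(z, y, x, nz, ny)];
        dt1d(f, d, spacing[0]);
        for (int z = 0; z < nz; ++z) out[lin3(z, y, x, nz, ny)] = d[z];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) f[y] = out[lin3(z, y, x, nz, ny)];
        dt1d(f, d, spacing[1]);
        for (int y = 0; y < ny; ++y) out[lin3(z, y, x, nz, ny)] = d[y];
      }
  }
  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        for (int x = 0; x < nx; ++x) f[x] = out[lin3(z, y, x, nz, ny)];
        dt1d(f, d, spacing[2]);
        for (int x = 0; x < nx; ++x) out[lin3(z, y, x, nz, ny)] = d[x];
      }
  }
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = std::sqrt(out[i]);
  return out;
}

struct QItem {
  double value;
  long order;
  int idx;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.value != b.value) return a.value < b.value; // max-heap on value
    return a.order > b.order;                          // FIFO among ties
  }
};

// Seeded watershed by priority flood, descending the landscape from the seeds.
// seeds: label volume (0 = unseeded). mask: voxels eligible for labeling.
// per_plane: if true, growth is confined to each z plane (4-connectivity);
// otherwise full 3D 6-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector landscape, IntegerVector mask,
                            IntegerVector seeds, IntegerVector dim,
                            bool per_plane) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector labels(mask.size(), 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long order = 0;
  for (R_xlen_t i = 0; i < seeds.size(); ++i) {
    if (seeds[i] > 0 && mask[i]) {
      labels[i] = seeds[i];
      pq.push({landscape[i], order++, (int)i});
    }
  }
  const int ndz[6] = {-1, 1, 0, 0, 0, 0};
  const int ndy[6] = {0, 0, -1, 1, 0, 0};
  const int ndx[6] = {0, 0, 0, 0, -1, 1};
  const int nb0 = per_plane ? 2 : 0; // skip z neighbors when per-plane
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    const int i = it.idx;
    const int x = i / (nz * ny), y = (i / nz) % ny, z = i % nz;
    const int lab = labels[i];
    for (int nn = nb0; nn < 6; ++nn) {
      const int zz = z + ndz[nn], yy = y + ndy[nn], xx = x + ndx[nn];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      const int j = lin3(zz, yy, xx, nz, ny);
      if (mask[j] && labels[j] == 0) {
        labels[j] = lab;
        pq.push({landscape[j], order++, j});
      }
    }
  }
  return labels;
}

// Local peaks of a landscape restricted to the mask: voxels >= all 26
// neighbours with value > 0; connected equal-value plateaus merged to the
// candidate nearest the plateau centroid; then greedy acceptance in
// descending value order subject to a Chebyshev minimum separation
// (anisotropy handled by per-axis separations, voxels).
// Returns 1-based linear indices of accepted peaks.
// [[Rcpp::export]]
IntegerVector cpp_find_peaks(NumericVector values, IntegerVector mask,
                             IntegerVector dim, IntegerVector min_sep) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = values.size();
  std::vector<char> cand(n, 0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const int i = lin3(z, y, x, nz, ny);
        if (!mask[i] || values[i] <= 0) continue;
        bool ok = true;
        for (int dz = -1; dz <= 1 && ok; ++dz)
          for (int dy = -1; dy <= 1 && ok; ++dy)
            for (int dx = -1; dx <= 1 && ok; ++dx) {
              if (!dz && !dy && !dx) continue;
              const int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
              if (values[lin3(zz, yy, xx, nz, ny)] > values[i]) ok = false;
            }
        if (ok) cand[i] = 1;
      }
  // merge connected equal-value plateaus (26-connectivity among candidates)
  std::vector<int> reps;
  std::vector<char> seen(n, 0);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!cand[s] || seen[s]) continue;
    std::vector<int> comp;
    std::vector<int> stack;
    stack.push_back((int)s);
    seen[s] = 1;
    const double v0 = values[s];
    while (!stack.empty()) {
      const int i = stack.back();
      stack.pop_back();
      comp.push_back(i);
      const int x = i / (nz * ny), y = (i / nz) % ny, z = i % nz;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            const int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            const int j = lin3(zz, yy, xx, nz, ny);
            if (cand[j] && !seen[j] && values[j] == v0) {
              seen[j] = 1;
              stack.push_back(j);
            }
          }
    }
    // representative: component member nearest the component centroid
    double cz = 0, cy = 0, cx = 0;
    for (int i : comp) {
      cz += i % nz;
      cy += (i / nz) % ny;
      cx += i / (nz * ny);
    }
    cz /= comp.size(); cy /= comp.size(); cx /= comp.size();
    int best = comp[0];
    double bd = INFINITY;
    for (int i : comp) {
      const double dz = i % nz - cz, dy = (i / nz) % ny - cy, dx = i / (nz * ny) - cx;
      const double d2 = dz * dz + dy * dy + dx * dx;
      if (d2 < bd || (d2 == bd && i < best)) { bd = d2; best = i; }
    }
    reps.push_back(best);
  }
  // greedy acceptance, descending value, stable by linear index
  std::sort(reps.begin(), reps.end(), [&](int a, int b) {
    if (values[a] != values[b]) return values[a] > values[b];
    return a < b;
  });
  std::vector<int> acc;
  const int sz = min_sep[0], sy = min_sep[1], sx = min_sep[2];
  for (int i : reps) {
    const int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
    bool ok = true;
    for (int j : acc) {
      const int zj = j % nz, yj = (j / nz) % ny, xj = j / (nz * ny);
      if (std::abs(z - zj) <= sz && std::abs(y - yj) <= sy && std::abs(x - xj) <= sx) {
        ok = false;
        break;
      }
    }
    if (ok) acc.push_back(i);
  }
  IntegerVector out(acc.size());
  for (size_t k = 0; k < acc.size(); ++k) out[k] = acc[k] + 1;
  return out;
}

// im2col for 3D convolution with zero padding ('same'). Input x has dim
// (nz, ny, nx, C); kernel (kz, ky, kx). Output matrix:
// rows = C*kz*ky*kx (row = c*kz*ky*kx + dz + kz*(dy + ky*dx)), cols = nz*ny*nx.
// [[Rcpp::export]]
NumericMatrix cpp_im2col3d(NumericVector x, IntegerVector dim, IntegerVector k) {
  const int nz = dim[0], ny = dim[1], nx = dim[2], C = dim[3];
  const int kz = k[0], ky = k[1], kx = k[2];
  const int hz = kz / 2, hy = ky / 2, hx = kx / 2;
  const int K = kz * ky * kx;
  const int nvox = nz * ny * nx;
  NumericMatrix out(C * K, nvox);
  for (int xx = 0; xx < nx; ++xx)
    for (int yy = 0; yy < ny; ++yy)
      for (int zz = 0; zz < nz; ++zz) {
        const int col = lin3(zz, yy, xx, nz, ny);
        double *dst = &out(0, col);
        for (int c = 0; c < C; ++c) {
          const double *src = &x[(R_xlen_t)c * nvox];
          for (int dx = 0; dx < kx; ++dx) {
            const int sx2 = xx + dx - hx;
            for (int dy = 0; dy < ky; ++dy) {
              const int sy2 = yy + dy - hy;
              for (int dz = 0; dz < kz; ++dz) {
                const int sz2 = zz + dz - hz;
                const int row = c * K + dz + kz * (dy + ky * dx);
                if (sz2 < 0 || sz2 >= nz || sy2 < 0 || sy2 >= ny || sx2 < 0 || sx2 >= nx)
                  dst[row] = 0.0;
                else
                  dst[row] = src[lin3(sz2, sy2, sx2, nz, ny)];
              }
            }
          }
        }
      }
  return out;
}

// Adjoint of cpp_im2col3d: scatter-add columns back into an image gradient.
// [[Rcpp::export]]
NumericVector cpp_col2im3d(NumericMatrix cols, IntegerVector dim, IntegerVector k) {
  const int nz = dim[0], ny = dim[1], nx = dim[2], C = dim[3];
  const int kz = k[0], ky = k[1], kx = k[2];
  const int hz = kz / 2, hy = ky / 2, hx = kx / 2;
  const int K = kz * ky * kx;
  const int nvox = nz * ny * nx;
  NumericVector out((R_xlen_t)nvox * C);
  for (int xx = 0; xx < nx; ++xx)
    for (int yy = 0; yy < ny; ++yy)
      for (int zz = 0; zz < nz; ++zz) {
        const int col = lin3(zz, yy, xx, nz, ny);
        const double *src = &cols(0, col);
        for (int c = 0; c < C; ++c) {
          double *dst = &out[(R_xlen_t)c * nvox];
          for (int dx = 0; dx < kx; ++dx) {
            const int sx2 = xx + dx - hx;
            if (sx2 < 0 || sx2 >= nx) continue;
            for (int dy = 0; dy < ky; ++dy) {
              const int sy2 = yy + dy - hy;
              if (sy2 < 0 || sy2 >= ny) continue;
              for (int dz = 0; dz < kz; ++dz) {
                const int sz2 = zz + dz - hz;
                if (sz2 < 0 || sz2 >= nz) continue;
                const int row = c * K + dz + kz * (dy + ky * dx);
                dst[lin3(sz2, sy2, sx2, nz, ny)] += src[row];
              }
            }
          }
        }
      }
  return out;
}
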