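// 3D morphology primitives shared by the marrow and focal modules:
//  - anisotropy-aware Euclidean distance transform (separable, exact)
//  - watershed by descending flooding with deterministic plateau handling
//  - connected-component labelling (6/18/26 neighbourhoods)
// All operate on flattened column-major arrays (R layout).

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::max() / 4.0;

// Exact 1D squared-distance transform (lower envelope of parabolas) for
// samples at physical positions i * step. f holds squared distances on
// input and output.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double step) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double fq = f[q];
    double s;
    while (true) {
      int p = v[k];
      // intersection of parabolas rooted at p and q (in grid units)
      s = ((fq + q * (double)q * s2) - (f[p] + p * (double)p * s2)) /
          (2.0 * s2 * (q - p));
      if (s <= z[k]) { --k; } else { break; }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest
// feature voxel. `feature` is a logical array of length prod(dim).
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector feature, IntegerVector dim,
                       NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (feature.size() != n) stop("feature length does not match dim");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      for (int xx = 0; xx < nx; ++xx) f[xx] = out[base + xx];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int xx = 0; xx < nx; ++xx) out[base + xx] = f[xx];
    }
  // pass along y
  for (int zz = 0; zz < nz; ++zz)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = xx + (R_xlen_t)nx * ny * (R_xlen_t)zz;
      for (int yy = 0; yy < ny; ++yy) f[yy] = out[base + (R_xlen_t)nx * yy];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int yy = 0; yy < ny; ++yy) out[base + (R_xlen_t)nx * yy] = f[yy];
    }
  // pass along z
  const R_xlen_t stridez = (R_xlen_t)nx * ny;
  for (int yy = 0; yy < ny; ++yy)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = xx + (R_xlen_t)nx * yy;
      for (int zz = 0; zz < nz; ++zz) f[zz] = out[base + stridez * zz];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int zz = 0; zz < nz; ++zz) out[base + stridez * zz] = f[zz];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] >= INF) out[i] = R_PosInf;
  return out;
}

static void neighbour_offsets(int connectivity, int nx, int ny,
                              std::vector<int64_t>& off,
                              std::vector<int>& dxs, std::vector<int>& dys,
                              std::vector<int>& dzs) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int order = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && order > 1) continue;
        if (connectivity == 18 && order > 2) continue;
        off.push_back((int64_t)dx + (int64_t)nx * (dy + (int64_t)ny * dz));
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
}

struct UnionFind {
  std::vector<int> parent;
  int make() { parent.push_back((int)parent.size()); return (int)parent.size() - 1; }
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  void link(int a, int b) { parent[find(a)] = find(b); } // a into b
};

// Watershed of the *negated* intensity landscape: every voxel is assigned
// to the catchment basin of a regional maximum of `values`. Voxels are
// flooded in order of decreasing value with ties broken by ascending
// linear index; equal-valued plateau fragments that turn out to be
// connected are merged so each regional-maximum plateau yields exactly one
// basin. Returns 1-based basin labels and, per basin, the 1-based linear
// index of its maximum (the smallest-index voxel attaining the basin peak).
// [[Rcpp::export(name = ".watershed3d")]]
List watershed3d(NumericVector values, IntegerVector dim,
                 int connectivity = 26) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (values.size() != n) stop("values length does not match dim");

  std::vector<int64_t> off; std::vector<int> dxs, dys, dzs;
  neighbour_offsets(connectivity, nx, ny, off, dxs, dys, dzs);
  const int noff = (int)off.size();

  std::vector<int> order(n);
  for (R_xlen_t i = 0; i < n; ++i) order[i] = (int)i;
  const double* val = REAL(values);
  std::stable_sort(order.begin(), order.end(),
                   [val](int a, int b) { return val[a] > val[b]; });

  std::vector<int> label(n, -1);          // basin id per voxel, -1 unprocessed
  UnionFind uf;
  std::vector<int> basin_max;             // linear index of each basin's maximum

  for (R_xlen_t k = 0; k < n; ++k) {
    const int idx = order[k];
    const double v = val[idx];
    const int xx = idx % nx;
    const int yy = (idx / nx) % ny;
    const int zz = idx / (nx * ny);

    int best = -1;              // root of the steepest neighbour's basin
    double best_val = -INF;
    int best_nb = -1;
    // roots of equal-level plateau basins seen among neighbours
    int plateau_roots[26];
    int n_plateau = 0;

    for (int j = 0; j < noff; ++j) {
      int x2 = xx + dxs[j];
      if (x2 < 0 || x2 >= nx) continue;
      int y2 = yy + dys[j];
      if (y2 < 0 || y2 >= ny) continue;
      int z2 = zz + dzs[j];
      if (z2 < 0 || z2 >= nz) continue;
      int nb = (int)(idx + off[j]);
      int lb = label[nb];
      if (lb < 0) continue;               // not yet flooded
      int root = uf.find(lb);
      double nv = val[nb];
      // steepest-ascent assignment: follow the highest neighbour,
      // breaking ties by lexicographic (linear index) order
      if (nv > best_val || (nv == best_val && nb < best_nb)) {
        best_val = nv; best_nb = nb; best = root;
      }
      if (val[basin_max[root]] == v) {    // plateau-level basin
        bool seen = false;
        for (int t = 0; t < n_plateau; ++t)
          if (plateau_roots[t] == root) { seen = true; break; }
        if (!seen) plateau_roots[n_plateau++] = root;
      }
    }

    if (best < 0) {
      int b = uf.make();
      basin_max.push_back(idx);
      label[idx] = b;
    } else {
      label[idx] = best;
      // connecting through an equal-valued voxel: plateau fragments whose
      // peak sits at this level belong to the same regional structure
      for (int t = 0; t < n_plateau; ++t) {
        int root = uf.find(plateau_roots[t]);
        if (root != uf.find(best)) {
          // keep the target basin's maximum
          int keep = uf.find(best);
          int mi_keep = basin_max[keep];
          int mi_drop = basin_max[root];
          // when both peaks sit at the same level, keep smallest index
          int mi = (val[mi_keep] > val[mi_drop]) ? mi_keep
                   : (val[mi_drop] > val[mi_keep]) ? mi_drop
                   : std::min(mi_keep, mi_drop);
          uf.link(root, keep);
          basin_max[uf.find(keep)] = mi;
        }
      }
    }
  }

  // compact basin ids
  std::vector<int> remap(uf.parent.size(), 0);
  int nb = 0;
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int root = uf.find(label[i]);
    if (remap[root] == 0) remap[root] = ++nb;
    out[i] = remap[root];
  }
  IntegerVector maxima(nb);
  for (size_t r = 0; r < uf.parent.size(); ++r)
    if ((int)r == uf.find((int)r) && remap[r] > 0)
      maxima[remap[r] - 1] = basin_max[r] + 1;   // 1-based for R
  return List::create(_["labels"] = out, _["maxima"] = maxima);
}

// Label connected components of a binary mask; 0 = background.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dim,
                               int connectivity = 26) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");

  std::vector<int64_t> off; std::vector<int> dxs, dys, dzs;
  neighbour_offsets(connectivity, nx, ny, off, dxs, dys, dzs);
  const int noff = (int)off.size();

  IntegerVector out(n, 0);
  std::vector<int> stack;
  int comp = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || out[i] != 0) continue;
    ++comp;
    out[i] = comp;
    stack.push_back((int)i);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int xx = cur % nx, yy = (cur / nx) % ny, zz = cur / (nx * ny);
      for (int j = 0; j < noff; ++j) {
        int x2 = xx + dxs[j];
        if (x2 < 0 || x2 >= nx) continue;
        int y2 = yy + dys[j];
        if (y2 < 0 || y2 >= ny) continue;
        int z2 = zz + dzs[j];
        if (z2 < 0 || z2 >= nz) continue;
        int nb2 = (int)(cur + off[j]);
        if (mask[nb2] && out[nb2] == 0) {
          out[nb2] = comp;
          stack.push_back(nb2);
        }
      }
    }
  }
  return out;
}
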