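#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Union-find with path halving; size stored at roots.
static inline int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void neighbour_offsets(int connectivity, std::vector<int>& dxs,
                              std::vector<int>& dys, std::vector<int>& dzs) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
}

// One-sided TFCE on a 3D grid; values <= 0 are inactive (callers split a
// signed map into positive and negated-negative passes).
//
// The suprathreshold cluster of a voxel is piecewise constant in the
// threshold h, changing only where h crosses a voxel height. With dh <= 0
// the TFCE integral is therefore evaluated EXACTLY: descending through the
// distinct heights h_1 > h_2 > ... (h_{M+1} = 0), every cluster present on
// the interval (h_{j+1}, h_j] contributes
//   size^E * (h_j^{H+1} - h_{j+1}^{H+1}) / (H + 1)
// to each member voxel. A single union-find sweep inserts each voxel once;
// per-cluster contributions are accumulated lazily at the roots, with an
// offset recorded at every merge so that contributions made to a cluster
// before a sub-cluster joined are not credited to the late joiners. A final
// reverse pass over the merge forest resolves per-voxel totals.
//
// With dh > 0 the conventional step approximation is computed instead:
// midpoint thresholds h_k = (k - 1/2) * dh, each contributing
// size^E * h_k^H * dh (the O(dh^2) midpoint rule).
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector values, IntegerVector dim,
                       double E, double H, double dh, int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  if (values.size() != n) stop("values length does not match dim");

  NumericVector out(n);
  double vmax = 0.0;
  for (int i = 0; i < n; ++i) if (values[i] > vmax) vmax = values[i];
  if (vmax <= 0.0) return out;

  std::vector<int> dxs, dys, dzs;
  neighbour_offsets(connectivity, dxs, dys, dzs);
  const int nb = (int)dxs.size();

  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i) if (values[i] > 0.0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return values[a] > values[b]; });

  std::vector<int> parent(n, -1), csize(n, 0);

  // merge candidate neighbours of voxel v into its cluster
  auto link_neighbours = [&](int v) {
    const int z = v / (nx * ny);
    const int rem = v - z * nx * ny;
    const int y = rem / nx;
    const int x = rem - y * nx;
    for (int j = 0; j < nb; ++j) {
      const int xx = x + dxs[j], yy = y + dys[j], zz = z + dzs[j];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      const int w = xx + nx * (yy + ny * zz);
      if (parent[w] < 0) continue;
      int rv = uf_find(parent, v), rw = uf_find(parent, w);
      if (rv != rw) {
        if (csize[rv] < csize[rw]) std::swap(rv, rw);
        parent[rw] = rv;
        csize[rv] += csize[rw];
      }
    }
  };

  if (dh > 0.0) {
    // midpoint step approximation
    const int K = (int)std::floor(vmax / dh + 0.5);
    std::vector<double> pow_cache(n, 0.0);
    std::vector<int> pow_stamp(n, -1);
    std::vector<int> active;
    active.reserve(order.size());
    size_t next = 0;
    for (int k = K; k >= 1; --k) {
      const double h = (k - 0.5) * dh;
      while (next < order.size() && values[order[next]] >= h) {
        const int v = order[next++];
        parent[v] = v; csize[v] = 1;
        active.push_back(v);
        link_neighbours(v);
      }
      const double hterm = std::pow(h, H) * dh;
      for (size_t a = 0; a < active.size(); ++a) {
        const int v = active[a];
        const int r = uf_find(parent, v);
        if (pow_stamp[r] != k) {
          pow_cache[r] = std::pow((double)csize[r], E);
          pow_stamp[r] = k;
        }
        out[v] += pow_cache[r] * hterm;
      }
    }
    return out;
  }

  // exact integral over the piecewise-constant cluster function
  std::vector<double> acc(n, 0.0);          // per-root lazy accumulator
  std::vector<int> merge_child, merge_parent;
  std::vector<double> merge_offset;         // -acc[parent] at merge time
  std::vector<int> roots, stamp(n, -1);
  roots.reserve(256);

  size_t next = 0;
  int level = 0;
  while (next < order.size()) {
    const double h = values[order[next]];
    while (next < order.size() && values[order[next]] == h) {
      const int v = order[next++];
      parent[v] = v; csize[v] = 1;
      // record merges with offsets (union by size, as in link_neighbours)
      const int z = v / (nx * ny);
      const int rem = v - z * nx * ny;
      const int y = rem / nx;
      const int x = rem - y * nx;
      for (int j = 0; j < nb; ++j) {
        const int xx = x + dxs[j], yy = y + dys[j], zz = z + dzs[j];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const int w = xx + nx * (yy + ny * zz);
        if (parent[w] < 0) continue;
        int rv = uf_find(parent, v), rw = uf_find(parent, w);
        if (rv == rw) continue;
        if (csize[rv] < csize[rw]) std::swap(rv, rw);
        parent[rw] = rv;
        csize[rv] += csize[rw];
        merge_child.push_back(rw);
        merge_parent.push_back(rv);
        merge_offset.push_back(-acc[rv]);
      }
    }
    const double h_next = (next < order.size()) ? values[order[next]] : 0.0;
    const double term = (std::pow(h, H + 1.0) - std::pow(h_next, H + 1.0)) /
                        (H + 1.0);
    // refresh the root list for this level and credit each live cluster
    std::vector<int> new_roots;
    new_roots.reserve(roots.size() + 8);
    for (size_t a = 0; a < roots.size(); ++a) {
      const int r = uf_find(parent, roots[a]);
      if (stamp[r] != level) { stamp[r] = level; new_roots.push_back(r); }
    }
    // include roots created this level (voxels inserted above)
    for (size_t a = next; a-- > 0; ) {
      const int v = order[a];
      if (values[v] != h) break;
      const int r = uf_find(parent, v);
      if (stamp[r] != level) { stamp[r] = level; new_roots.push_back(r); }
    }
    for (size_t a = 0; a < new_roots.size(); ++a) {
      const int r = new_roots[a];
      acc[r] += std::pow((double)csize[r], E) * term;
    }
    roots.swap(new_roots);
    ++level;
  }

  // resolve per-voxel totals: replay merges in reverse, folding each
  // child's accumulator into its (already final) parent total
  std::vector<double> total(n, 0.0);
  for (size_t a = 0; a < order.size(); ++a) total[order[a]] = acc[order[a]];
  for (size_t m = merge_child.size(); m-- > 0; )
    total[merge_child[m]] += merge_offset[m] + total[merge_parent[m]];
  for (size_t a = 0; a < order.size(); ++a) out[order[a]] = total[order[a]];
  return out;
}
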