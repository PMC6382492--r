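// Low-level voxel-grid primitives shared by the segmentation pipeline.
// All grids are passed as flat vectors in R's column-major layout
// (index = i + nx*(j + ny*k), 0-based here) with explicit dimensions.
// Outside-grid voxels are treated as background throughout.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(mask.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool hit = false;
        for (int dk = -1; dk <= 1 && !hit; ++dk) {
          const int kk = k + dk;
          if (kk < 0 || kk >= nz) continue;
          for (int dj = -1; dj <= 1 && !hit; ++dj) {
            const int jj = j + dj;
            if (jj < 0 || jj >= ny) continue;
            for (int di = -1; di <= 1; ++di) {
              const int ii = i + di;
              if (ii < 0 || ii >= nx) continue;
              if (mask[lin(ii, jj, kk, nx, ny)]) { hit = true; break; }
            }
          }
        }
        out[lin(i, j, k, nx, ny)] = hit;
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(mask.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int idx = lin(i, j, k, nx, ny);
        if (!mask[idx]) { out[idx] = false; continue; }
        bool all = true;
        for (int dk = -1; dk <= 1 && all; ++dk) {
          const int kk = k + dk;
          for (int dj = -1; dj <= 1 && all; ++dj) {
            const int jj = j + dj;
            for (int di = -1; di <= 1; ++di) {
              const int ii = i + di;
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz ||
                  !mask[lin(ii, jj, kk, nx, ny)]) { all = false; break; }
            }
          }
        }
        out[idx] = all;
      }
  return out;
}

// Fill background cavities: a cavity is a background region with no
// 6-connected path to the grid border.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = mask.size();
  std::vector<char> outside(n, 0);
  std::queue<int> q;
  // seed from every border background voxel
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && i != nx - 1 && j != 0 && j != ny - 1 && k != 0 && k != nz - 1)
          continue;
        const int idx = lin(i, j, k, nx, ny);
        if (!mask[idx] && !outside[idx]) { outside[idx] = 1; q.push(idx); }
      }
  const int d6i[6] = {1, -1, 0, 0, 0, 0};
  const int d6j[6] = {0, 0, 1, -1, 0, 0};
  const int d6k[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    const int idx = q.front(); q.pop();
    const int k = idx / (nx * ny), r = idx % (nx * ny);
    const int j = r / nx, i = r % nx;
    for (int m = 0; m < 6; ++m) {
      const int ii = i + d6i[m], jj = j + d6j[m], kk = k + d6k[m];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      const int nb = lin(ii, jj, kk, nx, ny);
      if (!mask[nb] && !outside[nb]) { outside[nb] = 1; q.push(nb); }
    }
  }
  LogicalVector out(n);
  for (int idx = 0; idx < n; ++idx) out[idx] = mask[idx] || !outside[idx];
  return out;
}

// Breadth-first labelling of connected components; connectivity 6 or 26.
// Labels are 1..k in scan order; deterministic reordering happens in R.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = mask.size();
  IntegerVector labels(n, 0);
  std::vector<int> di, dj, dk;
  for (int ck = -1; ck <= 1; ++ck)
    for (int cj = -1; cj <= 1; ++cj)
      for (int ci = -1; ci <= 1; ++ci) {
        if (ci == 0 && cj == 0 && ck == 0) continue;
        if (connectivity == 6 && std::abs(ci) + std::abs(cj) + std::abs(ck) != 1)
          continue;
        di.push_back(ci); dj.push_back(cj); dk.push_back(ck);
      }
  const int nn = (int) di.size();
  int next = 0;
  std::queue<int> q;
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    labels[start] = ++next;
    q.push(start);
    while (!q.empty()) {
      const int idx = q.front(); q.pop();
      const int k = idx / (nx * ny), r = idx % (nx * ny);
      const int j = r / nx, i = r % nx;
      for (int m = 0; m < nn; ++m) {
        const int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        const int nb = lin(ii, jj, kk, nx, ny);
        if (mask[nb] && labels[nb] == 0) { labels[nb] = next; q.push(nb); }
      }
    }
  }
  return labels;
}

// Detect weak-link voxels: a true voxel whose 26-neighbourhood contains
// exactly two true voxels and those two are the opposite face neighbours
// along a single axis. Detection is simultaneous on the input mask.
// [[Rcpp::export]]
LogicalVector cpp_weak_links(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector weak(mask.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int idx = lin(i, j, k, nx, ny);
        weak[idx] = false;
        if (!mask[idx]) continue;
        int count = 0;
        bool xm = false, xp = false, ym = false, yp = false, zm = false, zp = false;
        for (int dk = -1; dk <= 1; ++dk) {
          const int kk = k + dk;
          if (kk < 0 || kk >= nz) continue;
          for (int dj = -1; dj <= 1; ++dj) {
            const int jj = j + dj;
            if (jj < 0 || jj >= ny) continue;
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              const int ii = i + di;
              if (ii < 0 || ii >= nx) continue;
              if (!mask[lin(ii, jj, kk, nx, ny)]) continue;
              ++count;
              if (dj == 0 && dk == 0 && di == -1) xm = true;
              if (dj == 0 && dk == 0 && di ==  1) xp = true;
              if (di == 0 && dk == 0 && dj == -1) ym = true;
              if (di == 0 && dk == 0 && dj ==  1) yp = true;
              if (di == 0 && dj == 0 && dk == -1) zm = true;
              if (di == 0 && dj == 0 && dk ==  1) zp = true;
            }
          }
        }
        if (count == 2 && ((xm && xp) || (ym && yp) || (zm && zp)))
          weak[idx] = true;
      }
  return weak;
}

// Geodesic quasi-euclidean distance: Dijkstra over 26-neighbour steps with
// costs sqrt(sum (d*spacing)^2) (1, sqrt2, sqrt3 for unit spacing), from the
// seed set, restricted to traversable voxels (domain OR seed). Non-traversable
// and unreachable voxels get +Inf.
// [[Rcpp::export]]
NumericVector cpp_geodesic(LogicalVector seed, LogicalVector domain,
                           IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = seed.size();
  NumericVector dist(n, R_PosInf);
  std::vector<char> trav(n);
  for (int idx = 0; idx < n; ++idx) trav[idx] = (seed[idx] || domain[idx]) ? 1 : 0;

  std::vector<int> di, dj, dk;
  std::vector<double> cost;
  for (int ck = -1; ck <= 1; ++ck)
    for (int cj = -1; cj <= 1; ++cj)
      for (int ci = -1; ci <= 1; ++ci) {
        if (ci == 0 && cj == 0 && ck == 0) continue;
        di.push_back(ci); dj.push_back(cj); dk.push_back(ck);
        cost.push_back(std::sqrt(ci * ci * spacing[0] * spacing[0] +
                                 cj * cj * spacing[1] * spacing[1] +
                                 ck * ck * spacing[2] * spacing[2]));
      }
  const int nn = (int) di.size();

  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int idx = 0; idx < n; ++idx)
    if (seed[idx]) { dist[idx] = 0.0; pq.push(Node(0.0, idx)); }

  while (!pq.empty()) {
    const Node top = pq.top(); pq.pop();
    const double d = top.first;
    const int idx = top.second;
    if (d > dist[idx]) continue;
    const int k = idx / (nx * ny), r = idx % (nx * ny);
    const int j = r / nx, i = r % nx;
    for (int m = 0; m < nn; ++m) {
      const int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      const int nb = lin(ii, jj, kk, nx, ny);
      if (!trav[nb]) continue;
      const double nd = d + cost[m];
      if (nd < dist[nb]) { dist[nb] = nd; pq.push(Node(nd, nb)); }
    }
  }
  return dist;
}
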