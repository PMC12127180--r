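#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Voxel grids arrive as flat vectors in R column-major order with dims
// (d1, d2, d3) = (z, y, x) and voxel spacing vox = (dz, dy, dx) in um.
// All indices crossing the R boundary are 1-based.

static inline long long idx3(int i, int j, int k, int d1, int d2) {
  return (long long)i + (long long)d1 * ((long long)j + (long long)d2 * k);
}

struct Nbr { int di, dj, dk; double len; };

static std::vector<Nbr> neighbours26(const NumericVector& vox) {
  std::vector<Nbr> nb;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj)
      for (int dk = -1; dk <= 1; ++dk) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        double len = std::sqrt(di * di * vox[0] * vox[0] +
                               dj * dj * vox[1] * vox[1] +
                               dk * dk * vox[2] * vox[2]);
        nb.push_back({di, dj, dk, len});
      }
  return nb;
}

// Connected-component labelling, 26-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector fg, IntegerVector dims) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  long long n = (long long)d1 * d2 * d3;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<long long> stack;
  for (long long s = 0; s < n; ++s) {
    if (!fg[s] || lab[s]) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      long long v = stack.back(); stack.pop_back();
      int i = (int)(v % d1);
      int j = (int)((v / d1) % d2);
      int k = (int)(v / ((long long)d1 * d2));
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj)
          for (int dk = -1; dk <= 1; ++dk) {
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
              continue;
            long long w = idx3(ii, jj, kk, d1, d2);
            if (fg[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
          }
    }
  }
  return lab;
}

// Two-pass anisotropic chamfer distance transform (distance, in um, from each
// foreground voxel to the nearest background voxel; 0 outside).
// [[Rcpp::export]]
NumericVector cpp_chamfer_dt(LogicalVector fg, IntegerVector dims,
                             NumericVector vox) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  long long n = (long long)d1 * d2 * d3;
  double big = 1e30;
  NumericVector dt(n);
  for (long long s = 0; s < n; ++s) dt[s] = fg[s] ? big : 0.0;
  std::vector<Nbr> nb = neighbours26(vox);
  // forward pass uses neighbours preceding in scan order, backward the rest
  for (int pass = 0; pass < 2; ++pass) {
    bool fwd = (pass == 0);
    for (long long t = 0; t < n; ++t) {
      long long s = fwd ? t : (n - 1 - t);
      if (!fg[s]) continue;
      int i = (int)(s % d1);
      int j = (int)((s / d1) % d2);
      int k = (int)(s / ((long long)d1 * d2));
      double best = dt[s];
      for (const Nbr& e : nb) {
        // neighbour must precede current voxel in this pass's scan order
        long long off = e.di + (long long)d1 * (e.dj + (long long)d2 * e.dk);
        if (fwd ? (off >= 0) : (off <= 0)) continue;
        int ii = i + e.di, jj = j + e.dj, kk = k + e.dk;
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3) {
          // outside the grid counts as background
          if (e.len < best) best = e.len;
          continue;
        }
        double cand = dt[idx3(ii, jj, kk, d1, d2)] + e.len;
        if (cand < best) best = cand;
      }
      dt[s] = best;
    }
  }
  // boundary voxels adjacent to the grid edge in a face direction
  for (long long s = 0; s < n; ++s)
    if (fg[s] && dt[s] >= big) dt[s] = 0.0; // isolated pathologies
  return dt;
}

// Dijkstra over foreground voxels. Edge cost between adjacent voxels a,b is
//   len(a,b) * (w[a] + w[b]) / 2
// With w == 1 this is geodesic distance; with w = 1/dt^2 paths hug the
// medial axis (classic medialness-weighted centerline extraction).
static void dijkstra(const LogicalVector& fg, int d1, int d2, int d3,
                     const std::vector<Nbr>& nb, const NumericVector& w,
                     long long src, std::vector<double>& dist,
                     std::vector<long long>& prev) {
  long long n = (long long)d1 * d2 * d3;
  dist.assign(n, std::numeric_limits<double>::infinity());
  prev.assign(n, -1);
  typedef std::pair<double, long long> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  dist[src] = 0.0;
  pq.push({0.0, src});
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first; long long v = top.second;
    if (d > dist[v]) continue;
    int i = (int)(v % d1);
    int j = (int)((v / d1) % d2);
    int k = (int)(v / ((long long)d1 * d2));
    for (const Nbr& e : nb) {
      int ii = i + e.di, jj = j + e.dj, kk = k + e.dk;
      if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
        continue;
      long long u = idx3(ii, jj, kk, d1, d2);
      if (!fg[u]) continue;
      double cost = d + e.len * 0.5 * (w[v] + w[u]);
      if (cost < dist[u]) {
        dist[u] = cost;
        prev[u] = v;
        pq.push({cost, u});
      }
    }
  }
}

// Farthest foreground voxel (geodesic) from a 1-based start index.
// [[Rcpp::export]]
long long cpp_geodesic_farthest(LogicalVector fg, IntegerVector dims,
                                NumericVector vox, double start1) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  std::vector<Nbr> nb = neighbours26(vox);
  long long n = (long long)d1 * d2 * d3;
  NumericVector w(n, 1.0);
  std::vector<double> dist; std::vector<long long> prev;
  dijkstra(fg, d1, d2, d3, nb, w, (long long)start1 - 1, dist, prev);
  long long best = (long long)start1 - 1;
  double bd = -1.0;
  for (long long s = 0; s < n; ++s)
    if (fg[s] && std::isfinite(dist[s]) && dist[s] > bd) { bd = dist[s]; best = s; }
  return best + 1;
}

// Minimum-cost medial path between two 1-based voxel indices.
// [[Rcpp::export]]
NumericVector cpp_medial_path(LogicalVector fg, IntegerVector dims,
                              NumericVector vox, NumericVector dt,
                              double from1, double to1) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  long long n = (long long)d1 * d2 * d3;
  std::vector<Nbr> nb = neighbours26(vox);
  double vmin = std::min(vox[0], std::min(vox[1], vox[2]));
  NumericVector w(n);
  for (long long s = 0; s < n; ++s) {
    double d = dt[s] > 0.5 * vmin ? dt[s] : 0.5 * vmin;
    w[s] = 1.0 / (d * d);
  }
  std::vector<double> dist; std::vector<long long> prev;
  dijkstra(fg, d1, d2, d3, nb, w, (long long)from1 - 1, dist, prev);
  long long cur = (long long)to1 - 1;
  if (!std::isfinite(dist[cur])) return NumericVector(0);
  std::vector<double> path;
  while (cur >= 0) {
    path.push_back((double)(cur + 1));
    if (cur == (long long)from1 - 1) break;
    cur = prev[cur];
  }
  std::reverse(path.begin(), path.end());
  return wrap(path);
}

// Separable Gaussian blur with reflective boundaries; sigma in voxels,
// identical along all three axes (matching a plain image-stack blur).
// [[Rcpp::export]]
NumericVector cpp_blur3d(NumericVector vol, IntegerVector dims, double sigma) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  long long n = (long long)d1 * d2 * d3;
  if (sigma <= 0) return clone(vol);
  int half = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * half + 1);
  double ks = 0.0;
  for (int t = -half; t <= half; ++t) {
    ker[t + half] = std::exp(-0.5 * t * t / (sigma * sigma));
    ks += ker[t + half];
  }
  for (double& v : ker) v /= ks;
  NumericVector a = clone(vol), b(n);
  int dsz[3] = {d1, d2, d3};
  long long strd[3] = {1, d1, (long long)d1 * d2};
  for (int ax = 0; ax < 3; ++ax) {
    int len = dsz[ax];
    long long st = strd[ax];
    for (long long s = 0; s < n; ++s) {
      int i = (int)(s % d1);
      int j = (int)((s / d1) % d2);
      int k = (int)(s / ((long long)d1 * d2));
      int pos = (ax == 0) ? i : (ax == 1 ? j : k);
      double acc = 0.0;
      for (int t = -half; t <= half; ++t) {
        int p = pos + t;
        if (p < 0) p = -p - 1;           // reflect
        if (p >= len) p = 2 * len - p - 1;
        acc += ker[t + half] * a[s + (long long)(p - pos) * st];
      }
      b[s] = acc;
    }
    std::swap(a, b);
  }
  return a;
}
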