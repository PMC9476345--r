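#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Level maps arrive as flattened 3D integer arrays (column-major, dims d),
// with 0 marking out-of-mask voxels and 1..Ng the discretized gray levels.
// Out-of-mask voxels never contribute to any matrix: they break runs,
// separate zones and are excluded from neighborhoods (no zero padding).

static const int NDIR = 13;
static const int DIRS[NDIR][3] = {
  {1,0,0}, {0,1,0}, {0,0,1},
  {1,1,0}, {1,-1,0}, {1,0,1}, {1,0,-1}, {0,1,1}, {0,1,-1},
  {1,1,1}, {1,-1,1}, {1,1,-1}, {1,-1,-1}
};

static inline int idx3(int i, int j, int k, int d1, int d2) {
  return i + d1 * (j + d2 * k);
}
static inline bool inside(int i, int j, int k, int d1, int d2, int d3) {
  return i >= 0 && i < d1 && j >= 0 && j < d2 && k >= 0 && k < d3;
}

// Symmetric gray-level co-occurrence counts, one Ng x Ng slab per direction
// (distance-1 offsets; each ordered pair counted in both orientations).
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector levels, IntegerVector dims, int ng) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericVector out(ng * ng * NDIR);
  for (int dir = 0; dir < NDIR; ++dir) {
    int oi = DIRS[dir][0], oj = DIRS[dir][1], ok = DIRS[dir][2];
    double *slab = REAL(out) + (R_xlen_t)dir * ng * ng;
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j)
        for (int i = 0; i < d1; ++i) {
          int a = levels[idx3(i, j, k, d1, d2)];
          if (a == 0) continue;
          int i2 = i + oi, j2 = j + oj, k2 = k + ok;
          if (!inside(i2, j2, k2, d1, d2, d3)) continue;
          int b = levels[idx3(i2, j2, k2, d1, d2)];
          if (b == 0) continue;
          slab[(a - 1) + ng * (b - 1)] += 1.0;
          slab[(b - 1) + ng * (a - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, NDIR);
  return out;
}

// Gray-level run-length counts per direction: list of Ng x Nr matrices,
// Nr = longest run over all directions. Runs are maximal same-level
// segments along the direction, broken by the mask and volume edges.
// [[Rcpp::export]]
List cpp_glrlm(IntegerVector levels, IntegerVector dims, int ng) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  std::vector<std::vector<std::pair<int,int> > > runs(NDIR);
  int maxlen = 1;
  for (int dir = 0; dir < NDIR; ++dir) {
    int oi = DIRS[dir][0], oj = DIRS[dir][1], ok = DIRS[dir][2];
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j)
        for (int i = 0; i < d1; ++i) {
          int a = levels[idx3(i, j, k, d1, d2)];
          if (a == 0) continue;
          // run start: predecessor missing, out-of-mask, or different level
          int ip = i - oi, jp = j - oj, kp = k - ok;
          if (inside(ip, jp, kp, d1, d2, d3) &&
              levels[idx3(ip, jp, kp, d1, d2)] == a) continue;
          int len = 1;
          int i2 = i + oi, j2 = j + oj, k2 = k + ok;
          while (inside(i2, j2, k2, d1, d2, d3) &&
                 levels[idx3(i2, j2, k2, d1, d2)] == a) {
            ++len; i2 += oi; j2 += oj; k2 += ok;
          }
          runs[dir].push_back(std::make_pair(a, len));
          if (len > maxlen) maxlen = len;
        }
  }
  List out(NDIR);
  for (int dir = 0; dir < NDIR; ++dir) {
    NumericMatrix m(ng, maxlen);
    for (size_t r = 0; r < runs[dir].size(); ++r)
      m(runs[dir][r].first - 1, runs[dir][r].second - 1) += 1.0;
    out[dir] = m;
  }
  return out;
}

// Gray-level size-zone counts: Ng x Ns matrix, zones are 26-connected
// components of equal level inside the mask.
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector levels, IntegerVector dims, int ng) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int n = d1 * d2 * d3;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int,int> > zones;
  std::vector<int> stack;
  int maxsz = 1;
  for (int s = 0; s < n; ++s) {
    if (seen[s] || levels[s] == 0) continue;
    int lev = levels[s], size = 0;
    stack.clear(); stack.push_back(s); seen[s] = 1;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back(); ++size;
      int i = v % d1, j = (v / d1) % d2, k = v / (d1 * d2);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int i2 = i + di, j2 = j + dj, k2 = k + dk;
            if (!inside(i2, j2, k2, d1, d2, d3)) continue;
            int w = idx3(i2, j2, k2, d1, d2);
            if (!seen[w] && levels[w] == lev) { seen[w] = 1; stack.push_back(w); }
          }
    }
    zones.push_back(std::make_pair(lev, size));
    if (size > maxsz) maxsz = size;
  }
  NumericMatrix out(ng, maxsz);
  for (size_t z = 0; z < zones.size(); ++z)
    out(zones[z].first - 1, zones[z].second - 1) += 1.0;
  return out;
}

// Neighboring gray-tone difference accumulators: Ng x 2 matrix with
// columns (n_i, s_i); s_i sums |i - mean(26-neighborhood levels)| over
// in-mask voxels of level i that have at least one in-mask neighbor.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dims, int ng) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericMatrix out(ng, 2);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int a = levels[idx3(i, j, k, d1, d2)];
        if (a == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int i2 = i + di, j2 = j + dj, k2 = k + dk;
              if (!inside(i2, j2, k2, d1, d2, d3)) continue;
              int b = levels[idx3(i2, j2, k2, d1, d2)];
              if (b == 0) continue;
              sum += b; ++cnt;
            }
        if (cnt == 0) continue;
        out(a - 1, 0) += 1.0;
        out(a - 1, 1) += std::fabs((double)a - sum / cnt);
      }
  return out;
}

// Gray-level dependence counts: Ng x Nd matrix; dependence of a voxel is
// 1 + number of in-mask 26-neighbors within alpha gray levels of it.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dims, int ng,
                       int alpha) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  std::vector<std::pair<int,int> > deps;
  int maxd = 1;
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int a = levels[idx3(i, j, k, d1, d2)];
        if (a == 0) continue;
        int dep = 1;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int i2 = i + di, j2 = j + dj, k2 = k + dk;
              if (!inside(i2, j2, k2, d1, d2, d3)) continue;
              int b = levels[idx3(i2, j2, k2, d1, d2)];
              if (b == 0) continue;
              if (std::abs(a - b) <= alpha) ++dep;
            }
        deps.push_back(std::make_pair(a, dep));
        if (dep > maxd) maxd = dep;
      }
  NumericMatrix out(ng, maxd);
  for (size_t v = 0; v < deps.size(); ++v)
    out(deps[v].first - 1, deps[v].second - 1) += 1.0;
  return out;
}
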