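#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen thinning of a 2D binary image (column-major logical matrix).
// Produces the one-pixel-wide morphological skeleton used to sample the
// distance transform (redundant-pixel removal).
// [[Rcpp::export]]
LogicalMatrix cpp_thin2d(LogicalMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix a = clone(img);
  std::vector<std::pair<int,int> > kill;
  bool changed = true;
  // neighbor order P2..P9: N, NE, E, SE, S, SW, W, NW (row = y, col = x)
  const int di[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dj[8] = { 0,  1, 1, 1, 0,-1,-1, -1};
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          if (!a(i, j)) continue;
          int p[8], bsum = 0;
          for (int t = 0; t < 8; ++t) {
            int ii = i + di[t], jj = j + dj[t];
            p[t] = (ii >= 0 && ii < nr && jj >= 0 && jj < nc && a(ii, jj)) ? 1 : 0;
            bsum += p[t];
          }
          if (bsum < 2 || bsum > 6) continue;
          int trans = 0;
          for (int t = 0; t < 8; ++t)
            if (p[t] == 0 && p[(t + 1) % 8] == 1) ++trans;
          if (trans != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;  // P2*P4*P6
            if (p[2] * p[4] * p[6] != 0) continue;  // P4*P6*P8
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;  // P2*P4*P8
            if (p[0] * p[4] * p[6] != 0) continue;  // P2*P6*P8
          }
          kill.push_back(std::make_pair(i, j));
        }
      if (!kill.empty()) changed = true;
      for (size_t t = 0; t < kill.size(); ++t)
        a(kill[t].first, kill[t].second) = false;
    }
  }
  return a;
}
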