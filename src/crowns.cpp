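#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Variable-window local-maxima scan over a canopy height model.
// A pixel is a treetop when its value is >= min_height and strictly greater
// than every other pixel within a circular window of radius
// max(min_radius_m, radius_coef * height); equal-valued pixels are resolved
// in favour of the smallest (row, col) in row-major order.
// [[Rcpp::export(name = ".detect_treetops_cpp")]]
IntegerMatrix detect_treetops_cpp(NumericMatrix chm, double min_height,
                                  double res, double min_radius_m,
                                  double radius_coef) {
  int nr = chm.nrow(), nc = chm.ncol();
  std::vector<int> rows, cols;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double h = chm(r, c);
      if (h < min_height) continue;
      double rad = std::max(min_radius_m, radius_coef * h) / res;
      int w = (int)std::floor(rad);
      double rad2 = rad * rad;
      bool is_max = true;
      for (int dr = -w; dr <= w && is_max; ++dr) {
        int rr = r + dr;
        if (rr < 0 || rr >= nr) continue;
        for (int dc = -w; dc <= w; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int cc = c + dc;
          if (cc < 0 || cc >= nc) continue;
          if ((double)dr * dr + (double)dc * dc > rad2) continue;
          double o = chm(rr, cc);
          if (o > h) { is_max = false; break; }
          if (o == h) {
            // row-major precedence: keep only the first equal pixel
            if (rr < r || (rr == r && cc < c)) { is_max = false; break; }
          }
        }
      }
      if (is_max) { rows.push_back(r + 1); cols.push_back(c + 1); }
    }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i];
    out(i, 1) = cols[i];
  }
  return out;
}

struct QEntry {
  double h;
  int label;
  long long seq;
  int idx;
};
struct QCmp {
  // priority: higher CHM first; ties -> lower label; then earlier push
  bool operator()(const QEntry &a, const QEntry &b) const {
    if (a.h != b.h) return a.h < b.h;
    if (a.label != b.label) return a.label > b.label;
    return a.seq > b.seq;
  }
};

// Marker-based watershed on the inverted CHM restricted to mask pixels,
// implemented as a priority flood descending from the markers: pixels are
// claimed in order of decreasing height, ties going to the lower label.
// 4-connectivity. Unreached mask pixels keep label 0.
// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerMatrix watershed_cpp(NumericMatrix chm, LogicalMatrix mask,
                            IntegerMatrix marker_rc) {
  int nr = chm.nrow(), nc = chm.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  long long seq = 0;
  const int drs[4] = {-1, 1, 0, 0};
  const int dcs[4] = {0, 0, -1, 1};
  for (int k = 0; k < marker_rc.nrow(); ++k) {
    int r = marker_rc(k, 0) - 1, c = marker_rc(k, 1) - 1;
    pq.push(QEntry{chm(r, c), k + 1, seq++, r + c * nr});
  }
  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    int r = e.idx % nr, c = e.idx / nr;
    if (lab(r, c) != 0) continue;
    lab(r, c) = e.label;
    for (int d = 0; d < 4; ++d) {
      int rr = r + drs[d], cc = c + dcs[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!mask(rr, cc) || lab(rr, cc) != 0) continue;
      pq.push(QEntry{chm(rr, cc), e.label, seq++, rr + cc * nr});
    }
  }
  return lab;
}
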