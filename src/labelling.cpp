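#include <Rcpp.h>
#include <queue>
#include <vector>

using namespace Rcpp;

// Connected-component labelling of equal-valued pixels, 8-connectivity.
// Pixels whose value equals `background` stay 0. Components receive
// consecutive labels 1..K in raster (row-major) order of each component's
// first pixel, so the labelling is deterministic.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(IntegerMatrix x, int background) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  static const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (x(r, c) == background || lab(r, c) != 0) continue;
      const int v = x(r, c);
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      while (!stack.empty()) {
        const std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < 8; ++k) {
          const int rr = p.first + dr[k], cc2 = p.second + dc[k];
          if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
          if (lab(rr, cc2) == 0 && x(rr, cc2) == v) {
            lab(rr, cc2) = next;
            stack.push_back(std::make_pair(rr, cc2));
          }
        }
      }
    }
  }
  return lab;
}

struct QEntry {
  double value;
  long long seq;
  int idx;
};

// min-heap on (value, seq): lowest landscape value first, FIFO among ties
struct QCompare {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.value != b.value) return a.value > b.value;
    return a.seq > b.seq;
  }
};

// Seeded priority-flood watershed. Basins grow from seed labels in order of
// ascending landscape value; a pixel is labelled the moment it is first
// queued ("first-queued wins"), and the queue is ordered by
// (value, insertion sequence) so flat plateaus are flooded FIFO. Growth uses
// 4-connectivity (up, left, right, down), so on flat terrain the result is
// multi-source BFS, i.e. Manhattan-distance propagation from the seeds.
// Pixels where mask is FALSE are never queued and stay 0.
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerMatrix watershed_flood(NumericMatrix land, IntegerMatrix seeds,
                              Nullable<LogicalMatrix> mask_) {
  const int nr = land.nrow(), nc = land.ncol();
  IntegerMatrix lab(nr, nc);
  const bool has_mask = mask_.isNotNull();
  LogicalMatrix mask;
  if (has_mask) mask = mask_.get();

  static const int dr[4] = {-1, 0, 0, 1};
  static const int dc[4] = {0, -1, 1, 0};

  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> q;
  long long seq = 0;

  // seed pixels enter the queue in raster order
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (seeds(r, c) <= 0) continue;
      if (has_mask && !mask(r, c)) continue;
      lab(r, c) = seeds(r, c);
      QEntry e;
      e.value = land(r, c);
      e.seq = seq++;
      e.idx = r + c * nr;
      q.push(e);
    }
  }

  while (!q.empty()) {
    const QEntry e = q.top();
    q.pop();
    const int r = e.idx % nr, c = e.idx / nr;
    const int l = lab(r, c);
    for (int k = 0; k < 4; ++k) {
      const int rr = r + dr[k], cc2 = c + dc[k];
      if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
      if (lab(rr, cc2) != 0) continue;
      if (has_mask && !mask(rr, cc2)) continue;
      lab(rr, cc2) = l;
      QEntry n;
      n.value = land(rr, cc2);
      n.seq = seq++;
      n.idx = rr + cc2 * nr;
      q.push(n);
    }
  }
  return lab;
}
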