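#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 4-neighbour offsets (row, col)
static const int DR[4] = {-1, 1, 0, 0};
static const int DC[4] = {0, 0, -1, 1};

// Label connected plateaus (4-connectivity, equal value) that have no
// strictly lower 4-neighbour. Returns an integer matrix: 0 = not a minimum,
// k > 0 = k-th regional minimum in raster-scan order (deterministic).
// [[Rcpp::export]]
IntegerMatrix rcpp_regional_minima(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<char> seen(static_cast<size_t>(nr) * nc, 0);
  std::vector<int> stack, plateau;
  int next_label = 0;

  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      int idx0 = c0 * nr + r0;
      if (seen[idx0]) continue;
      double v = img[idx0];
      bool is_min = true;
      stack.clear(); plateau.clear();
      stack.push_back(idx0);
      seen[idx0] = 1;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        plateau.push_back(idx);
        int r = idx % nr, c = idx / nr;
        for (int k = 0; k < 4; ++k) {
          int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          int jdx = cc * nr + rr;
          double w = img[jdx];
          if (w < v) { is_min = false; }
          else if (w == v && !seen[jdx]) { seen[jdx] = 1; stack.push_back(jdx); }
        }
      }
      if (is_min) {
        ++next_label;
        for (size_t i = 0; i < plateau.size(); ++i) out[plateau[i]] = next_label;
      }
    }
  }
  return out;
}

struct QEntry {
  double value;
  long order;
  int idx;
};
struct QCompare {
  bool operator()(const QEntry &a, const QEntry &b) const {
    if (a.value != b.value) return a.value > b.value;  // lower intensity first
    return a.order > b.order;                          // FIFO among equals
  }
};

// Meyer's flooding watershed from integer seed labels. Pixels reachable from
// two or more different labels become dam pixels (output 0). Deterministic:
// the queue is ordered by (intensity, insertion order).
// [[Rcpp::export]]
IntegerMatrix rcpp_watershed_flood(NumericMatrix img, IntegerMatrix seeds) {
  int nr = img.nrow(), nc = img.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    stop("image and seed dimensions differ");
  IntegerMatrix lab(nr, nc);
  size_t n = static_cast<size_t>(nr) * nc;
  // state: 0 = untouched, 1 = queued, 2 = resolved
  std::vector<char> state(n, 0);
  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
  long counter = 0;

  for (size_t i = 0; i < n; ++i) {
    if (seeds[i] > 0) { lab[i] = seeds[i]; state[i] = 2; }
  }
  // queue unlabeled neighbours of the seed regions
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx = c * nr + r;
      if (state[idx] != 2) continue;
      for (int k = 0; k < 4; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int jdx = cc * nr + rr;
        if (state[jdx] == 0) {
          state[jdx] = 1;
          pq.push({img[jdx], counter++, jdx});
        }
      }
    }
  }

  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    int idx = e.idx;
    int r = idx % nr, c = idx / nr;
    int found = 0;   // distinct positive labels among resolved neighbours
    for (int k = 0; k < 4; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int jdx = cc * nr + rr;
      if (state[jdx] == 2 && lab[jdx] > 0) {
        if (found == 0) found = lab[jdx];
        else if (lab[jdx] != found) { found = -1; break; }
      }
    }
    state[idx] = 2;
    if (found > 0) {
      lab[idx] = found;
      for (int k = 0; k < 4; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int jdx = cc * nr + rr;
        if (state[jdx] == 0) {
          state[jdx] = 1;
          pq.push({img[jdx], counter++, jdx});
        }
      }
    } else {
      lab[idx] = 0;  // dam (found == -1) or isolated (found == 0)
    }
  }
  return lab;
}

// City-block distance (in pixels) to the nearest TRUE pixel of `mask`,
// capped at `max_dist`. Used for wall rasterisation in the tissue generator.
// [[Rcpp::export]]
IntegerMatrix rcpp_cityblock_distance(LogicalMatrix mask, int max_dist) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix d(nr, nc);
  std::fill(d.begin(), d.end(), max_dist);
  std::vector<int> frontier, nxt;
  for (int i = 0; i < nr * nc; ++i)
    if (mask[i]) { d[i] = 0; frontier.push_back(i); }
  int level = 0;
  while (!frontier.empty() && level < max_dist) {
    ++level;
    nxt.clear();
    for (size_t t = 0; t < frontier.size(); ++t) {
      int idx = frontier[t];
      int r = idx % nr, c = idx / nr;
      for (int k = 0; k < 4; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int jdx = cc * nr + rr;
        if (d[jdx] > level) { d[jdx] = level; nxt.push_back(jdx); }
      }
    }
    frontier.swap(nxt);
  }
  return d;
}
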