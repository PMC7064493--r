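#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Conway-style cellular automaton core: synchronous update on a torus.
// `neighbors` is 8 (Moore) or 4 (von Neumann); the birth/survival
// thresholds (birth on exactly 3, survival on 2-3) are kept for both
// neighbourhood variants.

namespace {

const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
const int dx4[4] = {0, -1, 1, 0};
const int dy4[4] = {-1, 0, 0, 1};

inline int wrap(int v, int m) {
  int r = v % m;
  return r < 0 ? r + m : r;
}

int step_grid(const std::vector<int>& cur, std::vector<int>& nxt,
              int w, int h, int neighbors) {
  const int* dx = neighbors == 8 ? dx8 : dx4;
  const int* dy = neighbors == 8 ? dy8 : dy4;
  int alive = 0;
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      int cnt = 0;
      for (int k = 0; k < neighbors; ++k)
        cnt += cur[wrap(x + dx[k], w) + wrap(y + dy[k], h) * w];
      int c = cur[x + y * w];
      int v = c ? (cnt == 2 || cnt == 3) : (cnt == 3);
      nxt[x + y * w] = v;
      alive += v;
    }
  }
  return alive;
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix gol_step_cpp(IntegerMatrix grid, int neighbors) {
  int h = grid.nrow(), w = grid.ncol();
  std::vector<int> cur(w * h), nxt(w * h);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) cur[x + y * w] = grid(y, x) != 0;
  step_grid(cur, nxt, w, h, neighbors);
  IntegerMatrix out(h, w);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) out(y, x) = nxt[x + y * w];
  return out;
}

// Runs up to max_ticks or until the alive count is unchanged for `window`
// consecutive steps. Returns the alive-count series (tick 0 first).
// [[Rcpp::export]]
List gol_run_cpp(IntegerMatrix grid, int neighbors, int max_ticks,
                 int window) {
  int h = grid.nrow(), w = grid.ncol();
  std::vector<int> cur(w * h), nxt(w * h);
  int alive = 0;
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      cur[x + y * w] = grid(y, x) != 0;
      alive += cur[x + y * w];
    }
  std::vector<int> counts;
  counts.reserve(max_ticks + 1);
  counts.push_back(alive);
  int streak = 0;
  bool stopped = false;
  for (int t = 1; t <= max_ticks; ++t) {
    int prev = alive;
    alive = step_grid(cur, nxt, w, h, neighbors);
    cur.swap(nxt);
    counts.push_back(alive);
    streak = (alive == prev) ? streak + 1 : 0;
    if (streak >= window) { stopped = true; break; }
  }
  IntegerMatrix out(h, w);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) out(y, x) = cur[x + y * w];
  return List::create(
    _["counts"] = IntegerVector(counts.begin(), counts.end()),
    _["stopped"] = stopped,
    _["grid"] = out);
}
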