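#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Grid-based stochastic wolf-sheep-grass simulator core. Uses R's RNG so
// runs are reproducible under set.seed(). Coordinates are 0-based; the
// grass matrix holds a regrowth countdown per cell (0 == grassy).
//
// Tick order (each agent, in freshly shuffled order): move -> eat ->
// die if energy < 0 -> reproduce (offspring gets half the parent's
// energy). Grass countdowns decrement at the end of the tick; a cell
// eaten at tick t with regrowth time g is grassy again at tick t + g.

namespace {

struct Agents {
  std::vector<int> x, y;
  std::vector<double> energy;
  std::vector<bool> alive;
  int n_alive = 0;
  void add(int xi, int yi, double e) {
    x.push_back(xi); y.push_back(yi); energy.push_back(e);
    alive.push_back(true); ++n_alive;
  }
  // drop dead entries once they dominate; per-cell indexes must be
  // rebuilt by the caller afterwards
  bool compact() {
    if ((int)x.size() < 64 || 2 * n_alive >= (int)x.size()) return false;
    size_t w = 0;
    for (size_t i = 0; i < x.size(); ++i) {
      if (!alive[i]) continue;
      x[w] = x[i]; y[w] = y[i]; energy[w] = energy[i];
      ++w;
    }
    x.resize(w); y.resize(w); energy.resize(w);
    alive.assign(w, true);
    return true;
  }
};

inline int wrap(int v, int m) {
  int r = v % m;
  return r < 0 ? r + m : r;
}

inline int ri(int n) {  // uniform integer in [0, n)
  int v = (int)std::floor(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

} // namespace

// [[Rcpp::export]]
List wsp_ticks_cpp(IntegerMatrix grass_in, NumericMatrix wolves_in,
                   NumericMatrix sheep_in, List params, int n_ticks,
                   bool stop_when_done) {
  const int w = params["world_width"], h = params["world_height"];
  const double sheep_gain = params["sheep_gain"];
  const double wolf_gain = params["wolf_gain"];
  const double move_cost = params["move_cost"];
  const double p_sheep = params["sheep_reproduce"];
  const double p_wolf = params["wolf_reproduce"];
  const int regrow = params["grass_regrowth_time"];
  const double mobility = params["mobility"];
  const int area = w * h;

  IntegerMatrix grass = clone(grass_in);  // countdown, 0 == grassy
  Agents wolves, sheep;
  for (int i = 0; i < wolves_in.nrow(); ++i)
    wolves.add((int)wolves_in(i, 0), (int)wolves_in(i, 1), wolves_in(i, 2));
  for (int i = 0; i < sheep_in.nrow(); ++i)
    sheep.add((int)sheep_in(i, 0), (int)sheep_in(i, 1), sheep_in(i, 2));

  // per-cell sheep index lists for wolf predation lookups
  std::vector<std::vector<int> > sheep_at(area);
  std::vector<int> pos_in_cell(sheep.x.size());
  for (size_t i = 0; i < sheep.x.size(); ++i) {
    int c = sheep.x[i] + sheep.y[i] * w;
    pos_in_cell[i] = (int)sheep_at[c].size();
    sheep_at[c].push_back((int)i);
  }
  auto sheep_cell = [&](int i) { return sheep.x[i] + sheep.y[i] * w; };
  auto remove_sheep_from_cell = [&](int i) {
    int c = sheep_cell(i), p = pos_in_cell[i];
    int last = sheep_at[c].back();
    sheep_at[c][p] = last;
    pos_in_cell[last] = p;
    sheep_at[c].pop_back();
  };
  auto add_sheep_to_cell = [&](int i) {
    int c = sheep_cell(i);
    pos_in_cell[i] = (int)sheep_at[c].size();
    sheep_at[c].push_back(i);
  };

  int grass_count = 0;
  for (int c = 0; c < area; ++c) if (grass[c] == 0) ++grass_count;

  std::vector<int> tr_w, tr_s, tr_g;
  tr_w.reserve(n_ticks); tr_s.reserve(n_ticks); tr_g.reserve(n_ticks);

  std::vector<int> order;       // encoded agent ids: wolf 2i, sheep 2i+1
  std::vector<int> eaten_cells; // cells eaten this tick (skip decrement fix)

  int done_ticks = 0;
  for (int tick = 0; tick < n_ticks; ++tick) {
    if (stop_when_done && wolves.n_alive == 0 && sheep.n_alive == 0 &&
        grass_count == area)
      break;

    wolves.compact();
    if (sheep.compact()) {
      for (int c = 0; c < area; ++c) sheep_at[c].clear();
      pos_in_cell.assign(sheep.x.size(), 0);
      for (size_t i = 0; i < sheep.x.size(); ++i) {
        int c = sheep.x[i] + sheep.y[i] * w;
        pos_in_cell[i] = (int)sheep_at[c].size();
        sheep_at[c].push_back((int)i);
      }
    }

    order.clear();
    for (size_t i = 0; i < wolves.x.size(); ++i)
      if (wolves.alive[i]) order.push_back(2 * (int)i);
    for (size_t i = 0; i < sheep.x.size(); ++i)
      if (sheep.alive[i]) order.push_back(2 * (int)i + 1);
    for (int i = (int)order.size() - 1; i > 0; --i)
      std::swap(order[i], order[ri(i + 1)]);

    for (size_t k = 0; k < order.size(); ++k) {
      bool is_sheep = order[k] & 1;
      int i = order[k] >> 1;
      Agents& a = is_sheep ? sheep : wolves;
      if (!a.alive[i]) continue;  // eaten earlier this tick

      // move: random heading, displacement of `mobility` cells, torus wrap
      double theta = 2.0 * M_PI * unif_rand();
      int nx = wrap(a.x[i] + (int)std::lround(mobility * std::cos(theta)), w);
      int ny = wrap(a.y[i] + (int)std::lround(mobility * std::sin(theta)), h);
      if (is_sheep) remove_sheep_from_cell(i);
      a.x[i] = nx; a.y[i] = ny;
      if (is_sheep) add_sheep_to_cell(i);
      a.energy[i] -= move_cost;

      // eat
      int cell = nx + ny * w;
      if (is_sheep) {
        if (grass[cell] == 0) {
          a.energy[i] += sheep_gain;
          grass[cell] = regrow + 1;  // +1: end-of-tick decrement follows
          --grass_count;
        }
      } else if (!sheep_at[cell].empty()) {
        int j = sheep_at[cell][ri((int)sheep_at[cell].size())];
        remove_sheep_from_cell(j);
        sheep.alive[j] = false;
        --sheep.n_alive;
        a.energy[i] += wolf_gain;
      }

      // die
      if (a.energy[i] < 0) {
        if (is_sheep) remove_sheep_from_cell(i);
        a.alive[i] = false;
        --a.n_alive;
        continue;
      }

      // reproduce: offspring takes half the parent's energy
      double p_rep = is_sheep ? p_sheep : p_wolf;
      if (p_rep > 0 && unif_rand() < p_rep) {
        a.energy[i] *= 0.5;
        a.add(a.x[i], a.y[i], a.energy[i]);
        if (is_sheep) {
          pos_in_cell.push_back(0);
          add_sheep_to_cell((int)a.x.size() - 1);
        }
      }
    }

    // grass regrowth: countdowns decrement, cells regrow at 0
    for (int c = 0; c < area; ++c) {
      if (grass[c] > 0 && --grass[c] == 0) ++grass_count;
    }

    tr_w.push_back(wolves.n_alive);
    tr_s.push_back(sheep.n_alive);
    tr_g.push_back(grass_count);
    ++done_ticks;
  }

  auto pack = [](const Agents& a) {
    NumericMatrix m(a.n_alive, 3);
    int r = 0;
    for (size_t i = 0; i < a.x.size(); ++i) {
      if (!a.alive[i]) continue;
      m(r, 0) = a.x[i]; m(r, 1) = a.y[i]; m(r, 2) = a.energy[i];
      ++r;
    }
    colnames(m) = CharacterVector::create("x", "y", "energy");
    return m;
  };

  return List::create(
    _["wolves_trace"] = IntegerVector(tr_w.begin(), tr_w.end()),
    _["sheep_trace"] = IntegerVector(tr_s.begin(), tr_s.end()),
    _["grass_trace"] = IntegerVector(tr_g.begin(), tr_g.end()),
    _["ticks_done"] = done_ticks,
    _["grass"] = grass,
    _["wolves"] = pack(wolves),
    _["sheep"] = pack(sheep));
}
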