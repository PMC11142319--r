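#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sheep-wolves-grass stepper. Animals live in continuous torus coordinates
// with persistent headings (correlated random walk: wiggle of up to +/-50
// degrees per tick, then a unit forward step), as in the source
// wolf-sheep-predation model; grazing and predation act on the lattice
// patch floor(x), floor(y). Uses R's RNG throughout so that set.seed() on
// the R side makes whole runs reproducible.

// torus wrap for |v - [0, n)| < n (unit steps only)
static inline double wrapd(double v, double n) {
  if (v < 0) v += n;
  else if (v >= n) v -= n;
  return v;
}

// uniform integer in 0..n-1
static inline int rint_n(int n) {
  int k = (int)(unif_rand() * n);
  return k < n ? k : n - 1;
}

static const double kDeg2Rad = 3.14159265358979323846 / 180.0;

static void shuffle_idx(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = rint_n(i + 1);
    std::swap(v[i], v[j]);
  }
}

struct Herd {
  std::vector<double> x, y, h, e; // position, heading (degrees), energy
  size_t size() const { return x.size(); }
  bool empty() const { return x.empty(); }
  void push(double xi, double yi, double hi, double ei) {
    x.push_back(xi); y.push_back(yi); h.push_back(hi); e.push_back(ei);
  }
};

static Herd herd_from_df(DataFrame df) {
  Herd hd;
  NumericVector x = df["x"], y = df["y"], h = df["heading"], e = df["energy"];
  hd.x.assign(x.begin(), x.end());
  hd.y.assign(y.begin(), y.end());
  hd.h.assign(h.begin(), h.end());
  hd.e.assign(e.begin(), e.end());
  return hd;
}

static DataFrame herd_to_df(const Herd& h) {
  return DataFrame::create(_["x"] = NumericVector(h.x.begin(), h.x.end()),
                           _["y"] = NumericVector(h.y.begin(), h.y.end()),
                           _["heading"] = NumericVector(h.h.begin(), h.h.end()),
                           _["energy"] = NumericVector(h.e.begin(), h.e.end()));
}

// One full run of n_steps ticks. Tick sub-phases, in fixed order:
//   1 move (wiggle + unit forward step, energy loss)
//   2 sheep graze grown patches
//   3 wolves eat one sheep sharing their patch
//   4 starvation deaths (energy < 0)
//   5 reproduction (energy halved, offspring gets the other half)
//   6 grass countdown decrement / regrowth
//   7 control: independent Bernoulli removal per animal, per grown patch
// [[Rcpp::export]]
List swg_run_cpp(List state, List params, List control, int n_steps,
                 bool bookkeeping) {
  const int W = as<int>(params["world_width"]);
  const int H = as<int>(params["world_height"]);
  const double gain_s = as<double>(params["sheep_gain_from_food"]);
  const double gain_w = as<double>(params["wolf_gain_from_food"]);
  const double pr_s = as<double>(params["sheep_reproduce_prob"]);
  const double pr_w = as<double>(params["wolf_reproduce_prob"]);
  const int regrow = as<int>(params["grass_regrowth_time"]);
  const double eloss = as<double>(params["energy_loss_per_step"]);
  const double k_g = as<double>(control["kappa_grass"]);
  const double k_s = as<double>(control["kappa_sheep"]);
  const double k_w = as<double>(control["kappa_wolves"]);

  const int P = W * H;
  IntegerMatrix grass_in = state["grass"];
  if (grass_in.nrow() != W || grass_in.ncol() != H)
    stop("grass matrix dimensions do not match world size");
  std::vector<int> grass(grass_in.begin(), grass_in.end()); // idx = x + W*y
  Herd sheep = herd_from_df(as<DataFrame>(state["sheep"]));
  Herd wolves = herd_from_df(as<DataFrame>(state["wolves"]));
  int step0 = as<int>(state["step"]);

  IntegerMatrix macro(n_steps + 1, 4);
  IntegerMatrix book(bookkeeping ? n_steps : 0, 8);

  auto patch_of = [&](double x, double y) {
    int px = (int)x, py = (int)y;
    if (px >= W) px = W - 1; // guard against x == W from rounding
    if (py >= H) py = H - 1;
    return px + W * py;
  };
  auto grown_count = [&]() {
    int g = 0;
    for (int i = 0; i < P; ++i) if (grass[i] == 0) ++g;
    return g;
  };
  auto record = [&](int row, int step) {
    macro(row, 0) = step;
    macro(row, 1) = grown_count();
    macro(row, 2) = (int)sheep.size();
    macro(row, 3) = (int)wolves.size();
  };
  record(0, step0);

  std::vector<int> order, bucket_off(P + 1), bucket_ix;
  std::vector<char> alive;

  auto move_herd = [&](Herd& hd) {
    for (size_t i = 0; i < hd.size(); ++i) {
      hd.h[i] += (unif_rand() - unif_rand()) * 50.0;
      double a = hd.h[i] * kDeg2Rad;
      hd.x[i] = wrapd(hd.x[i] + std::sin(a), (double)W);
      hd.y[i] = wrapd(hd.y[i] + std::cos(a), (double)H);
      hd.e[i] -= eloss;
    }
  };

  for (int t = 0; t < n_steps; ++t) {
    int births_s = 0, eaten_s = 0, starved_s = 0, removed_s = 0;
    int births_w = 0, starved_w = 0, removed_w = 0, grass_eaten = 0;

    // (1) movement + energy loss
    move_herd(sheep);
    move_herd(wolves);

    // (2) grazing: first sheep (in shuffled order) on a grown patch eats it.
    // Countdown is set to regrow+1 so that after this tick's phase-6
    // decrement the patch is grown again exactly `regrow` ticks after being
    // eaten.
    order.resize(sheep.size());
    for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
    shuffle_idx(order);
    for (int i : order) {
      int idx = patch_of(sheep.x[i], sheep.y[i]);
      if (grass[idx] == 0) {
        grass[idx] = regrow + 1;
        sheep.e[i] += gain_s;
        ++grass_eaten;
      }
    }

    // (3) predation: per-patch buckets of sheep, wolves in shuffled order
    // each eat one uniformly chosen surviving sheep on their patch.
    if (!wolves.empty() && !sheep.empty()) {
      std::fill(bucket_off.begin(), bucket_off.end(), 0);
      for (size_t i = 0; i < sheep.size(); ++i)
        ++bucket_off[patch_of(sheep.x[i], sheep.y[i]) + 1];
      for (int p = 0; p < P; ++p) bucket_off[p + 1] += bucket_off[p];
      bucket_ix.resize(sheep.size());
      {
        std::vector<int> cur(bucket_off.begin(), bucket_off.end() - 1);
        for (size_t i = 0; i < sheep.size(); ++i)
          bucket_ix[cur[patch_of(sheep.x[i], sheep.y[i])]++] = (int)i;
      }
      alive.assign(sheep.size(), 1);
      order.resize(wolves.size());
      for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
      shuffle_idx(order);
      std::vector<int> cand;
      for (int wi : order) {
        int idx = patch_of(wolves.x[wi], wolves.y[wi]);
        cand.clear();
        for (int k = bucket_off[idx]; k < bucket_off[idx + 1]; ++k)
          if (alive[bucket_ix[k]]) cand.push_back(bucket_ix[k]);
        if (!cand.empty()) {
          int victim = cand[rint_n((int)cand.size())];
          alive[victim] = 0;
          wolves.e[wi] += gain_w;
          ++eaten_s;
        }
      }
      Herd keep;
      keep.x.reserve(sheep.size());
      for (size_t i = 0; i < sheep.size(); ++i)
        if (alive[i]) keep.push(sheep.x[i], sheep.y[i], sheep.h[i],
                                sheep.e[i]);
      sheep = std::move(keep);
    }

    // (4) starvation
    {
      Herd keep;
      keep.x.reserve(sheep.size());
      for (size_t i = 0; i < sheep.size(); ++i) {
        if (sheep.e[i] < 0) ++starved_s;
        else keep.push(sheep.x[i], sheep.y[i], sheep.h[i], sheep.e[i]);
      }
      sheep = std::move(keep);
      Herd keepw;
      keepw.x.reserve(wolves.size());
      for (size_t i = 0; i < wolves.size(); ++i) {
        if (wolves.e[i] < 0) ++starved_w;
        else keepw.push(wolves.x[i], wolves.y[i], wolves.h[i], wolves.e[i]);
      }
      wolves = std::move(keepw);
    }

    // (5) reproduction: parent halves its energy, offspring gets the half
    // and a fresh random heading
    {
      size_t n0 = sheep.size();
      for (size_t i = 0; i < n0; ++i) {
        if (unif_rand() < pr_s) {
          sheep.e[i] *= 0.5;
          sheep.push(sheep.x[i], sheep.y[i], unif_rand() * 360.0,
                     sheep.e[i]);
          ++births_s;
        }
      }
      size_t m0 = wolves.size();
      for (size_t i = 0; i < m0; ++i) {
        if (unif_rand() < pr_w) {
          wolves.e[i] *= 0.5;
          wolves.push(wolves.x[i], wolves.y[i], unif_rand() * 360.0,
                      wolves.e[i]);
          ++births_w;
        }
      }
    }

    // (6) regrowth countdown
    for (int p = 0; p < P; ++p) if (grass[p] > 0) --grass[p];

    // (7) control: independent per-animal Bernoulli removal; grass control
    // resets grown patches to a full countdown with probability kappa_grass
    if (k_s > 0 && !sheep.empty()) {
      Herd keep;
      keep.x.reserve(sheep.size());
      for (size_t i = 0; i < sheep.size(); ++i) {
        if (unif_rand() < k_s) ++removed_s;
        else keep.push(sheep.x[i], sheep.y[i], sheep.h[i], sheep.e[i]);
      }
      sheep = std::move(keep);
    }
    if (k_w > 0 && !wolves.empty()) {
      Herd keep;
      keep.x.reserve(wolves.size());
      for (size_t i = 0; i < wolves.size(); ++i) {
        if (unif_rand() < k_w) ++removed_w;
        else keep.push(wolves.x[i], wolves.y[i], wolves.h[i], wolves.e[i]);
      }
      wolves = std::move(keep);
    }
    if (k_g > 0) {
      for (int p = 0; p < P; ++p)
        if (grass[p] == 0 && unif_rand() < k_g) grass[p] = regrow;
    }

    record(t + 1, step0 + t + 1);
    if (bookkeeping) {
      book(t, 0) = births_s;  book(t, 1) = eaten_s;
      book(t, 2) = starved_s; book(t, 3) = removed_s;
      book(t, 4) = births_w;  book(t, 5) = starved_w;
      book(t, 6) = removed_w; book(t, 7) = grass_eaten;
    }
  }

  IntegerMatrix grass_out(W, H);
  std::copy(grass.begin(), grass.end(), grass_out.begin());
  List out_state = List::create(
    _["grass"] = grass_out,
    _["sheep"] = herd_to_df(sheep),
    _["wolves"] = herd_to_df(wolves),
    _["step"] = step0 + n_steps);
  out_state.attr("class") = "swg_state";
  List out = List::create(_["state"] = out_state, _["macro"] = macro);
  if (bookkeeping) out["book"] = book;
  return out;
}
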