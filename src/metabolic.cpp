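#include <Rcpp.h>
using namespace Rcpp;

// Branched metabolic pathway lattice stepper.
//
// Metabolites: S=0, A=1, B=2, R=3, T=4 (integer codes, shared with the R side).
// Enzymes E1..E4 are persistent entities with a type (0..3), a bound-metabolite
// slot `bm` and a bound-regulator slot `br` (-1 = empty). Reactions (all
// irreversible): E1: S->A, E2: A->B, E3: B->R, E4: B->T. Regulation: R binds
// E1 / E1S, T binds E2 / E2A; a regulator-bound enzyme is catalytically inert.
// The 12 complex species are E1S, E1A, E1.R, E1S.R, E2A, E2B, E2.T, E2A.T,
// E3B, E3R, E4B, E4T.

static inline int wrap(int v, int n) { v %= n; if (v < 0) v += n; return v; }
static inline int rint_n(int n) {
  int k = (int)(unif_rand() * n);
  return k < n ? k : n - 1;
}
static const int DX8[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
static const int DY8[8] = {-1, 0, 1,-1, 1,-1, 0, 1};

static const int SUBSTRATE[4] = {0, 1, 2, 2}; // per enzyme type
static const int PRODUCT[4]   = {1, 2, 3, 4};
static const int REGULATOR[4] = {3, 4, -1, -1};

struct Enz { int type, bm, br, x, y; };

// can metabolite m bind entity e? slot: 0 -> metabolite slot, 1 -> regulator
static inline bool can_bind(const Enz& e, int m, int& slot) {
  const int sub = SUBSTRATE[e.type], prod = PRODUCT[e.type], reg = REGULATOR[e.type];
  if (e.bm < 0 && m == sub) { slot = 0; return true; }            // substrate
  if (e.bm < 0 && e.br < 0 && m == prod && m != sub) {            // product (free enzyme only)
    slot = 0; return true;
  }
  if (reg >= 0 && e.br < 0 && m == reg && (e.bm < 0 || e.bm == sub)) {
    slot = 1; return true;                                        // regulator on E or ES
  }
  return false;
}

// entity-state code 0..19 for complex accounting: 5*type + s with
// s = 0 free, 1 substrate complex, 2 product complex, 3 regulator only,
// 4 substrate + regulator. E3/E4 never occupy s = 3, 4.
static inline int enz_code(const Enz& e) {
  int s;
  if (e.br >= 0) s = (e.bm >= 0) ? 4 : 3;
  else if (e.bm < 0) s = 0;
  else s = (e.bm == SUBSTRATE[e.type]) ? 1 : 2;
  return 5 * e.type + s;
}

// [[Rcpp::export]]
List metabolic_run_cpp(List state, List params, int n_steps,
                       bool record_complexes) {
  const int W = as<int>(params["width"]);
  const int H = as<int>(params["height"]);
  const int met_speed = as<int>(params["metabolite_speed"]);
  const int enz_speed = as<int>(params["enzyme_speed"]);
  const double p_bind = as<double>(params["p_bind"]);
  const double p_diss = as<double>(params["p_diss"]);
  const double p_cat = as<double>(params["p_cat"]);
  const bool continuous = as<std::string>(params["mode"]) == "continuous";
  const double q_in = as<double>(params["q_in"]);
  const double outflow = as<double>(params["outflow_rate"]);
  const int P = W * H;

  DataFrame met_df = as<DataFrame>(state["met"]);
  IntegerVector ms = met_df["species"], mx = met_df["x"], my = met_df["y"];
  std::vector<int> msv(ms.begin(), ms.end()), mxv(mx.begin(), mx.end()),
      myv(my.begin(), my.end());

  DataFrame enz_df = as<DataFrame>(state["enz"]);
  IntegerVector et = enz_df["type"], ebm = enz_df["bound_met"],
                ebr = enz_df["bound_reg"], ex = enz_df["x"], ey = enz_df["y"];
  std::vector<Enz> enz(et.size());
  for (int i = 0; i < et.size(); ++i)
    enz[i] = Enz{et[i], ebm[i], ebr[i], ex[i], ey[i]};
  int step0 = as<int>(state["step"]);

  const int ncol = record_complexes ? 1 + 5 + 20 : 1 + 5;
  IntegerMatrix macro(n_steps + 1, ncol);

  auto record = [&](int row, int step) {
    macro(row, 0) = step;
    int cnt[5] = {0, 0, 0, 0, 0};
    for (int s : msv) ++cnt[s];
    for (int k = 0; k < 5; ++k) macro(row, 1 + k) = cnt[k];
    if (record_complexes) {
      int c[20] = {0};
      for (const Enz& e : enz) c[enz_code(e)]++;
      for (int k = 0; k < 20; ++k) macro(row, 6 + k) = c[k];
    }
  };
  record(0, step0);

  std::vector<std::vector<int>> cell(P);
  std::vector<int> order;

  for (int t = 0; t < n_steps; ++t) {
    // (1) movement
    for (size_t i = 0; i < msv.size(); ++i) {
      int x = mxv[i], y = myv[i];
      for (int k = 0; k < met_speed; ++k) {
        int d = rint_n(8);
        x = wrap(x + DX8[d], W);
        y = wrap(y + DY8[d], H);
      }
      mxv[i] = x; myv[i] = y;
    }
    for (Enz& e : enz) {
      for (int k = 0; k < enz_speed; ++k) {
        int d = rint_n(8);
        e.x = wrap(e.x + DX8[d], W);
        e.y = wrap(e.y + DY8[d], H);
      }
    }

    // enzyme occupancy grid (positions are fixed for the rest of the tick)
    for (auto& c : cell) c.clear();
    for (size_t i = 0; i < enz.size(); ++i)
      cell[enz[i].x + W * enz[i].y].push_back((int)i);

    // (2) binding: metabolites in shuffled order scan their 3x3 neighbourhood
    order.resize(msv.size());
    for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = rint_n(i + 1);
      std::swap(order[i], order[j]);
    }
    std::vector<int> cand_e, cand_slot;
    for (int mi : order) {
      int m = msv[mi];
      if (m < 0) continue;
      cand_e.clear(); cand_slot.clear();
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = wrap(myv[mi] + dy, H);
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = wrap(mxv[mi] + dx, W);
          for (int ei : cell[xx + W * yy]) {
            int slot;
            if (can_bind(enz[ei], m, slot)) {
              cand_e.push_back(ei);
              cand_slot.push_back(slot);
            }
          }
        }
      }
      if (!cand_e.empty() && unif_rand() < p_bind) {
        int k = rint_n((int)cand_e.size());
        Enz& e = enz[cand_e[k]];
        if (cand_slot[k] == 0) e.bm = m; else e.br = m;
        msv[mi] = -1; // bound; compacted below
      }
    }
    {
      size_t w = 0;
      for (size_t i = 0; i < msv.size(); ++i) {
        if (msv[i] >= 0) {
          msv[w] = msv[i]; mxv[w] = mxv[i]; myv[w] = myv[i]; ++w;
        }
      }
      msv.resize(w); mxv.resize(w); myv.resize(w);
    }

    // (3) dissociation: each bound molecule released independently
    for (Enz& e : enz) {
      if (e.bm >= 0 && unif_rand() < p_diss) {
        msv.push_back(e.bm); mxv.push_back(e.x); myv.push_back(e.y);
        e.bm = -1;
      }
      if (e.br >= 0 && unif_rand() < p_diss) {
        msv.push_back(e.br); mxv.push_back(e.x); myv.push_back(e.y);
        e.br = -1;
      }
    }

    // (4) catalysis: substrate complex -> product complex, inert if regulated
    for (Enz& e : enz) {
      if (e.br < 0 && e.bm == SUBSTRATE[e.type] && unif_rand() < p_cat)
        e.bm = PRODUCT[e.type];
    }

    // (5) continuous mode: Poisson inflow of S, Bernoulli outflow of free mets
    if (continuous) {
      if (q_in > 0) {
        int n_new = (int)R::rpois(q_in);
        for (int k = 0; k < n_new; ++k) {
          msv.push_back(0);
          mxv.push_back(rint_n(W));
          myv.push_back(rint_n(H));
        }
      }
      if (outflow > 0) {
        size_t w = 0;
        for (size_t i = 0; i < msv.size(); ++i) {
          if (unif_rand() >= outflow) {
            msv[w] = msv[i]; mxv[w] = mxv[i]; myv[w] = myv[i]; ++w;
          }
        }
        msv.resize(w); mxv.resize(w); myv.resize(w);
      }
    }

    record(t + 1, step0 + t + 1);
  }

  DataFrame met_out = DataFrame::create(
    _["species"] = IntegerVector(msv.begin(), msv.end()),
    _["x"] = IntegerVector(mxv.begin(), mxv.end()),
    _["y"] = IntegerVector(myv.begin(), myv.end()));
  int ne = (int)enz.size();
  IntegerVector ot(ne), obm(ne), obr(ne), ox(ne), oy(ne);
  for (int i = 0; i < ne; ++i) {
    ot[i] = enz[i].type; obm[i] = enz[i].bm; obr[i] = enz[i].br;
    ox[i] = enz[i].x; oy[i] = enz[i].y;
  }
  DataFrame enz_out = DataFrame::create(
    _["type"] = ot, _["bound_met"] = obm, _["bound_reg"] = obr,
    _["x"] = ox, _["y"] = oy);
  List out_state = List::create(_["met"] = met_out, _["enz"] = enz_out,
                                _["step"] = step0 + n_steps);
  out_state.attr("class") = "metabolic_state";
  return List::create(_["state"] = out_state, _["macro"] = macro);
}
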