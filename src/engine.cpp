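// Compiled core of the lattice war model.
//
// One implementation of the five-phase step procedure serves both the
// phase-level R wrappers (used for inspection and testing) and the fast
// full-run loop: every exported entry point below calls the same internal
// functions, in the same order, consuming R's RNG stream identically.
//
// Conventions: state ids are 1-based and never reused; dead states keep
// their row (alive = false). Cells are indexed 0-based as r * W + c
// internally; all R-facing coordinates are 1-based (row, col).

#include <Rcpp.h>
#include <vector>
#include <map>
#include <set>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

struct Params {
  int W, H, N0;
  bool torus;
  double k, r0, w, q, mu, sigma, init_res;
  int peace_stop, max_steps;
  bool log_odds;      // CSF form: true = logistic in logit(share), false = logistic in share
  bool alloc_by_res;  // front weights: opponent resources (true) or province count
};

static Params params_from(List cfg) {
  Params P;
  P.W = as<int>(cfg["width"]);
  P.H = as<int>(cfg["height"]);
  P.torus = as<bool>(cfg["torus"]);
  P.N0 = as<int>(cfg["n_initial_states"]);
  P.k = as<double>(cfg["k"]);
  P.r0 = as<double>(cfg["r0"]);
  P.w = as<double>(cfg["w"]);
  P.q = as<double>(cfg["q"]);
  P.mu = as<double>(cfg["alpha_mu"]);
  P.sigma = as<double>(cfg["alpha_sigma"]);
  P.init_res = as<double>(cfg["initial_resources_per_province"]);
  P.peace_stop = as<int>(cfg["peace_steps_to_stop"]);
  P.max_steps = as<int>(cfg["max_steps"]);
  P.log_odds = as<std::string>(cfg["csf_form"]) == "log_odds";
  P.alloc_by_res = as<std::string>(cfg["allocation_weights"]) == "resources";
  if (P.N0 > P.W * P.H) stop("n_initial_states exceeds the number of provinces");
  return P;
}

struct World {
  Params P;
  std::vector<int> owner;          // W*H, state id owning each cell
  std::vector<double> alpha, res;
  std::vector<int> cap;            // capital cell index (last known for dead states)
  std::vector<char> alive;
  std::vector<int> nprov;
  int t = 0, peace = 0;

  int n() const { return (int) alpha.size(); }
  int nalive() const {
    int m = 0;
    for (char a : alive) m += a ? 1 : 0;
    return m;
  }
  double median_alpha() const {
    std::vector<double> v;
    for (int i = 0; i < n(); ++i) if (alive[i]) v.push_back(alpha[i]);
    if (v.empty()) return NA_REAL;
    std::sort(v.begin(), v.end());
    size_t m = v.size();
    return (m % 2 == 1) ? v[m / 2] : 0.5 * (v[m / 2 - 1] + v[m / 2]);
  }
  void newborn(int cell, double a) {
    alpha.push_back(a);
    res.push_back(P.init_res);
    cap.push_back(cell);
    alive.push_back(1);
    nprov.push_back(1);
    owner[cell] = n();
  }
};

// ---- lattice helpers -------------------------------------------------------

// Up to 4 von Neumann neighbours of a cell; wraps on a torus. On degenerate
// 1-wide/1-high tori self-wraps are suppressed.
static int neigh4(const Params& P, int cell, int out[4]) {
  int r = cell / P.W, c = cell % P.W, m = 0;
  if (r > 0) out[m++] = cell - P.W;
  else if (P.torus && P.H > 1) out[m++] = (P.H - 1) * P.W + c;
  if (r < P.H - 1) out[m++] = cell + P.W;
  else if (P.torus && P.H > 1) out[m++] = c;
  if (c > 0) out[m++] = cell - 1;
  else if (P.torus && P.W > 1) out[m++] = r * P.W + (P.W - 1);
  if (c < P.W - 1) out[m++] = cell + 1;
  else if (P.torus && P.W > 1) out[m++] = r * P.W;
  return m;
}

static int draw_index(int n) {
  // uniform in 0..n-1 from R's RNG; unif_rand() lies in (0,1)
  int i = (int) (unif_rand() * n);
  return i >= n ? n - 1 : i;
}

// ---- conflict success function --------------------------------------------

static double csf_prob(double ra, double rt, const Params& P) {
  double r = ra / (ra + rt);
  double z;
  if (P.log_odds) {
    z = P.k * (std::log(r / (1.0 - r)) - std::log(P.r0 / (1.0 - P.r0)));
  } else {
    z = P.k * (r - P.r0);
  }
  return 1.0 / (1.0 + std::exp(-z));
}

// ---- world construction ----------------------------------------------------

static World build_world_internal(const Params& P) {
  World w;
  w.P = P;
  int cells = P.W * P.H;
  w.owner.assign(cells, 0);

  // capitals: partial Fisher-Yates over all cells
  std::vector<int> perm(cells);
  for (int i = 0; i < cells; ++i) perm[i] = i;
  for (int i = 0; i < P.N0; ++i) {
    int j = i + draw_index(cells - i);
    std::swap(perm[i], perm[j]);
  }
  for (int s = 0; s < P.N0; ++s) {
    w.cap.push_back(perm[s]);
    w.owner[perm[s]] = s + 1;
    w.alpha.push_back(std::exp(P.mu + P.sigma * norm_rand()));
    w.res.push_back(0.0);
    w.alive.push_back(1);
    w.nprov.push_back(1);
  }

  // synchronous multi-source BFS growth; each frontier cell joins the owner of
  // a uniformly chosen owned neighbouring cell (ties broken at random)
  int remaining = cells - P.N0;
  int nb[4];
  std::vector<std::pair<int, int> > assign;
  while (remaining > 0) {
    assign.clear();
    for (int cell = 0; cell < cells; ++cell) {
      if (w.owner[cell] != 0) continue;
      int owned[4], m = neigh4(P, cell, nb), no = 0;
      for (int i = 0; i < m; ++i) if (w.owner[nb[i]] != 0) owned[no++] = nb[i];
      if (no > 0) assign.push_back(std::make_pair(cell, w.owner[owned[draw_index(no)]]));
    }
    if (assign.empty()) stop("internal error: lattice growth stalled");
    for (size_t i = 0; i < assign.size(); ++i) {
      w.owner[assign[i].first] = assign[i].second;
      w.nprov[assign[i].second - 1]++;
    }
    remaining -= (int) assign.size();
  }
  for (int s = 0; s < P.N0; ++s) w.res[s] = P.init_res * w.nprov[s];
  return w;
}

// ---- phases ----------------------------------------------------------------

static void extract_internal(World& w) {
  for (int i = 0; i < w.n(); ++i) if (w.alive[i]) w.res[i] += (double) w.nprov[i];
}

// adjacency lists between living states, from the ownership grid
static std::vector<std::vector<int> > adjacency_internal(const World& w) {
  std::vector<std::vector<int> > adj(w.n() + 1);
  int nb[4];
  int cells = w.P.W * w.P.H;
  for (int cell = 0; cell < cells; ++cell) {
    int o = w.owner[cell];
    int m = neigh4(w.P, cell, nb);
    for (int i = 0; i < m; ++i) {
      int o2 = w.owner[nb[i]];
      if (o2 != o) adj[o].push_back(o2);
    }
  }
  for (size_t s = 1; s < adj.size(); ++s) {
    std::sort(adj[s].begin(), adj[s].end());
    adj[s].erase(std::unique(adj[s].begin(), adj[s].end()), adj[s].end());
  }
  return adj;
}

struct Attack { int a, t; double phat; };

// decision phase: perceived p uses alpha * own full stock vs opponent's true
// full stock; attack the argmax neighbour iff p-hat strictly exceeds w
static std::vector<Attack> decide_internal(const World& w) {
  std::vector<std::vector<int> > adj = adjacency_internal(w);
  std::vector<Attack> out;
  std::vector<int> ties;
  for (int s = 1; s <= w.n(); ++s) {
    if (!w.alive[s - 1] || adj[s].empty()) continue;
    double best = -1.0;
    ties.clear();
    for (size_t j = 0; j < adj[s].size(); ++j) {
      int o = adj[s][j];
      double p = csf_prob(w.alpha[s - 1] * w.res[s - 1], w.res[o - 1], w.P);
      if (p > best) { best = p; ties.assign(1, o); }
      else if (p == best) ties.push_back(o);
    }
    if (best > w.P.w) {
      int pick = (ties.size() == 1) ? ties[0] : ties[draw_index((int) ties.size())];
      Attack A; A.a = s; A.t = pick; A.phat = best;
      out.push_back(A);
    }
  }
  return out;
}

struct Front {
  int a, d;          // attacker, defender (lower id labelled attacker if mutual)
  bool mutual;
  double aa, da;     // allocations
  double p;          // attacker win probability from allocations
  int winner;
  int moved_cell;    // province transferred in structural change (-1 if none)
};

static std::vector<Front> fronts_internal(const std::vector<Attack>& atk) {
  std::vector<Front> fr;
  std::map<std::pair<int, int>, size_t> idx;
  for (size_t i = 0; i < atk.size(); ++i) {
    int lo = std::min(atk[i].a, atk[i].t), hi = std::max(atk[i].a, atk[i].t);
    std::map<std::pair<int, int>, size_t>::iterator it = idx.find(std::make_pair(lo, hi));
    if (it == idx.end()) {
      idx[std::make_pair(lo, hi)] = fr.size();
      Front f; f.a = atk[i].a; f.d = atk[i].t; f.mutual = false;
      f.aa = f.da = f.p = 0.0; f.winner = 0; f.moved_cell = -1;
      fr.push_back(f);
    } else {
      Front& f = fr[it->second];
      f.mutual = true;
      if (f.a > f.d) std::swap(f.a, f.d);
    }
  }
  return fr;
}

// allocation phase: each belligerent splits its full stock across its fronts
// in proportion to each opponent's size (resource stock by default)
static void allocate_internal(const World& w, std::vector<Front>& fr) {
  std::vector<double> wsum(w.n() + 1, 0.0);
  for (size_t i = 0; i < fr.size(); ++i) {
    double wa = w.P.alloc_by_res ? w.res[fr[i].d - 1] : (double) w.nprov[fr[i].d - 1];
    double wd = w.P.alloc_by_res ? w.res[fr[i].a - 1] : (double) w.nprov[fr[i].a - 1];
    wsum[fr[i].a] += wa;
    wsum[fr[i].d] += wd;
  }
  for (size_t i = 0; i < fr.size(); ++i) {
    double wa = w.P.alloc_by_res ? w.res[fr[i].d - 1] : (double) w.nprov[fr[i].d - 1];
    double wd = w.P.alloc_by_res ? w.res[fr[i].a - 1] : (double) w.nprov[fr[i].a - 1];
    fr[i].aa = w.res[fr[i].a - 1] * wa / wsum[fr[i].a];
    fr[i].da = w.res[fr[i].d - 1] * wd / wsum[fr[i].d];
  }
}

// interaction phase: independent Bernoulli draw per front, true allocations
static void resolve_internal(const World& w, std::vector<Front>& fr) {
  for (size_t i = 0; i < fr.size(); ++i) {
    fr[i].p = csf_prob(fr[i].aa, fr[i].da, w.P);
    fr[i].winner = (unif_rand() < fr[i].p) ? fr[i].a : fr[i].d;
  }
}

// war costs: each belligerent pays q x opponent's allocation, floored at 0
static double war_costs_internal(World& w, const std::vector<Front>& fr) {
  if (w.P.q <= 0.0) return 0.0;
  double paid = 0.0;
  for (size_t i = 0; i < fr.size(); ++i) {
    double ca = std::min(w.res[fr[i].a - 1], w.P.q * fr[i].da);
    double cd = std::min(w.res[fr[i].d - 1], w.P.q * fr[i].aa);
    w.res[fr[i].a - 1] -= ca;
    w.res[fr[i].d - 1] -= cd;
    paid += ca + cd;
  }
  return paid;
}

struct ScReport { int transferred, destroyed, newborns; ScReport() : transferred(0), destroyed(0), newborns(0) {} };

// capital capture: the loser dissolves; every remaining province becomes an
// independent single-province state inheriting the loser's alpha
static void dissolve_all(World& w, int los, ScReport& rep) {
  w.alive[los - 1] = 0;
  rep.destroyed++;
  int cells = w.P.W * w.P.H;
  double a = w.alpha[los - 1];
  for (int cell = 0; cell < cells; ++cell) {
    if (w.owner[cell] == los) {
      w.newborn(cell, a);
      rep.newborns++;
    }
  }
  w.nprov[los - 1] = 0;
}

// provinces cut off from the loser's capital become singleton newborns
static void shed_cutoff(World& w, int los, ScReport& rep) {
  int cells = w.P.W * w.P.H;
  std::vector<char> seen(cells, 0);
  std::vector<int> stack;
  stack.push_back(w.cap[los - 1]);
  seen[w.cap[los - 1]] = 1;
  int nb[4], reached = 0;
  while (!stack.empty()) {
    int cell = stack.back();
    stack.pop_back();
    reached++;
    int m = neigh4(w.P, cell, nb);
    for (int i = 0; i < m; ++i) {
      if (!seen[nb[i]] && w.owner[nb[i]] == los) {
        seen[nb[i]] = 1;
        stack.push_back(nb[i]);
      }
    }
  }
  if (reached == w.nprov[los - 1]) return;
  double a = w.alpha[los - 1];
  for (int cell = 0; cell < cells; ++cell) {
    if (w.owner[cell] == los && !seen[cell]) {
      w.newborn(cell, a);
      rep.newborns++;
      w.nprov[los - 1]--;
    }
  }
}

// structural change: apply (winner, loser) resolutions in uniformly random
// order; skip those invalidated by earlier changes
static ScReport struct_change_internal(World& w, std::vector<Front>& fr) {
  std::vector<size_t> order(fr.size());
  for (size_t i = 0; i < fr.size(); ++i) order[i] = i;
  for (size_t i = fr.size(); i > 1; --i) {
    size_t j = (size_t) draw_index((int) i);
    std::swap(order[i - 1], order[j]);
  }
  ScReport rep;
  int nb[4];
  int cells = w.P.W * w.P.H;
  std::vector<int> cand;
  for (size_t oi = 0; oi < order.size(); ++oi) {
    Front& f = fr[order[oi]];
    int win = f.winner, los = (f.winner == f.a) ? f.d : f.a;
    if (!w.alive[win - 1] || !w.alive[los - 1]) continue;
    cand.clear();
    for (int cell = 0; cell < cells; ++cell) {
      if (w.owner[cell] != los) continue;
      int m = neigh4(w.P, cell, nb);
      for (int i = 0; i < m; ++i) {
        if (w.owner[nb[i]] == win) { cand.push_back(cell); break; }
      }
    }
    if (cand.empty()) continue;  // adjacency lost earlier this phase
    int cell = cand[cand.size() == 1 ? 0 : draw_index((int) cand.size())];
    w.owner[cell] = win;
    w.nprov[win - 1]++;
    w.nprov[los - 1]--;
    f.moved_cell = cell;
    rep.transferred++;
    if (cell == w.cap[los - 1]) dissolve_all(w, los, rep);
    else shed_cutoff(w, los, rep);
  }
  return rep;
}

struct StepRep {
  int attacks, battles, transferred, destroyed, newborns;
  double costs;
};

static StepRep step_internal(World& w, std::vector<Front>* keep_fronts) {
  extract_internal(w);
  std::vector<Attack> atk = decide_internal(w);
  std::vector<Front> fr = fronts_internal(atk);
  allocate_internal(w, fr);
  resolve_internal(w, fr);
  double costs = war_costs_internal(w, fr);
  ScReport sc = struct_change_internal(w, fr);
  w.t++;
  w.peace = fr.empty() ? w.peace + 1 : 0;
  if (keep_fronts) *keep_fronts = fr;
  StepRep rep;
  rep.attacks = (int) atk.size();
  rep.battles = (int) fr.size();
  rep.transferred = sc.transferred;
  rep.destroyed = sc.destroyed;
  rep.newborns = sc.newborns;
  rep.costs = costs;
  return rep;
}

// ---- R <-> C++ conversion --------------------------------------------------

static World world_in(List cfg, IntegerMatrix owner, List st) {
  World w;
  w.P = params_from(cfg);
  if (owner.nrow() != w.P.H || owner.ncol() != w.P.W)
    stop("owner matrix does not match configured grid dimensions");
  w.owner.assign(w.P.W * w.P.H, 0);
  for (int r = 0; r < w.P.H; ++r)
    for (int c = 0; c < w.P.W; ++c)
      w.owner[r * w.P.W + c] = owner(r, c);
  NumericVector alpha = st["alpha"], res = st["resources"];
  IntegerVector cr = st["capital_row"], cc = st["capital_col"];
  LogicalVector al = st["alive"];
  int n = alpha.size();
  w.alpha.assign(alpha.begin(), alpha.end());
  w.res.assign(res.begin(), res.end());
  for (int i = 0; i < n; ++i) {
    w.cap.push_back((cr[i] - 1) * w.P.W + (cc[i] - 1));
    w.alive.push_back(al[i] ? 1 : 0);
  }
  w.nprov.assign(n, 0);
  for (size_t cell = 0; cell < w.owner.size(); ++cell) {
    int o = w.owner[cell];
    if (o < 1 || o > n) stop("owner matrix refers to an unknown state id");
    w.nprov[o - 1]++;
  }
  return w;
}

static List world_out(const World& w) {
  IntegerMatrix owner(w.P.H, w.P.W);
  for (int r = 0; r < w.P.H; ++r)
    for (int c = 0; c < w.P.W; ++c)
      owner(r, c) = w.owner[r * w.P.W + c];
  int n = w.n();
  IntegerVector id(n), cr(n), cc(n);
  NumericVector alpha(n), res(n);
  LogicalVector alive(n);
  for (int i = 0; i < n; ++i) {
    id[i] = i + 1;
    alpha[i] = w.alpha[i];
    res[i] = w.res[i];
    cr[i] = w.cap[i] / w.P.W + 1;
    cc[i] = w.cap[i] % w.P.W + 1;
    alive[i] = w.alive[i] != 0;
  }
  return List::create(
    _["owner"] = owner,
    _["states"] = List::create(
      _["id"] = id, _["alpha"] = alpha, _["resources"] = res,
      _["capital_row"] = cr, _["capital_col"] = cc, _["alive"] = alive));
}

static DataFrame fronts_out(const std::vector<Front>& fr, const Params& P) {
  int n = (int) fr.size();
  IntegerVector a(n), d(n), winner(n), mr(n), mc(n);
  LogicalVector mutual(n);
  NumericVector aa(n), da(n), p(n);
  for (int i = 0; i < n; ++i) {
    a[i] = fr[i].a; d[i] = fr[i].d; mutual[i] = fr[i].mutual;
    aa[i] = fr[i].aa; da[i] = fr[i].da; p[i] = fr[i].p;
    winner[i] = fr[i].winner;
    mr[i] = fr[i].moved_cell < 0 ? NA_INTEGER : fr[i].moved_cell / P.W + 1;
    mc[i] = fr[i].moved_cell < 0 ? NA_INTEGER : fr[i].moved_cell % P.W + 1;
  }
  return DataFrame::create(
    _["attacker"] = a, _["defender"] = d, _["mutual"] = mutual,
    _["attacker_alloc"] = aa, _["defender_alloc"] = da,
    _["p_attacker"] = p, _["winner"] = winner,
    _["moved_row"] = mr, _["moved_col"] = mc);
}

// ---- exported entry points -------------------------------------------------

// [[Rcpp::export]]
List cpp_build_world(List cfg) {
  Params P = params_from(cfg);
  World w = build_world_internal(P);
  return world_out(w);
}

// [[Rcpp::export]]
List cpp_extract(List cfg, IntegerMatrix owner, List st) {
  World w = world_in(cfg, owner, st);
  extract_internal(w);
  return world_out(w);
}

// [[Rcpp::export]]
DataFrame cpp_decide(List cfg, IntegerMatrix owner, List st) {
  World w = world_in(cfg, owner, st);
  std::vector<Attack> atk = decide_internal(w);
  int n = (int) atk.size();
  IntegerVector a(n), t(n);
  NumericVector p(n);
  for (int i = 0; i < n; ++i) { a[i] = atk[i].a; t[i] = atk[i].t; p[i] = atk[i].phat; }
  return DataFrame::create(_["attacker"] = a, _["target"] = t, _["p_perceived"] = p);
}

// [[Rcpp::export]]
DataFrame cpp_fronts(IntegerVector attacker, IntegerVector target) {
  std::vector<Attack> atk(attacker.size());
  for (int i = 0; i < attacker.size(); ++i) {
    atk[i].a = attacker[i]; atk[i].t = target[i]; atk[i].phat = 0.0;
  }
  std::vector<Front> fr = fronts_internal(atk);
  int n = (int) fr.size();
  IntegerVector a(n), d(n);
  LogicalVector mutual(n);
  for (int i = 0; i < n; ++i) { a[i] = fr[i].a; d[i] = fr[i].d; mutual[i] = fr[i].mutual; }
  return DataFrame::create(_["attacker"] = a, _["defender"] = d, _["mutual"] = mutual);
}

// [[Rcpp::export]]
List cpp_allocate(List cfg, IntegerMatrix owner, List st,
                  IntegerVector attacker, IntegerVector defender, LogicalVector mutual) {
  World w = world_in(cfg, owner, st);
  std::vector<Front> fr(attacker.size());
  for (int i = 0; i < attacker.size(); ++i) {
    fr[i].a = attacker[i]; fr[i].d = defender[i]; fr[i].mutual = mutual[i];
    fr[i].aa = fr[i].da = fr[i].p = 0.0; fr[i].winner = 0; fr[i].moved_cell = -1;
  }
  allocate_internal(w, fr);
  int n = (int) fr.size();
  NumericVector aa(n), da(n);
  for (int i = 0; i < n; ++i) { aa[i] = fr[i].aa; da[i] = fr[i].da; }
  return List::create(_["attacker_alloc"] = aa, _["defender_alloc"] = da);
}

// [[Rcpp::export]]
List cpp_resolve(List cfg, IntegerVector attacker, IntegerVector defender,
                 NumericVector attacker_alloc, NumericVector defender_alloc) {
  Params P = params_from(cfg);
  World w; w.P = P;  // csf params only
  std::vector<Front> fr(attacker.size());
  for (int i = 0; i < attacker.size(); ++i) {
    fr[i].a = attacker[i]; fr[i].d = defender[i];
    fr[i].aa = attacker_alloc[i]; fr[i].da = defender_alloc[i];
  }
  resolve_internal(w, fr);
  int n = (int) fr.size();
  NumericVector p(n);
  IntegerVector winner(n);
  for (int i = 0; i < n; ++i) { p[i] = fr[i].p; winner[i] = fr[i].winner; }
  return List::create(_["p_attacker"] = p, _["winner"] = winner);
}

// [[Rcpp::export]]
List cpp_war_costs(List cfg, IntegerMatrix owner, List st,
                   IntegerVector attacker, IntegerVector defender,
                   NumericVector attacker_alloc, NumericVector defender_alloc) {
  World w = world_in(cfg, owner, st);
  std::vector<Front> fr(attacker.size());
  for (int i = 0; i < attacker.size(); ++i) {
    fr[i].a = attacker[i]; fr[i].d = defender[i];
    fr[i].aa = attacker_alloc[i]; fr[i].da = defender_alloc[i];
  }
  double paid = war_costs_internal(w, fr);
  List out = world_out(w);
  out["costs_paid"] = paid;
  return out;
}

// [[Rcpp::export]]
List cpp_struct_change(List cfg, IntegerMatrix owner, List st,
                       IntegerVector winner, IntegerVector loser) {
  World w = world_in(cfg, owner, st);
  std::vector<Front> fr(winner.size());
  for (int i = 0; i < winner.size(); ++i) {
    fr[i].a = winner[i]; fr[i].d = loser[i]; fr[i].winner = winner[i];
    fr[i].aa = fr[i].da = fr[i].p = 0.0; fr[i].mutual = false; fr[i].moved_cell = -1;
  }
  ScReport rep = struct_change_internal(w, fr);
  List out = world_out(w);
  out["transferred"] = rep.transferred;
  out["destroyed"] = rep.destroyed;
  out["newborns"] = rep.newborns;
  out["events"] = fronts_out(fr, w.P);
  return out;
}

// [[Rcpp::export]]
List cpp_step(List cfg, IntegerMatrix owner, List st, int t, int peace_streak) {
  World w = world_in(cfg, owner, st);
  w.t = t;
  w.peace = peace_streak;
  std::vector<Front> fr;
  StepRep rep = step_internal(w, &fr);
  List out = world_out(w);
  out["t"] = w.t;
  out["peace_streak"] = w.peace;
  out["report"] = List::create(
    _["step"] = w.t, _["attacks"] = rep.attacks, _["battles"] = rep.battles,
    _["provinces_transferred"] = rep.transferred, _["states_destroyed"] = rep.destroyed,
    _["newborn_states"] = rep.newborns, _["war_costs_paid"] = rep.costs);
  out["events"] = fronts_out(fr, w.P);
  return out;
}

static List run_loop(World& w, bool capture) {
  const Params& P = w.P;
  std::vector<double> s_step, s_n, s_med, s_bat;
  std::vector<IntegerVector> frames;
  s_step.push_back(w.t); s_n.push_back(w.nalive());
  s_med.push_back(w.median_alpha()); s_bat.push_back(0);
  if (capture) frames.push_back(IntegerVector(w.owner.begin(), w.owner.end()));
  int termination = 0;
  if (w.nalive() <= 1) termination = 1;
  else if (w.peace >= P.peace_stop) termination = 2;
  else if (w.t >= P.max_steps) termination = 3;
  while (termination == 0) {
    StepRep rep = step_internal(w, 0);
    s_step.push_back(w.t);
    s_n.push_back(w.nalive());
    s_med.push_back(w.median_alpha());
    s_bat.push_back(rep.battles);
    if (capture) frames.push_back(IntegerVector(w.owner.begin(), w.owner.end()));
    if (w.nalive() <= 1) termination = 1;
    else if (w.peace >= P.peace_stop) termination = 2;
    else if (w.t >= P.max_steps) termination = 3;
  }
  int T = (int) s_step.size();
  NumericMatrix series(T, 4);
  for (int i = 0; i < T; ++i) {
    series(i, 0) = s_step[i]; series(i, 1) = s_n[i];
    series(i, 2) = s_med[i]; series(i, 3) = s_bat[i];
  }
  List out = world_out(w);
  out["series"] = series;
  out["t"] = w.t;
  out["peace_streak"] = w.peace;
  out["termination"] = termination;
  if (capture) {
    List fl(frames.size());
    for (size_t i = 0; i < frames.size(); ++i) fl[i] = frames[i];
    out["snapshots"] = fl;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_run(List cfg, bool capture) {
  Params P = params_from(cfg);
  World w = build_world_internal(P);
  return run_loop(w, capture);
}

// [[Rcpp::export]]
List cpp_run_world(List cfg, IntegerMatrix owner, List st, int t, int peace_streak,
                   bool capture) {
  World w = world_in(cfg, owner, st);
  w.t = t;
  w.peace = peace_streak;
  return run_loop(w, capture);
}

// [[Rcpp::export]]
IntegerVector cpp_components(IntegerVector row, IntegerVector col,
                             int width, int height, bool torus) {
  Params P; P.W = width; P.H = height; P.torus = torus;
  int n = row.size();
  std::map<int, int> at;  // cell -> input index
  for (int i = 0; i < n; ++i) {
    int cell = (row[i] - 1) * width + (col[i] - 1);
    if (at.count(cell)) stop("duplicate cells in territory");
    at[cell] = i;
  }
  IntegerVector label(n, 0);
  int nb[4], comp = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (label[i] != 0) continue;
    comp++;
    label[i] = comp;
    stack.clear();
    stack.push_back((row[i] - 1) * width + (col[i] - 1));
    while (!stack.empty()) {
      int cell = stack.back();
      stack.pop_back();
      int m = neigh4(P, cell, nb);
      for (int j = 0; j < m; ++j) {
        std::map<int, int>::iterator it = at.find(nb[j]);
        if (it != at.end() && label[it->second] == 0) {
          label[it->second] = comp;
          stack.push_back(nb[j]);
        }
      }
    }
  }
  return label;
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbour_pairs(IntegerMatrix owner, bool torus) {
  Params P; P.H = owner.nrow(); P.W = owner.ncol(); P.torus = torus;
  std::vector<int> ow(P.W * P.H);
  for (int r = 0; r < P.H; ++r)
    for (int c = 0; c < P.W; ++c)
      ow[r * P.W + c] = owner(r, c);
  std::set<std::pair<int, int> > pairs;
  int nb[4];
  for (int cell = 0; cell < P.W * P.H; ++cell) {
    int m = neigh4(P, cell, nb);
    for (int i = 0; i < m; ++i) {
      int a = ow[cell], b = ow[nb[i]];
      if (a != b) pairs.insert(std::make_pair(std::min(a, b), std::max(a, b)));
    }
  }
  IntegerMatrix out((int) pairs.size(), 2);
  int i = 0;
  for (std::set<std::pair<int, int> >::iterator it = pairs.begin(); it != pairs.end(); ++it, ++i) {
    out(i, 0) = it->first;
    out(i, 1) = it->second;
  }
  return out;
}
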