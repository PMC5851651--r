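// Compiled kernels: identity clustering for sequence weights, and the
// exact branch-and-bound backend for single-objective solves of the
// design ILP under objective-space box constraints.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Cluster sizes at identity threshold theta: for each sequence, the number
// of sequences (itself included) with identity >= theta. Gap states (and
// gap-gap pairs) count as mismatches.
// [[Rcpp::export]]
NumericVector cluster_sizes_cpp(IntegerMatrix enc, double theta,
                                int gap_state) {
  const int n = enc.nrow(), L = enc.ncol();
  NumericVector counts(n, 1.0);
  std::vector<int> e(n * L);
  for (int s = 0; s < n; ++s)
    for (int c = 0; c < L; ++c) e[s * L + c] = enc(s, c);
  for (int s = 0; s < n; ++s) {
    const int* es = &e[s * L];
    for (int t = s + 1; t < n; ++t) {
      const int* et = &e[t * L];
      int match = 0;
      for (int c = 0; c < L; ++c) {
        if (es[c] == et[c] && es[c] != gap_state) ++match;
      }
      if ((double)match / L >= theta) {
        counts[s] += 1.0;
        counts[t] += 1.0;
      }
    }
  }
  return counts;
}

namespace {

struct Window {
  double base;     // fixed contribution (immutable residues) minus tau
  double weight;   // allele population frequency p_h
  std::vector<int> slots;                      // free-position indices, 0-based
  std::vector<std::vector<double>> contrib;    // per slot, per option
  std::vector<double> rem_min, rem_max;        // suffix sums over slots with pos > d
};

struct Problem {
  int nf, k, objective;
  double z1const, z2const;
  double l1, u1, l2, u2;
  std::vector<int> nopt, wt;
  std::vector<std::vector<double>> field;      // z2 contribution per option
  std::vector<std::pair<int,int>> pairs;       // 0-based (p < q)
  std::vector<NumericMatrix> pairJ;            // z2 contribution
  std::vector<std::vector<int>> pairs_by_second; // pair idx with q == pos
  std::vector<double> pair_min_suffix, pair_max_suffix; // pairs with p > d
  std::vector<Window> windows;
  std::vector<std::vector<std::pair<int,int>>> win_by_pos; // (window, slot)
};

struct State {
  std::vector<int> assign;
  std::vector<double> winpart;
  double z2part;
  int muts;
  double best_obj;
  bool found;
  std::vector<int> best_assign;
  double best_z1, best_z2;
  long nodes;
};

const double FTOL = 1e-9;
const double PRUNE_EPS = 1e-12;

void eval_leaf(const Problem& P, State& S) {
  double z1 = P.z1const;
  for (size_t w = 0; w < P.windows.size(); ++w) {
    double v = S.winpart[w];
    if (v > 0) z1 += P.windows[w].weight * v;
  }
  double z2 = S.z2part;
  if (z1 < P.l1 - FTOL || z1 > P.u1 + FTOL) return;
  if (z2 < P.l2 - FTOL || z2 > P.u2 + FTOL) return;
  double obj = (P.objective == 1) ? z1 : z2;
  if (!S.found || obj < S.best_obj - PRUNE_EPS) {
    S.found = true;
    S.best_obj = obj;
    S.best_assign = S.assign;
    S.best_z1 = z1;
    S.best_z2 = z2;
  }
}

// Assign option a at position d, updating partial state; returns the undo
// deltas via arguments.
void apply_assign(const Problem& P, State& S, int d, int a) {
  S.assign[d] = a;
  double dz2 = P.field[d][a];
  for (int pp : P.pairs_by_second[d]) {
    int i = P.pairs[pp].first;
    dz2 += P.pairJ[pp](S.assign[i], a);
  }
  S.z2part += dz2;
  for (auto& ws : P.win_by_pos[d]) {
    S.winpart[ws.first] += P.windows[ws.first].contrib[ws.second][a];
  }
  if (a != P.wt[d]) S.muts += 1;
}

void undo_assign(const Problem& P, State& S, int d, int a) {
  double dz2 = P.field[d][a];
  for (int pp : P.pairs_by_second[d]) {
    int i = P.pairs[pp].first;
    dz2 += P.pairJ[pp](S.assign[i], a);
  }
  S.z2part -= dz2;
  for (auto& ws : P.win_by_pos[d]) {
    S.winpart[ws.first] -= P.windows[ws.first].contrib[ws.second][a];
  }
  if (a != P.wt[d]) S.muts -= 1;
  S.assign[d] = -1;
}

void dfs(const Problem& P, State& S, int d);

// Remaining budget exhausted: complete with wild type, evaluate, backtrack.
void complete_wt(const Problem& P, State& S, int d) {
  if (d == P.nf) { eval_leaf(P, S); return; }
  apply_assign(P, S, d, P.wt[d]);
  complete_wt(P, S, d + 1);
  undo_assign(P, S, d, P.wt[d]);
}

// Admissible bounds over completions of the partial assignment at depth d
// (positions 0..d-1 assigned), relaxing the mutation budget.
void bounds(const Problem& P, const State& S, int d,
            double& z1lo, double& z1hi, double& z2lo, double& z2hi) {
  z2lo = S.z2part + P.pair_min_suffix[d];
  z2hi = S.z2part + P.pair_max_suffix[d];
  for (int j = d; j < P.nf; ++j) {
    double lo = std::numeric_limits<double>::infinity();
    double hi = -std::numeric_limits<double>::infinity();
    for (int a = 0; a < P.nopt[j]; ++a) {
      double v = P.field[j][a];
      for (int pp : P.pairs_by_second[j]) {
        int i = P.pairs[pp].first;
        if (i < d) v += P.pairJ[pp](S.assign[i], a);
      }
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    z2lo += lo;
    z2hi += hi;
  }
  z1lo = P.z1const;
  z1hi = P.z1const;
  for (size_t w = 0; w < P.windows.size(); ++w) {
    double lo = S.winpart[w] + P.windows[w].rem_min[d];
    double hi = S.winpart[w] + P.windows[w].rem_max[d];
    if (lo > 0) z1lo += P.windows[w].weight * lo;
    if (hi > 0) z1hi += P.windows[w].weight * hi;
  }
}

void dfs(const Problem& P, State& S, int d) {
  S.nodes += 1;
  if (d == P.nf) { eval_leaf(P, S); return; }
  if (S.muts == P.k) { complete_wt(P, S, d); return; }
  double z1lo, z1hi, z2lo, z2hi;
  bounds(P, S, d, z1lo, z1hi, z2lo, z2hi);
  if (z1lo > P.u1 + FTOL || z1hi < P.l1 - FTOL) return;
  if (z2lo > P.u2 + FTOL || z2hi < P.l2 - FTOL) return;
  if (S.found) {
    double objlo = (P.objective == 1) ? z1lo : z2lo;
    if (objlo >= S.best_obj - PRUNE_EPS) return;
  }
  for (int a = 0; a < P.nopt[d]; ++a) {
    apply_assign(P, S, d, a);
    dfs(P, S, d + 1);
    undo_assign(P, S, d, a);
  }
}

} // namespace

// Exact single-objective solve of the compiled design instance within an
// objective-space box. Options are 0-based internally; the R wrapper uses
// 1-based indices into each position's candidate set.
// [[Rcpp::export]]
List bb_solve_cpp(List compiled, int objective, NumericVector box) {
  Problem P;
  P.nf = as<int>(compiled["nf"]);
  P.k = as<int>(compiled["k"]);
  P.objective = objective;
  P.z1const = as<double>(compiled["z1const"]);
  P.z2const = as<double>(compiled["z2const"]);
  P.l1 = box[0]; P.u1 = box[1]; P.l2 = box[2]; P.u2 = box[3];

  IntegerVector nopt = compiled["nopt"];
  IntegerVector wt = compiled["wt"];
  List field = compiled["field"];
  P.nopt.resize(P.nf);
  P.wt.resize(P.nf);
  P.field.resize(P.nf);
  for (int i = 0; i < P.nf; ++i) {
    P.nopt[i] = nopt[i];
    P.wt[i] = wt[i] - 1;
    NumericVector f = field[i];
    P.field[i] = std::vector<double>(f.begin(), f.end());
  }
  IntegerMatrix prs = compiled["pairs"];
  List pairJ = compiled["pairJ"];
  int npair = prs.nrow();
  P.pairs_by_second.resize(P.nf);
  P.pair_min_suffix.assign(P.nf + 1, 0.0);
  P.pair_max_suffix.assign(P.nf + 1, 0.0);
  std::vector<double> pmin(npair), pmax(npair);
  for (int pp = 0; pp < npair; ++pp) {
    int a = prs(pp, 0) - 1, b = prs(pp, 1) - 1;
    P.pairs.push_back({a, b});
    NumericMatrix J = pairJ[pp];
    P.pairJ.push_back(J);
    P.pairs_by_second[b].push_back(pp);
    double lo = J(0, 0), hi = J(0, 0);
    for (int r = 0; r < J.nrow(); ++r)
      for (int c = 0; c < J.ncol(); ++c) {
        if (J(r, c) < lo) lo = J(r, c);
        if (J(r, c) > hi) hi = J(r, c);
      }
    pmin[pp] = lo; pmax[pp] = hi;
  }
  // pairs with both positions unassigned at depth d: first index >= d
  for (int d = P.nf - 1; d >= 0; --d) {
    P.pair_min_suffix[d] = P.pair_min_suffix[d + 1];
    P.pair_max_suffix[d] = P.pair_max_suffix[d + 1];
    for (int pp = 0; pp < npair; ++pp) {
      if (P.pairs[pp].first == d) {
        P.pair_min_suffix[d] += pmin[pp];
        P.pair_max_suffix[d] += pmax[pp];
      }
    }
  }
  List wins = compiled["windows"];
  P.win_by_pos.resize(P.nf);
  for (int w = 0; w < wins.size(); ++w) {
    List wl = wins[w];
    Window W;
    W.base = as<double>(wl["base"]);
    W.weight = as<double>(wl["weight"]);
    IntegerVector slots = wl["slots"];
    List contrib = wl["contrib"];
    for (int s = 0; s < slots.size(); ++s) {
      int pos = slots[s] - 1;
      W.slots.push_back(pos);
      NumericVector cv = contrib[s];
      W.contrib.push_back(std::vector<double>(cv.begin(), cv.end()));
      P.win_by_pos[pos].push_back({w, s});
    }
    W.rem_min.assign(P.nf + 1, 0.0);
    W.rem_max.assign(P.nf + 1, 0.0);
    for (int d = P.nf - 1; d >= 0; --d) {
      W.rem_min[d] = W.rem_min[d + 1];
      W.rem_max[d] = W.rem_max[d + 1];
      for (size_t s = 0; s < W.slots.size(); ++s) {
        if (W.slots[s] == d) {
          double lo = W.contrib[s][0], hi = W.contrib[s][0];
          for (double v : W.contrib[s]) {
            if (v < lo) lo = v;
            if (v > hi) hi = v;
          }
          W.rem_min[d] += lo;
          W.rem_max[d] += hi;
        }
      }
    }
    P.windows.push_back(std::move(W));
  }

  State S;
  S.assign.assign(P.nf, -1);
  S.winpart.resize(P.windows.size());
  for (size_t w = 0; w < P.windows.size(); ++w) S.winpart[w] = P.windows[w].base;
  S.z2part = P.z2const;
  S.muts = 0;
  S.found = false;
  S.best_obj = std::numeric_limits<double>::infinity();
  S.nodes = 0;

  dfs(P, S, 0);

  if (!S.found) {
    return List::create(_["status"] = "infeasible",
                        _["nodes"] = (double)S.nodes);
  }
  IntegerVector assign(P.nf);
  for (int i = 0; i < P.nf; ++i) assign[i] = S.best_assign[i] + 1;
  return List::create(_["status"] = "optimal",
                      _["assign"] = assign,
                      _["z1"] = S.best_z1,
                      _["z2"] = S.best_z2,
                      _["nodes"] = (double)S.nodes);
}
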