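// Simulated-annealing structure search with BDeu scoring.
//
// The chain state is a DAG over the data variables; local moves are single
// edge additions, deletions and reversals, drawn uniformly among the valid
// moves by rejection sampling from the structural superset. Family scores
// are cached by (node, parent set), which makes the score delta of a move a
// couple of hash lookups after warm-up. Randomness comes from R's RNG so a
// set.seed() in the calling R code fixes the whole run.

#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

namespace {

struct Engine {
  int n;                 // variables
  int m;                 // samples
  IntegerMatrix data;    // n x m, 0-based states
  IntegerVector arity;
  double ess;
  int max_parents;

  std::vector<char> adj;             // n*n adjacency, adj[u*n+v] = u->v
  std::vector<std::pair<int,int>> edges;
  std::vector<std::vector<int>> par; // sorted parent lists
  std::vector<std::map<std::vector<int>, double>> cache;

  Engine(const IntegerMatrix& d, const IntegerVector& ar, double ess_,
         int maxp)
    : n(d.nrow()), m(d.ncol()), data(d), arity(ar), ess(ess_),
      max_parents(maxp), adj(n * n, 0), par(n), cache(n) {}

  bool has(int u, int v) const { return adj[u * n + v] != 0; }

  // is there a directed path from `from` to `to`? (edge skip_u->skip_v
  // treated as absent; pass -1 to skip nothing)
  bool path_exists(int from, int to, int skip_u, int skip_v) const {
    std::vector<char> seen(n, 0);
    std::vector<int> stack{from};
    seen[from] = 1;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      if (u == to) return true;
      for (int v = 0; v < n; ++v) {
        if (!has(u, v) || seen[v]) continue;
        if (u == skip_u && v == skip_v) continue;
        seen[v] = 1;
        stack.push_back(v);
      }
    }
    return false;
  }

  double family_score(int node, const std::vector<int>& pars) {
    auto& c = cache[node];
    auto it = c.find(pars);
    if (it != c.end()) return it->second;

    int r = arity[node];
    double qd = 1.0;
    for (int p : pars) qd *= arity[p];
    double sc;
    if (qd * r > 5e6) {
      // parent set too large to tabulate; such structures are never
      // competitive and the -Inf score keeps the chain away from them
      sc = -std::numeric_limits<double>::infinity();
    } else if (m == 0) {
      sc = 0.0;
    } else {
      long q = (long) qd;
      double aijk = ess / (r * (double) q);
      double aij = ess / (double) q;
      std::vector<int> counts((size_t) q * r, 0);
      for (int s = 0; s < m; ++s) {
        long idx = 0, stride = 1;
        for (int p : pars) { idx += (long) data(p, s) * stride; stride *= arity[p]; }
        counts[(size_t) idx * r + data(node, s)]++;
      }
      sc = 0.0;
      double lg_aijk = std::lgamma(aijk), lg_aij = std::lgamma(aij);
      for (long j = 0; j < q; ++j) {
        int nij = 0;
        bool any = false;
        for (int k = 0; k < r; ++k) {
          int njk = counts[(size_t) j * r + k];
          if (njk > 0) {
            nij += njk;
            sc += std::lgamma(aijk + njk) - lg_aijk;
            any = true;
          }
        }
        if (any) sc += lg_aij - std::lgamma(aij + nij);
      }
    }
    c[pars] = sc;
    return sc;
  }

  static std::vector<int> with(const std::vector<int>& v, int x) {
    std::vector<int> out(v);
    out.insert(std::lower_bound(out.begin(), out.end(), x), x);
    return out;
  }
  static std::vector<int> without(const std::vector<int>& v, int x) {
    std::vector<int> out(v);
    out.erase(std::find(out.begin(), out.end(), x));
    return out;
  }

  void apply_add(int u, int v) {
    adj[u * n + v] = 1;
    edges.emplace_back(u, v);
    par[v] = with(par[v], u);
  }
  void apply_delete(size_t idx) {
    int u = edges[idx].first, v = edges[idx].second;
    adj[u * n + v] = 0;
    edges[idx] = edges.back();
    edges.pop_back();
    par[v] = without(par[v], u);
  }
  void apply_reverse(size_t idx) {
    int u = edges[idx].first, v = edges[idx].second;
    adj[u * n + v] = 0;
    adj[v * n + u] = 1;
    edges[idx] = {v, u};
    par[v] = without(par[v], u);
    par[u] = with(par[u], v);
  }

  std::vector<int> canonical_key() const {
    std::vector<int> key;
    key.reserve(edges.size());
    for (auto& e : edges) key.push_back(e.first * n + e.second);
    std::sort(key.begin(), key.end());
    return key;
  }
};

struct TopTracker {
  size_t top_n;
  std::map<std::vector<int>, double> member;
  std::multimap<double, std::vector<int>> by_score;

  explicit TopTracker(size_t k) : top_n(k) {}

  void record(const std::vector<int>& key, double score) {
    if (member.count(key)) return;
    if (member.size() >= top_n) {
      if (score <= by_score.begin()->first) return;
      member.erase(by_score.begin()->second);
      by_score.erase(by_score.begin());
    }
    member[key] = score;
    by_score.emplace(score, key);
  }
};

} // namespace

// [[Rcpp::export(name = ".sa_search_cpp")]]
List sa_search_cpp(IntegerMatrix data, IntegerVector arity,
                   double n_proposals_, int top_n, double ess,
                   double t0, double cooling, double steps_per_level_,
                   double reanneal_after, int max_parents,
                   bool track_trajectory) {
  long long n_proposals = (long long) n_proposals_;
  long long steps_per_level = (long long) steps_per_level_;
  Engine eng(data, arity, ess, max_parents);
  int n = eng.n;
  if (n < 2) stop("need >= 2 variables");

  double score = 0.0;
  for (int v = 0; v < n; ++v) score += eng.family_score(v, eng.par[v]);

  TopTracker top((size_t) top_n);
  top.record(eng.canonical_key(), score);

  std::vector<double> traj;
  if (track_trajectory) traj.push_back(score);

  double T = t0;
  double since_accept = 0;
  const double P = (double) n * (n - 1);
  long n_accepted = 0;

  for (long long iter = 0; iter < n_proposals; ++iter) {
    if (steps_per_level > 0 && iter > 0 && iter % steps_per_level == 0)
      T *= cooling;
    if (reanneal_after > 0 && since_accept >= reanneal_after) {
      T = t0;
      since_accept = 0;
    }

    // draw a move uniformly among valid ones (rejection sampling)
    int type = -1;      // 0 add, 1 delete, 2 reverse
    int mu = -1, mv = -1;
    size_t eidx = 0;
    for (int attempt = 0; attempt < 10000 && type < 0; ++attempt) {
      double E = (double) eng.edges.size();
      double c = unif_rand() * P;
      if (c < E) {                       // delete
        eidx = (size_t) c;
        type = 1;
      } else if (c < 2 * E) {            // reverse
        eidx = (size_t) (c - E);
        int u = eng.edges[eidx].first, v = eng.edges[eidx].second;
        if ((int) eng.par[u].size() + 1 > max_parents) continue;
        if (eng.path_exists(u, v, u, v)) continue;  // reversal closes a cycle
        type = 2;
      } else {                           // add: absent pair, no opposite edge
        int u = (int) (unif_rand() * n);
        int v = (int) (unif_rand() * n);
        if (u >= n) u = n - 1;
        if (v >= n) v = n - 1;
        if (u == v || eng.has(u, v) || eng.has(v, u)) continue;
        if ((int) eng.par[v].size() + 1 > max_parents) continue;
        if (eng.path_exists(v, u, -1, -1)) continue;
        type = 0; mu = u; mv = v;
      }
    }
    if (type < 0) break;  // no valid move found (saturated tiny graph)

    double delta;
    if (type == 0) {
      delta = eng.family_score(mv, Engine::with(eng.par[mv], mu)) -
              eng.family_score(mv, eng.par[mv]);
    } else if (type == 1) {
      int u = eng.edges[eidx].first, v = eng.edges[eidx].second;
      delta = eng.family_score(v, Engine::without(eng.par[v], u)) -
              eng.family_score(v, eng.par[v]);
    } else {
      int u = eng.edges[eidx].first, v = eng.edges[eidx].second;
      delta = eng.family_score(v, Engine::without(eng.par[v], u)) -
              eng.family_score(v, eng.par[v]) +
              eng.family_score(u, Engine::with(eng.par[u], v)) -
              eng.family_score(u, eng.par[u]);
    }

    bool accept = delta >= 0 ||
      (T > 0 && std::isfinite(delta) && unif_rand() < std::exp(delta / T));
    if (accept) {
      if (type == 0) eng.apply_add(mu, mv);
      else if (type == 1) eng.apply_delete(eidx);
      else eng.apply_reverse(eidx);
      score += delta;
      since_accept = 0;
      ++n_accepted;
      top.record(eng.canonical_key(), score);
      if (track_trajectory) traj.push_back(score);
    } else {
      ++since_accept;
    }
  }

  // emit the tracked structures, best first
  std::vector<std::pair<double, const std::vector<int>*>> ranked;
  for (auto& kv : top.member) ranked.push_back({kv.second, &kv.first});
  std::sort(ranked.begin(), ranked.end(),
            [](const std::pair<double, const std::vector<int>*>& a,
               const std::pair<double, const std::vector<int>*>& b) {
              return a.first > b.first;
            });

  List out_edges(ranked.size());
  NumericVector out_scores(ranked.size());
  for (size_t i = 0; i < ranked.size(); ++i) {
    const std::vector<int>& key = *ranked[i].second;
    IntegerMatrix em(key.size(), 2);
    for (size_t j = 0; j < key.size(); ++j) {
      em(j, 0) = key[j] / n + 1;  // parent, 1-based
      em(j, 1) = key[j] % n + 1;  // child
    }
    out_edges[i] = em;
    out_scores[i] = ranked[i].first;
  }

  return List::create(_["edges"] = out_edges,
                      _["scores"] = out_scores,
                      _["n_accepted"] = (double) n_accepted,
                      _["trajectory"] = traj);
}
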