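// Correspondence-graph seed search.
//
// A node is a candidate residue pairing (i in P1, j in P2); two nodes are
// joined when their residue dyads have compatible (ca, cb, cn) distance
// triplets (triplet RMSD < tol).  A clique in this graph is a mutually
// consistent partial alignment.  Seeds are grown from every compatible
// starting dyad (edge) by a bounded backtracking depth-first search:
// candidates are taken best-first (smallest worst-case dyad RMSD to the
// current clique); a candidate that has been explored at a level joins that
// level's visited set and is not retried, which enumerates each maximal
// clique containing the start edge once.  Per-start expansion budgets and a
// cap on the number of starts bound the work on large or highly similar
// pockets; tiny instances are searched exhaustively.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <set>
#include <vector>
using namespace Rcpp;

namespace {

struct Seed {
  std::vector<int> nodes;  // sorted node ids
  double blosum;
};

struct Searcher {
  int n1, n2, nn;
  double tol;
  std::vector<float> rm;  // nn x nn dyad RMSD, INF when incompatible
  const double *blos;     // per-node raw BLOSUM score
  long budget;
  std::set<std::vector<int> > seen;
  std::vector<Seed> seeds;
  int best_len;

  float R(int u, int v) const { return rm[(size_t)u * nn + v]; }

  void record(std::vector<int> clique) {
    std::sort(clique.begin(), clique.end());
    if (!seen.insert(clique).second) return;
    double b = 0.0;
    for (size_t q = 0; q < clique.size(); ++q) b += blos[clique[q]];
    Seed s;
    s.nodes = clique;
    s.blosum = b;
    seeds.push_back(s);
    if ((int)clique.size() > best_len) best_len = (int)clique.size();
  }

  struct Cand {
    int node;
    float maxr;
    bool operator<(const Cand &o) const {
      if (maxr != o.maxr) return maxr < o.maxr;
      return node < o.node;
    }
  };

  // cands: nodes compatible with every clique member, best-first.
  void dfs(std::vector<int> &clique, const std::vector<Cand> &cands) {
    if (cands.empty()) {
      record(clique);
      return;
    }
    for (size_t c = 0; c < cands.size(); ++c) {
      if (budget <= 0) {
        // budget exhausted: finish this branch greedily (first candidate
        // only), then stop backtracking
        int w = cands[c].node;
        clique.push_back(w);
        std::vector<Cand> nxt;
        filter(cands, c, w, nxt);
        dfs(clique, nxt);
        clique.pop_back();
        return;
      }
      --budget;
      int w = cands[c].node;
      clique.push_back(w);
      std::vector<Cand> nxt;
      filter(cands, c, w, nxt);
      dfs(clique, nxt);
      clique.pop_back();
      // w now belongs to this level's visited set: later branches at this
      // level ignore it (handled by starting the filter past index c)
    }
  }

  // keep candidates after position c that are compatible with w
  void filter(const std::vector<Cand> &cands, size_t c, int w,
              std::vector<Cand> &out) const {
    int wi = w / n2, wj = w % n2;
    out.reserve(cands.size());
    for (size_t q = c + 1; q < cands.size(); ++q) {
      int v = cands[q].node;
      if (v / n2 == wi || v % n2 == wj) continue;
      float r = R(w, v);
      if (r >= tol) continue;
      Cand nc;
      nc.node = v;
      nc.maxr = std::max(cands[q].maxr, r);
      out.push_back(nc);
    }
    std::sort(out.begin(), out.end());
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_seed_search")]]
List cpp_seed_search(NumericVector d1, NumericVector d2, int n1, int n2,
                     double tol, int max_seeds, NumericVector node_blosum,
                     int max_starts, int budget_per_start) {
  const double *p1 = d1.begin(), *p2 = d2.begin();
  Searcher S;
  S.n1 = n1;
  S.n2 = n2;
  S.nn = n1 * n2;
  S.tol = tol;
  S.blos = node_blosum.begin();
  S.best_len = 0;
  const float INF = std::numeric_limits<float>::infinity();
  S.rm.assign((size_t)S.nn * S.nn, INF);

  // node u = i * n2 + j  (0-based); d arrays are n x n x 3, column-major
  for (int u = 0; u < S.nn; ++u) {
    int i = u / n2, j = u % n2;
    for (int v = u + 1; v < S.nn; ++v) {
      int k = v / n2, l = v % n2;
      if (k == i || l == j) continue;
      double s = 0.0;
      for (int c = 0; c < 3; ++c) {
        double a = p1[i + (size_t)k * n1 + (size_t)c * n1 * n1];
        double b = p2[j + (size_t)l * n2 + (size_t)c * n2 * n2];
        s += (a - b) * (a - b);
      }
      double r = std::sqrt(s / 3.0);
      if (r < tol) {
        S.rm[(size_t)u * S.nn + v] = (float)r;
        S.rm[(size_t)v * S.nn + u] = (float)r;
      }
    }
  }

  // starting dyads: all edges, smallest RMSD first
  std::vector<std::pair<float, std::pair<int, int> > > edges;
  for (int u = 0; u < S.nn; ++u)
    for (int v = u + 1; v < S.nn; ++v) {
      float r = S.R(u, v);
      if (r < tol) edges.push_back(std::make_pair(r, std::make_pair(u, v)));
    }
  std::sort(edges.begin(), edges.end());
  if ((int)edges.size() > max_starts) edges.resize(max_starts);

  int full = std::min(n1, n2);
  for (size_t e = 0; e < edges.size(); ++e) {
    int u = edges[e].second.first, v = edges[e].second.second;
    std::vector<int> clique;
    clique.push_back(u);
    clique.push_back(v);
    std::vector<Searcher::Cand> cands;
    int ui = u / n2, uj = u % n2, vi = v / n2, vj = v % n2;
    for (int w = 0; w < S.nn; ++w) {
      if (w == u || w == v) continue;
      int wi = w / n2, wj = w % n2;
      if (wi == ui || wi == vi || wj == uj || wj == vj) continue;
      float ru = S.R(u, w), rv = S.R(v, w);
      if (ru >= tol || rv >= tol) continue;
      Searcher::Cand c;
      c.node = w;
      c.maxr = std::max(ru, rv);
      cands.push_back(c);
    }
    std::sort(cands.begin(), cands.end());
    S.budget = budget_per_start;
    S.dfs(clique, cands);
    if (S.best_len >= full) break;  // a full-length seed cannot be beaten
  }

  // rank: length desc, raw BLOSUM sum desc, lexicographic node order asc
  std::sort(S.seeds.begin(), S.seeds.end(),
            [](const Seed &a, const Seed &b) {
              if (a.nodes.size() != b.nodes.size())
                return a.nodes.size() > b.nodes.size();
              if (a.blosum != b.blosum) return a.blosum > b.blosum;
              return a.nodes < b.nodes;
            });
  int keep = std::min((int)S.seeds.size(), max_seeds);
  List out(keep);
  for (int s = 0; s < keep; ++s) {
    const std::vector<int> &nd = S.seeds[s].nodes;
    IntegerMatrix pr(nd.size(), 2);
    for (size_t q = 0; q < nd.size(); ++q) {
      pr(q, 0) = nd[q] / n2 + 1;  // 1-based residue indices
      pr(q, 1) = nd[q] % n2 + 1;
    }
    out[s] = List::create(Named("pairs") = pr,
                          Named("blosum") = S.seeds[s].blosum);
  }
  return out;
}
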