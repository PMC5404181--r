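#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Connected-subgraph enumeration (ESU) for k in {3,4} with classification
// by the induced degree sequence, which identifies every connected graph
// on at most four nodes uniquely.
//
// Class indices:
//   k=3: 0 path3 (1,1,2)   1 triangle (2,2,2)
//   k=4: 0 path4   (1,1,2,2)
//        1 star4   (1,1,1,3)
//        2 cycle4  (2,2,2,2)
//        3 tadpole4(1,2,2,3)
//        4 diamond4(2,2,3,3)
//        5 clique4 (3,3,3,3)
//
// With per-depth branch-retention probabilities < 1 this becomes RAND-ESU:
// every recorded subgraph is up-weighted by the inverse of its inclusion
// probability (Horvitz-Thompson), giving unbiased count estimates.

namespace {

struct Esu {
  int n, k;
  const std::vector< std::vector<int> >& adj;
  std::vector<char> inSub;
  std::vector<int> sub;
  std::vector< std::vector<int> > extBuf; // per-depth extension buffers
  std::vector<double>& counts;
  const std::vector<double>& prob;
  double weight;
  bool sampling;

  Esu(int n_, int k_, const std::vector< std::vector<int> >& adj_,
      std::vector<double>& counts_, const std::vector<double>& prob_)
    : n(n_), k(k_), adj(adj_), inSub(n_, 0), extBuf(k_ + 1),
      counts(counts_), prob(prob_) {
    sampling = false;
    double p = 1.0;
    for (double q : prob) { if (q < 1.0) sampling = true; p *= q; }
    weight = 1.0 / p;
    sub.reserve(k_);
  }

  bool edge(int u, int v) const {
    const std::vector<int>& a = adj[u];
    return std::binary_search(a.begin(), a.end(), v);
  }

  // number of edges from u into the current sub
  int degToSub(int u) const {
    int d = 0;
    for (int s : sub) if (edge(u, s)) ++d;
    return d;
  }

  void record() {
    if (k == 3) {
      int e = edge(sub[0], sub[1]) + edge(sub[0], sub[2]) +
              edge(sub[1], sub[2]);
      counts[e == 3 ? 1 : 0] += weight;
    } else {
      int d0 = 0, d1 = 0, d2 = 0, d3 = 0, e = 0;
      if (edge(sub[0], sub[1])) { ++e; ++d0; ++d1; }
      if (edge(sub[0], sub[2])) { ++e; ++d0; ++d2; }
      if (edge(sub[0], sub[3])) { ++e; ++d0; ++d3; }
      if (edge(sub[1], sub[2])) { ++e; ++d1; ++d2; }
      if (edge(sub[1], sub[3])) { ++e; ++d1; ++d3; }
      if (edge(sub[2], sub[3])) { ++e; ++d2; ++d3; }
      int cls;
      if (e == 6) cls = 5;
      else if (e == 5) cls = 4;
      else {
        int mx = std::max(std::max(d0, d1), std::max(d2, d3));
        if (e == 4) cls = (mx == 3) ? 3 : 2;
        else cls = (mx == 3) ? 1 : 0; // e == 3, connected
      }
      counts[cls] += weight;
    }
  }

  void extend(int depth, int v) {
    std::vector<int>& ext = extBuf[depth];
    if (depth + 1 == k) {
      for (int w : ext) {
        if (sampling && prob[depth] < 1.0 && unif_rand() >= prob[depth])
          continue;
        sub.push_back(w);
        record();
        sub.pop_back();
      }
      return;
    }
    std::vector<int>& nxt = extBuf[depth + 1];
    for (size_t i = 0; i < ext.size(); ++i) {
      int w = ext[i];
      if (sampling && prob[depth] < 1.0 && unif_rand() >= prob[depth])
        continue;
      nxt.assign(ext.begin() + i + 1, ext.end());
      // exclusive neighbors of w: > v, not in sub, not adjacent to sub
      // (nodes already in ext are adjacent to sub, so no duplicates)
      for (int u : adj[w]) {
        if (u <= v || inSub[u]) continue;
        if (degToSub(u) == 0) nxt.push_back(u);
      }
      sub.push_back(w); inSub[w] = 1;
      extend(depth + 1, v);
      sub.pop_back(); inSub[w] = 0;
    }
  }

  void run() {
    for (int v = 0; v < n; ++v) {
      if (sampling && prob[0] < 1.0 && unif_rand() >= prob[0]) continue;
      extBuf[1].clear();
      for (int u : adj[v]) if (u > v) extBuf[1].push_back(u);
      sub.assign(1, v); inSub[v] = 1;
      extend(1, v);
      inSub[v] = 0;
      sub.clear();
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".esuCensus")]]
NumericVector esu_census(IntegerVector edges_from, IntegerVector edges_to,
                         int n_nodes, int k, NumericVector prob) {
  if (k != 3 && k != 4) stop("k must be 3 or 4");
  if ((int)prob.size() != k) stop("prob must have length k");
  std::vector< std::vector<int> > adj(n_nodes);
  for (int i = 0; i < edges_from.size(); ++i) {
    int a = edges_from[i], b = edges_to[i];
    if (a == b) continue;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  for (int i = 0; i < n_nodes; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
  }
  int ncls = (k == 3) ? 2 : 6;
  std::vector<double> counts(ncls, 0.0);
  std::vector<double> pr(prob.begin(), prob.end());
  Esu esu(n_nodes, k, adj, counts, pr);
  esu.run();
  return NumericVector(counts.begin(), counts.end());
}
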