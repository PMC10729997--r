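#include <Rcpp.h>
#include <deque>
#include <vector>
using namespace Rcpp;

// Brandes-style edge betweenness on an undirected, unweighted simple graph.
// Each unordered vertex pair contributes its shortest-path fraction once;
// equal-length path multiplicities are split fractionally via sigma ratios.
static std::vector<double> brandes_edge_betweenness(
    int n,
    const std::vector<int>& ei,
    const std::vector<int>& ej,
    const std::vector<bool>& active) {
  const int m = static_cast<int>(ei.size());
  std::vector<std::vector<std::pair<int, int>>> adj(n); // (neighbour, edge idx)
  for (int e = 0; e < m; ++e) {
    if (!active[e]) continue;
    adj[ei[e]].push_back({ej[e], e});
    adj[ej[e]].push_back({ei[e], e});
  }
  std::vector<double> eb(m, 0.0);
  std::vector<int> dist(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<std::pair<int, int>>> preds(n); // (pred, edge idx)
  std::vector<int> order;
  order.reserve(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (auto& p : preds) p.clear();
    order.clear();
    std::deque<int> queue;
    dist[s] = 0;
    sigma[s] = 1.0;
    queue.push_back(s);
    while (!queue.empty()) {
      int v = queue.front();
      queue.pop_front();
      order.push_back(v);
      for (const auto& nb : adj[v]) {
        int w = nb.first;
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          queue.push_back(w);
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          preds[w].push_back({v, nb.second});
        }
      }
    }
    // dependency accumulation, reverse BFS order
    for (int i = static_cast<int>(order.size()) - 1; i > 0; --i) {
      int w = order[i];
      for (const auto& pr : preds[w]) {
        double c = sigma[pr.first] / sigma[w] * (1.0 + delta[w]);
        eb[pr.second] += c;
        delta[pr.first] += c;
      }
    }
  }
  for (double& x : eb) x /= 2.0; // every pair was seen from both endpoints
  return eb;
}

// connected-component labels on the active subgraph, renumbered by first
// appearance in vertex order so labels are deterministic
static std::vector<int> components(
    int n,
    const std::vector<int>& ei,
    const std::vector<int>& ej,
    const std::vector<bool>& active) {
  std::vector<std::vector<int>> adj(n);
  for (size_t e = 0; e < ei.size(); ++e) {
    if (!active[e]) continue;
    adj[ei[e]].push_back(ej[e]);
    adj[ej[e]].push_back(ei[e]);
  }
  std::vector<int> comp(n, -1);
  int label = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    std::deque<int> queue{s};
    comp[s] = label;
    while (!queue.empty()) {
      int v = queue.front();
      queue.pop_front();
      for (int w : adj[v]) {
        if (comp[w] < 0) {
          comp[w] = label;
          queue.push_back(w);
        }
      }
    }
    ++label;
  }
  return comp;
}

// [[Rcpp::export]]
NumericVector cpp_edge_betweenness(int n, IntegerVector ei, IntegerVector ej) {
  std::vector<int> a(ei.begin(), ei.end()), b(ej.begin(), ej.end());
  std::vector<bool> active(a.size(), true);
  std::vector<double> eb = brandes_edge_betweenness(n, a, b, active);
  return NumericVector(eb.begin(), eb.end());
}

// Full Girvan-Newman removal sequence. Edges must arrive sorted so that a
// smaller index means a lexicographically smaller endpoint pair: ties in the
// maximum betweenness are broken by the smallest edge index.
// Returns the removal order (0-based edge indices) and an (m+1) x n membership
// matrix: row k holds component labels after k removals (row 0 = intact graph).
// [[Rcpp::export]]
List cpp_girvan_newman(int n, IntegerVector ei, IntegerVector ej) {
  std::vector<int> a(ei.begin(), ei.end()), b(ej.begin(), ej.end());
  const int m = static_cast<int>(a.size());
  std::vector<bool> active(m, true);
  IntegerMatrix membership(m + 1, n);
  IntegerVector removed(m);

  std::vector<int> comp = components(n, a, b, active);
  for (int v = 0; v < n; ++v) membership(0, v) = comp[v];

  for (int step = 0; step < m; ++step) {
    std::vector<double> eb = brandes_edge_betweenness(n, a, b, active);
    int pick = -1;
    double best = -1.0;
    for (int e = 0; e < m; ++e) {
      if (active[e] && eb[e] > best + 1e-9) { // strictly larger, ties keep first
        best = eb[e];
        pick = e;
      }
    }
    active[pick] = false;
    removed[step] = pick;
    comp = components(n, a, b, active);
    for (int v = 0; v < n; ++v) membership(step + 1, v) = comp[v];
  }
  return List::create(_["removed"] = removed, _["membership"] = membership);
}
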