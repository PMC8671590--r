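#include <Rcpp.h>
using namespace Rcpp;

// Dinucleotide-preserving shuffle of an integer-coded sequence
// (Altschul-Erickson): treat letters as vertices and adjacent pairs as edges
// of a multigraph, sample a uniform-ish Euler path by (1) rejection-sampling
// a "last edge" arborescence toward the final letter, (2) permuting the
// remaining out-edges of every vertex, (3) walking the path from the first
// letter. Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector dinuc_shuffle_cpp(IntegerVector x, int n_letters) {
  int n = x.size();
  if (n <= 3) return clone(x);

  std::vector< std::vector<int> > adj(n_letters);
  for (int i = 0; i + 1 < n; ++i) adj[x[i]].push_back(x[i + 1]);
  int first = x[0], last = x[n - 1];

  std::vector<int> last_edge(n_letters, -1);
  for (int tries = 0;; ++tries) {
    if (tries > 100000)
      stop("dinucleotide shuffle: failed to sample an Euler path");
    for (int v = 0; v < n_letters; ++v) {
      last_edge[v] = -1;
      if (v == last || adj[v].empty()) continue;
      int j = (int)(unif_rand() * adj[v].size());
      if (j >= (int)adj[v].size()) j = (int)adj[v].size() - 1;
      last_edge[v] = adj[v][j];
    }
    bool ok = true;
    for (int v = 0; v < n_letters && ok; ++v) {
      if (v == last || adj[v].empty()) continue;
      int cur = v, steps = 0;
      while (cur != last) {
        if (cur < 0 || adj[cur].empty()) { ok = false; break; }
        cur = last_edge[cur];
        if (++steps > n_letters) { ok = false; break; }
      }
    }
    if (ok) break;
  }

  std::vector< std::vector<int> > ordered(n_letters);
  for (int v = 0; v < n_letters; ++v) {
    std::vector<int> e = adj[v];
    bool reserve = (v != last && last_edge[v] >= 0);
    if (reserve) {
      for (size_t i = 0; i < e.size(); ++i) {
        if (e[i] == last_edge[v]) { e.erase(e.begin() + i); break; }
      }
    }
    for (int i = (int)e.size() - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(e[i], e[j]);
    }
    if (reserve) e.push_back(last_edge[v]);
    ordered[v] = e;
  }

  IntegerVector out(n);
  std::vector<size_t> ptr(n_letters, 0);
  out[0] = first;
  int cur = first;
  for (int i = 1; i < n; ++i) {
    int nxt = ordered[cur][ptr[cur]++];
    out[i] = nxt;
    cur = nxt;
  }
  return out;
}
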