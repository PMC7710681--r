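// Exact branch-and-bound search for minimum-length rooted binary trees
// under two-state parsimony with an implicit all-plesiomorphic ancestor
// above the root (a character may change 0->1 on the stem edge).
//
// Taxa are added sequentially in a fixed order; a new leaf may be attached
// on any edge of the partial tree or above its root. Partial-tree length
// never decreases on leaf addition, so length(partial) plus the number of
// characters whose derived taxa are all still unplaced is a valid lower
// bound. All co-optimal trees are collected up to a cap.

#include <Rcpp.h>
#include <chrono>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

const int INF = 1000000000;

struct Bnb {
  int n;                                 // taxa
  int nchar;
  std::vector<std::vector<int>> state;   // [taxon][char]: 0/1/-1 missing
  std::vector<int> parent, left, right;  // node arrays, size 2n
  int root;
  std::vector<int> future_at;            // lower-bound increment per depth
  std::vector<unsigned int> backbone;    // clade masks over taxon indices

  long long best;
  std::vector<std::string> best_trees;
  long long tie_count;
  int max_trees;
  double nodes_examined;
  bool exhausted;
  std::chrono::steady_clock::time_point deadline;
  long long tick;

  // postorder DP over current tree; also records leafset masks
  std::vector<unsigned int> mask;
  std::vector<int> order;                // postorder node list

  void compute_order() {
    order.clear();
    std::vector<std::pair<int, bool>> stack;
    stack.push_back({root, false});
    while (!stack.empty()) {
      auto [v, done] = stack.back();
      stack.pop_back();
      if (v < n) { order.push_back(v); continue; }
      if (done) { order.push_back(v); continue; }
      stack.push_back({v, true});
      stack.push_back({left[v], false});
      stack.push_back({right[v], false});
    }
  }

  // exact length of the current (partial or full) tree
  long long tree_length() {
    compute_order();
    size_t m = order.size();
    std::vector<int> c0(2 * n), c1(2 * n);
    for (size_t i = 0; i < m; ++i) {
      int v = order[i];
      mask[v] = (v < n) ? (1u << v) : (mask[left[v]] | mask[right[v]]);
    }
    long long total = 0;
    for (int ch = 0; ch < nchar; ++ch) {
      for (size_t i = 0; i < m; ++i) {
        int v = order[i];
        if (v < n) {
          int s = state[v][ch];
          c0[v] = (s == 1) ? INF : 0;
          c1[v] = (s == 0) ? INF : 0;
        } else {
          int l = left[v], r = right[v];
          c0[v] = std::min(c0[l], c1[l] + 1) + std::min(c0[r], c1[r] + 1);
          c1[v] = std::min(c1[l], c0[l] + 1) + std::min(c1[r], c0[r] + 1);
        }
      }
      total += std::min(c0[root], c1[root] + 1);
    }
    return total;
  }

  bool backbone_ok(unsigned int added_mask) {
    if (backbone.empty()) return true;
    for (unsigned int b : backbone) {
      unsigned int r = b & added_mask;
      int pc = __builtin_popcount(r);
      if (pc < 2 || r == added_mask) continue;
      bool found = false;
      for (int v : order) {
        if (v >= n && mask[v] == r) { found = true; break; }
      }
      if (!found) return false;
    }
    return true;
  }

  std::string newick(int v, const CharacterVector& labels) {
    if (v < n) return std::string(labels[v]);
    return "(" + newick(left[v], labels) + "," + newick(right[v], labels) + ")";
  }

  void record(const CharacterVector& labels) {
    long long len = tree_length();
    if (len > best) return;
    if (!backbone_ok((1u << n) - 1u)) return;
    if (len < best) {
      best = len;
      best_trees.clear();
      tie_count = 0;
    }
    ++tie_count;
    if ((int)best_trees.size() < max_trees) {
      best_trees.push_back(newick(root, labels) + ";");
    }
  }

  void search(int k, const CharacterVector& labels) {
    if (!exhausted) return;
    if (++tick % 4096 == 0) {
      if (std::chrono::steady_clock::now() > deadline) { exhausted = false; return; }
      Rcpp::checkUserInterrupt();
    }
    if (k == n) { record(labels); return; }

    long long len = tree_length();
    if (len + future_at[k] > best) return;
    unsigned int added_mask = (1u << k) - 1u;
    if (!backbone_ok(added_mask)) return;

    // candidate attachment points: every current node (above-root included)
    std::vector<int> nodes(order);   // copy: order is clobbered by recursion
    int v = n + k - 1;               // fresh internal node id
    for (int c : nodes) {
      nodes_examined += 1;
      if (c == root) {               // new root above old one
        parent[root] = v;
        left[v] = root; right[v] = k; parent[k] = v; parent[v] = -1;
        int old_root = root;
        root = v;
        search(k + 1, labels);
        root = old_root;
        parent[root] = -1;
      } else {
        int p = parent[c];
        if (left[p] == c) left[p] = v; else right[p] = v;
        parent[v] = p;
        left[v] = c; right[v] = k;
        parent[c] = v; parent[k] = v;
        search(k + 1, labels);
        if (left[p] == v) left[p] = c; else right[p] = c;
        parent[c] = p;
      }
      if (!exhausted) return;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".bnb_search")]]
List bnb_search(IntegerMatrix states, CharacterVector labels,
                double upper_bound, double time_budget,
                IntegerVector backbone_masks, int max_trees) {
  Bnb b;
  b.n = states.ncol();
  b.nchar = states.nrow();
  b.state.assign(b.n, std::vector<int>(b.nchar));
  for (int t = 0; t < b.n; ++t)
    for (int c = 0; c < b.nchar; ++c) {
      int s = states(c, t);
      b.state[t][c] = (s == NA_INTEGER) ? -1 : s;
    }
  b.parent.assign(2 * b.n, -1);
  b.left.assign(2 * b.n, -1);
  b.right.assign(2 * b.n, -1);
  b.mask.assign(2 * b.n, 0u);

  // lower-bound table: characters whose first derived taxon is still unplaced
  std::vector<int> first_derived(b.nchar, INT_MAX);
  for (int c = 0; c < b.nchar; ++c)
    for (int t = 0; t < b.n; ++t)
      if (b.state[t][c] == 1) { first_derived[c] = t; break; }
  b.future_at.assign(b.n + 1, 0);
  for (int k = 0; k <= b.n; ++k)
    for (int c = 0; c < b.nchar; ++c)
      if (first_derived[c] != INT_MAX && first_derived[c] >= k)
        b.future_at[k] += 1;

  b.backbone.assign(backbone_masks.begin(), backbone_masks.end());
  b.best = (long long)upper_bound;
  b.tie_count = 0;
  b.max_trees = max_trees;
  b.nodes_examined = 0;
  b.exhausted = true;
  b.tick = 0;
  b.deadline = std::chrono::steady_clock::now() +
    std::chrono::milliseconds((long long)(time_budget * 1000.0));

  if (b.n == 1) {
    return List::create(_["best_length"] = b.tree_length(),
                        _["trees"] = CharacterVector::create(),
                        _["nodes_examined"] = 0.0,
                        _["exhausted"] = true, _["tie_count"] = 0.0);
  }
  // initial tree: leaves 0 and 1 under internal node n
  b.root = b.n;
  b.left[b.n] = 0; b.right[b.n] = 1;
  b.parent[0] = b.n; b.parent[1] = b.n;
  b.search(2, labels);

  return List::create(_["best_length"] = (double)b.best,
                      _["trees"] = wrap(b.best_trees),
                      _["nodes_examined"] = b.nodes_examined,
                      _["exhausted"] = b.exhausted,
                      _["tie_count"] = (double)b.tie_count);
}
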