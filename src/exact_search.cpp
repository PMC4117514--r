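#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exhaustive search over rooted binary trees on a fixed leaf multiset,
// pruned by rooted-triplet constraints.
//
// Trees are enumerated by sequential leaf insertion: the j-th leaf can be
// attached on any of the 2j-3 positions (subdividing an existing edge, or
// as a sibling of the whole tree under a new root), which generates every
// rooted binary tree shape on j labeled leaves exactly once.  Insertions
// never change the relative ancestor order of the lowest common ancestors
// of leaves already placed, so once every occurrence of a triplet's three
// labels has been placed, its satisfiability is decided for good; each
// input triplet is therefore checked exactly once, at the first index where
// that holds, and failures prune the whole subtree of the search.

namespace {

struct Search {
  int m;                       // number of leaves
  std::vector<int> leaf_lab;   // label id per leaf (0-based)
  int nlab;
  std::vector<std::string> lab_names;

  // tree arrays; nodes: leaves 0..m-1, internals m..2m-2
  std::vector<int> parent, child1, child2;
  int root;
  int next_internal;

  // triplets: x,y,z label ids; grouped by decision index
  std::vector<std::array<int, 3>> trips;
  std::vector<std::vector<int>> group;   // per leaf index, triplet ids
  std::vector<std::vector<int>> occ;     // label id -> leaf indices

  double budget, nodes_visited;
  bool aborted;
  bool found;
  std::string best;

  int depth_of(int v) const {
    int d = 0;
    while (parent[v] != -1) { v = parent[v]; ++d; }
    return d;
  }

  // depth of lca(a, b)
  int lca_depth(int a, int b) const {
    int da = depth_of(a), db = depth_of(b);
    while (da > db) { a = parent[a]; --da; }
    while (db > da) { b = parent[b]; --db; }
    while (a != b) { a = parent[a]; b = parent[b]; --da; }
    return da;
  }

  // is triplet t satisfiable using leaves 0..placed-1 (all occurrences in)?
  bool satisfiable(const std::array<int, 3>& t) const {
    const std::vector<int>& ox = occ[t[0]];
    const std::vector<int>& oy = occ[t[1]];
    const std::vector<int>& oz = occ[t[2]];
    for (int xi : ox)
      for (int yj : oy) {
        int dxy = lca_depth(xi, yj);
        for (int zk : oz) {
          if (dxy > lca_depth(xi, zk) && dxy > lca_depth(yj, zk))
            return true;
        }
      }
    return false;
  }

  std::string canon(int v) const {
    if (v < m) return lab_names[leaf_lab[v]];
    std::string a = canon(child1[v]), b = canon(child2[v]);
    if (b < a) std::swap(a, b);
    return "(" + a + "," + b + ")";
  }

  void complete_tree() {
    std::string s = canon(root) + ";";
    if (!found || s < best) { found = true; best = s; }
  }

  void place(int j) {  // leaves 0..j-1 already placed
    if (aborted) return;
    if (j == m) { complete_tree(); return; }
    if (++nodes_visited > budget) { aborted = true; return; }

    // candidate attachment points: every node of the current tree
    int ncur = 2 * j - 1;  // j leaves + j-1 internals
    std::vector<int> targets;
    targets.reserve(ncur);
    for (int v = 0; v < j; ++v) targets.push_back(v);
    for (int v = m; v < m + j - 1; ++v) targets.push_back(v);

    for (int c : targets) {
      int v = next_internal++;
      int p = parent[c];
      parent[c] = v; parent[j] = v;
      child1[v] = c; child2[v] = j; parent[v] = p;
      int old_root = root;
      if (p == -1) root = v;
      else { if (child1[p] == c) child1[p] = v; else child2[p] = v; }

      bool ok = true;
      for (int ti : group[j])
        if (!satisfiable(trips[ti])) { ok = false; break; }
      if (ok) place(j + 1);

      // undo
      if (p == -1) root = old_root;
      else { if (child1[p] == v) child1[p] = c; else child2[p] = c; }
      parent[c] = p; parent[j] = -1;
      --next_internal;
      if (aborted) return;
    }
  }

  void run() {
    parent.assign(2 * m - 1, -1);
    child1.assign(2 * m - 1, -1);
    child2.assign(2 * m - 1, -1);
    next_internal = m;
    root = 0;
    nodes_visited = 0;
    aborted = false;
    found = false;

    occ.assign(nlab, {});
    for (int i = 0; i < m; ++i) occ[leaf_lab[i]].push_back(i);

    group.assign(m, {});
    for (size_t t = 0; t < trips.size(); ++t) {
      int last = 0;
      for (int s = 0; s < 3; ++s) {
        const std::vector<int>& o = occ[trips[t][s]];
        last = std::max(last, o.back());
      }
      group[last].push_back((int)t);
    }

    if (m == 1) { complete_tree(); return; }
    // leaf 0 alone, then insert leaf 1, 2, ...
    place(1);
  }
};

}  // namespace

// [[Rcpp::export]]
List exact_search_cpp(IntegerVector leaf_labels, IntegerMatrix triplet_ids,
                      CharacterVector label_names, double max_nodes) {
  Search s;
  s.m = leaf_labels.size();
  s.nlab = label_names.size();
  s.leaf_lab.assign(leaf_labels.begin(), leaf_labels.end());
  for (int& v : s.leaf_lab) --v;  // to 0-based
  // leaves must be sorted by label so that occ[].back() is the last index
  for (int i = 1; i < s.m; ++i)
    if (s.leaf_lab[i - 1] > s.leaf_lab[i])
      stop("leaf labels must be sorted");
  for (int i = 0; i < s.nlab; ++i)
    s.lab_names.push_back(as<std::string>(label_names[i]));
  for (int r = 0; r < triplet_ids.nrow(); ++r) {
    std::array<int, 3> t = {triplet_ids(r, 0) - 1, triplet_ids(r, 1) - 1,
                            triplet_ids(r, 2) - 1};
    for (int v : t)
      if (v < 0 || v >= s.nlab) stop("triplet label id out of range");
    s.trips.push_back(t);
  }
  s.budget = max_nodes;
  s.run();
  return List::create(_["found"] = s.found,
                      _["newick"] = s.found ? s.best : std::string(""),
                      _["nodes"] = s.nodes_visited,
                      _["aborted"] = s.aborted);
}
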