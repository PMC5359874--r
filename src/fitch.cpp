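#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Unordered-character parsimony step counting on a rooted tree that may
// contain polytomies.  For binary nodes this is Fitch's algorithm; for
// polytomies the state-vote generalization (Hartigan) is used, which is
// exact for unit-cost unordered characters.  The node-outer /
// pattern-inner loop keeps the hot path contiguous in memory.
//
// edge:      2-column integer matrix (parent, child), 1-based ape ids
// n_tip:     number of tips (internal ids are n_tip+1 .. n_tip+n_node)
// tip_state: n_pattern x n_taxa integer matrix of state bitmasks
//            (pattern-major: column = taxon; missing = union of the
//            character's observed states)
// tip_row:   length-n_tip vector of 1-based rows of tip_state per tip,
//            so callers can reuse one encoding across many trees
// n_states:  number of distinct states overall (<= 30)
//
// Returns an integer vector of steps per pattern.
// [[Rcpp::export(name = ".fitch_steps_cpp")]]
IntegerVector fitch_steps_cpp(const IntegerMatrix edge, const int n_tip,
                              const IntegerMatrix tip_state,
                              const IntegerVector tip_row,
                              const int n_states) {
  const int n_edge = edge.nrow();
  const int n_all = n_tip + n_edge + 1; // upper bound on node count
  const int n_pat = tip_state.nrow();

  std::vector<std::vector<int> > kids(n_all + 1);
  for (int e = 0; e < n_edge; ++e) kids[edge(e, 0)].push_back(edge(e, 1));

  // explicit postorder of nodes starting from the root (n_tip + 1)
  std::vector<int> order;
  order.reserve(n_all);
  std::vector<int> stack;
  stack.push_back(n_tip + 1);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (size_t i = 0; i < kids[v].size(); ++i) stack.push_back(kids[v][i]);
  }

  std::vector<int> mask((size_t)(n_all + 1) * n_pat, 0);
  IntegerVector steps(n_pat);
  int* stepp = INTEGER(steps);
  const int* ts = INTEGER(tip_state);

  // reverse preorder = postorder
  for (size_t oi = order.size(); oi-- > 0; ) {
    const int v = order[oi];
    int* mv = &mask[(size_t)v * n_pat];
    if (v <= n_tip) {
      const int row = tip_row[v - 1] - 1;
      const int* src = ts + (size_t)row * n_pat;
      for (int p = 0; p < n_pat; ++p) mv[p] = src[p];
      continue;
    }
    const std::vector<int>& ch = kids[v];
    if (ch.size() == 2) {
      const int* a = &mask[(size_t)ch[0] * n_pat];
      const int* b = &mask[(size_t)ch[1] * n_pat];
      for (int p = 0; p < n_pat; ++p) {
        const int inter = a[p] & b[p];
        if (inter) mv[p] = inter;
        else { mv[p] = a[p] | b[p]; ++stepp[p]; }
      }
    } else {
      const size_t nc = ch.size();
      for (int p = 0; p < n_pat; ++p) {
        int uni = 0;
        for (size_t c = 0; c < nc; ++c) uni |= mask[(size_t)ch[c] * n_pat + p];
        int kmax = 0, m = 0;
        for (int st = 0; st < n_states; ++st) {
          const int bit = 1 << st;
          if (!(uni & bit)) continue;
          int cnt = 0;
          for (size_t c = 0; c < nc; ++c)
            if (mask[(size_t)ch[c] * n_pat + p] & bit) ++cnt;
          if (cnt > kmax) { kmax = cnt; m = bit; }
          else if (cnt == kmax) m |= bit;
        }
        mv[p] = m;
        stepp[p] += (int)nc - kmax;
      }
    }
  }
  return steps;
}

// Scores of attaching a new tip to every edge of a tree, exactly, by
// re-running the Fitch count per candidate edge entirely in C++ (one call
// per added taxon instead of one per candidate edge).  Returns a numeric
// vector of weighted step totals per edge, using per-pattern weights.
// [[Rcpp::export(name = ".fitch_addition_scores_cpp")]]
NumericVector fitch_addition_scores_cpp(const IntegerMatrix edge,
                                        const int n_tip,
                                        const IntegerMatrix tip_state,
                                        const IntegerVector tip_row,
                                        const int query_row,
                                        const NumericVector weights,
                                        const int n_states) {
  const int n_edge = edge.nrow();
  const int n_pat = tip_state.nrow();
  NumericVector out(n_edge);
  // new tree: tips 1..n_tip stay, new tip = n_tip+1, internals shift by 1,
  // new internal node appended last.
  const int n_node = n_edge / 2; // binary rooted: n_edge = 2*n_node - 2? not used
  (void)n_node;
  for (int e = 0; e < n_edge; ++e) {
    IntegerMatrix E2(n_edge + 2, 2);
    int newnode = 0;
    // renumber internals (+1) and find max id
    int maxid = 0;
    for (int i = 0; i < n_edge; ++i) {
      int p = edge(i, 0), c = edge(i, 1);
      if (p > n_tip) p += 1;
      if (c > n_tip) c += 1;
      E2(i, 0) = p; E2(i, 1) = c;
      if (p > maxid) maxid = p;
      if (c > maxid) maxid = c;
    }
    newnode = maxid + 1;
    const int child = E2(e, 1);
    E2(e, 1) = newnode;
    E2(n_edge, 0) = newnode;     E2(n_edge, 1) = child;
    E2(n_edge + 1, 0) = newnode; E2(n_edge + 1, 1) = n_tip + 1;
    IntegerVector rows(n_tip + 1);
    for (int i = 0; i < n_tip; ++i) rows[i] = tip_row[i];
    rows[n_tip] = query_row;
    IntegerVector st = fitch_steps_cpp(E2, n_tip + 1, tip_state, rows,
                                       n_states);
    double s = 0;
    for (int p = 0; p < n_pat; ++p) s += weights[p] * st[p];
    out[e] = s;
  }
  return out;
}
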