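// Irreversible (gains-only) binary parsimony and heuristic tree search.
//
// Characters are binary with missing data. The root state is forced to 0,
// so a character may change 0 -> 1 along an edge (one step) and never back.
// For this model the minimum number of gains on a rooted tree equals the
// number of edges (p, c) where the subtree below c contains a scored
// present leaf, no scored absent leaf, and the subtree below p contains a
// scored absent leaf (plus a gain at the root edge for characters whose
// whole tree is free of scored absences). This lets a tree be scored with
// two presence/absence bitmasks per node, 64 characters per machine word.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <random>
#include <cstdio>

using namespace Rcpp;

typedef uint64_t word;

static inline int popcount64(word x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// ---------------------------------------------------------------------------
// Generic scorer for a rooted tree in ape postorder edge form (polytomies ok)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
int cpp_irrev_score(IntegerMatrix edge, int n_tip, int n_node,
                    IntegerMatrix tip_states) {
  const int nchar = tip_states.ncol();
  const int nwords = (nchar + 63) / 64;
  const int total = n_tip + n_node;
  std::vector<word> has0((size_t)total * nwords, 0);
  std::vector<word> has1((size_t)total * nwords, 0);
  for (int t = 0; t < n_tip; ++t) {
    for (int c = 0; c < nchar; ++c) {
      int s = tip_states(t, c);
      if (s == 0) has0[(size_t)t * nwords + c / 64] |= (word)1 << (c % 64);
      else if (s == 1) has1[(size_t)t * nwords + c / 64] |= (word)1 << (c % 64);
    }
  }
  const int ne = edge.nrow();
  // postorder: children before parents
  for (int e = 0; e < ne; ++e) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    for (int w = 0; w < nwords; ++w) {
      has0[(size_t)p * nwords + w] |= has0[(size_t)c * nwords + w];
      has1[(size_t)p * nwords + w] |= has1[(size_t)c * nwords + w];
    }
  }
  const int root = n_tip; // ape root id is n_tip + 1 (1-based)
  const word full = ~(word)0;
  int steps = 0;
  for (int e = 0; e < ne; ++e) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    for (int w = 0; w < nwords; ++w) {
      word tailmask = full;
      if (w == nwords - 1 && nchar % 64 != 0)
        tailmask = ((word)1 << (nchar % 64)) - 1;
      word parent0 = (p == root) ? full : has0[(size_t)p * nwords + w];
      word gain = ~has0[(size_t)c * nwords + w] &
                  has1[(size_t)c * nwords + w] & parent0 & tailmask;
      steps += popcount64(gain);
    }
  }
  return steps;
}

// ---------------------------------------------------------------------------
// Heuristic search on unrooted binary trees, scored rooted at an outgroup tip
// ---------------------------------------------------------------------------

struct UTree {
  // adjacency; tips 0..ntip-1 (degree 1), internals (degree 3)
  int ntip;
  std::vector<std::array<int, 3>> nb;
  std::vector<bool> in_tree;   // node present?
  std::vector<int> free_nodes; // recycled internal ids

  explicit UTree(int ntip_) : ntip(ntip_) {
    int maxn = 2 * ntip_ - 2;
    nb.assign(maxn, {-1, -1, -1});
    in_tree.assign(maxn, false);
  }
  void link(int a, int b) {
    for (int k = 0; k < 3; ++k) if (nb[a][k] == -1) { nb[a][k] = b; break; }
    for (int k = 0; k < 3; ++k) if (nb[b][k] == -1) { nb[b][k] = a; break; }
  }
  void unlink(int a, int b) {
    for (int k = 0; k < 3; ++k) if (nb[a][k] == b) { nb[a][k] = -1; break; }
    for (int k = 0; k < 3; ++k) if (nb[b][k] == a) { nb[b][k] = -1; break; }
  }
  int degree(int a) const {
    int d = 0;
    for (int k = 0; k < 3; ++k) if (nb[a][k] != -1) ++d;
    return d;
  }
};

struct Searcher {
  int ntip, nchar, nwords;
  std::vector<word> leaf0, leaf1; // per tip
  std::mt19937 rng;
  int outgroup;

  // scratch
  std::vector<word> h0, h1;
  std::vector<int> order, parent;

  Searcher(const IntegerMatrix& tip_states, int outgroup_, unsigned seed)
      : ntip(tip_states.nrow()), nchar(tip_states.ncol()),
        nwords((tip_states.ncol() + 63) / 64), rng(seed),
        outgroup(outgroup_) {
    leaf0.assign((size_t)ntip * nwords, 0);
    leaf1.assign((size_t)ntip * nwords, 0);
    for (int t = 0; t < ntip; ++t)
      for (int c = 0; c < nchar; ++c) {
        int s = tip_states(t, c);
        if (s == 0) leaf0[(size_t)t * nwords + c / 64] |= (word)1 << (c % 64);
        else if (s == 1) leaf1[(size_t)t * nwords + c / 64] |= (word)1 << (c % 64);
      }
    int maxn = 2 * ntip - 2;
    h0.assign((size_t)maxn * nwords, 0);
    h1.assign((size_t)maxn * nwords, 0);
    order.reserve(maxn);
    parent.assign(maxn, -1);
  }

  // score tree rooted at the outgroup tip, root state forced 0
  int score(const UTree& t) {
    // iterative DFS from outgroup
    order.clear();
    std::fill(parent.begin(), parent.end(), -1);
    std::vector<int> stack;
    stack.push_back(t.nb[outgroup][0]);
    parent[t.nb[outgroup][0]] = outgroup;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      order.push_back(v);
      for (int k = 0; k < 3; ++k) {
        int u = t.nb[v][k];
        if (u != -1 && u != parent[v]) {
          parent[u] = v;
          stack.push_back(u);
        }
      }
    }
    // compute has0/has1 in reverse DFS order (children before parents)
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int v = order[i];
      word* v0 = &h0[(size_t)v * nwords];
      word* v1 = &h1[(size_t)v * nwords];
      if (v < ntip) {
        const word* l0 = &leaf0[(size_t)v * nwords];
        const word* l1 = &leaf1[(size_t)v * nwords];
        for (int w = 0; w < nwords; ++w) { v0[w] = l0[w]; v1[w] = l1[w]; }
      } else {
        for (int w = 0; w < nwords; ++w) { v0[w] = 0; v1[w] = 0; }
        for (int k = 0; k < 3; ++k) {
          int u = t.nb[v][k];
          if (u != -1 && u != parent[v]) {
            const word* u0 = &h0[(size_t)u * nwords];
            const word* u1 = &h1[(size_t)u * nwords];
            for (int w = 0; w < nwords; ++w) { v0[w] |= u0[w]; v1[w] |= u1[w]; }
          }
        }
      }
    }
    const word full = ~(word)0;
    word tailmask = full;
    if (nchar % 64 != 0) tailmask = ((word)1 << (nchar % 64)) - 1;
    int steps = 0;
    for (size_t i = 0; i < order.size(); ++i) {
      int v = order[i];
      int p = parent[v];
      const word* v0 = &h0[(size_t)v * nwords];
      const word* v1 = &h1[(size_t)v * nwords];
      for (int w = 0; w < nwords; ++w) {
        word tm = (w == nwords - 1) ? tailmask : full;
        word p0 = (p == outgroup) ? full : h0[(size_t)p * nwords + w];
        steps += popcount64(~v0[w] & v1[w] & p0 & tm);
      }
    }
    // gain on the outgroup's own pendant edge (virtual root is 0)
    {
      const word* o1 = &leaf1[(size_t)outgroup * nwords];
      for (int w = 0; w < nwords; ++w) {
        word tm = (w == nwords - 1) ? tailmask : full;
        steps += popcount64(o1[w] & tm);
      }
    }
    return steps;
  }

  // edges as pairs (a < b by traversal), excluding none
  void collect_edges(const UTree& t, std::vector<std::pair<int, int>>& out) {
    out.clear();
    int maxn = 2 * ntip - 2;
    for (int v = 0; v < maxn; ++v) {
      if (!t.in_tree[v]) continue;
      for (int k = 0; k < 3; ++k) {
        int u = t.nb[v][k];
        if (u != -1 && v < u) out.emplace_back(v, u);
      }
    }
  }

  // nodes in the component containing `start` when edge (a,b) is removed
  void component(const UTree& t, int start, int a, int b,
                 std::vector<int>& out) {
    out.clear();
    std::vector<int> stack{start};
    std::vector<bool> seen(t.nb.size(), false);
    seen[start] = true;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      out.push_back(v);
      for (int k = 0; k < 3; ++k) {
        int u = t.nb[v][k];
        if (u == -1 || seen[u]) continue;
        if ((v == a && u == b) || (v == b && u == a)) continue;
        seen[u] = true;
        stack.push_back(u);
      }
    }
  }

  int pick(int n) { return (int)(rng() % (unsigned)n); }
};

// build initial 3-tip star and run stepwise addition in `addorder`
static void stepwise_addition(Searcher& S, UTree& t,
                              const std::vector<int>& addorder) {
  int next_internal = S.ntip;
  int a = addorder[0], b = addorder[1], c = addorder[2];
  int v = next_internal++;
  t.in_tree[a] = t.in_tree[b] = t.in_tree[c] = t.in_tree[v] = true;
  t.link(a, v); t.link(b, v); t.link(c, v);
  std::vector<std::pair<int, int>> edges;
  for (size_t i = 3; i < addorder.size(); ++i) {
    int x = addorder[i];
    S.collect_edges(t, edges);
    int best = INT32_MAX, nties = 0;
    std::pair<int, int> beste{-1, -1};
    int v2 = next_internal; // node to be used for insertion
    for (auto& e : edges) {
      // subdivide e with v2, attach x
      t.unlink(e.first, e.second);
      t.in_tree[v2] = true; t.in_tree[x] = true;
      t.link(e.first, v2); t.link(e.second, v2); t.link(v2, x);
      int sc = S.score(t);
      // undo
      t.unlink(e.first, v2); t.unlink(e.second, v2); t.unlink(v2, x);
      t.in_tree[v2] = false; t.in_tree[x] = false;
      t.link(e.first, e.second);
      if (sc < best) { best = sc; beste = e; nties = 1; }
      else if (sc == best) { ++nties; if (S.pick(nties) == 0) beste = e; }
    }
    t.unlink(beste.first, beste.second);
    t.in_tree[v2] = true; t.in_tree[x] = true;
    t.link(beste.first, v2); t.link(beste.second, v2); t.link(v2, x);
    ++next_internal;
  }
}

// Apply one TBR/SPR-style reconnection: bisect edge (u,v); within the
// component of u choose reconnection edge e1 (or the suppressed edge),
// likewise e2 for v; returns false if the move is a no-op.
//
// Implemented as: remove edge (u,v); suppress u and v if they become
// degree-2 (tips of a pruned component stay as they are); then re-insert.
// For simplicity we implement the standard form: both endpoints are
// internal after bisection of an internal edge; pendant edges give SPR.

struct Move { int u, v; std::pair<int, int> e1, e2; };

// enumerate and apply moves lazily inside the swap loop

static bool do_swap(Searcher& S, UTree& t, int swap_type, int& cur_score) {
  // swap_type: 0 = NNI, 1 = SPR, 2 = TBR
  std::vector<std::pair<int, int>> edges, e1s, e2s;
  std::vector<int> comp1, comp2;
  bool improved_any = false;
  bool improved = true;
  while (improved) {
    improved = false;
    S.collect_edges(t, edges);
    for (auto& e : edges) {
      int u = e.first, v = e.second;
      bool u_int = u >= S.ntip, v_int = v >= S.ntip;
      if (!u_int && !v_int) continue;
      // prune: remove edge (u,v)
      // components on each side
      S.component(t, u, u, v, comp1);
      S.component(t, v, u, v, comp2);
      // candidate reconnection edges on u side
      auto side_edges = [&](int end_node, const std::vector<int>& comp, bool internal_end,
                            std::vector<std::pair<int, int>>& out,
                            std::array<int, 2>& suppressed) {
        out.clear();
        suppressed = {-1, -1};
        if (!internal_end) { out.emplace_back(end_node, -1); return; } // pendant: reattach the tip itself
        // neighbours of the end other than across the removed edge
        int x1 = -1, x2 = -1;
        for (int k = 0; k < 3; ++k) {
          int w = t.nb[end_node][k];
          if (w == -1 || w == ((end_node == u) ? v : u)) continue;
          if (x1 == -1) x1 = w; else x2 = w;
        }
        suppressed = {x1, x2};
        for (int a : comp) {
          if (a == end_node) continue;
          for (int k = 0; k < 3; ++k) {
            int b = t.nb[a][k];
            if (b == -1 || b == end_node || a > b) continue;
            if (std::find(comp.begin(), comp.end(), b) == comp.end()) continue;
            out.emplace_back(a, b);
          }
        }
        out.emplace_back(x1, x2); // the edge created by suppressing the end
      };
      std::array<int, 2> sup1, sup2;
      side_edges(u, comp1, u_int, e1s, sup1);
      side_edges(v, comp2, v_int, e2s, sup2);
      // TBR: all pairs; SPR: one side stays at its original position;
      // NNI: only the suppressed edge on one side and edges adjacent to the
      // other end (distance-1) -- implemented as SPR moves of distance 1.
      for (size_t i1 = 0; i1 < e1s.size(); ++i1) {
        for (size_t i2 = 0; i2 < e2s.size(); ++i2) {
          bool orig1 = (e1s[i1].second == -1) ||
                       (u_int && e1s[i1] == std::make_pair(sup1[0], sup1[1]));
          bool orig2 = (e2s[i2].second == -1) ||
                       (v_int && e2s[i2] == std::make_pair(sup2[0], sup2[1]));
          if (orig1 && orig2) continue;     // identity move
          if (swap_type <= 1 && !orig1 && !orig2) continue; // SPR/NNI: move one side only
          if (swap_type == 0) {
            // NNI: reconnection edge must be adjacent to the suppressed edge
            auto adj_ok = [&](const std::pair<int, int>& ed,
                              const std::array<int, 2>& sup, bool is_orig) {
              if (is_orig) return true;
              return ed.first == sup[0] || ed.first == sup[1] ||
                     ed.second == sup[0] || ed.second == sup[1];
            };
            if (!adj_ok(e1s[i1], sup1, orig1) || !adj_ok(e2s[i2], sup2, orig2))
              continue;
          }
          // --- apply move on a working copy ---
          UTree t2 = t;
          t2.unlink(u, v);
          int uu = u, vv = v;
          if (u_int) { // suppress u
            t2.unlink(u, sup1[0]); t2.unlink(u, sup1[1]);
            t2.link(sup1[0], sup1[1]);
            t2.in_tree[u] = false;
          }
          if (v_int) {
            t2.unlink(v, sup2[0]); t2.unlink(v, sup2[1]);
            t2.link(sup2[0], sup2[1]);
            t2.in_tree[v] = false;
          }
          // reattach side 1
          int attach1;
          if (e1s[i1].second == -1) {
            attach1 = e1s[i1].first; // bare tip
          } else {
            t2.unlink(e1s[i1].first, e1s[i1].second);
            t2.in_tree[uu] = true;
            t2.link(e1s[i1].first, uu); t2.link(e1s[i1].second, uu);
            attach1 = uu;
          }
          int attach2;
          if (e2s[i2].second == -1) {
            attach2 = e2s[i2].first;
          } else {
            t2.unlink(e2s[i2].first, e2s[i2].second);
            t2.in_tree[vv] = true;
            t2.link(e2s[i2].first, vv); t2.link(e2s[i2].second, vv);
            attach2 = vv;
          }
          t2.link(attach1, attach2);
          int sc = S.score(t2);
          if (sc < cur_score) {
            t = t2;
            cur_score = sc;
            improved = true;
            improved_any = true;
            break;
          }
        }
        if (improved) break;
      }
      if (improved) break;
    }
  }
  return improved_any;
}

// canonical newick-like string of the tree rooted at the outgroup
static std::string canon_node(const UTree& t, int v, int par,
                              std::vector<std::string>& tipname) {
  if (v < t.ntip) return tipname[v];
  std::vector<std::string> parts;
  for (int k = 0; k < 3; ++k) {
    int u = t.nb[v][k];
    if (u != -1 && u != par) parts.push_back(canon_node(t, u, v, tipname));
  }
  std::sort(parts.begin(), parts.end());
  std::string s = "(";
  for (size_t i = 0; i < parts.size(); ++i) {
    if (i) s += ",";
    s += parts[i];
  }
  s += ")";
  return s;
}

// [[Rcpp::export]]
List cpp_parsimony_search(IntegerMatrix tip_states, int outgroup1,
                          int n_reps, int swap_type, int seed) {
  int ntip = tip_states.nrow();
  Searcher S(tip_states, outgroup1 - 1, (unsigned)seed);
  std::vector<std::string> tipname(ntip);
  for (int i = 0; i < ntip; ++i) {
    char buf[16]; snprintf(buf, sizeof(buf), "t%05d", i + 1);
    tipname[i] = buf;
  }
  IntegerVector scores(n_reps);
  CharacterVector canon(n_reps);
  List edges_out(n_reps);
  std::vector<int> ingroup;
  for (int i = 0; i < ntip; ++i) if (i != S.outgroup) ingroup.push_back(i);
  for (int rep = 0; rep < n_reps; ++rep) {
    // random addition order: outgroup first, then a seeded shuffle
    std::vector<int> ord = ingroup;
    std::shuffle(ord.begin(), ord.end(), S.rng);
    std::vector<int> addorder;
    addorder.push_back(S.outgroup);
    for (int x : ord) addorder.push_back(x);
    UTree t(ntip);
    stepwise_addition(S, t, addorder);
    int sc = S.score(t);
    do_swap(S, t, swap_type, sc);
    scores[rep] = sc;
    canon[rep] = canon_node(t, t.nb[S.outgroup][0], S.outgroup, tipname);
    // emit edge list
    std::vector<std::pair<int, int>> edges;
    S.collect_edges(t, edges);
    IntegerMatrix em(edges.size(), 2);
    for (size_t i = 0; i < edges.size(); ++i) {
      em(i, 0) = edges[i].first + 1;
      em(i, 1) = edges[i].second + 1;
    }
    edges_out[rep] = em;
    if (rep % 20 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["scores"] = scores, _["canonical"] = canon,
                      _["edges"] = edges_out);
}
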