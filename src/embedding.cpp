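#include <Rcpp.h>
#include <chrono>
#include <random>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// Cells of an s x s grid are indexed 0..s*s-1 in row-major order:
// cell c sits at row i = c / s, column j = c % s.

static inline int mdist(int a, int b, int s) {
  return std::abs(a / s - b / s) + std::abs(a % s - b % s);
}

static std::vector<std::pair<int, int> > edge_list(const IntegerMatrix& adj) {
  std::vector<std::pair<int, int> > edges;
  int n = adj.nrow();
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b)
      if (adj(a, b) != 0) edges.push_back(std::make_pair(a, b));
  return edges;
}

static int objective_of(const IntegerMatrix& adj, const std::vector<int>& pos,
                        int s) {
  int total = 0, n = adj.nrow();
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b)
      if (adj(a, b) != 0) total += mdist(pos[a], pos[b], s);
  return total;
}

// ---- exhaustive oracle: full enumeration of injective placements ----------

struct BruteState {
  const IntegerMatrix* adj;
  int n, s, ncell;
  std::vector<int> pos;
  std::vector<bool> used;
  std::vector<int> best_pos;
  long best;
};

static void brute_rec(BruteState& st, int node, int partial) {
  if (node == st.n) {
    if (partial < st.best) {
      st.best = partial;
      st.best_pos = st.pos;
    }
    return;
  }
  for (int c = 0; c < st.ncell; ++c) {
    if (st.used[c]) continue;
    int add = 0;
    for (int v = 0; v < node; ++v)
      if ((*st.adj)(node, v) != 0) add += mdist(c, st.pos[v], st.s);
    st.used[c] = true;
    st.pos[node] = c;
    brute_rec(st, node + 1, partial + add);
    st.used[c] = false;
  }
}

// [[Rcpp::export]]
List cpp_embed_bruteforce(IntegerMatrix adj, int side) {
  BruteState st;
  st.adj = &adj;
  st.n = adj.nrow();
  st.s = side;
  st.ncell = side * side;
  if (st.ncell < st.n) stop("grid too small for graph");
  st.pos.assign(st.n, -1);
  st.used.assign(st.ncell, false);
  st.best = LONG_MAX;
  brute_rec(st, 0, 0);
  return List::create(_["assignment"] = wrap(st.best_pos),
                      _["objective"] = (double)st.best,
                      _["proven_optimal"] = true);
}

// ---- exact branch and bound solver of the placement integer program -------
//
// Minimizes sum_{(a,b) in E} d_ab over injective placements (the assignment
// constraints), with d_ab the Manhattan distance between the chosen cells.
// Nodes are placed in a connectivity-driven order; partial placements are
// pruned with an admissible bound: each fully-unplaced edge contributes at
// least 1, and a node u with placed neighbors contributes at least the
// minimum over free cells of its distance sum to those neighbors.
// Symmetry breaking restricts the first placed node to a fundamental domain
// of the grid's dihedral symmetry group. A motif-derived root lower bound
// (valid inequalities on edge-induced subgraphs) allows early proof of
// optimality and is reported back for the gap.

struct BBState {
  int n, s, ncell;
  std::vector<std::vector<int> > nbrs;   // in placement order indexing
  std::vector<int> order;                // order[k] = original node index
  std::vector<int> pos;                  // by placement order
  std::vector<bool> used;
  std::vector<int> best_pos;
  long best;
  long root_lb;
  bool timed_out;
  long checks;
  std::chrono::steady_clock::time_point deadline;
  std::vector<std::vector<int> > later_nbrs;  // neighbors placed earlier, per k
  std::vector<int> unplaced_edges_after;      // edges with both ends at >= k
};

// bound for the subproblem after nodes 0..k-1 placed
static long bb_bound(BBState& st, int k) {
  long b = st.unplaced_edges_after[k];
  // edges between unplaced node u (>= k) and its already placed neighbors
  for (int u = k; u < st.n; ++u) {
    int np = 0;
    for (size_t t = 0; t < st.later_nbrs[u].size(); ++t)
      if (st.later_nbrs[u][t] < k) ++np;
    if (np == 0) continue;
    int bmin = INT_MAX;
    for (int c = 0; c < st.ncell; ++c) {
      if (st.used[c]) continue;
      int sum = 0;
      for (size_t t = 0; t < st.later_nbrs[u].size(); ++t) {
        int v = st.later_nbrs[u][t];
        if (v < k) sum += mdist(c, st.pos[v], st.s);
      }
      if (sum < bmin) bmin = sum;
    }
    b += bmin;
  }
  return b;
}

static void bb_rec(BBState& st, int k, long partial, bool sym_break) {
  if (st.best <= st.root_lb) return;  // proven optimal already
  if (++st.checks % 4096 == 0 &&
      std::chrono::steady_clock::now() > st.deadline) {
    st.timed_out = true;
  }
  if (st.timed_out) return;
  if (k == st.n) {
    if (partial < st.best) {
      st.best = partial;
      st.best_pos = st.pos;
    }
    return;
  }
  for (int c = 0; c < st.ncell; ++c) {
    if (st.used[c]) continue;
    if (sym_break && k == 0) {
      // fundamental domain of the dihedral group: i <= mirrored i,
      // j <= mirrored j, i <= j (upper-left octant)
      int i = c / st.s, j = c % st.s;
      if (i > st.s - 1 - i || j > st.s - 1 - j || i > j) continue;
    }
    int add = 0;
    for (size_t t = 0; t < st.later_nbrs[k].size(); ++t) {
      int v = st.later_nbrs[k][t];
      if (v < k) add += mdist(c, st.pos[v], st.s);
    }
    st.pos[k] = c;
    st.used[c] = true;
    long lb = partial + add + bb_bound(st, k + 1);
    if (lb < st.best) bb_rec(st, k + 1, partial + add, sym_break);
    st.used[c] = false;
  }
  st.pos[k] = -1;
}

// [[Rcpp::export]]
List cpp_embed_exact(IntegerMatrix adj, int side, bool symmetry_breaking,
                     double time_limit, int root_lb) {
  int n = adj.nrow();
  BBState st;
  st.n = n;
  st.s = side;
  st.ncell = side * side;
  if (st.ncell < n) stop("grid too small for graph");
  st.root_lb = root_lb;
  st.timed_out = false;
  st.checks = 0;
  st.deadline = std::chrono::steady_clock::now() +
                std::chrono::milliseconds((long)(time_limit * 1000.0));

  // placement order: highest degree first, then most edges into placed set
  std::vector<int> deg(n, 0);
  for (int a = 0; a < n; ++a)
    for (int b = 0; b < n; ++b)
      if (adj(a, b) != 0) ++deg[a];
  std::vector<bool> chosen(n, false);
  st.order.clear();
  for (int k = 0; k < n; ++k) {
    int best_v = -1, best_key = -1;
    for (int v = 0; v < n; ++v) {
      if (chosen[v]) continue;
      int into = 0;
      for (size_t t = 0; t < st.order.size(); ++t)
        if (adj(v, st.order[t]) != 0) ++into;
      int key = into * (n + 1) + deg[v];
      if (key > best_key) {
        best_key = key;
        best_v = v;
      }
    }
    chosen[best_v] = true;
    st.order.push_back(best_v);
  }
  std::vector<int> rank(n);
  for (int k = 0; k < n; ++k) rank[st.order[k]] = k;

  st.later_nbrs.assign(n, std::vector<int>());
  for (int a = 0; a < n; ++a)
    for (int b = 0; b < n; ++b)
      if (adj(a, b) != 0) st.later_nbrs[rank[a]].push_back(rank[b]);
  st.unplaced_edges_after.assign(n + 1, 0);
  for (int k = n; k >= 0; --k) {
    int cnt = 0;
    for (int a = k; a < n; ++a)
      for (size_t t = 0; t < st.later_nbrs[a].size(); ++t)
        if (st.later_nbrs[a][t] > a) ++cnt;
    st.unplaced_edges_after[k] = cnt;
  }

  st.pos.assign(n, -1);
  st.used.assign(st.ncell, false);
  st.best = LONG_MAX;
  st.best_pos.assign(n, -1);

  // greedy incumbent: place in order at the free cell minimizing added cost
  {
    std::vector<int> gpos(n, -1);
    std::vector<bool> gused(st.ncell, false);
    long gobj = 0;
    for (int k = 0; k < n; ++k) {
      int bc = -1, badd = INT_MAX;
      for (int c = 0; c < st.ncell; ++c) {
        if (gused[c]) continue;
        int add = 0;
        for (size_t t = 0; t < st.later_nbrs[k].size(); ++t) {
          int v = st.later_nbrs[k][t];
          if (v < k) add += mdist(c, gpos[v], st.s);
        }
        if (add < badd) {
          badd = add;
          bc = c;
        }
      }
      gpos[k] = bc;
      gused[bc] = true;
      gobj += badd;
    }
    st.best = gobj;
    st.best_pos = gpos;
  }

  bb_rec(st, 0, 0, symmetry_breaking);

  // map back to original node order
  std::vector<int> out(n, -1);
  for (int k = 0; k < n; ++k) out[st.order[k]] = st.best_pos[k];
  bool proven = !st.timed_out || st.best <= st.root_lb;
  return List::create(_["assignment"] = wrap(out),
                      _["objective"] = (double)st.best,
                      _["proven_optimal"] = proven,
                      _["timed_out"] = st.timed_out);
}

// ---- simulated annealing heuristic ----------------------------------------

// [[Rcpp::export]]
List cpp_embed_anneal(IntegerMatrix adj, int side, int seed, int iterations,
                      double t0) {
  int n = adj.nrow();
  int ncell = side * side;
  if (ncell < n) stop("grid too small for graph");
  std::mt19937 rng((unsigned)seed);

  // random injective initial placement
  std::vector<int> cells(ncell);
  for (int c = 0; c < ncell; ++c) cells[c] = c;
  for (int c = ncell - 1; c > 0; --c) {
    std::uniform_int_distribution<int> u(0, c);
    std::swap(cells[c], cells[u(rng)]);
  }
  std::vector<int> pos(n);
  std::vector<int> occ(ncell, -1);
  for (int v = 0; v < n; ++v) {
    pos[v] = cells[v];
    occ[cells[v]] = v;
  }
  std::vector<std::vector<int> > nbrs(n);
  for (int a = 0; a < n; ++a)
    for (int b = 0; b < n; ++b)
      if (adj(a, b) != 0) nbrs[a].push_back(b);

  long obj = objective_of(adj, pos, side);
  long best = obj;
  std::vector<int> best_pos = pos;
  if (iterations > 0) {
    double cool = std::pow(1e-3 / std::max(t0, 1e-3),
                           1.0 / (double)iterations);
    double temp = t0;
    std::uniform_int_distribution<int> pick_v(0, n - 1);
    std::uniform_int_distribution<int> pick_c(0, ncell - 1);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    for (int it = 0; it < iterations; ++it, temp *= cool) {
      int u = pick_v(rng);
      int c2 = pick_c(rng);
      int c1 = pos[u];
      if (c1 == c2) continue;
      int w = occ[c2];  // -1 if free
      long delta = 0;
      for (size_t t = 0; t < nbrs[u].size(); ++t) {
        int v = nbrs[u][t];
        if (v == w) continue;
        delta += mdist(c2, pos[v], side) - mdist(c1, pos[v], side);
      }
      if (w >= 0) {
        for (size_t t = 0; t < nbrs[w].size(); ++t) {
          int v = nbrs[w][t];
          if (v == u) continue;
          delta += mdist(c1, pos[v], side) - mdist(c2, pos[v], side);
        }
      }
      if (delta <= 0 || unif(rng) < std::exp(-(double)delta / temp)) {
        pos[u] = c2;
        occ[c2] = u;
        occ[c1] = w;
        if (w >= 0) pos[w] = c1;
        obj += delta;
        if (obj < best) {
          best = obj;
          best_pos = pos;
        }
      }
    }
  }
  return List::create(_["assignment"] = wrap(best_pos),
                      _["objective"] = (double)best,
                      _["proven_optimal"] = false);
}

// [[Rcpp::export]]
double cpp_total_edge_length(IntegerMatrix adj, IntegerVector assignment,
                             int side) {
  std::vector<int> pos(assignment.begin(), assignment.end());
  return (double)objective_of(adj, pos, side);
}
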