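#include <Rcpp.h>
#include <vector>
#include <utility>
#include <cstdint>
using namespace Rcpp;

// Allele coding: 0 = major, 1 = minor, NA_INTEGER = missing.
// All interval arithmetic here is 0-based inclusive; R wrappers are 1-based.

static inline bool is_miss(int v) { return v == NA_INTEGER; }

// Two rows are compatible iff alleles agree at every locus in [j,k] where
// both are non-missing.
static bool rows_compatible(const IntegerMatrix& A, int a, int b, int j, int k) {
  for (int c = j; c <= k; ++c) {
    int x = A(a, c), y = A(b, c);
    if (!is_miss(x) && !is_miss(y) && x != y) return false;
  }
  return true;
}

// Full classification of rows within [j,k] from first principles (pairwise).
// row_class: 0 = ambiguous, 1 = common, 2 = singleton.
// group: positive id for common rows (compatibility class), 0 otherwise.
static void classify_pairwise(const IntegerMatrix& A, int j, int k,
                              std::vector<int>& row_class,
                              std::vector<int>& group,
                              int& U, int& C, int& S, int& amb) {
  const int m = A.nrow();
  std::vector<uint8_t> comp((size_t)m * m, 0);
  std::vector<std::vector<int>> adj(m);
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b)
      if (rows_compatible(A, a, b, j, k)) {
        comp[(size_t)a * m + b] = comp[(size_t)b * m + a] = 1;
        adj[a].push_back(b);
        adj[b].push_back(a);
      }
  row_class.assign(m, 2);
  group.assign(m, 0);
  // ambiguous: compatible with two rows that are mutually incompatible
  for (int r = 0; r < m; ++r) {
    const std::vector<int>& nb = adj[r];
    bool a_ = false;
    for (size_t x = 0; x < nb.size() && !a_; ++x)
      for (size_t y = x + 1; y < nb.size(); ++y)
        if (!comp[(size_t)nb[x] * m + nb[y]]) { a_ = true; break; }
    if (a_) row_class[r] = 0;
  }
  // among unambiguous rows: common iff some other unambiguous row compatible
  for (int r = 0; r < m; ++r) {
    if (row_class[r] == 0) continue;
    bool has = false;
    for (int nb : adj[r]) if (row_class[nb] != 0) { has = true; break; }
    row_class[r] = has ? 1 : 2;
  }
  // groups: compatibility is transitive among unambiguous rows, so one pass
  int g = 0;
  for (int r = 0; r < m; ++r) {
    if (row_class[r] != 1 || group[r] != 0) continue;
    ++g;
    group[r] = g;
    for (int nb : adj[r]) if (row_class[nb] == 1) group[nb] = g;
  }
  U = C = S = amb = 0;
  for (int r = 0; r < m; ++r) {
    if (row_class[r] == 0) ++amb;
    else if (row_class[r] == 1) ++C;
    else ++S;
  }
  U = C + S;
}

static double delta_from_counts(int U, int S) {
  return U > 0 ? (double)S / (double)U : 0.0;
}

// [[Rcpp::export]]
List cpp_classify_interval(IntegerMatrix A, int j, int k) {
  const int m = A.nrow();
  std::vector<int> rc, gr;
  int U, C, S, amb;
  classify_pairwise(A, j - 1, k - 1, rc, gr, U, C, S, amb);
  IntegerVector row_class(m), group(m);
  for (int r = 0; r < m; ++r) { row_class[r] = rc[r]; group[r] = gr[r]; }
  return List::create(_["U"] = U, _["C"] = C, _["S"] = S,
                      _["ambiguous"] = amb,
                      _["delta"] = delta_from_counts(U, S),
                      _["row_class"] = row_class, _["group"] = group);
}

static double delta_interval(const IntegerMatrix& A, int j, int k) {
  std::vector<int> rc, gr;
  int U, C, S, amb;
  classify_pairwise(A, j, k, rc, gr, U, C, S, amb);
  return delta_from_counts(U, S);
}

// ---------------------------------------------------------------------------
// Interval scoring: for each start j, delta for all widths 1..W (clipped at n).
// Complete data: successive partition refinement, O(m) per extension.
// Missing data: incremental pairwise-compatibility maintenance; compatibility
// only shrinks as the interval grows, so pairs are removed monotonically.
// ---------------------------------------------------------------------------

static void score_start_complete(const IntegerMatrix& A, int c0, int W,
                                 NumericMatrix& out, int outrow) {
  const int m = A.nrow(), n = A.ncol();
  const int cend = std::min(n, c0 + W);
  std::vector<int> cls(m, 0), cls2(m), a0, a1, size2;
  int ncls = 1;
  for (int c = c0; c < cend; ++c) {
    a0.assign(ncls, -1);
    a1.assign(ncls, -1);
    int next = 0;
    for (int r = 0; r < m; ++r) {
      int o = cls[r];
      int& slot = A(r, c) == 0 ? a0[o] : a1[o];
      if (slot < 0) slot = next++;
      cls2[r] = slot;
    }
    size2.assign(next, 0);
    for (int r = 0; r < m; ++r) ++size2[cls2[r]];
    int singles = 0;
    for (int g = 0; g < next; ++g) if (size2[g] == 1) ++singles;
    std::swap(cls, cls2);
    ncls = next;
    out(outrow, c - c0) = (double)singles / m; // U = m with complete data
  }
}

static void erase_one(std::vector<int>& v, int val) {
  for (size_t i = 0; i < v.size(); ++i)
    if (v[i] == val) { v[i] = v.back(); v.pop_back(); return; }
}

static void score_start_missing(const IntegerMatrix& A, int c0, int W,
                                NumericMatrix& out, int outrow,
                                std::vector<uint8_t>& alive,
                                std::vector<int>& deg,
                                std::vector<std::vector<int>>& adj,
                                std::vector<std::pair<int,int>>& pairs,
                                std::vector<int>& seen,
                                std::vector<int>& stack_,
                                std::vector<int>& comp,
                                std::vector<int8_t>& rc) {
  const int m = A.nrow(), n = A.ncol();
  const int cend = std::min(n, c0 + W);
  std::fill(alive.begin(), alive.end(), (uint8_t)1);
  std::fill(deg.begin(), deg.end(), m - 1);
  pairs.clear();
  for (int a = 0; a < m; ++a) {
    adj[a].clear();
    for (int b = 0; b < m; ++b) if (b != a) adj[a].push_back(b);
    for (int b = a + 1; b < m; ++b) pairs.push_back(std::make_pair(a, b));
  }
  std::fill(seen.begin(), seen.end(), -1);
  for (int c = c0; c < cend; ++c) {
    // drop pairs that conflict at the new column
    for (size_t p = 0; p < pairs.size();) {
      const int a = pairs[p].first, b = pairs[p].second;
      const int x = A(a, c), y = A(b, c);
      if (!is_miss(x) && !is_miss(y) && x != y) {
        alive[(size_t)a * m + b] = alive[(size_t)b * m + a] = 0;
        --deg[a]; --deg[b];
        erase_one(adj[a], b);
        erase_one(adj[b], a);
        pairs[p] = pairs.back();
        pairs.pop_back();
      } else ++p;
    }
    // classify rows for interval [c0, c]
    int amb = 0, C_ = 0, S_ = 0;
    const int token = c;
    for (int r = 0; r < m; ++r) rc[r] = -2;
    for (int r = 0; r < m; ++r) if (deg[r] == 0) rc[r] = 2;
    for (int r = 0; r < m; ++r) {
      if (deg[r] == 0 || seen[r] == token) continue;
      comp.clear();
      stack_.clear();
      stack_.push_back(r);
      seen[r] = token;
      while (!stack_.empty()) {
        int u = stack_.back(); stack_.pop_back();
        comp.push_back(u);
        for (int v : adj[u]) if (seen[v] != token) { seen[v] = token; stack_.push_back(v); }
      }
      const int sz = (int)comp.size();
      bool clique = true;
      for (int u : comp) if (deg[u] != sz - 1) { clique = false; break; }
      if (clique) {
        for (int u : comp) rc[u] = 1; // sz >= 2 here since deg > 0
      } else {
        for (int u : comp) {
          const std::vector<int>& nb = adj[u];
          bool a_ = false;
          for (size_t x = 0; x < nb.size() && !a_; ++x)
            for (size_t y = x + 1; y < nb.size(); ++y)
              if (!alive[(size_t)nb[x] * m + nb[y]]) { a_ = true; break; }
          rc[u] = a_ ? 0 : -1;
        }
        for (int u : comp) {
          if (rc[u] != -1) continue;
          bool has = false;
          for (int v : adj[u]) if (rc[v] != 0) { has = true; break; }
          rc[u] = has ? 1 : 2;
        }
      }
    }
    for (int r = 0; r < m; ++r) {
      if (rc[r] == 0) ++amb;
      else if (rc[r] == 1) ++C_;
      else ++S_;
    }
    const int U = m - amb;
    out(outrow, c - c0) = U > 0 ? (double)S_ / U : 0.0;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_score_intervals(IntegerMatrix A, IntegerVector starts, int W) {
  const int m = A.nrow(), n = A.ncol();
  bool hasNA = false;
  for (int c = 0; c < n && !hasNA; ++c)
    for (int r = 0; r < m; ++r)
      if (is_miss(A(r, c))) { hasNA = true; break; }
  NumericMatrix out(starts.size(), W);
  std::fill(out.begin(), out.end(), NA_REAL);
  if (!hasNA) {
    for (int i = 0; i < starts.size(); ++i)
      score_start_complete(A, starts[i] - 1, W, out, i);
  } else {
    std::vector<uint8_t> alive((size_t)m * m);
    std::vector<int> deg(m), seen(m), stack_, comp;
    std::vector<std::vector<int>> adj(m);
    std::vector<std::pair<int,int>> pairs;
    std::vector<int8_t> rc(m);
    pairs.reserve((size_t)m * (m - 1) / 2);
    for (int i = 0; i < starts.size(); ++i)
      score_start_missing(A, starts[i] - 1, W, out, i,
                          alive, deg, adj, pairs, seen, stack_, comp, rc);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Good-partner table: L[i] = smallest start s with delta(s, i) <= D and
// width <= W; NA when no feasible block ends at i.
// Complete data: two-pointer sweep (delta monotone in both endpoints).
// Missing data: delta is not provably monotone, so each window is scanned
// from its left edge and every candidate is verified directly.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_good_partner(IntegerMatrix A, double D, int W) {
  const int m = A.nrow(), n = A.ncol();
  bool hasNA = false;
  for (int c = 0; c < n && !hasNA; ++c)
    for (int r = 0; r < m; ++r)
      if (is_miss(A(r, c))) { hasNA = true; break; }
  IntegerVector L(n, NA_INTEGER);
  if (!hasNA) {
    int l = 0;
    for (int i = 0; i < n; ++i) {
      if (l < i - W + 1) l = i - W + 1;
      if (l < 0) l = 0;
      while (l <= i && delta_interval(A, l, i) > D) ++l;
      if (l <= i) L[i] = l + 1;
    }
  } else {
    for (int i = 0; i < n; ++i) {
      int s = i - W + 1;
      if (s < 0) s = 0;
      while (s <= i && delta_interval(A, s, i) > D) ++s;
      if (s <= i) L[i] = s + 1;
    }
  }
  return L;
}

// L derived from a precomputed n x W score table (scores(s-1, w-1) =
// delta of [s, s+w-1]); this is the reduce-side construction.
// [[Rcpp::export]]
IntegerVector cpp_partner_from_scores(NumericMatrix scores, double D, int W) {
  const int n = scores.nrow();
  IntegerVector L(n, NA_INTEGER);
  for (int i = 1; i <= n; ++i) {
    int s0 = i - W + 1;
    if (s0 < 1) s0 = 1;
    for (int s = s0; s <= i; ++s) {
      const double v = scores(s - 1, i - s);
      if (!NumericMatrix::is_na(v) && v <= D) { L[i - 1] = s; break; }
    }
  }
  return L;
}
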