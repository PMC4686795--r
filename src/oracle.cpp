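// Brute-force ground truth for the Hultman recurrences.
//
// Enumerates matchings on nv labelled vertices (perfect, all, or with a
// fixed number of unsaturated vertices) in a fixed deterministic order:
// the smallest unassigned vertex is either skipped or paired with each
// larger unassigned partner in turn.  No counting shortcuts: every matching
// is generated and its breakpoint graph against the identity matching is
// decomposed by direct traversal.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

const int MAX_VERTICES = 16;  // hard guard against combinatorial blow-up

struct Tabulator {
  // counts[c][p]
  std::vector<std::vector<double>> counts;
  const std::vector<int>& identity;  // pair vector, -1 = unsaturated
  int nv;

  Tabulator(const std::vector<int>& id, int nv_)
      : counts(nv_ / 2 + 1, std::vector<double>(nv_ + 1, 0.0)),
        identity(id), nv(nv_) {}

  void visit(const std::vector<int>& pair) {
    // decompose the union of `pair` and `identity` into cycles and paths
    std::vector<char> visited(nv, 0);
    int cycles = 0, paths = 0;
    for (int v = 0; v < nv; ++v) {
      if (visited[v]) continue;
      int deg = (pair[v] >= 0) + (identity[v] >= 0);
      if (deg == 2) continue;  // handled in the cycle sweep
      // path: walk alternating colours starting with the saturating one
      int col = (pair[v] >= 0) ? 0 : 1;  // 0 = pair, 1 = identity
      int cur = v;
      while (true) {
        visited[cur] = 1;
        int nxt = (col == 0) ? pair[cur] : identity[cur];
        if (nxt < 0) break;
        cur = nxt;
        col = 1 - col;
      }
      ++paths;
    }
    for (int v = 0; v < nv; ++v) {
      if (visited[v]) continue;
      // degree 2 everywhere in this component: a cycle
      int cur = v, col = 0;
      while (true) {
        visited[cur] = 1;
        cur = (col == 0) ? pair[cur] : identity[cur];
        col = 1 - col;
        if (cur == v && col == 0) break;
      }
      ++cycles;
    }
    counts[cycles][paths] += 1.0;
  }
};

// mode: 0 = perfect, 1 = all, 2 = fixed number of unsaturated vertices
template <typename Visitor>
void enumerate(std::vector<int>& pair, std::vector<char>& assigned, int nv,
               int mode, int unsat_left, Visitor& vis) {
  int u = -1;
  for (int v = 0; v < nv; ++v)
    if (!assigned[v]) { u = v; break; }
  if (u < 0) {
    if (mode != 2 || unsat_left == 0) vis.visit(pair);
    return;
  }
  // option 1: leave u unsaturated
  if (mode == 1 || (mode == 2 && unsat_left > 0)) {
    assigned[u] = 1;
    pair[u] = -1;
    enumerate(pair, assigned, nv, mode, unsat_left - 1, vis);
    assigned[u] = 0;
  }
  // option 2: pair u with each larger unassigned vertex
  for (int v = u + 1; v < nv; ++v) {
    if (assigned[v]) continue;
    assigned[u] = assigned[v] = 1;
    pair[u] = v; pair[v] = u;
    enumerate(pair, assigned, nv, mode, unsat_left, vis);
    assigned[u] = assigned[v] = 0;
  }
  pair[u] = -1;
}

struct Collector {
  std::vector<int> rows;  // flattened pair vectors (1-based, 0 = unsaturated)
  long long count = 0;
  int nv;
  explicit Collector(int nv_) : nv(nv_) {}
  void visit(const std::vector<int>& pair) {
    for (int v = 0; v < nv; ++v) rows.push_back(pair[v] + 1);
    ++count;
  }
};

void check_spec(int nv, int mode, int unsat) {
  if (nv < 0 || nv % 2 != 0)
    stop("oracle: vertex count must be even and >= 0");
  if (nv > MAX_VERTICES)
    stop("oracle: refusing vertex counts above %d (exhaustive enumeration "
         "grows super-exponentially); use the recurrences instead", MAX_VERTICES);
  if (mode == 2 && (unsat < 0 || unsat > nv || unsat % 2 != 0))
    stop("oracle: unsaturated count must be even and within 0..vertices");
}

}  // namespace

// [[Rcpp::export(name = ".oracle_tabulate_cpp")]]
NumericMatrix oracle_tabulate_cpp(int nv, int mode, int unsat,
                                  IntegerVector identity_pair) {
  check_spec(nv, mode, unsat);
  if (identity_pair.size() != nv)
    stop("oracle: identity pair vector must have length nv");
  std::vector<int> id(nv);
  for (int v = 0; v < nv; ++v) id[v] = identity_pair[v] - 1;  // 0 -> -1
  Tabulator tab(id, nv);
  std::vector<int> pair(nv, -1);
  std::vector<char> assigned(nv, 0);
  if (nv == 0) {
    if (mode != 2 || unsat == 0) tab.counts[0][0] = 1.0;
  } else {
    enumerate(pair, assigned, nv, mode, unsat, tab);
  }
  NumericMatrix out(nv / 2 + 1, nv + 1);
  for (int c = 0; c <= nv / 2; ++c)
    for (int p = 0; p <= nv; ++p) out(c, p) = tab.counts[c][p];
  return out;
}

// [[Rcpp::export(name = ".oracle_enumerate_cpp")]]
IntegerMatrix oracle_enumerate_cpp(int nv, int mode, int unsat) {
  check_spec(nv, mode, unsat);
  Collector col(nv);
  if (nv == 0) {
    IntegerMatrix out(mode != 2 || unsat == 0 ? 1 : 0, 0);
    return out;
  }
  std::vector<int> pair(nv, -1);
  std::vector<char> assigned(nv, 0);
  enumerate(pair, assigned, nv, mode, unsat, col);
  IntegerMatrix out(col.count, nv);
  for (long long r = 0; r < col.count; ++r)
    for (int v = 0; v < nv; ++v) out(r, v) = col.rows[r * nv + v];
  return out;
}
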