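#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Synchronous threshold dynamics on a signed interaction matrix I (N x N,
// entries -1/0/+1, symmetric, zero diagonal). States are encoded as integers
// with node 0 as the least significant bit; the full state space 0..2^N-1 is
// enumerated exhaustively, so N is capped by the caller (default 20).

namespace {

inline int lowest_bit_index(uint32_t s) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_ctz(s);
#else
  int j = 0;
  while (!(s & 1u)) { s >>= 1; ++j; }
  return j;
#endif
}

// Fill nxt[s] = successor of state s under the majority-vote rule.
// Uses an incremental field computation: h(s) = h(s minus lowest bit) + column
// of that bit, so the whole map costs O(2^N * N).
void transition_map(const int* I, int N, std::vector<int>& nxt,
                    std::vector<int>& h) {
  const size_t S = size_t(1) << N;
  nxt.resize(S);
  h.assign(S * N, 0);
  // state 0: all fields are zero, every node retains 0
  nxt[0] = 0;
  for (size_t s = 1; s < S; ++s) {
    const int j = lowest_bit_index((uint32_t)s);
    const size_t sp = s & (s - 1);
    int* hs = &h[s * N];
    const int* hp = &h[sp * N];
    const int* col = I + size_t(j) * N; // column j of I (column-major)
    for (int i = 0; i < N; ++i) hs[i] = hp[i] + col[i];
    int t = 0;
    for (int i = 0; i < N; ++i) {
      const int hi = hs[i];
      const int bit = hi > 0 ? 1 : (hi < 0 ? 0 : int((s >> i) & 1));
      t |= bit << i;
    }
    nxt[s] = t;
  }
}

// States lying on attractors (fixed points and cycle states) of the
// functional graph s -> nxt[s], found by repeatedly peeling in-degree-0
// states. Output is ascending.
void attractor_states(const std::vector<int>& nxt, std::vector<int>& out,
                      std::vector<int>& indeg, std::vector<size_t>& stack) {
  const size_t S = nxt.size();
  indeg.assign(S, 0);
  for (size_t s = 0; s < S; ++s) indeg[nxt[s]]++;
  stack.clear();
  for (size_t s = 0; s < S; ++s)
    if (indeg[s] == 0) stack.push_back(s);
  while (!stack.empty()) {
    const size_t s = stack.back();
    stack.pop_back();
    indeg[s] = -1; // mark removed
    const size_t t = nxt[s];
    if (indeg[t] > 0 && --indeg[t] == 0) stack.push_back(t);
  }
  out.clear();
  for (size_t s = 0; s < S; ++s)
    if (indeg[s] >= 0) out.push_back((int)s);
}

double jaccard_sorted(const std::vector<int>& a, const int* b, int nb) {
  size_t ia = 0;
  int ib = 0, inter = 0;
  while (ia < a.size() && ib < nb) {
    if (a[ia] == b[ib]) { ++inter; ++ia; ++ib; }
    else if (a[ia] < b[ib]) ++ia;
    else ++ib;
  }
  const double uni = double(a.size()) + nb - inter;
  if (uni == 0) return 1.0;
  return inter / uni;
}

} // namespace

// [[Rcpp::export]]
IntegerVector bn_transition_map(IntegerMatrix I) {
  const int N = I.nrow();
  std::vector<int> nxt, h;
  transition_map(&I[0], N, nxt, h);
  return IntegerVector(nxt.begin(), nxt.end());
}

// [[Rcpp::export]]
IntegerVector bn_attractor_states(IntegerMatrix I) {
  const int N = I.nrow();
  std::vector<int> nxt, h, out, indeg;
  std::vector<size_t> stack;
  transition_map(&I[0], N, nxt, h);
  attractor_states(nxt, out, indeg, stack);
  return IntegerVector(out.begin(), out.end());
}

// Full analysis: transition map, attractor orbits (each ordered along the
// dynamics), and per-state attractor id (1-based, indexing the orbit list).
// [[Rcpp::export]]
List bn_analyze(IntegerMatrix I) {
  const int N = I.nrow();
  const size_t S = size_t(1) << N;
  std::vector<int> nxt, h, astates, indeg;
  std::vector<size_t> stack;
  transition_map(&I[0], N, nxt, h);
  attractor_states(nxt, astates, indeg, stack);

  std::vector<int> orbit_id(S, 0); // 0 = not on an attractor (yet)
  std::vector<std::vector<int>> orbits;
  for (int s : astates) {
    if (orbit_id[s]) continue;
    std::vector<int> orb;
    int t = s;
    while (!orbit_id[t]) {
      orbit_id[t] = (int)orbits.size() + 1;
      orb.push_back(t);
      t = nxt[t];
    }
    orbits.push_back(orb);
  }
  // propagate attractor ids to transient states by path following
  std::vector<int> aid(S, 0);
  for (int s : astates) aid[s] = orbit_id[s];
  std::vector<size_t> path;
  for (size_t s = 0; s < S; ++s) {
    if (aid[s]) continue;
    path.clear();
    size_t t = s;
    while (!aid[t]) { path.push_back(t); t = nxt[t]; }
    const int a = aid[t];
    for (size_t p : path) aid[p] = a;
  }
  List orb_list(orbits.size());
  for (size_t k = 0; k < orbits.size(); ++k)
    orb_list[k] = IntegerVector(orbits[k].begin(), orbits[k].end());
  return List::create(
      _["next_state"] = IntegerVector(nxt.begin(), nxt.end()),
      _["orbits"] = orb_list,
      _["attractor_id"] = IntegerVector(aid.begin(), aid.end()));
}

// First-improvement sweep over candidate edge-pair state changes.
// pairs: rows (i1, j1, i2, j2), 0-based node indices; combos: rows (c1, c2)
// over {-1,0,+1}; target: ascending attractor-state encodings of the target
// set; ji_current: attractor Jaccard of the current network vs the target.
// For each pair (in row order) and each combo differing from the pair's
// current states, the candidate network is evaluated; the first candidate
// with JI == 1 (success) or JI > ji_current (improvement) is returned.
//
// A candidate differs from the base network by at most two edges, so only
// the (at most four) incident nodes can change their update bit: the base
// transition map and per-state input fields are computed once, and each
// candidate's successor map is patched per state on the affected nodes
// only.
// [[Rcpp::export]]
List bn_sweep(IntegerMatrix I, IntegerVector target, IntegerMatrix pairs,
              IntegerMatrix combos, double ji_current) {
  const int N = I.nrow();
  const size_t S = size_t(1) << N;
  std::vector<int> nxt0, h0, nxt, out, indeg;
  std::vector<size_t> stack;
  transition_map(&I[0], N, nxt0, h0);
  nxt.resize(S);
  const int np = pairs.nrow(), nc = combos.nrow(), nt = target.size();
  int n_evals = 0;
  for (int p = 0; p < np; ++p) {
    const int i1 = pairs(p, 0), j1 = pairs(p, 1);
    const int i2 = pairs(p, 2), j2 = pairs(p, 3);
    const int c1cur = I(i1, j1), c2cur = I(i2, j2);
    // parsimony-first combo order: combinations changing one edge of the
    // pair are screened before those changing both, so the greedy prefers
    // minimal edits; combo order is preserved within each group
    int corder[16];
    int ncord = 0;
    for (int pass = 1; pass <= 2; ++pass)
      for (int c = 0; c < nc; ++c) {
        const int nch = (combos(c, 0) != c1cur) + (combos(c, 1) != c2cur);
        if (nch == pass) corder[ncord++] = c;
      }
    for (int cc = 0; cc < ncord; ++cc) {
      const int c = corder[cc];
      const int c1 = combos(c, 0), c2 = combos(c, 1);
      if (c1 == c1cur && c2 == c2cur) continue;
      const int d1 = c1 - c1cur, d2 = c2 - c2cur;
      // affected nodes and, per node, the partner/delta of each changed
      // incident edge (the two edges of a pair may share a node)
      int un[4], upart[4][2], udel[4][2], udeg[4];
      int nu = 0;
      if (d1 != 0) {
        un[nu] = i1; upart[nu][0] = j1; udel[nu][0] = d1; udeg[nu] = 1; ++nu;
        un[nu] = j1; upart[nu][0] = i1; udel[nu][0] = d1; udeg[nu] = 1; ++nu;
      }
      if (d2 != 0) {
        const int ends[2] = {i2, j2};
        for (int e = 0; e < 2; ++e) {
          const int u = ends[e], v = ends[1 - e];
          int at = -1;
          for (int q = 0; q < nu; ++q)
            if (un[q] == u) at = q;
          if (at >= 0) {
            upart[at][1] = v; udel[at][1] = d2; udeg[at] = 2;
          } else {
            un[nu] = u; upart[nu][0] = v; udel[nu][0] = d2; udeg[nu] = 1;
            ++nu;
          }
        }
      }
      if (nu == 0) continue; // no actual change
      int mask = 0;
      for (int q = 0; q < nu; ++q) mask |= 1 << un[q];
      for (size_t s = 0; s < S; ++s) {
        int t = nxt0[s] & ~mask;
        const int* hs = &h0[s * N];
        for (int q = 0; q < nu; ++q) {
          const int u = un[q];
          int hu = hs[u] + udel[q][0] * int((s >> upart[q][0]) & 1);
          if (udeg[q] == 2) hu += udel[q][1] * int((s >> upart[q][1]) & 1);
          const int bit = hu > 0 ? 1 : (hu < 0 ? 0 : int((s >> u) & 1));
          t |= bit << u;
        }
        nxt[s] = t;
      }
      attractor_states(nxt, out, indeg, stack);
      const double ji = jaccard_sorted(out, &target[0], nt);
      ++n_evals;
      if (ji >= 1.0 || ji > ji_current) {
        return List::create(
            _["found"] = true, _["success"] = (ji >= 1.0),
            _["pair"] = p + 1, _["combo"] = c + 1, _["ji"] = ji,
            _["n_evals"] = n_evals);
      }
    }
  }
  return List::create(_["found"] = false, _["success"] = false,
                      _["pair"] = NA_INTEGER, _["combo"] = NA_INTEGER,
                      _["ji"] = ji_current, _["n_evals"] = n_evals);
}
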