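// Exact signed reversal distance by bidirectional breadth-first search.
//
// Independent validation oracle for the breakpoint-graph distance: explores
// the move graph (all O(n^2) reversals per state) from both the query
// permutation and the identity, meeting in the middle.  States are signed
// permutations with n <= 9, packed 5 bits per entry into a 64-bit word.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using state_t = uint64_t;

static inline state_t pack(const std::vector<int>& v) {
  state_t s = 0;
  for (size_t i = 0; i < v.size(); ++i) {
    int x = v[i];
    unsigned e = (static_cast<unsigned>(x > 0 ? x : -x) << 1) |
                 (x < 0 ? 1u : 0u);
    s |= static_cast<state_t>(e) << (5 * i);
  }
  return s;
}

static inline void unpack(state_t s, int n, std::vector<int>& v) {
  for (int i = 0; i < n; ++i) {
    unsigned e = (s >> (5 * i)) & 31u;
    int x = static_cast<int>(e >> 1);
    v[i] = (e & 1u) ? -x : x;
  }
}

static void expand(const std::unordered_map<state_t, int>& frontier_src,
                   std::vector<state_t>& frontier,
                   std::unordered_map<state_t, int>& visited,
                   int depth, int n) {
  std::vector<state_t> next;
  std::vector<int> v(n), w(n);
  next.reserve(frontier.size() * n);
  for (state_t s : frontier) {
    unpack(s, n, v);
    for (int i = 0; i < n; ++i) {
      w = v;
      for (int j = i; j < n; ++j) {
        // grow the reversed interval [i, j] one step at a time
        int tmp = -v[j];
        for (int k = j; k > i; --k) w[k] = w[k - 1];
        w[i] = tmp;
        state_t t = pack(w);
        if (visited.find(t) == visited.end()) {
          visited.emplace(t, depth);
          next.push_back(t);
        }
      }
    }
  }
  (void)frontier_src;
  frontier.swap(next);
}

// [[Rcpp::export]]
int bfs_reversal_distance_cpp(Rcpp::IntegerVector perm) {
  int n = perm.size();
  if (n > 9) Rcpp::stop("BFS oracle limited to n <= 9");
  std::vector<int> v(n), id(n);
  for (int i = 0; i < n; ++i) { v[i] = perm[i]; id[i] = i + 1; }
  state_t start = pack(v), goal = pack(id);
  if (start == goal) return 0;

  std::unordered_map<state_t, int> visA, visB;
  std::vector<state_t> frA{start}, frB{goal};
  visA.emplace(start, 0);
  visB.emplace(goal, 0);
  int dA = 0, dB = 0;
  const int max_depth = 2 * n + 2;
  while (dA + dB < max_depth) {
    bool expandA = frA.size() <= frB.size();
    if (expandA) { ++dA; expand(visB, frA, visA, dA, n); }
    else         { ++dB; expand(visA, frB, visB, dB, n); }
    const std::vector<state_t>& fr = expandA ? frA : frB;
    const std::unordered_map<state_t, int>& other = expandA ? visB : visA;
    int best = -1;
    for (state_t s : fr) {
      auto it = other.find(s);
      if (it != other.end()) {
        int d = (expandA ? dA : dB) + it->second;
        if (best < 0 || d < best) best = d;
      }
    }
    if (best >= 0) return best;
    if (fr.empty()) break;
  }
  Rcpp::stop("BFS oracle failed to meet (should not happen)");
  return -1;
}
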