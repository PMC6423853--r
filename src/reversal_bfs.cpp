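// Exhaustive breadth-first search over the reversal graph of all signed
// permutations of size n (2^n * n! states).  Serves as the independent
// oracle for the breakpoint-graph reversal distance; practical for n <= 8.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

// Lehmer rank of the absolute permutation, mixed-radix with sign bits:
// index = rank * 2^n + bits, bit i-1 set iff element i is negative.
// Must match perm_index() on the R side.
uint64_t encode(const int *e, int n) {
  uint64_t rank = 0;
  uint32_t bits = 0;
  bool used[9] = {false};
  for (int i = 0; i < n; ++i) {
    int v = e[i] < 0 ? -e[i] : e[i];
    if (e[i] < 0) bits |= (1u << i);
    int pos = 0;
    for (int x = 1; x < v; ++x) if (!used[x]) ++pos;
    used[v] = true;
    rank = rank * (uint64_t)(n - i) + (uint64_t)pos;
  }
  return (rank << n) | bits;
}

void decode(uint64_t idx, int n, int *e) {
  uint32_t bits = (uint32_t)(idx & ((1u << n) - 1u));
  uint64_t rank = idx >> n;
  int digits[9];
  for (int i = n - 1; i >= 0; --i) {
    digits[i] = (int)(rank % (uint64_t)(n - i));
    rank /= (uint64_t)(n - i);
  }
  bool used[9] = {false};
  for (int i = 0; i < n; ++i) {
    int pos = digits[i], v = 0;
    for (int x = 1; x <= n; ++x) {
      if (!used[x]) {
        if (pos == 0) { v = x; break; }
        --pos;
      }
    }
    used[v] = true;
    e[i] = (bits & (1u << i)) ? -v : v;
  }
}

} // namespace

// [[Rcpp::export(name = "reversal_bfs_table")]]
IntegerVector reversal_bfs_table(int n) {
  if (n < 1 || n > 8) stop("n must be in 1..8");
  uint64_t total = 1;
  for (int i = 2; i <= n; ++i) total *= (uint64_t)i;
  total <<= n;
  std::vector<uint8_t> dist(total, 255);
  std::vector<uint64_t> frontier, next;
  int id[9];
  for (int i = 0; i < n; ++i) id[i] = i + 1;
  uint64_t start = encode(id, n);
  dist[start] = 0;
  frontier.push_back(start);
  int e[9], e2[9];
  uint8_t level = 0;
  while (!frontier.empty()) {
    ++level;
    next.clear();
    for (uint64_t s : frontier) {
      decode(s, n, e);
      for (int i = 0; i < n; ++i) {
        for (int j = i; j < n; ++j) {
          for (int k = 0; k < n; ++k) e2[k] = e[k];
          for (int k = i, m = j; k <= j; ++k, --m) e2[k] = -e[m];
          uint64_t t = encode(e2, n);
          if (dist[t] == 255) {
            dist[t] = level;
            next.push_back(t);
          }
        }
      }
    }
    frontier.swap(next);
  }
  IntegerVector out((R_xlen_t)total);
  for (uint64_t i = 0; i < total; ++i) out[(R_xlen_t)i] = dist[i];
  return out;
}
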