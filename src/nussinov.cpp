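#include <Rcpp.h>
using namespace Rcpp;

// Base-pair maximization (Nussinov-style) with a minimum loop size.
// seq: integer codes 0=A,1=C,2=G,3=U, -1=other (never pairs).
// canPair: 4x4 logical matrix of allowed pairs.
// Returns a 2-column matrix of 1-based pair indices (i < j).
// Traceback is deterministic: at (i, j), pairing branches are examined in
// increasing k and preferred over leaving i unpaired on ties.

static inline bool pair_ok(int a, int b, const LogicalMatrix& canPair) {
  if (a < 0 || b < 0) return false;
  return canPair(a, b);
}

// [[Rcpp::export(name = ".nussinov_pairs")]]
IntegerMatrix nussinov_pairs(IntegerVector seq, int min_loop,
                             LogicalMatrix canPair) {
  int n = seq.size();
  if (n == 0) return IntegerMatrix(0, 2);
  std::vector<int> N((size_t)n * n, 0);
  // N[i*n + j] = max pairs in seq[i..j], 0-based inclusive
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = N[(size_t)(i + 1) * n + j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!pair_ok(seq[i], seq[k], canPair)) continue;
        int inner = (k - i > min_loop + 1) ? N[(size_t)(i + 1) * n + (k - 1)]
                                           : 0;
        int right = (k < j) ? N[(size_t)(k + 1) * n + j] : 0;
        int cand = inner + 1 + right;
        if (cand > best) best = cand;
      }
      N[(size_t)i * n + j] = best;
    }
  }
  // deterministic traceback
  std::vector<std::pair<int, int> > stack, pairs;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    int target = N[(size_t)i * n + j];
    if (target == 0) continue;
    bool done = false;
    for (int k = i + min_loop + 1; k <= j && !done; ++k) {
      if (!pair_ok(seq[i], seq[k], canPair)) continue;
      int inner = (k - i > min_loop + 1) ? N[(size_t)(i + 1) * n + (k - 1)]
                                         : 0;
      int right = (k < j) ? N[(size_t)(k + 1) * n + j] : 0;
      if (inner + 1 + right == target) {
        pairs.push_back(std::make_pair(i + 1, k + 1));
        if (k - i > min_loop + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        done = true;
      }
    }
    if (!done) stack.push_back(std::make_pair(i + 1, j)); // i unpaired
  }
  IntegerMatrix out(pairs.size(), 2);
  for (size_t p = 0; p < pairs.size(); ++p) {
    out(p, 0) = pairs[p].first;
    out(p, 1) = pairs[p].second;
  }
  return out;
}
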