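#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// bases encoded 0=A, 1=C, 2=G, 3=U
static inline bool pair_ok(int a, int b, bool wobble) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return true;  // A-U
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return true;  // C-G
  if (wobble && ((a == 2 && b == 3) || (a == 3 && b == 2))) return true;
  return false;
}

// Fill the maximum base-pairing DP table. M[i*n+j] = max pairs on i..j
// subject to j - i - 1 >= minloop for every pair (i, j).
static void fill_dp(const std::vector<int>& s, int minloop, bool wobble,
                    std::vector<int>& M) {
  const int n = (int)s.size();
  M.assign((size_t)n * n, 0);
  for (int len = minloop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      int best = M[(size_t)(i + 1) * n + j];  // i unpaired
      for (int k = i + minloop + 1; k <= j; ++k) {
        if (pair_ok(s[i], s[k], wobble)) {
          int v = 1;
          if (k - 1 >= i + 1) v += M[(size_t)(i + 1) * n + (k - 1)];
          if (k + 1 <= j)     v += M[(size_t)(k + 1) * n + j];
          if (v > best) best = v;
        }
      }
      M[(size_t)i * n + j] = best;
    }
  }
}

// Fast count-only variant used by the simulation core: same recurrence as
// fill_dp, but iterates only over chemically pairable partners and keeps a
// transposed copy of the table so both inner-loop reads are contiguous.
int nussinov_count(const std::vector<int>& s, int minloop, bool wobble) {
  const int n = (int)s.size();
  if (n < minloop + 2) return 0;
  bool tab[4][4];
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      tab[a][b] = pair_ok(a, b, wobble);
  std::vector<short> M((size_t)n * n, 0), Mt((size_t)n * n, 0);
  std::vector<int> partners;
  partners.reserve(n);
  for (int i = n - 2 - minloop; i >= 0; --i) {
    const bool* prow = tab[s[i]];
    partners.clear();
    for (int k = i + minloop + 1; k < n; ++k)
      if (prow[s[k]]) partners.push_back(k);
    if (partners.empty()) {
      for (int j = i + minloop + 1; j < n; ++j) {
        short v = M[(size_t)(i + 1) * n + j];
        M[(size_t)i * n + j] = v;
        Mt[(size_t)j * n + i] = v;
      }
      continue;
    }
    const short* rowi1 = &M[(size_t)(i + 1) * n];
    size_t tmax = 0;
    for (int j = i + minloop + 1; j < n; ++j) {
      while (tmax < partners.size() && partners[tmax] <= j) ++tmax;
      short best = rowi1[j];  // i unpaired
      const short* colj = &Mt[(size_t)j * n];
      for (size_t t = 0; t < tmax; ++t) {
        const int k = partners[t];
        short v = 1;
        if (k - 1 >= i + 1) v += rowi1[k - 1];
        if (k + 1 <= j) v += colj[k + 1];
        if (v > best) best = v;
      }
      M[(size_t)i * n + j] = best;
      Mt[(size_t)j * n + i] = best;
    }
  }
  return M[n - 1];
}

// [[Rcpp::export]]
int nussinov_count_cpp(IntegerVector seq, int min_loop, bool allow_wobble) {
  std::vector<int> s(seq.begin(), seq.end());
  return nussinov_count(s, min_loop, allow_wobble);
}

// Deterministic traceback: at each region, position i pairs with the
// leftmost admissible partner achieving the optimum, else stays unpaired.
// [[Rcpp::export]]
IntegerMatrix nussinov_pairs_cpp(IntegerVector seq, int min_loop,
                                 bool allow_wobble) {
  std::vector<int> s(seq.begin(), seq.end());
  const int n = (int)s.size();
  if (n < min_loop + 2) return IntegerMatrix(0, 2);
  std::vector<int> M;
  fill_dp(s, min_loop, allow_wobble, M);
  std::vector<std::pair<int, int> > pairs;
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    const int target = M[(size_t)i * n + j];
    if (target == 0) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!pair_ok(s[i], s[k], allow_wobble)) continue;
      int v = 1;
      if (k - 1 >= i + 1) v += M[(size_t)(i + 1) * n + (k - 1)];
      if (k + 1 <= j)     v += M[(size_t)(k + 1) * n + j];
      if (v == target) {
        pairs.push_back(std::make_pair(i + 1, k + 1));  // 1-based
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
  IntegerMatrix out((int)pairs.size(), 2);
  for (int r = 0; r < (int)pairs.size(); ++r) {
    out(r, 0) = pairs[r].first;
    out(r, 1) = pairs[r].second;
  }
  return out;
}
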