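#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Lexicographically-first minimum tagSNP set.
//
// reps: k x w matrix of group representatives over {0, 1, NA}. A locus
// distinguishes a pair of groups iff both are non-missing there and differ.
// For gamma = gamma0 .. max_gamma, the gamma-subsets of 1..w are visited in
// lexicographic order (depth-first over ascending prefixes, which shares
// partial pair coverage between neighbouring combinations) and the first
// subset hitting every pair is returned. Equivalent to flat lexicographic
// enumeration, just with subtree pruning when the remaining depth cannot
// hit the remaining pairs.

namespace {

struct Search {
  int w, gamma, words;
  long long npairs;
  const std::vector<std::vector<uint64_t>>* locus_mask;
  const std::vector<long long>* suffix_max; // max hits among loci >= c
  std::vector<int> chosen;
  std::vector<std::vector<uint64_t>> buf; // per-depth unhit scratch

  bool dfs(int next_locus, int depth, long long unhit_count) {
    const std::vector<uint64_t>& unhit = buf[depth];
    if (unhit_count == 0) {
      // lex-first completion: ascend from the last chosen locus
      for (int d = depth; d < gamma; ++d)
        chosen[d] = (d == 0 ? 0 : chosen[d - 1] + 1);
      return true;
    }
    if (depth == gamma) return false;
    const int remaining = gamma - depth;
    for (int c = next_locus; c <= w - remaining; ++c) {
      if (unhit_count > (long long)remaining * (*suffix_max)[c]) return false;
      const std::vector<uint64_t>& lm = (*locus_mask)[c];
      long long newly = 0;
      for (int q = 0; q < words; ++q) {
        uint64_t h = unhit[q] & lm[q];
        if (h) newly += __builtin_popcountll(h);
      }
      const long long rest = unhit_count - newly;
      if (rest > 0) {
        if (remaining == 1) continue;
        if (c + 1 < w && rest > (long long)(remaining - 1) * (*suffix_max)[c + 1])
          continue;
        if (c + 1 >= w) continue;
      }
      std::vector<uint64_t>& nu = buf[depth + 1];
      for (int q = 0; q < words; ++q) nu[q] = unhit[q] & ~lm[q];
      chosen[depth] = c;
      if (dfs(c + 1, depth + 1, rest)) return true;
    }
    return false;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_select_tagsnps(IntegerMatrix reps, int gamma0, int max_gamma) {
  const int k = reps.nrow(), w = reps.ncol();
  if (k <= 1) {
    return List::create(_["found"] = true, _["loci"] = IntegerVector(0));
  }
  const long long npairs = (long long)k * (k - 1) / 2;
  const int words = (int)((npairs + 63) / 64);
  // per-locus bitmask over pairs it distinguishes
  std::vector<std::vector<uint64_t>> locus_mask(
      w, std::vector<uint64_t>(words, 0));
  {
    long long p = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b, ++p)
        for (int c = 0; c < w; ++c) {
          const int x = reps(a, c), y = reps(b, c);
          if (x != NA_INTEGER && y != NA_INTEGER && x != y)
            locus_mask[c][p / 64] |= (uint64_t)1 << (p % 64);
        }
  }
  // a pair no locus distinguishes can never be separated
  {
    std::vector<uint64_t> any(words, 0);
    for (int c = 0; c < w; ++c)
      for (int q = 0; q < words; ++q) any[q] |= locus_mask[c][q];
    long long hit = 0;
    for (int q = 0; q < words; ++q) hit += __builtin_popcountll(any[q]);
    if (hit < npairs) {
      return List::create(_["found"] = false, _["loci"] = IntegerVector(0));
    }
  }
  std::vector<long long> suffix_max(w + 1, 0);
  for (int c = w - 1; c >= 0; --c) {
    long long h = 0;
    for (int q = 0; q < words; ++q)
      h += __builtin_popcountll(locus_mask[c][q]);
    suffix_max[c] = std::max(suffix_max[c + 1], h);
  }
  std::vector<uint64_t> all_unhit(words, 0);
  for (long long p = 0; p < npairs; ++p)
    all_unhit[p / 64] |= (uint64_t)1 << (p % 64);
  if (max_gamma > w) max_gamma = w;
  for (int gamma = gamma0; gamma <= max_gamma; ++gamma) {
    Search s;
    s.w = w;
    s.gamma = gamma;
    s.words = words;
    s.npairs = npairs;
    s.locus_mask = &locus_mask;
    s.suffix_max = &suffix_max;
    s.chosen.assign(gamma, -1);
    s.buf.assign(gamma + 1, std::vector<uint64_t>(words, 0));
    s.buf[0] = all_unhit;
    if (s.dfs(0, 0, npairs)) {
      IntegerVector loci(gamma);
      for (int i = 0; i < gamma; ++i) loci[i] = s.chosen[i] + 1;
      return List::create(_["found"] = true, _["loci"] = loci);
    }
  }
  return List::create(_["found"] = false, _["loci"] = IntegerVector(0));
}
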