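#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit base encoding; A=0, C=1, G=2, T=3 so that the numeric order of a
// packed word equals the lexicographic order of the decoded string.
static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// Rolling 2-bit k-mer counter. Windows containing any non-ACGT byte are
// skipped entirely; with canonical=true each window contributes to
// min(word, reverse_complement(word)). k <= 31 so a word fits in 62 bits.
// [[Rcpp::export(name = ".countKmersCpp")]]
List countKmersCpp(CharacterVector reads, int k, bool canonical) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, double> tab;
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  const int shift = 2 * (k - 1);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    SEXP sr = STRING_ELT(reads, r);
    if (sr == NA_STRING) continue;
    const char* s = CHAR(sr);
    const int n = (int) LENGTH(sr);
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      const int c = baseCode(s[i]);
      if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t) c) & mask;
      rev = (rev >> 2) | (((uint64_t) (3 - c)) << shift);
      if (++valid >= k) {
        tab[canonical ? std::min(fwd, rev) : fwd] += 1.0;
      }
    }
  }
  std::vector<uint64_t> keys;
  keys.reserve(tab.size());
  for (const auto& kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  const R_xlen_t m = (R_xlen_t) keys.size();
  CharacterVector nm(m);
  NumericVector cnt(m);
  std::string buf((size_t) k, 'A');
  static const char B[] = "ACGT";
  for (R_xlen_t i = 0; i < m; ++i) {
    uint64_t v = keys[i];
    for (int j = k - 1; j >= 0; --j) { buf[(size_t) j] = B[v & 3ULL]; v >>= 2; }
    nm[i] = buf;
    cnt[i] = tab[keys[i]];
  }
  return List::create(_["kmer"] = nm, _["count"] = cnt);
}
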