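#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

// 2-bit base codes; anything that is not A/C/G/T (upper case) is invalid
// and excludes every window overlapping it.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// Exact count of k-mers occurring exactly once across all sequences.
// Keys are 2-bit packed into byte strings so arbitrary k fits; windows
// containing invalid bases (N etc.) are skipped. canonical=true counts a
// k-mer and its reverse complement as one key (lexicographically smaller
// packed form).
// [[Rcpp::export]]
double count_unique_kmers_cpp(CharacterVector seqs, int k, bool canonical) {
  if (k < 1) stop("k must be >= 1");
  const size_t nbytes = (size_t)((k + 3) / 4);
  std::unordered_map<std::string, unsigned int> counts;
  std::string key(nbytes, '\0'), rckey(nbytes, '\0');
  {
    double total = 0;
    for (R_xlen_t si = 0; si < seqs.size(); ++si)
      total += LENGTH(STRING_ELT(seqs, si));
    counts.reserve((size_t)std::min(total, 2e8));
  }

  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const char *s = CHAR(STRING_ELT(seqs, si));
    const long n = (long)LENGTH(STRING_ELT(seqs, si));
    if (n < k) continue;
    std::vector<signed char> code(n);
    for (long i = 0; i < n; ++i) code[i] = (signed char)base_code(s[i]);
    // next_bad[i]: windows starting at i are valid iff no invalid base in
    // [i, i+k); track the most recent invalid position from the left.
    long last_bad = -1;
    for (long i = 0; i + k <= n; ++i) {
      if (i == 0) {
        for (long j = 0; j < k; ++j) if (code[j] < 0) last_bad = j;
      } else {
        if (code[i + k - 1] < 0) last_bad = i + k - 1;
      }
      if (last_bad >= i) continue;
      std::fill(key.begin(), key.end(), '\0');
      for (long w = 0; w < k; ++w)
        key[w >> 2] |= (char)(code[i + w] << ((w & 3) * 2));
      if (canonical) {
        std::fill(rckey.begin(), rckey.end(), '\0');
        for (long w = 0; w < k; ++w) {
          int c = 3 - code[i + k - 1 - w];
          rckey[w >> 2] |= (char)(c << ((w & 3) * 2));
        }
        ++counts[rckey < key ? rckey : key];
      } else {
        ++counts[key];
      }
    }
  }
  double unique_n = 0;
  for (std::unordered_map<std::string, unsigned int>::const_iterator it =
         counts.begin(); it != counts.end(); ++it)
    if (it->second == 1u) unique_n += 1;
  return unique_n;
}
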