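#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Best tandem-rotation match count per window.
//
// For every window of length m (the monomer length) starting at position
// i of seq, returns the maximum number of matching bases over all m
// cyclic rotations of the monomer and of its reverse complement.
// Comparing window [i, i+m) against rotation r is equivalent to comparing
// seq against the periodic extension with phase p = (r - i) mod m, so one
// pass per phase covers all windows: O(2 * m * n) byte compares overall.
// Each pass is three branch-free linear sweeps (periodic compare into a
// byte mask, prefix sum, windowed max), which the compiler vectorizes.
// Non-ACGT bases (N) never match an A/C/G/T monomer.
// [[Rcpp::export]]
IntegerVector tandem_best_match_cpp(std::string seq, std::string monomer,
                                    std::string monomer_rc) {
  const long n = (long)seq.size();
  const long m = (long)monomer.size();
  if (m < 1) stop("monomer must be non-empty");
  if ((long)monomer_rc.size() != m)
    stop("monomer and reverse complement differ in length");
  if (n < m) return IntegerVector(0);
  const long nw = n - m + 1;
  IntegerVector best(nw, 0);
  int *bp = INTEGER(best);
  const char *s = seq.data();
  std::vector<unsigned char> v((size_t)n);
  std::vector<int> P((size_t)n + 1);
  const std::string *monos[2] = { &monomer, &monomer_rc };

  for (int which = 0; which < 2; ++which) {
    const std::string &mono = *monos[which];
    for (long p = 0; p < m; ++p) {
      // v[t] = (seq[t] == mono[(t + p) % m]), computed in wrap-free chunks
      long t0 = 0, j = p;
      while (t0 < n) {
        const long len = std::min(m - j, n - t0);
        const char *mp = mono.data() + j;
        unsigned char *vp = v.data() + t0;
        const char *sp = s + t0;
        for (long t = 0; t < len; ++t) vp[t] = (unsigned char)(sp[t] == mp[t]);
        t0 += len;
        j += len;
        if (j == m) j = 0;
      }
      P[0] = 0;
      for (long t = 0; t < n; ++t) P[t + 1] = P[t] + v[t];
      for (long i = 0; i < nw; ++i) {
        const int w = P[i + m] - P[i];
        if (w > bp[i]) bp[i] = w;
      }
    }
  }
  return best;
}
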