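#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Best-match PWM scan over a set of sequences.
//
// fwd/rev are 4 x L log-odds matrices (rows A,C,G,T); rev must be the
// reverse-complemented matrix so that scanning a sequence with rev equals
// scanning its reverse complement with fwd. Windows containing non-ACGT
// characters are skipped; sequences shorter than L give NA.
// [[Rcpp::export(name = ".scan_best_cpp")]]
NumericVector scan_best_cpp(CharacterVector seqs, NumericMatrix fwd,
                            NumericMatrix rev) {
  const int L = fwd.ncol();
  const int n = seqs.size();
  NumericVector out(n);
  std::vector<int> code;
  for (int i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    const char *s = CHAR(STRING_ELT(seqs, i));
    const int len = (int) std::strlen(s);
    if (len < L) { out[i] = NA_REAL; continue; }
    code.resize(len);
    for (int p = 0; p < len; ++p) {
      switch (s[p]) {
        case 'A': case 'a': code[p] = 0; break;
        case 'C': case 'c': code[p] = 1; break;
        case 'G': case 'g': code[p] = 2; break;
        case 'T': case 't': code[p] = 3; break;
        default: code[p] = -1;
      }
    }
    double best = R_NegInf;
    for (int o = 0; o + L <= len; ++o) {
      double sf = 0.0, sr = 0.0;
      bool ok = true;
      for (int j = 0; j < L; ++j) {
        const int b = code[o + j];
        if (b < 0) { ok = false; break; }
        sf += fwd(b, j);
        sr += rev(b, j);
      }
      if (!ok) continue;
      const double m = sf > sr ? sf : sr;
      if (m > best) best = m;
    }
    out[i] = (best == R_NegInf) ? NA_REAL : best;
  }
  return out;
}
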