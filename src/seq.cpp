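#include <Rcpp.h>
#include <string>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'a': return 't';
  case 'c': return 'g';
  case 'g': return 'c';
  case 't': return 'a';
  default:  return 'N';
  }
}

std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    out[i] = revcomp_str(as<std::string>(seqs[i]));
  }
  return out;
}

// Substitution errors at a fixed per-base rate; uses the R RNG so results
// are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector seqs, double rate) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  if (rate <= 0) return clone(seqs);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() < rate) {
        char cur = s[j];
        char sub;
        do {
          sub = BASES[(int)(unif_rand() * 4.0) & 3];
        } while (sub == cur);
        s[j] = sub;
      }
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gc_content(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int gc = 0, tot = 0;
    for (char c : s) {
      if (c == 'G' || c == 'C') { ++gc; ++tot; }
      else if (c == 'A' || c == 'T') ++tot;
    }
    out[i] = tot > 0 ? (double)gc / tot : NA_REAL;
  }
  return out;
}
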