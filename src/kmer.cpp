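#include <Rcpp.h>
#include <unordered_map>
#include <string>
using namespace Rcpp;

// 2-bit encoded canonical k-mer index, k <= 31.  Values are small bitmasks
// over marker labels (bit l set <=> some reference of label l contains the
// k-mer).  N-containing windows are never indexed or queried.

struct KmerIndex {
  int k;
  int n_labels;
  std::unordered_map<uint64_t, uint16_t> map;
};

static inline int code_of(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// Enumerate canonical codes of all valid k-mer windows of s; calls f(code).
template <typename F>
static void for_each_canonical(const std::string &s, int k, F f) {
  int n = (int)s.size();
  if (n < k) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0; // number of consecutive valid bases ending here
  for (int i = 0; i < n; ++i) {
    int c = code_of(s[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++valid >= k) f(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export]]
SEXP cpp_kmer_index_build(CharacterVector seqs, IntegerVector label_idx,
                          int k, int n_labels) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  KmerIndex *idx = new KmerIndex();
  idx->k = k;
  idx->n_labels = n_labels;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    uint16_t bit = (uint16_t)1 << label_idx[i];
    for_each_canonical(s, k, [&](uint64_t code) { idx->map[code] |= bit; });
  }
  XPtr<KmerIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
int cpp_kmer_index_size(SEXP xp) {
  XPtr<KmerIndex> p(xp);
  return (int)p->map.size();
}

// Per-label counts of k-mer window positions of `seq` found under that label.
// [[Rcpp::export]]
IntegerVector cpp_kmer_hits(SEXP xp, std::string seq) {
  XPtr<KmerIndex> p(xp);
  IntegerVector out(p->n_labels);
  for_each_canonical(seq, p->k, [&](uint64_t code) {
    auto it = p->map.find(code);
    if (it == p->map.end()) return;
    for (int l = 0; l < p->n_labels; ++l)
      if (it->second & ((uint16_t)1 << l)) ++out[l];
  });
  return out;
}

// Classify read pairs: per label, hits summed over both mates; assign the
// top label if its hits >= min_hits and the top is unique, else 0
// (unassigned).  Returns 1-based label index or 0.
// [[Rcpp::export]]
IntegerVector cpp_classify_pairs(SEXP xp, CharacterVector seq1,
                                 CharacterVector seq2, int min_hits) {
  XPtr<KmerIndex> p(xp);
  R_xlen_t n = seq1.size();
  IntegerVector out(n);
  std::vector<int> hits(p->n_labels);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::fill(hits.begin(), hits.end(), 0);
    for (int m = 0; m < 2; ++m) {
      std::string s = as<std::string>(m == 0 ? seq1[i] : seq2[i]);
      for_each_canonical(s, p->k, [&](uint64_t code) {
        auto it = p->map.find(code);
        if (it == p->map.end()) return;
        for (int l = 0; l < p->n_labels; ++l)
          if (it->second & ((uint16_t)1 << l)) ++hits[l];
      });
    }
    int best = -1, best_hits = 0;
    bool tie = false;
    for (int l = 0; l < p->n_labels; ++l) {
      if (hits[l] > best_hits) { best = l; best_hits = hits[l]; tie = false; }
      else if (hits[l] == best_hits && hits[l] > 0) tie = true;
    }
    out[i] = (best >= 0 && !tie && best_hits >= min_hits) ? best + 1 : 0;
  }
  return out;
}
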