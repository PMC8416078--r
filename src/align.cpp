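#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

std::string revcomp_str(const std::string &s); // seq.cpp

static const int NEG = std::numeric_limits<int>::min() / 4;

// ---------------------------------------------------------------------------
// Local alignment with affine gaps (gap of length L costs open + ext * L,
// matching the convention of Biostrings::pairwiseAlignment).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sw_affine(std::string a, std::string b, double match = 1,
                   double mismatch = -2, double gap_open = 5,
                   double gap_ext = 2) {
  int n = (int)a.size(), m = (int)b.size();
  std::vector<double> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0); // 0 stop,1 diag,2 up,3 left
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  double best = 0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e = std::max(H[at(i, j - 1)] - (gap_open + gap_ext),
                          E[at(i, j - 1)] - gap_ext);
      double f = std::max(H[at(i - 1, j)] - (gap_open + gap_ext),
                          F[at(i - 1, j)] - gap_ext);
      bool eq = a[i - 1] == b[j - 1] && a[i - 1] != 'N';
      double d = H[at(i - 1, j - 1)] + (eq ? match : mismatch);
      double h = 0;
      unsigned char t = 0;
      if (d > h) { h = d; t = 1; }
      if (f > h) { h = f; t = 2; }
      if (e > h) { h = e; t = 3; }
      H[at(i, j)] = h;
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      tb[at(i, j)] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback (greedy over H pointers; adequate for identity bookkeeping)
  int i = bi, j = bj, nmatch = 0, cols = 0;
  while (i > 0 && j > 0 && H[at(i, j)] > 0) {
    unsigned char t = tb[at(i, j)];
    if (t == 0) break;
    ++cols;
    if (t == 1) {
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++nmatch;
      --i; --j;
    } else if (t == 2) --i;
    else --j;
  }
  return List::create(
      _["score"] = best, _["nmatch"] = nmatch, _["align_len"] = cols,
      _["identity"] = cols > 0 ? 100.0 * nmatch / cols : 0.0,
      _["qstart"] = i + 1, _["qend"] = bi, _["sstart"] = j + 1,
      _["send"] = bj);
}

// ---------------------------------------------------------------------------
// Needleman-Wunsch (linear gap) alignment projected onto the query:
// match[q] is TRUE where query position q is aligned to an identical base.
// mode 0: global; mode 1: trailing end gaps free on both sequences
// (prefix-anchored, for scoring left segments); mode 2: leading end gaps
// free (suffix-anchored, for right segments).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_match_profile(std::string query, std::string ref, int mode = 0) {
  const int MATCH = 1, MISMATCH = -1, GAP = -2;
  int n = (int)query.size(), m = (int)ref.size();
  std::vector<int> H((n + 1) * (m + 1));
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  bool free_start = (mode == 2), free_end = (mode == 1);
  for (int i = 0; i <= n; ++i) H[at(i, 0)] = free_start ? 0 : i * GAP;
  for (int j = 0; j <= m; ++j) H[at(0, j)] = free_start ? 0 : j * GAP;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      bool eq = query[i - 1] == ref[j - 1] && query[i - 1] != 'N';
      int d = H[at(i - 1, j - 1)] + (eq ? MATCH : MISMATCH);
      int u = H[at(i - 1, j)] + GAP;
      int l = H[at(i, j - 1)] + GAP;
      H[at(i, j)] = std::max(d, std::max(u, l));
    }
  // alignment end: global corner, or best last-row/column cell when
  // trailing gaps are free
  int bi = n, bj = m;
  if (free_end) {
    int best = H[at(n, m)];
    for (int j = 0; j <= m; ++j)
      if (H[at(n, j)] > best) { best = H[at(n, j)]; bi = n; bj = j; }
    for (int i = 0; i <= n; ++i)
      if (H[at(i, m)] > best) { best = H[at(i, m)]; bi = i; bj = m; }
  }
  LogicalVector match(n, false);
  int i = bi, j = bj, cols = 0, nmatch = 0;
  while (i > 0 || j > 0) {
    if (free_start && (i == 0 || j == 0) && H[at(i, j)] == 0) break;
    ++cols;
    if (i > 0 && j > 0) {
      bool eq = query[i - 1] == ref[j - 1] && query[i - 1] != 'N';
      if (H[at(i, j)] == H[at(i - 1, j - 1)] + (eq ? MATCH : MISMATCH)) {
        if (eq) { match[i - 1] = true; ++nmatch; }
        --i; --j;
        continue;
      }
    }
    if (i > 0 && H[at(i, j)] == H[at(i - 1, j)] + GAP) { --i; continue; }
    if (j > 0) { --j; continue; }
    --i;
  }
  return List::create(_["match"] = match, _["nmatch"] = nmatch,
                      _["align_len"] = cols,
                      _["identity"] = cols > 0 ? 100.0 * nmatch / cols : 0.0,
                      _["score"] = H[at(n, m)]);
}

// ---------------------------------------------------------------------------
// Read mapping: exact-seed anchoring on the representative plus a windowed
// extension alignment.  A mate is accepted iff its identity over the aligned
// columns is >= min_identity and the aligned read span covers >= min_frac of
// the mate.  Read ends may be soft-clipped only at representative
// boundaries.
// ---------------------------------------------------------------------------

struct MapHit {
  bool accepted = false;
  int start = 0, end = 0; // 0-based half-open on the representative
  double identity = 0;
  int strand = 0; // 1 = forward, -1 = reverse
};

static bool encode_kmer(const std::string &s, int pos, int k, uint64_t &code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int c;
    switch (s[pos + i]) {
    case 'A': c = 0; break;
    case 'C': c = 1; break;
    case 'G': c = 2; break;
    case 'T': c = 3; break;
    default: return false;
    }
    code = (code << 2) | (uint64_t)c;
  }
  return true;
}

static bool extend_window(const std::string &read, const std::string &rep,
                          int diag, int band, double min_identity,
                          double min_frac, MapHit &hit) {
  const int MATCH = 1, MISMATCH = -1, GAP = -2;
  int n = (int)read.size(), replen = (int)rep.size();
  int wstart = diag - band;
  if (wstart < 0) wstart = 0;
  int wend = diag + n + band;
  if (wend > replen) wend = replen;
  int m = wend - wstart;
  if (m <= 0) return false;
  bool free_left = (wstart == 0), free_right = (wend == replen);
  std::vector<int> H((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) H[at(0, j)] = 0; // window prefix free
  for (int i = 1; i <= n; ++i) H[at(i, 0)] = free_left ? 0 : i * GAP;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      bool eq = read[i - 1] == rep[wstart + j - 1] && read[i - 1] != 'N';
      int d = H[at(i - 1, j - 1)] + (eq ? MATCH : MISMATCH);
      int u = H[at(i - 1, j)] + GAP;
      int l = H[at(i, j - 1)] + GAP;
      H[at(i, j)] = std::max(d, std::max(u, l));
    }
  // best end: read fully aligned (any j), or read suffix clipped at rep end
  int bi = -1, bj = -1, best = NEG;
  for (int j = 0; j <= m; ++j)
    if (H[at(n, j)] > best) { best = H[at(n, j)]; bi = n; bj = j; }
  if (free_right)
    for (int i = 0; i < n; ++i)
      if (H[at(i, m)] > best) { best = H[at(i, m)]; bi = i; bj = m; }
  if (bi <= 0 || bj <= 0) return false;
  // traceback
  int i = bi, j = bj, nmatch = 0, cols = 0;
  while (i > 0 && j > 0) {
    bool eq = read[i - 1] == rep[wstart + j - 1] && read[i - 1] != 'N';
    if (H[at(i, j)] == H[at(i - 1, j - 1)] + (eq ? MATCH : MISMATCH)) {
      ++cols;
      if (eq) ++nmatch;
      --i; --j;
      continue;
    }
    if (H[at(i, j)] == H[at(i - 1, j)] + GAP) { ++cols; --i; continue; }
    if (H[at(i, j)] == H[at(i, j - 1)] + GAP) { ++cols; --j; continue; }
    break; // reached a free-start cell
  }
  int read_span = bi - i; // soft-clipped prefix (rep start) excluded
  if (i > 0 && !(free_left && j == 0)) {
    // read prefix consumed by gaps before the window: count the columns
    cols += i;
    read_span = bi;
  }
  if (cols <= 0) return false;
  double ident = (double)nmatch / cols;
  double frac = (double)read_span / n;
  hit.start = wstart + j;
  hit.end = wstart + bj;
  hit.identity = 100.0 * ident;
  hit.accepted = (ident >= min_identity) && (frac >= min_frac);
  return true;
}

// [[Rcpp::export]]
DataFrame cpp_map_reads(std::string rep, CharacterVector seqs,
                        double min_identity, double min_frac = 0.8,
                        int seed_len = 15, int band = 8) {
  int replen = (int)rep.size();
  if (replen < seed_len) stop("representative shorter than seed length");
  std::unordered_map<uint64_t, int> seeds;
  seeds.reserve(replen);
  for (int p = 0; p + seed_len <= replen; ++p) {
    uint64_t code;
    if (encode_kmer(rep, p, seed_len, code)) seeds.emplace(code, p);
  }
  std::vector<int> out_idx, out_start, out_end, out_strand;
  std::vector<double> out_ident;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string fwd = as<std::string>(seqs[r]);
    for (int strand = 0; strand < 2; ++strand) {
      std::string read = (strand == 0) ? fwd : revcomp_str(fwd);
      int n = (int)read.size();
      if (n < seed_len) break;
      MapHit hit;
      bool tried = false;
      for (int p = 0; p + seed_len <= n && !tried; ++p) {
        uint64_t code;
        if (!encode_kmer(read, p, seed_len, code)) continue;
        auto it = seeds.find(code);
        if (it == seeds.end()) continue;
        tried = true;
        int diag = it->second - p;
        extend_window(read, rep, diag, band, min_identity, min_frac, hit);
      }
      if (tried && hit.accepted) {
        out_idx.push_back((int)r + 1);
        out_start.push_back(hit.start);
        out_end.push_back(hit.end);
        out_ident.push_back(hit.identity);
        out_strand.push_back(strand == 0 ? 1 : -1);
        break; // do not also map the reverse orientation
      }
    }
  }
  return DataFrame::create(
      _["read"] = wrap(out_idx), _["start"] = wrap(out_start),
      _["end"] = wrap(out_end), _["identity"] = wrap(out_ident),
      _["strand"] = wrap(out_strand));
}

// ---------------------------------------------------------------------------
// IUPAC-aware semi-global primer search: the primer aligns globally, the
// subject ends are free.  Unit-cost edit distance (mismatches + indels).
// ---------------------------------------------------------------------------

static int iupac_mask(char c) {
  switch (c) {
  case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
  case 'R': return 5; case 'Y': return 10; case 'S': return 6; case 'W': return 9;
  case 'K': return 12; case 'M': return 3; case 'B': return 14; case 'D': return 13;
  case 'H': return 11; case 'V': return 7; case 'N': return 15;
  default: return 0;
  }
}

// [[Rcpp::export]]
List cpp_primer_find(std::string seq, std::string primer) {
  int n = (int)primer.size(), m = (int)seq.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  // start[j] tracks where the alignment ending at column j began
  std::vector<int> sprev(m + 1), scur(m + 1);
  for (int j = 0; j <= m; ++j) { prev[j] = 0; sprev[j] = j; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    scur[0] = 0;
    int pm = iupac_mask(primer[i - 1]);
    for (int j = 1; j <= m; ++j) {
      int sm = iupac_mask(seq[j - 1]);
      int sub = prev[j - 1] + ((pm & sm) ? 0 : 1);
      int del = prev[j] + 1;  // primer base unmatched
      int ins = cur[j - 1] + 1; // extra subject base inside primer
      int v = sub, s = sprev[j - 1];
      if (del < v) { v = del; s = sprev[j]; }
      if (ins < v) { v = ins; s = scur[j - 1]; }
      cur[j] = v;
      scur[j] = s;
    }
    std::swap(prev, cur);
    std::swap(sprev, scur);
  }
  int bj = 0, bd = prev[0];
  for (int j = 1; j <= m; ++j)
    if (prev[j] < bd) { bd = prev[j]; bj = j; }
  return List::create(_["start"] = sprev[bj], _["end"] = bj,
                      _["dist"] = bd);
}
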