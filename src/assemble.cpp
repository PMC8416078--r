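#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
using namespace Rcpp;

std::string revcomp_str(const std::string &s); // seq.cpp

// Single-k de Bruijn assembly: nodes are (k-1)-mers, edges are k-mers with
// coverage counts accumulated from both strands of the input reads.
// Edges below min_edge_cov are dropped, tip paths (exactly one dead end)
// shorter than 2k are iteratively removed, and maximal non-branching paths
// (unitigs) of length >= min_len are emitted with their mean edge coverage.

struct NodeInfo {
  std::string out; // outgoing edge characters
  int indeg = 0;
};

struct Unitig {
  std::string seq;
  double cov;
  bool dead_start, dead_end;
  int start_outdeg, end_indeg; // degrees at the terminal nodes
  std::vector<std::string> kmers;
};

static void extract_unitigs(
    const std::unordered_set<std::string> &S,
    const std::unordered_map<std::string, int> &counts, int k,
    std::vector<Unitig> &out) {
  std::unordered_map<std::string, NodeInfo> nodes;
  for (const auto &kmer : S) {
    std::string u = kmer.substr(0, k - 1), v = kmer.substr(1);
    nodes[u].out += kmer[k - 1];
    nodes[v].indeg++;
    nodes.emplace(v, NodeInfo()); // ensure v exists even as sink
  }
  std::unordered_set<std::string> visited;
  visited.reserve(S.size());

  auto walk = [&](const std::string &u0, char c0) {
    Unitig ut;
    ut.seq = u0;
    ut.cov = 0;
    std::string cur = u0;
    char ch = c0;
    int ne = 0;
    while (true) {
      std::string kmer = cur + ch;
      if (visited.count(kmer)) break;
      visited.insert(kmer);
      ut.kmers.push_back(kmer);
      ut.seq += ch;
      ut.cov += counts.at(kmer);
      ++ne;
      std::string v = kmer.substr(1);
      const NodeInfo &nv = nodes.at(v);
      if (nv.indeg == 1 && nv.out.size() == 1) {
        cur = v;
        ch = nv.out[0];
      } else break;
    }
    if (ne == 0) return;
    ut.cov /= ne;
    const std::string su = ut.seq.substr(0, k - 1);
    const std::string eu = ut.seq.substr(ut.seq.size() - (k - 1));
    ut.dead_start = nodes.at(su).indeg == 0;
    ut.dead_end = nodes.at(eu).out.empty();
    ut.start_outdeg = (int)nodes.at(su).out.size();
    ut.end_indeg = nodes.at(eu).indeg;
    out.push_back(std::move(ut));
  };

  for (const auto &nd : nodes) {
    const NodeInfo &ni = nd.second;
    if (ni.indeg == 1 && ni.out.size() == 1) continue; // interior node
    for (char c : ni.out)
      if (!visited.count(nd.first + c)) walk(nd.first, c);
  }
  // leftover pure cycles
  for (const auto &kmer : S) {
    if (visited.count(kmer)) continue;
    walk(kmer.substr(0, k - 1), kmer[k - 1]);
  }
}

// Relative cleanup at graph junctions: among the out-edges (and,
// symmetrically, in-edges) of a node, edges whose coverage is below
// alpha times the strongest competing edge are dropped.  At high depth
// sequencing errors recur above any absolute cutoff; this removes those
// branches while keeping genuine haplotype bubbles of comparable depth.
static bool junction_cleanup(std::unordered_set<std::string> &S,
                             const std::unordered_map<std::string, int> &counts,
                             int k, double alpha) {
  std::unordered_map<std::string, std::vector<const std::string *>> outs, ins;
  for (const auto &kmer : S) {
    outs[kmer.substr(0, k - 1)].push_back(&kmer);
    ins[kmer.substr(1)].push_back(&kmer);
  }
  std::vector<std::string> drop;
  auto scan = [&](const std::unordered_map<std::string,
                                           std::vector<const std::string *>> &m) {
    for (const auto &kv : m) {
      if (kv.second.size() < 2) continue;
      int mx = 0;
      for (const std::string *e : kv.second)
        mx = std::max(mx, counts.at(*e));
      for (const std::string *e : kv.second)
        if (counts.at(*e) < alpha * mx) drop.push_back(*e);
    }
  };
  scan(outs);
  scan(ins);
  for (const auto &e : drop) S.erase(e);
  return !drop.empty();
}

// [[Rcpp::export]]
List cpp_assemble(CharacterVector seqs, int k, int min_edge_cov,
                  int min_len, double junction_alpha = 0.05) {
  if (k < 2) stop("k must be >= 2");
  std::unordered_map<std::string, int> counts;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &t = (strand == 0) ? s : (s = revcomp_str(s));
      int n = (int)t.size();
      for (int j = 0; j + k <= n; ++j) {
        std::string kmer = t.substr(j, k);
        bool ok = true;
        for (char c : kmer)
          if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
        if (ok) ++counts[kmer];
      }
    }
  }
  std::unordered_set<std::string> S;
  S.reserve(counts.size());
  for (const auto &kv : counts)
    if (kv.second >= min_edge_cov) S.insert(kv.first);
  if (junction_alpha > 0)
    for (int iter = 0; iter < 5; ++iter)
      if (!junction_cleanup(S, counts, k, junction_alpha)) break;

  std::vector<Unitig> unitigs;
  for (int iter = 0; iter < 20; ++iter) {
    unitigs.clear();
    extract_unitigs(S, counts, k, unitigs);
    bool removed = false;
    for (const Unitig &ut : unitigs) {
      // removable short paths: isolated debris, or a dead-ended path
      // whose junction node offers a competing continuation
      bool tip = (int)ut.seq.size() < 2 * k &&
                 ((ut.dead_start && ut.dead_end) ||
                  (ut.dead_start && !ut.dead_end && ut.end_indeg >= 2) ||
                  (ut.dead_end && !ut.dead_start && ut.start_outdeg >= 2));
      if (tip) {
        for (const auto &km : ut.kmers) S.erase(km);
        removed = true;
      }
    }
    if (!removed) break;
  }

  std::vector<std::string> out_seqs;
  std::vector<double> out_cov;
  for (const Unitig &ut : unitigs) {
    if ((int)ut.seq.size() >= min_len) {
      out_seqs.push_back(ut.seq);
      out_cov.push_back(ut.cov);
    }
  }
  return List::create(_["sequence"] = wrap(out_seqs),
                      _["coverage"] = wrap(out_cov));
}
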