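// k-mer anchoring, sparse chaining and k-mer containment.
// Sequences arrive as plain upper-case character strings; DNA k-mers are
// 2-bit packed (k <= 31), protein k-mers 5-bit packed (k <= 12).  Any k-mer
// touching a symbol outside the alphabet is skipped.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int dna_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static inline int aa_code(char c) {
  if (c >= 'A' && c <= 'Z') return c - 'A';
  return -1;
}

// Collect packed k-mers with their start positions.  Returns false at
// positions where the window contains an invalid symbol.
static void scan_kmers(const std::string& s, int k, bool dna,
                       std::vector<uint64_t>& kmers,
                       std::vector<int>& pos) {
  const int bits = dna ? 2 : 5;
  const uint64_t mask = (k * bits >= 64) ? ~0ULL : ((1ULL << (k * bits)) - 1);
  uint64_t cur = 0;
  int run = 0;
  const int n = (int)s.size();
  for (int i = 0; i < n; ++i) {
    int c = dna ? dna_code(s[i]) : aa_code(s[i]);
    if (c < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << bits) | (uint64_t)c) & mask;
    if (++run >= k) {
      kmers.push_back(cur);
      pos.push_back(i - k + 1);
    }
  }
}

struct KmerIndex {
  int k;
  int max_occ;
  std::vector<std::string> names;
  std::vector<int> lens;
  // value packs (sequence index << 32) | position
  std::unordered_map<uint64_t, std::vector<uint64_t>> map;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int k, int max_occ = 64) {
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->max_occ = max_occ;
  CharacterVector nm = seqs.names();
  for (int si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    idx->names.push_back(nm.size() ? as<std::string>(nm[si]) : std::to_string(si));
    idx->lens.push_back((int)s.size());
    std::vector<uint64_t> kk; std::vector<int> pp;
    scan_kmers(s, k, true, kk, pp);
    for (size_t j = 0; j < kk.size(); ++j) {
      auto& v = idx->map[kk[j]];
      if ((int)v.size() <= max_occ)  // over-cap vectors flagged, never used
        v.push_back(((uint64_t)si << 32) | (uint64_t)pp[j]);
    }
  }
  XPtr<KmerIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
CharacterVector cpp_index_names(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return wrap(idx->names);
}

struct RawMatch { int q, t; };

// Query anchors against every indexed sequence; maximal same-diagonal runs
// of shared k-mers are merged into ungapped blocks.
// Returns a list (one element per target sequence) of lists
// (q_start, t_start, len), all 0-based.
// [[Rcpp::export]]
List cpp_query_index(SEXP xp, std::string query) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  std::vector<uint64_t> kk; std::vector<int> pp;
  scan_kmers(query, k, true, kk, pp);

  const int nseq = (int)idx->names.size();
  std::vector<std::vector<RawMatch>> hits(nseq);
  for (size_t j = 0; j < kk.size(); ++j) {
    auto it = idx->map.find(kk[j]);
    if (it == idx->map.end()) continue;
    const auto& v = it->second;
    if ((int)v.size() > idx->max_occ) continue;  // repetitive k-mer, skip
    for (uint64_t packed : v) {
      int si = (int)(packed >> 32);
      int tp = (int)(packed & 0xffffffffULL);
      hits[si].push_back({pp[j], tp});
    }
  }

  List out(nseq);
  for (int si = 0; si < nseq; ++si) {
    auto& h = hits[si];
    std::sort(h.begin(), h.end(), [](const RawMatch& a, const RawMatch& b) {
      long da = (long)a.t - a.q, db = (long)b.t - b.q;
      if (da != db) return da < db;
      return a.q < b.q;
    });
    std::vector<int> qs, ts, ls;
    size_t i = 0;
    while (i < h.size()) {
      long diag = (long)h[i].t - h[i].q;
      int q0 = h[i].q, qlast = h[i].q;
      size_t j = i + 1;
      // strictly contiguous runs only: a same-diagonal match further than
      // +1 away (e.g. a chance k-mer across a breakpoint, or matches
      // resuming after a skipped repetitive k-mer) starts its own anchor
      // and is handled by the chainer
      while (j < h.size() && ((long)h[j].t - h[j].q) == diag &&
             h[j].q == qlast + 1) { qlast = h[j].q; ++j; }
      qs.push_back(q0);
      ts.push_back((int)(q0 + diag));
      ls.push_back(qlast - q0 + k);
      i = j;
    }
    out[si] = List::create(_["q_start"] = wrap(qs), _["t_start"] = wrap(ts),
                           _["len"] = wrap(ls));
  }
  out.names() = wrap(idx->names);
  return out;
}

// Sparse-DP chain of maximal score over colinear anchors.  Anchors may
// overlap by up to max_overlap bp on either axis (chance extensions across
// breakpoints); the overlap is charged against the score and trimmed off
// the downstream block by the caller.
// Returns list(idx = 1-based indices of chained anchors in input order,
//              score = chain score).
// [[Rcpp::export]]
List cpp_chain(IntegerVector q_start, IntegerVector t_start, IntegerVector len,
               double gap_penalty, double max_gap, int max_overlap = 0) {
  const int n = q_start.size();
  if (n == 0) return List::create(_["idx"] = IntegerVector(0), _["score"] = 0.0);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (q_start[a] != q_start[b]) return q_start[a] < q_start[b];
    return t_start[a] < t_start[b];
  });
  std::vector<double> sc(n);
  std::vector<int> pre(n, -1);
  for (int jj = 0; jj < n; ++jj) {
    int j = ord[jj];
    sc[j] = (double)len[j];
    for (int ii = 0; ii < jj; ++ii) {
      int i = ord[ii];
      if (q_start[i] >= q_start[j] || t_start[i] >= t_start[j]) continue;
      long qe = (long)q_start[i] + len[i], te = (long)t_start[i] + len[i];
      long ov = std::max(qe - q_start[j], te - t_start[j]);
      if (ov > max_overlap || ov >= len[j]) continue;
      double dq = std::max(0L, (long)q_start[j] - qe);
      double dt = std::max(0L, (long)t_start[j] - te);
      if (dq > max_gap || dt > max_gap) continue;
      double cand = sc[i] + len[j] - std::max(0L, ov) -
        gap_penalty * (dq + dt);
      if (cand > sc[j]) { sc[j] = cand; pre[j] = i; }
    }
  }
  int best = 0;
  for (int i = 1; i < n; ++i)
    if (sc[i] > sc[best]) best = i;
  std::vector<int> chain;
  for (int c = best; c != -1; c = pre[c]) chain.push_back(c + 1);
  std::reverse(chain.begin(), chain.end());
  return List::create(_["idx"] = wrap(chain), _["score"] = sc[best]);
}

// Containment matrix: |kmers(a_i) n kmers(b_j)| / |kmers(a_i)| over k-mer SETS.
// [[Rcpp::export]]
NumericMatrix cpp_containment(CharacterVector a, CharacterVector b, int k,
                              bool dna) {
  const int na = a.size(), nb = b.size();
  std::vector<std::unordered_set<uint64_t>> sa(na), sb(nb);
  for (int i = 0; i < na; ++i) {
    std::vector<uint64_t> kk; std::vector<int> pp;
    scan_kmers(as<std::string>(a[i]), k, dna, kk, pp);
    sa[i].insert(kk.begin(), kk.end());
  }
  for (int j = 0; j < nb; ++j) {
    std::vector<uint64_t> kk; std::vector<int> pp;
    scan_kmers(as<std::string>(b[j]), k, dna, kk, pp);
    sb[j].insert(kk.begin(), kk.end());
  }
  NumericMatrix out(na, nb);
  for (int i = 0; i < na; ++i) {
    if (sa[i].empty()) continue;
    for (int j = 0; j < nb; ++j) {
      const auto& small = sa[i].size() < sb[j].size() ? sa[i] : sb[j];
      const auto& big   = sa[i].size() < sb[j].size() ? sb[j] : sa[i];
      size_t shared = 0;
      for (uint64_t x : small)
        if (big.count(x)) ++shared;
      out(i, j) = (double)shared / (double)sa[i].size();
    }
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default:  c = 'N'; break;
    }
  }
  return r;
}
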