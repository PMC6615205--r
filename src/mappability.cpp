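#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int bcode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

struct ProbeKey {
  uint64_t hi, lo;
  uint32_t idx;
};

// Position p is uniquely mappable iff the probe_len-mer starting at p occurs
// exactly once in the whole genome, counting both strands, and contains no N.
// Probes are canonicalized (min of forward and reverse-complement encoding),
// so a probe and its reverse complement share one multiset entry.
// [[Rcpp::export]]
List cpp_unique_positions(CharacterVector seqs, int probe_len) {
  if (probe_len < 20 || probe_len > 64)
    stop("probe_len must be between 20 and 64");
  int n_chrom = (int) seqs.size();
  std::vector<int64_t> offset(n_chrom + 1);
  int64_t total = 0;
  for (int c = 0; c < n_chrom; ++c) {
    offset[c] = total;
    total += LENGTH(STRING_ELT(seqs, c));
  }
  offset[n_chrom] = total;
  if (total > (int64_t) UINT32_MAX) stop("genome too large");

  std::vector<ProbeKey> keys;
  keys.reserve((size_t) total);
  for (int c = 0; c < n_chrom; ++c) {
    const char *s = CHAR(STRING_ELT(seqs, c));
    int64_t n = LENGTH(STRING_ELT(seqs, c));
    if (n < probe_len) continue;
    // N positions invalidate every probe overlapping them
    std::vector<int8_t> code(n);
    std::vector<int32_t> lastN(n);
    int32_t ln = -1;
    for (int64_t i = 0; i < n; ++i) {
      code[i] = (int8_t) bcode(s[i]);
      if (code[i] < 0) ln = (int32_t) i;
      lastN[i] = ln;
    }
    for (int64_t p = 0; p + probe_len <= n; ++p) {
      if (lastN[p + probe_len - 1] >= p) continue;
      uint64_t fh = 0, fl = 0, rh = 0, rl = 0;
      for (int j = 0; j < probe_len; ++j) {
        uint64_t b = (uint64_t) code[p + j];
        if (j < 32) fh = (fh << 2) | b; else fl = (fl << 2) | b;
        uint64_t rb = 3 - (uint64_t) code[p + probe_len - 1 - j];
        if (j < 32) rh = (rh << 2) | rb; else rl = (rl << 2) | rb;
      }
      uint64_t hi = fh, lo = fl;
      if (rh < fh || (rh == fh && rl < fl)) { hi = rh; lo = rl; }
      keys.push_back({hi, lo, (uint32_t) (offset[c] + p)});
    }
  }

  std::sort(keys.begin(), keys.end(), [](const ProbeKey &a, const ProbeKey &b) {
    if (a.hi != b.hi) return a.hi < b.hi;
    return a.lo < b.lo;
  });

  List out(n_chrom);
  std::vector<LogicalVector> vecs;
  for (int c = 0; c < n_chrom; ++c) {
    LogicalVector v((R_xlen_t) (offset[c + 1] - offset[c]), false);
    out[c] = v;
  }
  size_t i = 0;
  while (i < keys.size()) {
    size_t j = i + 1;
    while (j < keys.size() && keys[j].hi == keys[i].hi && keys[j].lo == keys[i].lo) ++j;
    if (j - i == 1) {
      int64_t g = keys[i].idx;
      int lo_c = 0, hi_c = n_chrom;
      while (hi_c - lo_c > 1) {
        int mid = (lo_c + hi_c) / 2;
        if (offset[mid] <= g) lo_c = mid; else hi_c = mid;
      }
      LogicalVector v = out[lo_c];
      v[(R_xlen_t) (g - offset[lo_c])] = true;
    }
    i = j;
  }
  return out;
}
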