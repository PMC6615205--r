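#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// ---- encoding -------------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

// ---- seed index -----------------------------------------------------------

// Exact-match k-mer index over the forward strand of every chromosome.
// Reverse-strand hits are found by looking up the reverse complement of the
// read k-mer, so the index itself stores forward k-mers only.
struct SeedIndex {
  int k;
  int n_chrom;
  std::vector<int8_t> codes;    // concatenated chromosome base codes
  std::vector<int64_t> offset;  // chrom start offsets, length n_chrom + 1
  std::vector<uint32_t> starts; // bucket starts, length 4^k + 1
  std::vector<uint32_t> pos;    // global positions grouped by k-mer code

  int chrom_of(int64_t g) const {
    int lo = 0, hi = n_chrom;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (offset[mid] <= g) lo = mid; else hi = mid;
    }
    return lo;
  }
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int k) {
  if (k < 8 || k > 13)
    stop("seed length k must be between 8 and 13");
  SeedIndex *idx = new SeedIndex();
  idx->k = k;
  idx->n_chrom = (int) seqs.size();
  idx->offset.resize(seqs.size() + 1);
  int64_t total = 0;
  for (R_xlen_t c = 0; c < seqs.size(); ++c) {
    idx->offset[c] = total;
    total += LENGTH(STRING_ELT(seqs, c));
  }
  idx->offset[seqs.size()] = total;
  if (total < k) { delete idx; stop("genome shorter than seed length k"); }
  if (total > (int64_t) UINT32_MAX) { delete idx; stop("genome too large for index"); }
  idx->codes.resize(total);
  for (R_xlen_t c = 0; c < seqs.size(); ++c) {
    const char *s = CHAR(STRING_ELT(seqs, c));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, c));
    for (R_xlen_t i = 0; i < n; ++i)
      idx->codes[idx->offset[c] + i] = (int8_t) base_code(s[i]);
  }

  const uint64_t nbuck = 1ULL << (2 * k);
  const uint64_t mask = nbuck - 1;
  idx->starts.assign(nbuck + 1, 0u);

  // pass 1: bucket counts (k-mers containing N are skipped)
  for (int c = 0; c < idx->n_chrom; ++c) {
    int64_t beg = idx->offset[c], end = idx->offset[c + 1];
    uint64_t code = 0; int run = 0;
    for (int64_t i = beg; i < end; ++i) {
      int b = idx->codes[i];
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t) b) & mask;
      if (++run >= k) idx->starts[code + 1]++;
    }
  }
  for (uint64_t b = 0; b < nbuck; ++b) idx->starts[b + 1] += idx->starts[b];
  idx->pos.resize(idx->starts[nbuck]);

  // pass 2: fill positions
  std::vector<uint32_t> fill(idx->starts.begin(), idx->starts.end() - 1);
  for (int c = 0; c < idx->n_chrom; ++c) {
    int64_t beg = idx->offset[c], end = idx->offset[c + 1];
    uint64_t code = 0; int run = 0;
    for (int64_t i = beg; i < end; ++i) {
      int b = idx->codes[i];
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t) b) & mask;
      if (++run >= k) idx->pos[fill[code]++] = (uint32_t) (i - k + 1);
    }
  }
  XPtr<SeedIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP ptr) {
  XPtr<SeedIndex> idx(ptr);
  return idx->k;
}

// Look up one k-mer (forward and reverse complement); inspection/testing
// helper, not on the mapping hot path.
// [[Rcpp::export]]
DataFrame cpp_index_lookup(SEXP ptr, std::string kmer) {
  XPtr<SeedIndex> idx(ptr);
  int k = idx->k;
  if ((int) kmer.size() != k) stop("query length must equal index k");
  uint64_t fwd = 0, rc = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(kmer[i]);
    if (b < 0) stop("query contains non-ACGT base");
    fwd = (fwd << 2) | (uint64_t) b;
    rc |= ((uint64_t) (3 - b)) << (2 * i);
  }
  std::vector<int> chrom; std::vector<double> p; std::vector<int> strand;
  for (int pass = 0; pass < 2; ++pass) {
    uint64_t code = pass == 0 ? fwd : rc;
    if (pass == 1 && rc == fwd) break; // palindromic k-mer: same bucket
    for (uint32_t i = idx->starts[code]; i < idx->starts[code + 1]; ++i) {
      int64_t g = idx->pos[i];
      int c = idx->chrom_of(g);
      chrom.push_back(c + 1);
      p.push_back((double) (g - idx->offset[c]));
      strand.push_back(pass == 0 ? 1 : -1);
    }
  }
  return DataFrame::create(_["chrom"] = chrom, _["pos"] = p, _["strand"] = strand);
}

// ---- banded affine x-drop extension with traceback ------------------------

struct ExtParams {
  int match, mismatch, gap_open, gap_ext, xdrop, band;
};

struct ExtResult {
  int score, qlen, tlen;
  // ops in extension direction: 'M' (diag), 'D' (consumes target only),
  // 'I' (consumes query only)
  std::vector<char> ops;
};

static const int NEG = -(1 << 28);

// Reusable scratch for extend_one: grow-only buffers.  Cells are written
// before they are read on every row that the DP visits, so stale contents
// from a previous extension are never observed.
struct ExtScratch {
  std::vector<uint8_t> tb;
  std::vector<int> Hprev, Fprev, Hcur, Fcur;
};

// Extend q[0..qmax) against t[0..tmax) starting at (0,0): the path is
// anchored at (0,0) and free at the far end; the reported endpoint is the
// best-scoring cell, so score >= 0 (empty extension allowed).
static ExtResult extend_one(const int8_t *q, int qmax, const int8_t *t, int tmax,
                            const ExtParams &pp, ExtScratch &sc) {
  ExtResult res; res.score = 0; res.qlen = 0; res.tlen = 0;
  if (qmax <= 0 || tmax <= 0) return res;
  const int W = pp.band;
  const int width = 2 * W + 1;
  const int GO = pp.gap_open + pp.gap_ext;

  // traceback flags, banded storage: column index = j - (i - W)
  // bits 0-1: H source (0 diag, 1 E, 2 F, 3 none/pruned)
  // bit 2: E extends E; bit 3: F extends F
  if (sc.tb.size() < (size_t) (qmax + 1) * width)
    sc.tb.resize((size_t) (qmax + 1) * width);
  if (sc.Hprev.size() < (size_t) tmax + 1) {
    sc.Hprev.resize(tmax + 1); sc.Fprev.resize(tmax + 1);
    sc.Hcur.resize(tmax + 1); sc.Fcur.resize(tmax + 1);
  }
  std::vector<uint8_t> &tb = sc.tb;
  std::vector<int> &Hprev = sc.Hprev, &Fprev = sc.Fprev;
  std::vector<int> &Hcur = sc.Hcur, &Fcur = sc.Fcur;

  int best = 0, bi = 0, bj = 0;
  int plo = 0, phi = std::min(tmax, W); // active j range of previous row

  // row 0: leading gap in target (ops 'D')
  for (int j = 0; j <= phi; ++j) {
    int h = (j == 0) ? 0 : -(pp.gap_open + j * pp.gap_ext);
    if (j > 0 && h < best - pp.xdrop) { phi = j - 1; break; }
    Hprev[j] = h;
    Fprev[j] = NEG;
    if (j > 0) {
      uint8_t f = 1;            // H from E
      if (j > 1) f |= 4;        // E extends E
      tb[(size_t) 0 * width + (j + W)] = f;
    } else {
      tb[(size_t) 0 * width + W] = 3; // origin
    }
  }

  for (int i = 1; i <= qmax; ++i) {
    int jlo = std::max(0, i - W), jhi = std::min(tmax, i + W);
    if (jlo > phi + 1) break;   // band has left the active region
    int qi = q[i - 1];
    int rowmax = NEG;
    int E = NEG;                // E along current row
    for (int j = jlo; j <= jhi; ++j) Hcur[j] = NEG, Fcur[j] = NEG;
    for (int j = jlo; j <= jhi; ++j) {
      size_t ti = (size_t) i * width + (j - (i - W));
      uint8_t flag = 3;
      // F: vertical (consumes query), from row i-1 same j
      int f = NEG;
      if (j >= plo && j <= phi) {
        int open = Hprev[j] > NEG / 2 ? Hprev[j] - GO : NEG;
        int ext  = Fprev[j] > NEG / 2 ? Fprev[j] - pp.gap_ext : NEG;
        f = std::max(open, ext);
        if (f == ext && ext > NEG / 2 && ext >= open) flag |= 8;
      }
      Fcur[j] = f;
      // E: horizontal (consumes target), from current row j-1
      int e = NEG;
      if (j - 1 >= jlo) {
        int open = Hcur[j - 1] > NEG / 2 ? Hcur[j - 1] - GO : NEG;
        int ext  = E > NEG / 2 ? E - pp.gap_ext : NEG;
        e = std::max(open, ext);
        if (e == ext && ext > NEG / 2 && ext >= open) flag |= 4;
      }
      E = e;
      // diagonal
      int d = NEG;
      if (j - 1 >= plo && j - 1 <= phi && j - 1 >= 0 && Hprev[j - 1] > NEG / 2) {
        int s = (qi >= 0 && t[j - 1] >= 0 && qi == t[j - 1]) ? pp.match : -pp.mismatch;
        d = Hprev[j - 1] + s;
      }
      int h = d; int src = 0;
      if (e > h) { h = e; src = 1; }
      if (f > h) { h = f; src = 2; }
      if (h <= NEG / 2 || h < best - pp.xdrop) {
        Hcur[j] = NEG;
        flag = (uint8_t) ((flag & 12) | 3);
      } else {
        Hcur[j] = h;
        flag = (uint8_t) ((flag & 12) | src);
        if (h > rowmax) rowmax = h;
        if (h > best) { best = h; bi = i; bj = j; }
      }
      tb[ti] = flag;
    }
    if (rowmax <= NEG / 2) break; // whole row pruned
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
    plo = jlo; phi = jhi;
  }

  // traceback from (bi, bj)
  res.score = best; res.qlen = bi; res.tlen = bj;
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  std::vector<char> rev;
  while (i > 0 || j > 0) {
    uint8_t flag = tb[(size_t) i * width + (j - (i - pp.band))];
    if (state == 0) {
      int src = flag & 3;
      if (src == 0) { rev.push_back('M'); --i; --j; }
      else if (src == 1) state = 1;
      else if (src == 2) state = 2;
      else break; // pruned cell: should not happen on the best path
    } else if (state == 1) {
      rev.push_back('D');
      state = (flag & 4) ? 1 : 0;
      --j;
    } else {
      rev.push_back('I');
      state = (flag & 8) ? 2 : 0;
      --i;
    }
  }
  res.ops.assign(rev.rbegin(), rev.rend());
  return res;
}

// ---- chains ---------------------------------------------------------------

struct Hit {
  int64_t diag;  // g - r in (possibly reverse-complemented) read coordinates
  int64_t g;     // global reference position of the k-mer
  int r;         // read position (rc coordinates for '-' strand)
  uint8_t strand; // 0 = '+', 1 = '-'
};

struct Chain {
  int rstart, rend;       // read interval covered by seeds (strand coords)
  int64_t gstart, gend;
  int weight;             // read bases covered by seeds
  uint8_t strand;
  int chrom;
  int a_r, a_len;         // anchor: longest exact run (read pos, length)
  int64_t a_g;
};

struct Candidate {
  int rstart, rend;       // final-read coordinates
  int chrom;
  int64_t gstart, gend;   // chromosome-local
  uint8_t strand;
  int score;
  int second;
  std::string cigar;
};

static void compress_cigar(const std::vector<char> &ops, std::string &out) {
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out += ops[i];
    i = j;
  }
}

// [[Rcpp::export]]
List cpp_map_reads(SEXP ptr, CharacterVector reads,
                   int match, int mismatch, int gap_open, int gap_ext,
                   int min_seed_len, int min_chain_weight, int min_report_score,
                   int chain_band, int max_seed_gap, int max_occ,
                   int xdrop, int ext_band, bool chains_only) {
  XPtr<SeedIndex> idx(ptr);
  const int k = idx->k;
  if (min_seed_len < k) min_seed_len = k;
  ExtParams pp; pp.match = match; pp.mismatch = mismatch;
  pp.gap_open = gap_open; pp.gap_ext = gap_ext; pp.xdrop = xdrop; pp.band = ext_band;
  const uint64_t mask = (1ULL << (2 * k)) - 1;

  std::vector<int> out_read, out_rs, out_re, out_chrom, out_score, out_second;
  std::vector<double> out_gs, out_ge;
  std::vector<std::string> out_strand, out_cigar;

  std::vector<int8_t> fc, rc; // forward / reverse-complement read codes
  std::vector<Hit> hits;
  std::vector<Chain> chains;
  std::vector<Candidate> cands;
  std::vector<int> cand_weight;  // chain weight behind each candidate
  std::vector<int8_t> buf; // reversed sequences for left extensions
  ExtScratch scratch;

  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    const char *s = CHAR(STRING_ELT(reads, ri));
    int n = LENGTH(STRING_ELT(reads, ri));
    if (n < k) continue;
    fc.resize(n); rc.resize(n);
    for (int i = 0; i < n; ++i) {
      fc[i] = (int8_t) base_code(s[i]);
      rc[n - 1 - i] = fc[i] < 0 ? (int8_t) -1 : (int8_t) (3 - fc[i]);
    }

    // collect seed hits on both strands; '-' hits are expressed in
    // reverse-complement read coordinates so all chains run forward
    hits.clear();
    uint64_t fcode = 0, rcode = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = fc[i];
      if (b < 0) { run = 0; fcode = 0; rcode = 0; continue; }
      fcode = ((fcode << 2) | (uint64_t) b) & mask;
      rcode = (rcode >> 2) | (((uint64_t) (3 - b)) << (2 * (k - 1)));
      if (++run < k) continue;
      int r = i - k + 1;
      uint32_t b0 = idx->starts[fcode], b1 = idx->starts[fcode + 1];
      if (b1 - b0 > 0 && b1 - b0 <= (uint32_t) max_occ)
        for (uint32_t h = b0; h < b1; ++h) {
          int64_t g = idx->pos[h];
          hits.push_back({g - r, g, r, 0});
        }
      if (rcode != fcode) {
        uint32_t c0 = idx->starts[rcode], c1 = idx->starts[rcode + 1];
        if (c1 - c0 > 0 && c1 - c0 <= (uint32_t) max_occ)
          for (uint32_t h = c0; h < c1; ++h) {
            int64_t g = idx->pos[h];
            int rr = n - r - k; // position in rc read
            hits.push_back({g - rr, g, rr, 1});
          }
      } else {
        // palindromic k-mer: same bucket serves both strands
        uint32_t c0 = idx->starts[rcode], c1 = idx->starts[rcode + 1];
        if (c1 - c0 > 0 && c1 - c0 <= (uint32_t) max_occ)
          for (uint32_t h = c0; h < c1; ++h) {
            int64_t g = idx->pos[h];
            int rr = n - r - k;
            hits.push_back({g - rr, g, rr, 1});
          }
      }
    }
    if (hits.empty()) continue;
    std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
      if (a.strand != b.strand) return a.strand < b.strand;
      if (a.diag != b.diag) return a.diag < b.diag;
      return a.r < b.r;
    });

    // cluster hits into diagonal bands, then order by read position and
    // build co-linear chains
    chains.clear();
    size_t ci = 0;
    while (ci < hits.size()) {
      size_t cj = ci + 1;
      while (cj < hits.size() && hits[cj].strand == hits[ci].strand &&
             hits[cj].diag - hits[cj - 1].diag <= chain_band)
        ++cj;
      // hits[ci..cj) share a diagonal band; sort by read position
      std::sort(hits.begin() + ci, hits.begin() + cj,
                [](const Hit &a, const Hit &b) {
                  if (a.r != b.r) return a.r < b.r;
                  return a.g < b.g;
                });
      int start = (int) ci;
      for (size_t h = ci; h < cj; ++h) {
        bool close = false;
        if (h + 1 >= cj) close = true;
        else if (hits[h + 1].r == hits[h].r) continue; // duplicate read pos
        else if (hits[h + 1].r - hits[h].r > max_seed_gap) close = true;
        if (!close) continue;
        // build chain over hits[start..h], skipping duplicate read positions
        Chain ch; ch.strand = hits[start].strand;
        ch.weight = 0; ch.a_len = 0;
        int prev_r = -(1 << 30); int64_t prev_g = -1; int64_t prev_diag = 0;
        int run_r = 0, run_len = 0; int64_t run_g = 0;
        bool first = true;
        for (size_t x = (size_t) start; x <= h; ++x) {
          if (hits[x].r == prev_r) continue;
          if (!first && hits[x].g <= prev_g) continue; // keep g monotone
          int novel = first ? k : std::min(k, hits[x].r - prev_r);
          ch.weight += novel;
          if (first) { ch.rstart = hits[x].r; ch.gstart = hits[x].g; }
          if (!first && hits[x].diag == prev_diag && hits[x].r == prev_r + 1) {
            run_len += 1;
          } else {
            run_r = hits[x].r; run_g = hits[x].g; run_len = k;
          }
          if (run_len > ch.a_len) { ch.a_len = run_len; ch.a_r = run_r; ch.a_g = run_g; }
          prev_r = hits[x].r; prev_g = hits[x].g; prev_diag = hits[x].diag;
          ch.rend = hits[x].r + k; ch.gend = hits[x].g + k;
          first = false;
        }
        if (!first && ch.weight >= min_chain_weight && ch.a_len >= min_seed_len) {
          ch.chrom = idx->chrom_of(ch.a_g);
          // chains must not span a chromosome boundary
          if (ch.gstart >= idx->offset[ch.chrom] && ch.gend <= idx->offset[ch.chrom + 1])
            chains.push_back(ch);
        }
        start = (int) h + 1;
      }
      ci = cj;
    }
    if (chains.empty()) continue;

    // chain filtering: heavier chain wins when overlapping >50% on the read,
    // but near-equal competitors are retained so uniqueness can be assessed
    std::sort(chains.begin(), chains.end(), [](const Chain &a, const Chain &b) {
      return a.weight > b.weight;
    });
    std::vector<Chain> kept;
    for (const Chain &ch : chains) {
      bool drop = false;
      for (const Chain &kc : kept) {
        // overlap in final read coordinates
        int a0 = ch.strand ? n - ch.rend : ch.rstart;
        int a1 = ch.strand ? n - ch.rstart : ch.rend;
        int b0 = kc.strand ? n - kc.rend : kc.rstart;
        int b1 = kc.strand ? n - kc.rstart : kc.rend;
        int ov = std::min(a1, b1) - std::max(a0, b0);
        int shorter = std::min(a1 - a0, b1 - b0);
        if (ov > shorter / 2 && ch.weight < (9 * kc.weight) / 10) { drop = true; break; }
      }
      if (!drop) kept.push_back(ch);
      if (kept.size() >= 400) break;
    }

    if (chains_only) {
      // report chains (final-read coordinates) without extension
      for (const Chain &ch : kept) {
        out_read.push_back((int) ri + 1);
        out_rs.push_back(ch.strand ? n - ch.rend : ch.rstart);
        out_re.push_back(ch.strand ? n - ch.rstart : ch.rend);
        out_chrom.push_back(ch.chrom + 1);
        out_gs.push_back((double) (ch.gstart - idx->offset[ch.chrom]));
        out_ge.push_back((double) (ch.gend - idx->offset[ch.chrom]));
        out_strand.push_back(ch.strand ? "-" : "+");
        out_score.push_back(ch.weight);
        out_second.push_back(0);
        out_cigar.push_back("");
      }
      continue;
    }

    // extend each kept chain from its anchor (heaviest first, so light
    // single-seed chains already covered by a reported fragment can skip
    // extension without losing near-tied competitors)
    cands.clear();
    cand_weight.clear();
    for (const Chain &ch : kept) {
      if (ch.weight < 2 * min_chain_weight) {
        int c0 = ch.strand ? n - ch.rend : ch.rstart;
        int c1 = ch.strand ? n - ch.rstart : ch.rend;
        bool covered = false;
        for (size_t ci2 = 0; ci2 < cands.size(); ++ci2) {
          int ov = std::min(c1, cands[ci2].rend) - std::max(c0, cands[ci2].rstart);
          if (2 * ov > (c1 - c0) && ch.weight < (9 * cand_weight[ci2]) / 10) {
            covered = true; break;
          }
        }
        if (covered) continue;
      }
      const int8_t *rd = ch.strand ? rc.data() : fc.data();
      int64_t cbeg = idx->offset[ch.chrom], cend = idx->offset[ch.chrom + 1];
      int a_r = ch.a_r, a_len = ch.a_len; int64_t a_g = ch.a_g;
      int score = match * a_len;

      // right extension
      int qmax = n - (a_r + a_len);
      int tmax = (int) std::min<int64_t>(cend - (a_g + a_len), (int64_t) qmax + pp.band);
      ExtResult right = extend_one(rd + a_r + a_len, qmax,
                                   idx->codes.data() + (a_g + a_len), tmax, pp,
                                   scratch);
      // left extension on reversed sequences
      qmax = a_r;
      tmax = (int) std::min<int64_t>(a_g - cbeg, (int64_t) qmax + pp.band);
      buf.clear(); buf.reserve(qmax + tmax);
      for (int x = a_r - 1; x >= 0; --x) buf.push_back(rd[x]);
      size_t toff = buf.size();
      for (int64_t x = a_g - 1; x >= a_g - tmax; --x) buf.push_back(idx->codes[x]);
      ExtResult left = extend_one(buf.data(), (int) toff,
                                  buf.data() + toff, tmax, pp, scratch);
      score += right.score + left.score;
      if (score < min_report_score) continue;

      Candidate cd;
      cd.strand = ch.strand; cd.chrom = ch.chrom;
      int rs = a_r - left.qlen, re = a_r + a_len + right.qlen; // strand coords
      int64_t gs = a_g - left.tlen, ge = a_g + a_len + right.tlen;
      cd.gstart = gs - cbeg; cd.gend = ge - cbeg;
      cd.rstart = ch.strand ? n - re : rs;
      cd.rend = ch.strand ? n - rs : re;
      cd.score = score; cd.second = 0;
      // cigar along the strand-oriented read (SAM convention for '-')
      std::vector<char> ops(left.ops.rbegin(), left.ops.rend());
      // left ops were produced on reversed strings; D/I meanings are
      // preserved, only the order flips
      for (int x = 0; x < a_len; ++x) ops.push_back('M');
      ops.insert(ops.end(), right.ops.begin(), right.ops.end());
      compress_cigar(ops, cd.cigar);
      cands.push_back(cd);
      cand_weight.push_back(ch.weight);
    }
    if (cands.empty()) continue;

    // resolve overlapping candidates on the read, greedily by score;
    // ties broken by (chrom, ref_start, strand) for determinism
    std::sort(cands.begin(), cands.end(), [](const Candidate &a, const Candidate &b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.chrom != b.chrom) return a.chrom < b.chrom;
      if (a.gstart != b.gstart) return a.gstart < b.gstart;
      return a.strand < b.strand;
    });
    std::vector<Candidate> final_;
    for (const Candidate &cd : cands) {
      bool drop = false;
      for (Candidate &kc : final_) {
        int ov = std::min(cd.rend, kc.rend) - std::max(cd.rstart, kc.rstart);
        if (ov <= 0) continue;
        int shorter = std::min(cd.rend - cd.rstart, kc.rend - kc.rstart);
        if (ov * 5 > shorter) { // > 20% of the shorter fragment
          drop = true;
          if (ov * 2 >= shorter && cd.score > kc.second)
            kc.second = cd.score; // competing placement for uniqueness
          break;
        }
      }
      if (!drop) final_.push_back(cd);
    }
    std::sort(final_.begin(), final_.end(), [](const Candidate &a, const Candidate &b) {
      return a.rstart < b.rstart;
    });
    for (const Candidate &cd : final_) {
      out_read.push_back((int) ri + 1);
      out_rs.push_back(cd.rstart); out_re.push_back(cd.rend);
      out_chrom.push_back(cd.chrom + 1);
      out_gs.push_back((double) cd.gstart); out_ge.push_back((double) cd.gend);
      out_strand.push_back(cd.strand ? "-" : "+");
      out_score.push_back(cd.score);
      out_second.push_back(cd.second);
      out_cigar.push_back(cd.cigar);
    }
  }

  return List::create(
    _["read"] = out_read, _["read_start"] = out_rs, _["read_end"] = out_re,
    _["chrom"] = out_chrom, _["ref_start"] = out_gs, _["ref_end"] = out_ge,
    _["strand"] = out_strand, _["score"] = out_score,
    _["second_best"] = out_second, _["cigar"] = out_cigar);
}
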