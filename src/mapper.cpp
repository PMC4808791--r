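// Exact mismatch-bounded read placement against a k-mer indexed genome.
//
// Completeness contract: for a read of length L and mismatch budget N, every
// ungapped placement (either strand) with Hamming distance <= N is reported.
// Guarantee comes from a generalized pigeonhole: split the read into
// s = floor(L/k) disjoint k-mer segments; a placement with <= N mismatches
// has at least one segment with <= d = floor(N/s) mismatches (if every
// segment had >= d+1, the total would be >= s*(d+1) > N).  Each segment is
// therefore searched with all k-mers within Hamming distance d of it,
// enumerated over a direct-addressed 4^k table.  When d would exceed 3 (very
// short reads or very large N) the engine falls back to a full scan of every
// genome window, which is trivially complete.
//
// N handling: 'N' (or any non-ACGT letter) never matches anything, on either
// side.  For seeding, N is encoded as 'A', which can only shrink a segment's
// seed distance (an N position is always a true mismatch but at most a
// mismatch under the substitute letter), so pigeonhole completeness is
// preserved; verification uses the true never-matches semantics.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct PraIndex {
  std::vector<uint8_t> code;   // genome, 2-bit codes; N stored as 0
  std::vector<uint8_t> isN;    // 1 where the genome letter is not ACGT
  int k;
  std::vector<uint32_t> offs;  // 4^k + 1 bucket offsets
  std::vector<uint32_t> pos;   // k-mer start positions grouped by key
  // packed mirrors for fast Hamming verification: 2 bits per base,
  // LSB-first within each 64-bit word; npack has 01 at N positions
  std::vector<uint64_t> gpack;
  std::vector<uint64_t> gnpack;
};

static const uint64_t LOW_BITS = 0x5555555555555555ULL;

static void pack_codes(const std::vector<uint8_t>& code,
                       const std::vector<uint8_t>& isN,
                       std::vector<uint64_t>& pk, std::vector<uint64_t>& npk) {
  const size_t n = code.size();
  const size_t nw = n / 32 + 2;  // slack word so unaligned reads never overrun
  pk.assign(nw, 0);
  npk.assign(nw, 0);
  for (size_t i = 0; i < n; ++i) {
    pk[i >> 5] |= (uint64_t)code[i] << (2 * (i & 31));
    if (isN[i]) npk[i >> 5] |= 1ULL << (2 * (i & 31));
  }
}

struct PackedRead {
  int L;
  std::vector<uint64_t> words;   // packed bases
  std::vector<uint64_t> nwords;  // 01 at N positions
  std::vector<uint64_t> tmask;   // valid-base mask per word
};

static void pack_read(const std::vector<uint8_t>& r,
                      const std::vector<uint8_t>& rN, PackedRead& pr) {
  const int L = (int)r.size();
  const int nw = (L + 31) / 32;
  pr.L = L;
  pr.words.assign(nw, 0);
  pr.nwords.assign(nw, 0);
  pr.tmask.assign(nw, 0);
  for (int i = 0; i < L; ++i) {
    pr.words[i >> 5] |= (uint64_t)r[i] << (2 * (i & 31));
    if (rN[i]) pr.nwords[i >> 5] |= 1ULL << (2 * (i & 31));
    pr.tmask[i >> 5] |= 3ULL << (2 * (i & 31));
  }
}

// mismatch count of a packed read placed at genome position p (early exit
// above cap -> returns cap + 1); an N on either side always mismatches
static inline int packed_mism(const PraIndex& ix, const PackedRead& pr,
                              int64_t p, int cap) {
  const uint64_t off = (uint64_t)p * 2;
  const size_t wi = off >> 6;
  const int sh = (int)(off & 63);
  int m = 0;
  const int nw = (int)pr.words.size();
  for (int j = 0; j < nw; ++j) {
    uint64_t g = ix.gpack[wi + j] >> sh;
    uint64_t gn = ix.gnpack[wi + j] >> sh;
    if (sh) {
      g |= ix.gpack[wi + j + 1] << (64 - sh);
      gn |= ix.gnpack[wi + j + 1] << (64 - sh);
    }
    const uint64_t x = g ^ pr.words[j];
    uint64_t bad = ((x | (x >> 1)) & LOW_BITS) | gn | pr.nwords[j];
    bad &= pr.tmask[j] & LOW_BITS;
    m += __builtin_popcountll(bad);
    if (m > cap) return cap + 1;
  }
  return m;
}

static void encode_seq(const std::string& s, std::vector<uint8_t>& code,
                       std::vector<uint8_t>& isN) {
  const size_t n = s.size();
  code.resize(n);
  isN.resize(n);
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { code[i] = 0; isN[i] = 1; } else { code[i] = (uint8_t)c; isN[i] = 0; }
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(std::string genome, int k) {
  if (k < 8) stop("seed length k must be >= 8");
  if (k > 12) stop("seed length k must be <= 12");
  PraIndex* ix = new PraIndex();
  ix->k = k;
  encode_seq(genome, ix->code, ix->isN);
  const int64_t n = (int64_t)ix->code.size();
  const int64_t nk = n - k + 1;
  const uint32_t nkeys = 1u << (2 * k);
  const uint32_t mask = nkeys - 1u;
  ix->offs.assign((size_t)nkeys + 1, 0u);
  if (nk > 0) {
    uint32_t key = 0;
    for (int64_t i = 0; i < n; ++i) {
      key = ((key << 2) | ix->code[i]) & mask;
      if (i >= k - 1) ix->offs[key + 1]++;
    }
    for (uint32_t j = 0; j < nkeys; ++j) ix->offs[j + 1] += ix->offs[j];
    ix->pos.resize((size_t)nk);
    std::vector<uint32_t> cur(ix->offs.begin(), ix->offs.end() - 1);
    key = 0;
    for (int64_t i = 0; i < n; ++i) {
      key = ((key << 2) | ix->code[i]) & mask;
      if (i >= k - 1) ix->pos[cur[key]++] = (uint32_t)(i - k + 1);
    }
  }
  pack_codes(ix->code, ix->isN, ix->gpack, ix->gnpack);
  XPtr<PraIndex> xp(ix, true);
  return xp;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xpsexp) { return XPtr<PraIndex>(xpsexp)->k; }

// [[Rcpp::export]]
double cpp_index_genome_length(SEXP xpsexp) {
  return (double)XPtr<PraIndex>(xpsexp)->code.size();
}

// enumerate all keys at Hamming distance <= d_left from `key`, substituting
// at segment positions >= startpos; collect candidate placement starts
static void enum_rec(const PraIndex& ix, uint32_t key, int startpos, int d_left,
                     int64_t seg_off, int64_t start_max,
                     std::vector<int64_t>& cand) {
  const uint32_t b = ix.offs[key], e = ix.offs[key + 1];
  for (uint32_t t = b; t < e; ++t) {
    int64_t start = (int64_t)ix.pos[t] - seg_off;
    if (start >= 0 && start <= start_max) cand.push_back(start);
  }
  if (d_left == 0) return;
  const int k = ix.k;
  for (int p = startpos; p < k; ++p) {
    const int shift = 2 * (k - 1 - p);
    const uint32_t orig = (key >> shift) & 3u;
    const uint32_t cleared = key & ~(3u << shift);
    for (uint32_t bb = 0; bb < 4; ++bb) {
      if (bb == orig) continue;
      enum_rec(ix, cleared | (bb << shift), p + 1, d_left - 1, seg_off,
               start_max, cand);
    }
  }
}

struct Placement { int64_t pos; int strand; int mism; };  // strand 0:'+', 1:'-'

// all placements of one oriented read with <= N mismatches
static void place_oriented(const PraIndex& ix, const std::vector<uint8_t>& r,
                           const std::vector<uint8_t>& rN, int N, int strand,
                           std::vector<Placement>& out) {
  const int L = (int)r.size();
  const int64_t glen = (int64_t)ix.code.size();
  if (L > glen) return;
  const int64_t start_max = glen - L;
  const int k = ix.k;
  const int s = L / k;
  const int d = (s > 0) ? N / s : 4;
  PackedRead pr;
  pack_read(r, rN, pr);
  if (d <= 3 && s > 0) {
    std::vector<int64_t> cand;
    cand.reserve(256);
    for (int seg = 0; seg < s; ++seg) {
      const int off = seg * k;
      uint32_t key = 0;
      for (int i = 0; i < k; ++i) key = (key << 2) | r[off + i];
      enum_rec(ix, key, 0, d, off, start_max, cand);
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    for (int64_t p : cand) {
      int m = packed_mism(ix, pr, p, N);
      if (m <= N) out.push_back({p, strand, m});
    }
  } else {
    for (int64_t p = 0; p <= start_max; ++p) {
      int m = packed_mism(ix, pr, p, N);
      if (m <= N) out.push_back({p, strand, m});
    }
  }
}

static void revcomp(const std::vector<uint8_t>& r, const std::vector<uint8_t>& rN,
                    std::vector<uint8_t>& rc, std::vector<uint8_t>& rcN) {
  const size_t L = r.size();
  rc.resize(L);
  rcN.resize(L);
  for (size_t i = 0; i < L; ++i) {
    rc[L - 1 - i] = (uint8_t)(3 - r[i]);
    rcN[L - 1 - i] = rN[i];
  }
}

// all placements of a read (both orientations); a locus found by both
// orientations is reported once with the smaller mismatch count
static std::vector<Placement> place_read(const PraIndex& ix,
                                         const std::string& read, int N) {
  std::vector<uint8_t> r, rN, rc, rcN;
  encode_seq(read, r, rN);
  revcomp(r, rN, rc, rcN);
  const int L = (int)r.size();
  if (N > L) N = L;
  std::vector<Placement> out;
  place_oriented(ix, r, rN, N, 0, out);
  place_oriented(ix, rc, rcN, N, 1, out);
  std::sort(out.begin(), out.end(), [](const Placement& a, const Placement& b) {
    if (a.pos != b.pos) return a.pos < b.pos;
    if (a.mism != b.mism) return a.mism < b.mism;
    return a.strand < b.strand;
  });
  std::vector<Placement> dedup;
  dedup.reserve(out.size());
  for (const Placement& pl : out) {
    if (!dedup.empty() && dedup.back().pos == pl.pos) continue;
    dedup.push_back(pl);
  }
  return dedup;
}

// [[Rcpp::export]]
List cpp_map_reads(SEXP xpsexp, CharacterVector reads, int N) {
  XPtr<PraIndex> xp(xpsexp);
  const PraIndex& ix = *xp;
  if (N < 0) stop("mismatch budget N must be >= 0");
  const R_xlen_t n = reads.size();
  List placements(n);
  LogicalVector too_short(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if ((i & 255) == 0) Rcpp::checkUserInterrupt();
    std::string read = as<std::string>(reads[i]);
    if ((int)read.size() < ix.k) {
      too_short[i] = true;
      placements[i] = IntegerMatrix(0, 3);
      continue;
    }
    std::vector<Placement> pl = place_read(ix, read, N);
    IntegerMatrix m((int)pl.size(), 3);
    for (int j = 0; j < (int)pl.size(); ++j) {
      m(j, 0) = (int)pl[j].pos;
      m(j, 1) = pl[j].strand;
      m(j, 2) = pl[j].mism;
    }
    placements[i] = m;
  }
  return List::create(_["placements"] = placements,
                      _["too_short"] = too_short);
}

// per-read placement-count matrix over thresholds N = 0..Nmax (columns);
// entry [i, N+1] = number of placements of read i with mismatches <= N,
// capped at `cap` (2 is enough to classify unmapped/unique/multi)
// [[Rcpp::export]]
IntegerMatrix cpp_placement_counts(SEXP xpsexp, CharacterVector reads,
                                   int Nmax, int cap) {
  XPtr<PraIndex> xp(xpsexp);
  const PraIndex& ix = *xp;
  const R_xlen_t n = reads.size();
  IntegerMatrix counts(n, Nmax + 1);
  for (R_xlen_t i = 0; i < n; ++i) {
    if ((i & 127) == 0) Rcpp::checkUserInterrupt();
    std::string read = as<std::string>(reads[i]);
    if ((int)read.size() < ix.k) continue;
    std::vector<Placement> pl = place_read(ix, read, Nmax);
    for (const Placement& p : pl) {
      for (int N = p.mism; N <= Nmax; ++N) {
        if (counts(i, N) < cap) counts(i, N)++; else break;
      }
    }
  }
  return counts;
}

// exact occurrences of a k-mer: forward matches ('+') and positions whose
// forward text equals the reverse complement of the query ('-'); a position
// hit by both strands is reported once as '+'
// [[Rcpp::export]]
List cpp_lookup_kmer(SEXP xpsexp, std::string kmer) {
  XPtr<PraIndex> xp(xpsexp);
  const PraIndex& ix = *xp;
  if ((int)kmer.size() != ix.k) stop("query length must equal index k");
  std::vector<uint8_t> q, qN;
  encode_seq(kmer, q, qN);
  std::vector<int> pos_out, strand_out;
  for (size_t i = 0; i < qN.size(); ++i) {
    if (qN[i]) {  // N never matches: no exact occurrence possible
      return List::create(_["pos"] = IntegerVector(0),
                          _["strand"] = IntegerVector(0));
    }
  }
  uint32_t key = 0, rckey = 0;
  for (int i = 0; i < ix.k; ++i) {
    key = (key << 2) | q[i];
    rckey = (rckey << 2) | (uint8_t)(3 - q[ix.k - 1 - i]);
  }
  // verify: bucket entries may start at genome N positions (encoded as A)
  auto verify = [&](uint32_t p, bool rc) {
    for (int i = 0; i < ix.k; ++i) {
      if (ix.isN[p + i]) return false;
      uint8_t want = rc ? (uint8_t)(3 - q[ix.k - 1 - i]) : q[i];
      if (ix.code[p + i] != want) return false;
    }
    return true;
  };
  for (uint32_t t = ix.offs[key]; t < ix.offs[key + 1]; ++t)
    if (verify(ix.pos[t], false)) { pos_out.push_back((int)ix.pos[t]); strand_out.push_back(0); }
  if (rckey != key) {
    for (uint32_t t = ix.offs[rckey]; t < ix.offs[rckey + 1]; ++t)
      if (verify(ix.pos[t], true)) { pos_out.push_back((int)ix.pos[t]); strand_out.push_back(1); }
  }
  return List::create(_["pos"] = wrap(pos_out), _["strand"] = wrap(strand_out));
}
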