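// Low-level kernels: 2-bit k-mer packing and Murmur-finalizer hashing,
// k-mer / min-hash candidate indexes, seeded semi-global alignment scanning
// for short accurate reads, and seed-chain + banded forward scoring for long
// noisy reads.  All coordinates are 0-based half-open on the forward strand
// of the target; read ids returned are 1-based positions in the input vector.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <deque>
#include <cmath>

using namespace Rcpp;

static const uint64_t MASK53 = (1ULL << 53) - 1;
static const uint16_t INF16 = 60000;

static inline int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char compBase(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  case 'N': case 'n': return 'N';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = compBase(r[i]);
  return r;
}

// Murmur3 64-bit finalizer.
static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

// Expand a small integer seed into a 64-bit per-function xor mask.
static inline uint64_t seed64(int s) {
  return fmix64((uint64_t)(uint32_t)s + 0x9E3779B97F4A7C15ULL);
}

static inline uint64_t hashKmer(uint64_t packed, uint64_t seed) {
  return fmix64(packed ^ seed) & MASK53;
}

static inline uint64_t rcPacked(uint64_t v, int k) {
  uint64_t r = 0;
  for (int b = 0; b < k; ++b) {
    r = (r << 2) | (3ULL - (v & 3ULL));
    v >>= 2;
  }
  return r;
}

// Emit all valid (no non-ACGT base) k-mers of seq as (pos, packed) pairs.
template <typename F>
static void forEachKmer(const std::string& seq, int k, F fun) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t val = 0;
  int run = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int c = baseCode(seq[i]);
    if (c < 0) { run = 0; val = 0; continue; }
    val = ((val << 2) | (uint64_t)c) & mask;
    if (++run >= k) fun((int)(i + 1 - k), val);
  }
}

static std::string decodeKmer(uint64_t v, int k) {
  static const char* B = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = B[v & 3]; v >>= 2; }
  return s;
}

// ---------------------------------------------------------------------------
// k-mer counting (de Bruijn construction support)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cppCountKmers(CharacterVector seqs, int k, bool canonical = true) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  std::unordered_map<uint64_t, int> counts;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    forEachKmer(s, k, [&](int, uint64_t v) {
      uint64_t key = canonical ? std::min(v, rcPacked(v, k)) : v;
      counts[key]++;
    });
  }
  std::vector<std::pair<uint64_t, int>> items(counts.begin(), counts.end());
  std::sort(items.begin(), items.end());
  CharacterVector kmers(items.size());
  IntegerVector cnt(items.size());
  for (size_t i = 0; i < items.size(); ++i) {
    kmers[i] = decodeKmer(items[i].first, k);
    cnt[i] = items[i].second;
  }
  return List::create(_["kmer"] = kmers, _["count"] = cnt);
}

// ---------------------------------------------------------------------------
// Min-hash values
// ---------------------------------------------------------------------------

// Min-hash of an explicit k-mer set, one value per seed.
// [[Rcpp::export]]
NumericVector cppMinHashKmers(CharacterVector kmers, IntegerVector seeds) {
  if (kmers.size() == 0) stop("empty k-mer set");
  int k = LENGTH(STRING_ELT(kmers, 0));
  if (k > 26) stop("k-mers longer than 26 not supported");
  std::vector<uint64_t> packed;
  packed.reserve(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != k) stop("k-mers must have equal length");
    uint64_t v = 0;
    for (char c : s) {
      int b = baseCode(c);
      if (b < 0) stop("k-mer contains a non-ACGT base");
      v = (v << 2) | (uint64_t)b;
    }
    packed.push_back(v);
  }
  NumericVector out(seeds.size());
  for (R_xlen_t f = 0; f < seeds.size(); ++f) {
    uint64_t sd = seed64(seeds[f]);
    uint64_t mn = ~0ULL;
    for (uint64_t v : packed) mn = std::min(mn, hashKmer(v, sd));
    out[f] = (double)mn;
  }
  return out;
}

// Min-hash over the (optionally canonical) k-mer set of a sequence.
// [[Rcpp::export]]
NumericVector cppMinHashSeq(std::string seq, int k, IntegerVector seeds,
                            bool canonical = true) {
  if (k < 2 || k > 26) stop("k must be in [2, 26]");
  std::vector<uint64_t> packed;
  forEachKmer(seq, k, [&](int, uint64_t v) {
    packed.push_back(canonical ? std::min(v, rcPacked(v, k)) : v);
  });
  if (packed.empty()) stop("sequence contains no valid k-mer");
  NumericVector out(seeds.size());
  for (R_xlen_t f = 0; f < seeds.size(); ++f) {
    uint64_t sd = seed64(seeds[f]);
    uint64_t mn = ~0ULL;
    for (uint64_t v : packed) mn = std::min(mn, hashKmer(v, sd));
    out[f] = (double)mn;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Candidate indexes
// ---------------------------------------------------------------------------

struct SeqIndex {
  int k;
  int type;                 // 0 = k-mer, 1 = min-hash
  std::vector<uint64_t> seeds;
  // k-mer mode: canonical k-mer -> sorted unique read ids
  std::unordered_map<uint64_t, std::vector<int>> kmap;
  // min-hash mode: one map per hash function, min-hash value -> read ids
  std::vector<std::unordered_map<uint64_t, std::vector<int>>> hmaps;
};

// [[Rcpp::export]]
SEXP cppBuildKmerIndex(CharacterVector reads, int k) {
  if (k < 2 || k > 26) stop("k must be in [2, 26]");
  XPtr<SeqIndex> ptr(new SeqIndex(), true);
  ptr->k = k;
  ptr->type = 0;
  std::vector<uint64_t> buf;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    buf.clear();
    forEachKmer(s, k, [&](int, uint64_t v) {
      buf.push_back(std::min(v, rcPacked(v, k)));
    });
    std::sort(buf.begin(), buf.end());
    buf.erase(std::unique(buf.begin(), buf.end()), buf.end());
    for (uint64_t v : buf) ptr->kmap[v].push_back((int)i + 1);
  }
  return ptr;
}

// [[Rcpp::export]]
SEXP cppBuildMinHashIndex(CharacterVector reads, int k, IntegerVector seeds) {
  if (k < 2 || k > 26) stop("k must be in [2, 26]");
  XPtr<SeqIndex> ptr(new SeqIndex(), true);
  ptr->k = k;
  ptr->type = 1;
  for (R_xlen_t f = 0; f < seeds.size(); ++f) ptr->seeds.push_back(seed64(seeds[f]));
  ptr->hmaps.resize(seeds.size());
  std::vector<uint64_t> buf;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    buf.clear();
    forEachKmer(s, k, [&](int, uint64_t v) {
      buf.push_back(std::min(v, rcPacked(v, k)));
    });
    if (buf.empty()) continue;
    for (size_t f = 0; f < ptr->seeds.size(); ++f) {
      uint64_t mn = ~0ULL;
      for (uint64_t v : buf) mn = std::min(mn, hashKmer(v, ptr->seeds[f]));
      ptr->hmaps[f][mn].push_back((int)i + 1);
    }
  }
  return ptr;
}

// [[Rcpp::export]]
int cppIndexType(SEXP idx) {
  XPtr<SeqIndex> ptr(idx);
  return ptr->type;
}

// Candidate read ids for a target sequence.  k-mer mode: reads sharing any
// canonical k-mer with the target.  min-hash mode: reads whose min-hash (any
// function) equals the min-hash of some length-lr substring of the target.
// [[Rcpp::export]]
IntegerVector cppQueryIndex(SEXP idx, std::string target, int lr = 0) {
  XPtr<SeqIndex> ptr(idx);
  std::vector<int> out;
  if (ptr->type == 0) {
    std::vector<uint64_t> buf;
    forEachKmer(target, ptr->k, [&](int, uint64_t v) {
      buf.push_back(std::min(v, rcPacked(v, ptr->k)));
    });
    std::sort(buf.begin(), buf.end());
    buf.erase(std::unique(buf.begin(), buf.end()), buf.end());
    for (uint64_t v : buf) {
      auto it = ptr->kmap.find(v);
      if (it != ptr->kmap.end())
        out.insert(out.end(), it->second.begin(), it->second.end());
    }
  } else {
    if (lr <= 0) stop("min-hash query needs the read length lr");
    // positional canonical k-mer hashes; -1 runs (invalid) break windows
    std::vector<int> pos;
    std::vector<uint64_t> can;
    forEachKmer(target, ptr->k, [&](int p, uint64_t v) {
      pos.push_back(p);
      can.push_back(std::min(v, rcPacked(v, ptr->k)));
    });
    if (can.empty()) return IntegerVector(0);
    int w = std::max(1, lr - ptr->k + 1); // k-mers per length-lr window
    for (size_t f = 0; f < ptr->seeds.size(); ++f) {
      std::vector<uint64_t> h(can.size());
      for (size_t i = 0; i < can.size(); ++i) h[i] = hashKmer(can[i], ptr->seeds[f]);
      // sliding min over windows of w consecutive k-mer positions
      std::deque<size_t> dq;
      std::vector<uint64_t> mins;
      for (size_t i = 0; i < h.size(); ++i) {
        while (!dq.empty() && h[dq.back()] >= h[i]) dq.pop_back();
        dq.push_back(i);
        if ((int)i >= w && dq.front() <= i - w) dq.pop_front();
        if ((int)i >= w - 1 || i == h.size() - 1) mins.push_back(h[dq.front()]);
      }
      std::sort(mins.begin(), mins.end());
      mins.erase(std::unique(mins.begin(), mins.end()), mins.end());
      for (uint64_t v : mins) {
        auto it = ptr->hmaps[f].find(v);
        if (it != ptr->hmaps[f].end())
          out.insert(out.end(), it->second.begin(), it->second.end());
      }
    }
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return wrap(out);
}

// ---------------------------------------------------------------------------
// Short-read semi-global scanning
// ---------------------------------------------------------------------------

struct Hit {
  int idx, start, end, strand, s, m;
};

// Align one oriented read against the target within a diagonal corridor
// [dLo, dHi] (cells (i, j) with i + dLo <= j <= i + dHi; semi-global: read
// global, target local).  Any alignment with <= kmax edits whose seeds lie
// on diagonals in [dLo + kmax + 2, dHi - kmax - 2] is fully contained, so
// qualifying end positions and their edit distances match an unbanded scan.
// Emits canonical hits: end positions with edit distance <= kmax, grouped
// into maximal consecutive runs, keeping positions achieving the run
// minimum.  Traceback tie-break: diagonal, then horizontal (target base
// consumed), then vertical.
static void alignBand(const std::string& target, const std::vector<int8_t>& tcode,
                      const std::string& read, int dLo, int dHi, int kmax,
                      int idx, int strand, std::vector<Hit>& hits) {
  const int len = (int)read.size();
  const int n = (int)target.size();
  if (len == 0 || n == 0) return;
  if (dLo > n || dHi < -len) return;
  const int W = dHi - dLo + 1;
  if (W <= 0) return;
  std::vector<int8_t> rcd(len);
  for (int i = 0; i < len; ++i) {
    int c = baseCode(read[i]);
    rcd[i] = (int8_t)(c < 0 ? -2 : c); // -2 never equals a target code
  }
  // banded layout: cell (i, j) at row i, column j - i - dLo
  std::vector<uint16_t> D((size_t)(len + 1) * W, INF16);
  {
    uint16_t* r0 = &D[0];
    const int jlo = std::max(0, dLo), jhi = std::min(n, dHi);
    for (int j = jlo; j <= jhi; ++j) r0[j - dLo] = 0;
  }
  for (int i = 1; i <= len; ++i) {
    const int8_t rb = rcd[i - 1];
    const uint16_t* prev = &D[(size_t)(i - 1) * W];
    uint16_t* cur = &D[(size_t)i * W];
    const int jlo = std::max(0, i + dLo), jhi = std::min(n, i + dHi);
    const int cLo = jlo - i - dLo, cHi = jhi - i - dLo;
    uint16_t left = INF16;
    for (int c = cLo; c <= cHi; ++c) {
      const int j = c + i + dLo;
      // diagonal (i-1, j-1) has the same column index; j == 0 has no
      // diagonal predecessor but prev[c] is INF there anyway only when out
      // of band -- guard explicitly
      uint16_t v = (j >= 1)
        ? (uint16_t)(prev[c] + (rb == tcode[j - 1] ? 0 : 1))
        : INF16;
      const uint16_t v2 = (uint16_t)((c + 1 < W ? prev[c + 1] : INF16) + 1);
      const uint16_t v3 = (uint16_t)(left + 1); // horizontal (i, j-1)
      if (v2 < v) v = v2;
      if (v3 < v) v = v3;
      if (v > INF16) v = INF16;
      left = v;
      cur[c] = v;
    }
  }
  const uint16_t* last = &D[(size_t)len * W];
  const int jlo = std::max(0, len + dLo), jhi = std::min(n, len + dHi);
  int j = jlo;
  while (j <= jhi) {
    if (last[j - len - dLo] > kmax) { ++j; continue; }
    int j0 = j;
    int best = last[j - len - dLo];
    while (j + 1 <= jhi && last[j + 1 - len - dLo] <= kmax) {
      ++j;
      if (last[j - len - dLo] < best) best = last[j - len - dLo];
    }
    int j1 = j;
    ++j;
    for (int je = j0; je <= j1; ++je) {
      if (last[je - len - dLo] != best) continue;
      // traceback
      int i = len, jj = je, m = 0;
      while (i > 0) {
        const int c = jj - i - dLo;
        const uint16_t* cur = &D[(size_t)i * W];
        const uint16_t* prev = &D[(size_t)(i - 1) * W];
        const uint16_t here = cur[c];
        if (jj > 0 && c >= 0 && c < W) {
          int sub = (rcd[i - 1] == tcode[jj - 1]) ? 0 : 1;
          if (here == prev[c] + sub) { // diagonal
            if (sub == 0) ++m;
            --i; --jj;
            continue;
          }
          if (c >= 1 && here == cur[c - 1] + 1) { --jj; continue; }
        }
        --i; // vertical
      }
      Hit h;
      h.idx = idx; h.start = jj; h.end = je;
      h.strand = strand; h.s = best; h.m = m;
      hits.push_back(h);
    }
  }
}

// Canonicalise one read's hits: a placement is identified by (strand,
// start); among equal-distance variants of one placement (indel wobble at
// the alignment end) keep the one with the most matches, then the shortest
// target span.  Also removes duplicates found from overlapping windows.
static void dedupReadHits(std::vector<Hit>& rhits) {
  std::sort(rhits.begin(), rhits.end(), [](const Hit& x, const Hit& y) {
    if (x.strand != y.strand) return x.strand > y.strand;
    if (x.start != y.start) return x.start < y.start;
    if (x.s != y.s) return x.s < y.s;
    if (x.m != y.m) return x.m > y.m;
    return x.end < y.end;
  });
  rhits.erase(std::unique(rhits.begin(), rhits.end(),
                          [](const Hit& x, const Hit& y) {
                            return x.strand == y.strand && x.start == y.start;
                          }),
              rhits.end());
}

// Scan a target with a set of reads: shared-13-mer seeding, diagonal
// clustering, windowed semi-global DP, canonical hit extraction, per-read
// deduplication.  kmax is per read (ceil(max_edit_fraction * length)).
// [[Rcpp::export]]
DataFrame cppScanShort(std::string target, CharacterVector reads,
                       IntegerVector kmax, int seedK) {
  const int n = (int)target.size();
  std::unordered_map<uint64_t, std::vector<int>> tmap;
  forEachKmer(target, seedK, [&](int p, uint64_t v) { tmap[v].push_back(p); });
  std::vector<int8_t> tcode(n);
  for (int j = 0; j < n; ++j) tcode[j] = (int8_t)baseCode(target[j]);
  std::vector<Hit> hits;
  std::vector<int> diagsF, diagsR;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string fwd = as<std::string>(reads[i]);
    const int len = (int)fwd.size();
    const int km = kmax[i];
    std::vector<Hit> rhits;
    // one pass over forward k-mers collects seed diagonals on both strands:
    // the reverse-complement read carries rc(v) at position len - seedK - p
    diagsF.clear(); diagsR.clear();
    forEachKmer(fwd, seedK, [&](int p, uint64_t v) {
      auto it = tmap.find(v);
      if (it != tmap.end())
        for (int tp : it->second) diagsF.push_back(tp - p);
      auto it2 = tmap.find(rcPacked(v, seedK));
      if (it2 != tmap.end()) {
        const int prc = len - seedK - p;
        for (int tp : it2->second) diagsR.push_back(tp - prc);
      }
    });
    std::string rc;
    for (int strand = 1; strand >= -1; strand -= 2) {
      std::vector<int>& diags = (strand == 1) ? diagsF : diagsR;
      if (diags.empty()) continue;
      if (strand == -1 && rc.empty()) rc = revcomp(fwd);
      const std::string& rd = (strand == 1) ? fwd : rc;
      std::sort(diags.begin(), diags.end());
      diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
      size_t a = 0;
      while (a < diags.size()) {
        size_t b = a;
        while (b + 1 < diags.size() && diags[b + 1] - diags[b] <= km + 1) ++b;
        alignBand(target, tcode, rd, diags[a] - km - 2, diags[b] + km + 2,
                  km, (int)i + 1, strand, rhits);
        a = b + 1;
      }
    }
    dedupReadHits(rhits);
    hits.insert(hits.end(), rhits.begin(), rhits.end());
  }
  const size_t nh = hits.size();
  IntegerVector idx(nh), start(nh), end(nh), strand(nh), s(nh), m(nh);
  for (size_t i = 0; i < nh; ++i) {
    idx[i] = hits[i].idx; start[i] = hits[i].start; end[i] = hits[i].end;
    strand[i] = hits[i].strand; s[i] = hits[i].s; m[i] = hits[i].m;
  }
  return DataFrame::create(_["idx"] = idx, _["start"] = start, _["end"] = end,
                           _["strand"] = strand, _["s"] = s, _["m"] = m);
}

// Exhaustive variant: no seeding, every read aligned against the whole
// target (both strands).  Used for short targets and as the enumeration
// backend on small instances.
// [[Rcpp::export]]
DataFrame cppScanExhaustive(std::string target, CharacterVector reads,
                            IntegerVector kmax) {
  const int n = (int)target.size();
  std::vector<int8_t> tcode(n);
  for (int j = 0; j < n; ++j) tcode[j] = (int8_t)baseCode(target[j]);
  std::vector<Hit> hits;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string fwd = as<std::string>(reads[i]);
    const int len = (int)fwd.size();
    std::vector<Hit> rhits;
    for (int strand = 1; strand >= -1; strand -= 2) {
      std::string rd = (strand == 1) ? fwd : revcomp(fwd);
      alignBand(target, tcode, rd, -(len + kmax[i]), n, kmax[i],
                (int)i + 1, strand, rhits);
    }
    dedupReadHits(rhits);
    hits.insert(hits.end(), rhits.begin(), rhits.end());
  }
  const size_t nh = hits.size();
  IntegerVector idx(nh), start(nh), end(nh), strand(nh), s(nh), m(nh);
  for (size_t i = 0; i < nh; ++i) {
    idx[i] = hits[i].idx; start[i] = hits[i].start; end[i] = hits[i].end;
    strand[i] = hits[i].strand; s[i] = hits[i].s; m[i] = hits[i].m;
  }
  return DataFrame::create(_["idx"] = idx, _["start"] = start, _["end"] = end,
                           _["strand"] = strand, _["s"] = s, _["m"] = m);
}

// ---------------------------------------------------------------------------
// Long-read scanning: seed-chain corridor alignment + banded forward mass
// ---------------------------------------------------------------------------

// Forward mass over paths restricted to per-row column bands [bl[i], bh[i]]
// (inclusive, in target coordinates; row i consumed i read bases).  Free
// alignment start anywhere in row 0's band; mass summed over the final row's
// band.  Returns log mass.
static double bandedForwardMass(const std::string& target, const std::string& read,
                                const std::vector<int>& bl, const std::vector<int>& bh,
                                double eps) {
  const int len = (int)read.size();
  double logscale = 0.0;
  std::vector<double> prev, cur;
  prev.assign(bh[0] - bl[0] + 1, 1.0);
  for (int i = 1; i <= len; ++i) {
    const int lo = bl[i], hi = bh[i];
    cur.assign(hi - lo + 1, 0.0);
    const char rc = read[i - 1];
    for (int j = lo; j <= hi; ++j) {
      double v = 0.0;
      if (j >= 1) {
        // diagonal from (i-1, j-1)
        if (j - 1 >= bl[i - 1] && j - 1 <= bh[i - 1]) {
          const char tc = target[j - 1];
          double pm = (baseCode(rc) >= 0 && rc == tc) ? (1.0 - eps) : eps;
          v += prev[j - 1 - bl[i - 1]] * pm;
        }
        // horizontal from (i, j-1): target base consumed, no read base
        if (j - 1 >= lo) v += cur[j - 1 - lo] * eps;
      }
      // vertical from (i-1, j): read base consumed, no target base
      if (j >= bl[i - 1] && j <= bh[i - 1]) v += prev[j - bl[i - 1]] * eps;
      cur[j - lo] = v;
    }
    double mx = 0.0;
    for (double v : cur) mx = std::max(mx, v);
    if (mx <= 0.0) return R_NegInf;
    for (double& v : cur) v /= mx;
    logscale += std::log(mx);
    prev.swap(cur);
  }
  double total = 0.0;
  for (double v : prev) total += v;
  if (total <= 0.0) return R_NegInf;
  return std::log(total) + logscale;
}

// Exported wrapper: banded forward mass around an explicit guide path.
// pathI/pathJ are the guide alignment's DP cells (read, target prefix
// lengths), monotone non-decreasing, from (0, j0) to (len, j1).
// [[Rcpp::export]]
double cppBandedForwardPath(std::string read, std::string target,
                            IntegerVector pathI, IntegerVector pathJ,
                            int band, double eps) {
  const int len = (int)read.size();
  const int n = (int)target.size();
  if (pathI.size() != pathJ.size() || pathI.size() < 1) stop("invalid guide path");
  std::vector<int> bl(len + 1, INT32_MAX), bh(len + 1, INT32_MIN);
  for (R_xlen_t t = 0; t < pathI.size(); ++t) {
    int i = pathI[t], j = pathJ[t];
    if (i < 0 || i > len || j < 0 || j > n) stop("guide path out of bounds");
    bl[i] = std::min(bl[i], j);
    bh[i] = std::max(bh[i], j);
  }
  for (int i = 0; i <= len; ++i) {
    if (bl[i] > bh[i]) stop("guide path must touch every read position");
    bl[i] = std::max(0, bl[i] - band);
    bh[i] = std::min(n, bh[i] + band);
  }
  return bandedForwardMass(target, read, bl, bh, eps);
}

struct LongHit {
  int idx, start, end, strand, s, m;
  double logmass;
  std::vector<int> pathLo, pathHi; // per-row j extent of the guide path
};

// Corridor-banded semi-global alignment of one oriented long read; returns
// false if no alignment within kmax edits exists.
static bool corridorAlign(const std::string& target, const std::string& read,
                          int diagLo, int diagHi, int kmax,
                          LongHit& out) {
  const int len = (int)read.size();
  const int n = (int)target.size();
  const int W = diagHi - diagLo + 1;
  if (W <= 0) return false;
  // cell (i, j) stored at row i, column j - (i + diagLo), j in [i+diagLo, i+diagHi]
  std::vector<uint16_t> D((size_t)(len + 1) * W, INF16);
  auto at = [&](int i, int j) -> uint16_t& {
    return D[(size_t)i * W + (j - (i + diagLo))];
  };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= n && j >= i + diagLo && j <= i + diagHi;
  };
  for (int j = std::max(0, diagLo); j <= std::min(n, diagHi); ++j) at(0, j) = 0;
  for (int i = 1; i <= len; ++i) {
    const char rc = read[i - 1];
    for (int j = std::max(0, i + diagLo); j <= std::min(n, i + diagHi); ++j) {
      int best = INF16;
      if (j >= 1 && inband(i - 1, j - 1) && at(i - 1, j - 1) < INF16) {
        int sub = (baseCode(rc) >= 0 && rc == target[j - 1]) ? 0 : 1;
        best = std::min(best, at(i - 1, j - 1) + sub);
      }
      if (inband(i - 1, j) && at(i - 1, j) < INF16)
        best = std::min(best, at(i - 1, j) + 1);
      if (j >= 1 && inband(i, j - 1) && at(i, j - 1) < INF16)
        best = std::min(best, at(i, j - 1) + 1);
      at(i, j) = (uint16_t)std::min(best, (int)INF16);
    }
  }
  int bestJ = -1, bestE = kmax + 1;
  for (int j = std::max(0, len + diagLo); j <= std::min(n, len + diagHi); ++j) {
    if (at(len, j) < bestE) { bestE = at(len, j); bestJ = j; }
  }
  if (bestJ < 0) return false;
  // traceback recording per-row path extent
  out.pathLo.assign(len + 1, INT32_MAX);
  out.pathHi.assign(len + 1, INT32_MIN);
  int i = len, j = bestJ, m = 0;
  out.pathLo[i] = out.pathHi[i] = j;
  while (i > 0) {
    bool moved = false;
    if (j >= 1 && inband(i - 1, j - 1)) {
      int sub = (baseCode(read[i - 1]) >= 0 && read[i - 1] == target[j - 1]) ? 0 : 1;
      if (at(i, j) == at(i - 1, j - 1) + sub) {
        if (sub == 0) ++m;
        --i; --j; moved = true;
      }
    }
    if (!moved && j >= 1 && inband(i, j - 1) && at(i, j) == at(i, j - 1) + 1) {
      --j; moved = true;
    }
    if (!moved) --i;
    out.pathLo[i] = std::min(out.pathLo[i], j);
    out.pathHi[i] = std::max(out.pathHi[i], j);
  }
  out.start = j;
  out.end = bestJ;
  out.s = bestE;
  out.m = m;
  return true;
}

// Scan a target with long noisy reads: 11-mer seeding, diagonal clustering
// with drift tolerance, corridor alignment, banded forward mass (+/- band
// diagonals around the guide path).
// [[Rcpp::export]]
DataFrame cppScanLong(std::string target, CharacterVector reads, int seedK,
                      double maxEditFrac, int band, double eps, int minSeeds) {
  const int n = (int)target.size();
  std::unordered_map<uint64_t, std::vector<int>> tmap;
  forEachKmer(target, seedK, [&](int p, uint64_t v) { tmap[v].push_back(p); });
  std::vector<int> idxv, startv, endv, strandv, sv, mv;
  std::vector<double> massv;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string fwd = as<std::string>(reads[i]);
    const int len = (int)fwd.size();
    const int kmaxE = (int)std::ceil(maxEditFrac * len);
    for (int strand = 1; strand >= -1; strand -= 2) {
      std::string rd = (strand == 1) ? fwd : revcomp(fwd);
      std::vector<int> diags;
      forEachKmer(rd, seedK, [&](int p, uint64_t v) {
        auto it = tmap.find(v);
        if (it == tmap.end()) return;
        for (int tp : it->second) diags.push_back(tp - p);
      });
      if ((int)diags.size() < minSeeds) continue;
      std::sort(diags.begin(), diags.end());
      const int gap = std::max(50, (int)(0.1 * len) + 20);
      size_t a = 0;
      while (a < diags.size()) {
        size_t b = a;
        while (b + 1 < diags.size() && diags[b + 1] - diags[b] <= gap) ++b;
        if ((int)(b - a + 1) >= minSeeds) {
          const int pad = std::max(10, (int)(0.05 * len)) + kmaxE / 4;
          LongHit h;
          if (corridorAlign(target, rd, diags[a] - pad, diags[b] + pad, kmaxE, h)) {
            std::vector<int> bl(len + 1), bh(len + 1);
            for (int r = 0; r <= len; ++r) {
              bl[r] = std::max(0, h.pathLo[r] - band);
              bh[r] = std::min(n, h.pathHi[r] + band);
            }
            double lm = bandedForwardMass(target, rd, bl, bh, eps);
            idxv.push_back((int)i + 1); startv.push_back(h.start);
            endv.push_back(h.end); strandv.push_back(strand);
            sv.push_back(h.s); mv.push_back(h.m); massv.push_back(lm);
          }
        }
        a = b + 1;
      }
    }
  }
  return DataFrame::create(_["idx"] = idxv, _["start"] = startv, _["end"] = endv,
                           _["strand"] = strandv, _["s"] = sv, _["m"] = mv,
                           _["logmass"] = massv);
}

// Seed-overlap pairs between contigs and long reads: for each (contig, read)
// report whether a seed cluster with >= minSeeds seeds spanning >= minSpan
// bases of the read exists (either strand of the contig).
// [[Rcpp::export]]
DataFrame cppSeedOverlapPairs(CharacterVector contigs, CharacterVector reads,
                              int seedK, int minSeeds, int minSpan) {
  std::vector<int> ci, ri;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string rs = as<std::string>(reads[r]);
    std::unordered_map<uint64_t, std::vector<int>> tmap;
    forEachKmer(rs, seedK, [&](int p, uint64_t v) { tmap[v].push_back(p); });
    for (R_xlen_t c = 0; c < contigs.size(); ++c) {
      std::string fwd = as<std::string>(contigs[c]);
      bool found = false;
      for (int strand = 1; strand >= -1 && !found; strand -= 2) {
        std::string cs = (strand == 1) ? fwd : revcomp(fwd);
        // (diag, read position) seed pairs
        std::vector<std::pair<int, int>> seeds;
        forEachKmer(cs, seedK, [&](int p, uint64_t v) {
          auto it = tmap.find(v);
          if (it == tmap.end()) return;
          for (int tp : it->second) seeds.push_back(std::make_pair(tp - p, tp));
        });
        if ((int)seeds.size() < minSeeds) continue;
        std::sort(seeds.begin(), seeds.end());
        const int gap = std::max(50, (int)(0.1 * cs.size()) + 20);
        size_t a = 0;
        while (a < seeds.size()) {
          size_t b = a;
          int lo = seeds[a].second, hi = seeds[a].second;
          while (b + 1 < seeds.size() && seeds[b + 1].first - seeds[b].first <= gap) {
            ++b;
            lo = std::min(lo, seeds[b].second);
            hi = std::max(hi, seeds[b].second);
          }
          if ((int)(b - a + 1) >= minSeeds && hi - lo + seedK >= minSpan) {
            found = true;
            break;
          }
          a = b + 1;
        }
      }
      if (found) { ci.push_back((int)c + 1); ri.push_back((int)r + 1); }
    }
  }
  return DataFrame::create(_["contig"] = ci, _["read"] = ri);
}
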