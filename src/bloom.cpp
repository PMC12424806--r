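#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <random>
#include "kmer_utils.h"

using namespace Rcpp;

// Bloom filter over canonical s-mer codes. h indices are derived by double
// hashing from two seeded 64-bit mixes (splitmix64 finalizer), so index
// content is a pure function of (code, seed1, seed2, m, h).

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline void bloom_set(unsigned char *bits, uint64_t m, int h,
                             uint64_t seed1, uint64_t seed2, uint64_t code) {
  uint64_t h1 = splitmix64(code ^ seed1);
  uint64_t h2 = splitmix64(code ^ seed2) | 1ULL;
  for (int i = 0; i < h; ++i) {
    uint64_t idx = (h1 + (uint64_t)i * h2) % m;
    bits[idx >> 3] |= (unsigned char)(1u << (idx & 7));
  }
}

static inline bool bloom_get(const unsigned char *bits, uint64_t m, int h,
                             uint64_t seed1, uint64_t seed2, uint64_t code) {
  uint64_t h1 = splitmix64(code ^ seed1);
  uint64_t h2 = splitmix64(code ^ seed2) | 1ULL;
  for (int i = 0; i < h; ++i) {
    uint64_t idx = (h1 + (uint64_t)i * h2) % m;
    if (!(bits[idx >> 3] & (1u << (idx & 7)))) return false;
  }
  return true;
}

// Count distinct canonical s-mers across sequences (for Bloom sizing).
// [[Rcpp::export]]
double cpp_distinct_smers(CharacterVector seqs, int s) {
  std::unordered_set<uint64_t> seen;
  uint64_t mask = (1ULL << (2 * s)) - 1;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char *str = CHAR(STRING_ELT(seqs, r));
    int n = (int)LENGTH(STRING_ELT(seqs, r));
    uint64_t fwd = 0, rc = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base_bits(str[i]);
      if (b < 0) { run = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((3ULL - (uint64_t)b) << (2 * (s - 1)));
      ++run;
      if (run >= s) seen.insert(rc < fwd ? rc : fwd);
    }
  }
  return (double)seen.size();
}

// Build a filter: insert all canonical s-mers of all sequences.
// [[Rcpp::export]]
List cpp_bloom_build(CharacterVector seqs, int s, double m_bits, int h,
                     double seed1, double seed2) {
  if (s < 1 || s > 31) stop("s must be in 1..31");
  uint64_t m = (uint64_t)m_bits;
  if (m < 1) stop("filter size must be positive");
  RawVector bits((m + 7) / 8);
  unsigned char *p = (unsigned char *)RAW(bits);
  uint64_t s1 = (uint64_t)seed1, s2 = (uint64_t)seed2;
  std::unordered_set<uint64_t> seen;
  uint64_t mask = (1ULL << (2 * s)) - 1;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char *str = CHAR(STRING_ELT(seqs, r));
    int n = (int)LENGTH(STRING_ELT(seqs, r));
    uint64_t fwd = 0, rc = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base_bits(str[i]);
      if (b < 0) { run = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((3ULL - (uint64_t)b) << (2 * (s - 1)));
      ++run;
      if (run >= s) {
        uint64_t c = rc < fwd ? rc : fwd;
        if (seen.insert(c).second) bloom_set(p, m, h, s1, s2, c);
      }
    }
  }
  return List::create(_["bits"] = bits, _["n_inserted"] = (double)seen.size());
}

static inline bool findere_code_positive(const unsigned char *p, uint64_t m,
                                         int h, uint64_t s1, uint64_t s2,
                                         uint64_t kcode, int k, int z) {
  int s = k - z;
  uint64_t smask = (1ULL << (2 * s)) - 1;
  for (int j = 0; j <= z; ++j) {
    uint64_t sm = (kcode >> (2 * (z - j))) & smask;
    if (!bloom_get(p, m, h, s1, s2, canon_u(sm, s))) return false;
  }
  return true;
}

// Findere membership for a vector of k-mer strings: positive iff all z+1
// constituent canonical s-mers are positive. Ambiguous windows answer false.
// [[Rcpp::export]]
LogicalVector cpp_findere_contains(RawVector bits, double m_bits, int h,
                                   double seed1, double seed2,
                                   CharacterVector kmers, int k, int z) {
  uint64_t m = (uint64_t)m_bits;
  const unsigned char *p = (const unsigned char *)RAW(bits);
  uint64_t s1 = (uint64_t)seed1, s2 = (uint64_t)seed2;
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char *str = CHAR(STRING_ELT(kmers, i));
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k) stop("k-mer of wrong length");
    int64_t code = encode_u(str, k);
    out[i] = (code >= 0) &&
             findere_code_positive(p, m, h, s1, s2, (uint64_t)code, k, z);
  }
  return out;
}

// Count positive k-mer windows of a query sequence. s-mer positivity is
// evaluated once per s-window; a k-window is positive iff its z+1 s-windows
// are all positive. Windows with ambiguous bases are excluded from n_total.
// [[Rcpp::export]]
NumericVector cpp_findere_query(RawVector bits, double m_bits, int h,
                                double seed1, double seed2, std::string seq,
                                int k, int z) {
  uint64_t m = (uint64_t)m_bits;
  const unsigned char *p = (const unsigned char *)RAW(bits);
  uint64_t s1 = (uint64_t)seed1, s2 = (uint64_t)seed2;
  int s = k - z;
  int n = (int)seq.size();
  int n_total = 0, n_found = 0;
  if (n >= k) {
    // valid[i]: s-window starting at i is unambiguous and Bloom-positive
    std::vector<signed char> spos(n - s + 1, -1); // -1 ambiguous
    uint64_t smask = (1ULL << (2 * s)) - 1;
    uint64_t fwd = 0, rc = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base_bits(seq[i]);
      if (b < 0) { run = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & smask;
      rc = (rc >> 2) | ((3ULL - (uint64_t)b) << (2 * (s - 1)));
      ++run;
      if (run >= s) {
        uint64_t c = rc < fwd ? rc : fwd;
        spos[i - s + 1] = bloom_get(p, m, h, s1, s2, c) ? 1 : 0;
      }
    }
    for (int i = 0; i + k <= n; ++i) {
      bool ok = true, valid = true;
      for (int j = 0; j <= z; ++j) {
        signed char v = spos[i + j];
        if (v < 0) { valid = false; break; }
        if (v == 0) ok = false;
      }
      if (!valid) continue;
      ++n_total;
      if (ok) ++n_found;
    }
  }
  return NumericVector::create(n_total, n_found);
}

// Empirical false-positive measurement: draw uniform random k-mers from a
// dedicated RNG, skip those whose canonical form is truly present, and count
// Findere positives among the rest.
// [[Rcpp::export]]
NumericVector cpp_measure_fpr(RawVector bits, double m_bits, int h,
                              double seed1, double seed2, int k, int z,
                              double n_queries, double rng_seed,
                              CharacterVector present_kmers) {
  uint64_t m = (uint64_t)m_bits;
  const unsigned char *p = (const unsigned char *)RAW(bits);
  uint64_t s1 = (uint64_t)seed1, s2 = (uint64_t)seed2;
  std::unordered_set<uint64_t> present;
  for (R_xlen_t i = 0; i < present_kmers.size(); ++i) {
    int64_t c = encode_u(CHAR(STRING_ELT(present_kmers, i)), k);
    if (c < 0) stop("ambiguous character in present k-mer set");
    present.insert(canon_u((uint64_t)c, k));
  }
  std::mt19937_64 rng((uint64_t)rng_seed);
  uint64_t kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  double tested = 0, positive = 0;
  uint64_t want = (uint64_t)n_queries;
  for (uint64_t i = 0; i < want; ++i) {
    uint64_t code = rng() & kmask;
    if (present.count(canon_u(code, k))) continue; // verified absent only
    tested += 1;
    if (findere_code_positive(p, m, h, s1, s2, code, k, z)) positive += 1;
  }
  return NumericVector::create(tested, positive);
}
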