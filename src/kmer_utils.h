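#ifndef UNITIGR_KMER_UTILS_H
#define UNITIGR_KMER_UTILS_H

#include <cstdint>
#include <string>
#include <stdexcept>

// 2-bit base code, A=0 C=1 G=2 T=3, most-significant base first.
// k <= 31 so a k-mer fits a uint64; (k+1)-mers (k+1 <= 32) also fit.

static inline int base_bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BIT_BASES[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_code_u(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

static inline uint64_t canon_u(uint64_t code, int k) {
  uint64_t rc = revcomp_code_u(code, k);
  return rc < code ? rc : code;
}

// full-range encoder (valid for k up to 32); false on ambiguous character
static inline bool encode_chk(const char *s, int k, uint64_t *out) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_bits(s[i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  *out = code;
  return true;
}

// returns -1 on ambiguous character, else code (k <= 31 only)
static inline int64_t encode_u(const char *s, int k) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_bits(s[i]);
    if (b < 0) return -1;
    code = (code << 2) | (uint64_t)b;
  }
  return (int64_t)code;
}

static inline std::string decode_u(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BIT_BASES[code & 3ULL];
    code >>= 2;
  }
  return s;
}

#endif
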