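#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include "kmer_utils.h"

using namespace Rcpp;

// [[Rcpp::export]]
double cpp_encode_kmer(std::string seq) {
  int k = (int)seq.size();
  if (k < 1 || k > 31) stop("k-mer length must be in 1..31, got %d", k);
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_bits(seq[i]);
    if (b < 0)
      stop("ambiguous or illegal character '%c' at position %d", seq[i], i + 1);
    code = (code << 2) | (uint64_t)b;
  }
  return (double)code;
}

// [[Rcpp::export]]
std::string cpp_decode_kmer(double code, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  return decode_u((uint64_t)code, k);
}

// [[Rcpp::export]]
double cpp_revcomp_code(double code, int k) {
  return (double)revcomp_code_u((uint64_t)code, k);
}

// [[Rcpp::export]]
double cpp_canonical_code(double code, int k) {
  return (double)canon_u((uint64_t)code, k);
}

// Scan one sequence: every length-k window of unambiguous bases, canonicalized.
// Positions are 1-based. Windows containing non-ACGT characters are skipped.
// [[Rcpp::export]]
List cpp_scan_kmers(std::string seq, int k) {
  std::vector<int> pos;
  std::vector<std::string> kmer;
  int n = (int)seq.size();
  if (n >= k) {
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t fwd = 0, rc = 0;
    int run = 0; // length of current unambiguous run
    for (int i = 0; i < n; ++i) {
      int b = base_bits(seq[i]);
      if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((3ULL - (uint64_t)b) << (2 * (k - 1)));
      ++run;
      if (run >= k) {
        uint64_t c = rc < fwd ? rc : fwd;
        pos.push_back(i - k + 2); // 1-based window start
        kmer.push_back(decode_u(c, k));
      }
    }
  }
  return List::create(_["pos"] = pos, _["kmer"] = kmer);
}

// Exact canonical k-mer counting over a read collection. Reads shorter than k
// contribute nothing; ambiguous windows are skipped. Output sorted by code.
// [[Rcpp::export]]
List cpp_count_canonical(CharacterVector reads, int k) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  std::unordered_map<uint64_t, double> counts;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (CharacterVector::is_na(reads[r])) continue;
    const char *s = CHAR(STRING_ELT(reads, r));
    int n = (int)LENGTH(STRING_ELT(reads, r));
    if (n < k) continue;
    uint64_t fwd = 0, rc = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base_bits(s[i]);
      if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((3ULL - (uint64_t)b) << (2 * (k - 1)));
      ++run;
      if (run >= k) counts[rc < fwd ? rc : fwd] += 1.0;
    }
  }
  std::vector<uint64_t> keys;
  keys.reserve(counts.size());
  for (auto &kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector kmer(keys.size());
  NumericVector count(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmer[i] = decode_u(keys[i], k);
    count[i] = counts[keys[i]];
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}

// Per-k-mer abundance from (k+1)-mer counts: for each length-k window of each
// input sequence, sum the counts of the distinct canonical (k+1)-mers that
// contain it (as prefix or suffix, either strand) and divide by two.
// Returns one numeric vector per input sequence.
// [[Rcpp::export]]
List cpp_kmer_abundances(CharacterVector seqs, int k,
                         CharacterVector k1_kmer, NumericVector k1_count) {
  int k1 = k + 1;
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, double> tab;
  for (R_xlen_t i = 0; i < k1_kmer.size(); ++i) {
    uint64_t c;
    if (!encode_chk(CHAR(STRING_ELT(k1_kmer, i)), k1, &c))
      stop("ambiguous character in (k+1)-mer table");
    tab[c] = k1_count[i];
  }
  List out(seqs.size());
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    int n = (int)LENGTH(STRING_ELT(seqs, r));
    int nw = n - k + 1;
    if (nw < 1) { out[r] = NumericVector(0); continue; }
    NumericVector ab(nw);
    for (int i = 0; i < nw; ++i) {
      int64_t x = encode_u(s + i, k);
      if (x < 0) { ab[i] = NA_REAL; continue; }
      uint64_t cand[8];
      int nc = 0;
      // x as prefix: x<<2 | b ; x as suffix: b<<2k | x
      for (uint64_t b = 0; b < 4; ++b) {
        cand[nc++] = canon_u(((uint64_t)x << 2) | b, k1);
        cand[nc++] = canon_u((b << (2 * k)) | (uint64_t)x, k1);
      }
      std::sort(cand, cand + 8);
      double sum = 0;
      for (int j = 0; j < 8; ++j) {
        if (j > 0 && cand[j] == cand[j - 1]) continue; // each (k+1)-mer once
        auto it = tab.find(cand[j]);
        if (it != tab.end()) sum += it->second;
      }
      ab[i] = sum / 2.0;
    }
    out[r] = ab;
  }
  return out;
}
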