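#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include "kmer_utils.h"

using namespace Rcpp;

// Bidirected de Bruijn graph compaction over a set of solid canonical k-mers.
// An oriented node is (canonical code, rev flag); its forward sequence is the
// canonical string or its reverse complement. An edge a->b (exact (k-1)
// overlap) is identified by its junction (k+1)-mer; blacklisted junctions are
// treated as absent (used for weak-link removal).

namespace {

struct Oriented {
  uint64_t canon;
  bool rev;
  bool operator==(const Oriented &o) const {
    return canon == o.canon && rev == o.rev;
  }
};

struct Ctx {
  int k;
  std::unordered_set<uint64_t> solid;     // canonical k-mer codes
  std::unordered_set<uint64_t> forbidden; // canonical (k+1)-mer junction codes
  std::unordered_set<uint64_t> allowed;   // observed junctions (edge-centric)
  bool use_allowed;
  uint64_t kmask;

  uint64_t fwd_code(const Oriented &o) const {
    return o.rev ? revcomp_code_u(o.canon, k) : o.canon;
  }

  // successors of o in its forward direction
  std::vector<Oriented> right_exts(const Oriented &o) const {
    std::vector<Oriented> out;
    uint64_t f = fwd_code(o);
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t nf = ((f << 2) | b) & kmask;
      uint64_t nc = canon_u(nf, k);
      if (!solid.count(nc)) continue;
      uint64_t junc = canon_u((f << 2) | b, k + 1);
      if (forbidden.count(junc)) continue;
      if (use_allowed && !allowed.count(junc)) continue;
      out.push_back(Oriented{nc, nc != nf});
    }
    return out;
  }

  Oriented flip(const Oriented &o) const { return Oriented{o.canon, !o.rev}; }
};

} // namespace

// [[Rcpp::export]]
List cpp_build_unitigs(CharacterVector kmers, int k, CharacterVector blacklist,
                       Nullable<CharacterVector> edges = R_NilValue) {
  if (k < 2 || k > 31) stop("k must be in 2..31");
  Ctx ctx;
  ctx.k = k;
  ctx.kmask = (1ULL << (2 * k)) - 1;
  ctx.use_allowed = edges.isNotNull();
  if (ctx.use_allowed) {
    CharacterVector ev(edges);
    for (R_xlen_t i = 0; i < ev.size(); ++i) {
      uint64_t c;
      if (!encode_chk(CHAR(STRING_ELT(ev, i)), k + 1, &c))
        stop("ambiguous character in edge (k+1)-mer set");
      ctx.allowed.insert(canon_u(c, k + 1));
    }
  }
  std::vector<uint64_t> codes;
  codes.reserve(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k) stop("k-mer of wrong length");
    int64_t c = encode_u(s, k);
    if (c < 0) stop("ambiguous character in k-mer set");
    uint64_t cc = canon_u((uint64_t)c, k);
    if (ctx.solid.insert(cc).second) codes.push_back(cc);
  }
  for (R_xlen_t i = 0; i < blacklist.size(); ++i) {
    uint64_t c;
    if (!encode_chk(CHAR(STRING_ELT(blacklist, i)), k + 1, &c))
      stop("ambiguous character in junction blacklist");
    ctx.forbidden.insert(canon_u(c, k + 1));
  }
  std::sort(codes.begin(), codes.end());

  std::unordered_set<uint64_t> visited;
  std::vector<std::string> seqs;

  for (uint64_t c : codes) {
    if (visited.count(c)) continue;
    std::vector<Oriented> path;
    path.push_back(Oriented{c, false});
    visited.insert(c);
    bool circular = false;
    // extend right
    for (;;) {
      Oriented cur = path.back();
      auto exts = ctx.right_exts(cur);
      if (exts.size() != 1) break;
      Oriented nxt = exts[0];
      auto back = ctx.right_exts(ctx.flip(nxt));
      if (back.size() != 1) break;
      if (nxt == path.front()) { circular = true; break; }
      if (visited.count(nxt.canon)) break;
      path.push_back(nxt);
      visited.insert(nxt.canon);
    }
    if (!circular) {
      // extend left: walk right from the flipped front, then mirror
      std::vector<Oriented> left;
      for (;;) {
        Oriented cur = left.empty() ? ctx.flip(path.front()) : left.back();
        auto exts = ctx.right_exts(cur);
        if (exts.size() != 1) break;
        Oriented nxt = exts[0];
        auto back = ctx.right_exts(ctx.flip(nxt));
        if (back.size() != 1) break;
        if (visited.count(nxt.canon)) break;
        left.push_back(nxt);
        visited.insert(nxt.canon);
      }
      if (!left.empty()) {
        std::vector<Oriented> full;
        for (auto it = left.rbegin(); it != left.rend(); ++it)
          full.push_back(ctx.flip(*it));
        full.insert(full.end(), path.begin(), path.end());
        path.swap(full);
      }
    }
    // spell the unitig
    std::string s = decode_u(ctx.fwd_code(path[0]), k);
    for (size_t i = 1; i < path.size(); ++i)
      s.push_back(BIT_BASES[ctx.fwd_code(path[i]) & 3ULL]);
    // stored strand: lexicographically smaller of seq and revcomp(seq)
    std::string rcs(s.size(), 'A');
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_bits(s[s.size() - 1 - i]);
      rcs[i] = BIT_BASES[3 - b];
    }
    if (rcs < s) s.swap(rcs);
    seqs.push_back(s);
  }

  // deterministic order: length desc, sequence asc
  std::vector<size_t> ord(seqs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (seqs[a].size() != seqs[b].size()) return seqs[a].size() > seqs[b].size();
    return seqs[a] < seqs[b];
  });
  std::vector<std::string> sorted;
  sorted.reserve(seqs.size());
  for (size_t i : ord) sorted.push_back(seqs[i]);
  seqs.swap(sorted);

  // locate every canonical k-mer: unitig id (1-based), position, stored strand
  struct Loc { int uid; int pos; bool rev; };
  std::unordered_map<uint64_t, Loc> where;
  for (size_t u = 0; u < seqs.size(); ++u) {
    const std::string &s = seqs[u];
    for (size_t i = 0; i + k <= s.size(); ++i) {
      uint64_t f = (uint64_t)encode_u(s.c_str() + i, k);
      uint64_t cc = canon_u(f, k);
      where[cc] = Loc{(int)u + 1, (int)i, cc != f};
    }
  }

  // links at unitig ends
  std::vector<int> Lfrom, Lto;
  std::vector<std::string> Lfe, Lte;
  for (size_t u = 0; u < seqs.size(); ++u) {
    const std::string &s = seqs[u];
    int last = (int)s.size() - k;
    for (int endi = 0; endi < 2; ++endi) {
      // endi 0: '+' end (rightmost k-mer, forward); endi 1: '-' end
      uint64_t f;
      if (endi == 0) f = (uint64_t)encode_u(s.c_str() + last, k);
      else f = revcomp_code_u((uint64_t)encode_u(s.c_str(), k), k);
      uint64_t cc = canon_u(f, k);
      Oriented o{cc, cc != f};
      for (const Oriented &nxt : ctx.right_exts(o)) {
        auto it = where.find(nxt.canon);
        if (it == where.end()) stop("internal error: dangling link target");
        const Loc &loc = it->second;
        const std::string &t = seqs[loc.uid - 1];
        int tlast = (int)t.size() - k;
        std::string sign;
        if (nxt.rev == loc.rev && loc.pos == 0) sign = "+";
        else if (nxt.rev != loc.rev && loc.pos == tlast) sign = "-";
        else stop("internal error: link lands inside a unitig");
        Lfrom.push_back((int)u + 1);
        Lfe.push_back(endi == 0 ? "+" : "-");
        Lto.push_back(loc.uid);
        Lte.push_back(sign);
      }
    }
  }

  return List::create(
      _["seq"] = wrap(seqs),
      _["links"] = DataFrame::create(
          _["from"] = wrap(Lfrom), _["from_end"] = wrap(Lfe),
          _["to"] = wrap(Lto), _["to_end"] = wrap(Lte),
          _["stringsAsFactors"] = false));
}
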