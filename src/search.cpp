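// Mismatch-tolerant, PAM-anchored search of protospacers against a genome.
//
// Strategy: pigeonhole seeding. The S-nt protospacer is split into
// (max_mm + 1) disjoint seeds; any site within max_mm mismatches must match
// at least one seed exactly. Seed occurrences are looked up in a per-genome
// hash index and candidates verified with 2-bit-packed XOR + popcount.
// The PAM (IUPAC pattern, default TTTV) is required to match exactly at the
// candidate site unless require_pam is false. Windows containing N never
// match. Output is equivalent to a full scan of every window; tests assert
// this against an independent brute-force oracle written in R.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cctype>

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

// IUPAC letter -> bitmask over bases (bit 0 = A, 1 = C, 2 = G, 3 = T)
static int iupac_mask(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
    case 'R': return 5;  case 'Y': return 10; case 'S': return 6;  case 'W': return 9;
    case 'K': return 12; case 'M': return 3;  case 'B': return 14; case 'D': return 13;
    case 'H': return 11; case 'V': return 7;  case 'N': return 15;
    default:  return 0;
  }
}

static inline int mm_count(uint64_t a, uint64_t b) {
  uint64_t x = a ^ b;
  uint64_t y = (x | (x >> 1)) & 0x5555555555555555ULL;
  return __builtin_popcountll(y);
}

struct ContigData {
  std::vector<int8_t> code;      // -1 for N / non-ACGT
  std::vector<uint64_t> pkS;     // packed S-mer starting at i (valid iff no N)
  std::vector<uint8_t> ok_win;   // window [p, p+k) free of N
  std::vector<uint8_t> pam_plus; // PAM pattern matches at [p, p+plen)
  std::vector<uint8_t> pam_minus;// PAM matches the revcomp site of window p
  long L = 0, np = 0;            // np = number of windows = L - k + 1 (>= 0)
  // seed index: seed length -> (packed seed -> positions)
  std::unordered_map<int, std::unordered_map<uint64_t, std::vector<int> > > index;
};

struct Hit {
  int query, contig, start, mm;
  char strand;
};

static bool hit_less(const Hit& a, const Hit& b) {
  if (a.query != b.query) return a.query < b.query;
  if (a.contig != b.contig) return a.contig < b.contig;
  if (a.start != b.start) return a.start < b.start;
  return a.strand < b.strand;  // '+' (43) before '-' (45)
}

// [[Rcpp::export]]
DataFrame cpp_search_offtargets(CharacterVector contigs, CharacterVector spacers,
                                std::string pam, int max_mm, bool require_pam) {
  const int plen = static_cast<int>(pam.size());
  if (plen < 1) stop("PAM pattern must be non-empty");
  if (spacers.size() == 0)
    return DataFrame::create(_["query"] = IntegerVector(0),
                             _["contig"] = IntegerVector(0),
                             _["start"] = IntegerVector(0),
                             _["strand"] = CharacterVector(0),
                             _["mismatches"] = IntegerVector(0));
  const int S = LENGTH(STRING_ELT(spacers, 0));
  if (S < 1 || S > 32) stop("protospacer length must be in 1..32");
  for (R_xlen_t i = 0; i < spacers.size(); ++i)
    if (LENGTH(STRING_ELT(spacers, i)) != S)
      stop("all protospacers must have equal length");
  if (max_mm < 0 || max_mm > S) stop("max_mm must be in 0..protospacer length");
  const int k = plen + S;

  std::vector<int> pmask(plen);
  for (int j = 0; j < plen; ++j) {
    pmask[j] = iupac_mask(pam[j]);
    if (pmask[j] == 0) stop("invalid IUPAC letter in PAM pattern");
  }

  // seed partition of [0, S): (max_mm + 1) near-equal pieces
  const int nseed = max_mm + 1;
  const bool full_scan = nseed > S;
  std::vector<int> seed_off, seed_len;
  if (!full_scan) {
    int base = S / nseed, rem = S % nseed, off = 0;
    for (int j = 0; j < nseed; ++j) {
      int l = base + (j < rem ? 1 : 0);
      seed_off.push_back(off);
      seed_len.push_back(l);
      off += l;
    }
  }

  // ---- per-contig precomputation ----
  const int nc = static_cast<int>(contigs.size());
  std::vector<ContigData> cd(nc);
  for (int ci = 0; ci < nc; ++ci) {
    const char* s = CHAR(STRING_ELT(contigs, ci));
    const long L = LENGTH(STRING_ELT(contigs, ci));
    ContigData& C = cd[ci];
    C.L = L;
    C.np = L - k + 1;
    C.code.resize(L);
    for (long i = 0; i < L; ++i) C.code[i] = static_cast<int8_t>(base_code(s[i]));
    if (C.np <= 0) continue;

    // rolling packed S-mers and N-freedom
    C.pkS.assign(L - S + 1, 0);
    std::vector<int> nextN(L + 1);  // nextN[i] = first j >= i with code[j] < 0 (or L)
    nextN[L] = L;
    for (long i = L - 1; i >= 0; --i) nextN[i] = (C.code[i] < 0) ? i : nextN[i + 1];
    uint64_t key = 0;
    const uint64_t maskS = (S == 32) ? ~0ULL : ((1ULL << (2 * S)) - 1);
    for (long i = 0; i < L; ++i) {
      key = ((key >> 2) | (static_cast<uint64_t>(C.code[i] < 0 ? 0 : C.code[i]) << (2 * (S - 1)))) & maskS;
      if (i >= S - 1) C.pkS[i - S + 1] = key;
    }
    C.ok_win.assign(C.np, 0);
    C.pam_plus.assign(C.np, 0);
    C.pam_minus.assign(C.np, 0);
    for (long p = 0; p < C.np; ++p) {
      C.ok_win[p] = (nextN[p] >= p + k);
      if (!C.ok_win[p]) continue;
      int okp = 1, okm = 1;
      for (int j = 0; j < plen; ++j) {
        if (!((pmask[j] >> C.code[p + j]) & 1)) okp = 0;
        int comp = 3 - C.code[p + k - 1 - j];  // revcomp site base j
        if (!((pmask[j] >> comp) & 1)) okm = 0;
        if (!okp && !okm) break;
      }
      C.pam_plus[p] = static_cast<uint8_t>(okp);
      C.pam_minus[p] = static_cast<uint8_t>(okm);
    }

    // seed index over N-free seed-length windows
    if (!full_scan) {
      std::vector<int> lens(seed_len);
      std::sort(lens.begin(), lens.end());
      lens.erase(std::unique(lens.begin(), lens.end()), lens.end());
      for (int l : lens) {
        auto& m = C.index[l];
        uint64_t kk = 0;
        const uint64_t maskl = (1ULL << (2 * l)) - 1;
        long sinceN = 0;  // bases since last N (inclusive run length)
        for (long i = 0; i < L; ++i) {
          if (C.code[i] < 0) { sinceN = 0; kk = 0; continue; }
          ++sinceN;
          kk = ((kk >> 2) | (static_cast<uint64_t>(C.code[i]) << (2 * (l - 1)))) & maskl;
          if (sinceN >= l) m[kk].push_back(static_cast<int>(i - l + 1));
        }
      }
    }
  }

  // packed S-mer starting at i, forward orientation
  // (pkS[i] packs code[i] in the LOW bits: built by right-shifting rolls)

  std::vector<Hit> hits;
  for (R_xlen_t qi = 0; qi < spacers.size(); ++qi) {
    const char* sp = CHAR(STRING_ELT(spacers, qi));
    std::vector<int> scode(S), rcode(S);
    for (int t = 0; t < S; ++t) {
      scode[t] = base_code(sp[t]);
      if (scode[t] < 0) stop("protospacer contains a non-ACGT base");
    }
    for (int t = 0; t < S; ++t) rcode[t] = 3 - scode[S - 1 - t];
    uint64_t pk_fwd = 0, pk_rc = 0;
    for (int t = 0; t < S; ++t) {
      pk_fwd |= static_cast<uint64_t>(scode[t]) << (2 * t);
      pk_rc  |= static_cast<uint64_t>(rcode[t]) << (2 * t);
    }

    for (int ci = 0; ci < nc; ++ci) {
      ContigData& C = cd[ci];
      if (C.np <= 0) continue;

      std::vector<int> cand_plus, cand_minus;
      if (full_scan) {
        cand_plus.resize(C.np);
        for (long p = 0; p < C.np; ++p) cand_plus[p] = static_cast<int>(p);
        cand_minus = cand_plus;
      } else {
        for (int j = 0; j < nseed; ++j) {
          const int l = seed_len[j], off = seed_off[j];
          uint64_t kf = 0, kr = 0;
          for (int t = 0; t < l; ++t) {
            kf |= static_cast<uint64_t>(scode[off + t]) << (2 * t);
            kr |= static_cast<uint64_t>(rcode[off + t]) << (2 * t);
          }
          auto& m = C.index[l];
          auto itf = m.find(kf);
          if (itf != m.end())
            for (int q : itf->second) {
              int p = q - plen - off;  // '+' site: spacer sits at window offset plen
              if (p >= 0 && p < C.np) cand_plus.push_back(p);
            }
          auto itr = m.find(kr);
          if (itr != m.end())
            for (int q : itr->second) {
              int p = q - off;         // '-' site: revcomp(spacer) sits at offset 0
              if (p >= 0 && p < C.np) cand_minus.push_back(p);
            }
        }
        std::sort(cand_plus.begin(), cand_plus.end());
        cand_plus.erase(std::unique(cand_plus.begin(), cand_plus.end()), cand_plus.end());
        std::sort(cand_minus.begin(), cand_minus.end());
        cand_minus.erase(std::unique(cand_minus.begin(), cand_minus.end()), cand_minus.end());
      }

      for (int p : cand_plus) {
        if (!C.ok_win[p]) continue;
        if (require_pam && !C.pam_plus[p]) continue;
        int mm = mm_count(C.pkS[p + plen], pk_fwd);
        if (mm <= max_mm)
          hits.push_back(Hit{static_cast<int>(qi + 1), ci + 1, p, mm, '+'});
      }
      for (int p : cand_minus) {
        if (!C.ok_win[p]) continue;
        if (require_pam && !C.pam_minus[p]) continue;
        int mm = mm_count(C.pkS[p], pk_rc);
        if (mm <= max_mm)
          hits.push_back(Hit{static_cast<int>(qi + 1), ci + 1, p, mm, '-'});
      }
    }
  }

  std::sort(hits.begin(), hits.end(), hit_less);

  const int n = static_cast<int>(hits.size());
  IntegerVector query(n), contig(n), start(n), mism(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    query[i] = hits[i].query;
    contig[i] = hits[i].contig;
    start[i] = hits[i].start;
    mism[i] = hits[i].mm;
    strand[i] = (hits[i].strand == '+') ? "+" : "-";
  }
  return DataFrame::create(_["query"] = query, _["contig"] = contig,
                           _["start"] = start, _["strand"] = strand,
                           _["mismatches"] = mism,
                           _["stringsAsFactors"] = false);
}
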