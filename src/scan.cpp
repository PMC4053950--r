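// Inner scanning loops over the integer-encoded concatenated sequence
// (A=1, C=2, G=3, U=4, separator/other=5).  Window position j (1-based,
// miRNA 5'->3') pairs antiparallel with site position 12-j, i.e. 0-based
// site index t + 10 - j0 for a site starting at t.

#include <Rcpp.h>
using namespace Rcpp;

// pair class: 2 = Watson-Crick, 1 = G:U wobble, 0 = mismatch, -1 = non-base
static inline int pair_code(int m, int s) {
  if (m > 4 || s > 4) return -1;
  switch (m) {
  case 1: return s == 4 ? 2 : 0;                    // A:U
  case 2: return s == 3 ? 2 : 0;                    // C:G
  case 3: return s == 2 ? 2 : (s == 4 ? 1 : 0);     // G:C / G:U
  case 4: return s == 1 ? 2 : (s == 3 ? 1 : 0);     // U:A / U:G
  }
  return -1;
}

// All qualifying 11-mer alignments of one centered window.
// Returns a list of integer vectors: start (0-based), n_gu, n_mm,
// mm_pos (1-based window position of the single mismatch, 0 if none or
// more than one).
// [[Rcpp::export]]
List cpp_scan_centered(IntegerVector enc, IntegerVector wenc, int max_mm,
                       bool allow_gu, double max_gu, bool interior_only) {
  const int L = enc.size();
  std::vector<int> starts, gus, mms, mmps;
  int w[11];
  for (int j = 0; j < 11; ++j) w[j] = wenc[j];
  for (int t = 0; t + 11 <= L; ++t) {
    int gu = 0, mm = 0;
    int mmpos[3];
    bool bad = false;
    for (int j = 0; j < 11; ++j) {
      int c = pair_code(w[j], enc[t + 10 - j]);
      if (c < 0) { bad = true; break; }
      if (c == 1 && allow_gu) {
        ++gu;
      } else if (c < 2) {
        if (mm < 3) mmpos[mm] = j + 1;
        if (++mm > max_mm) { bad = true; break; }
      }
    }
    if (bad || gu > max_gu) continue;
    if (interior_only) {
      bool terminal = false;
      for (int k = 0; k < mm; ++k)
        if (mmpos[k] == 1 || mmpos[k] == 11) { terminal = true; break; }
      if (terminal) continue;
    }
    starts.push_back(t);
    gus.push_back(gu);
    mms.push_back(mm);
    mmps.push_back(mm == 1 ? mmpos[0] : 0);
  }
  return List::create(_["start"] = wrap(starts), _["n_gu"] = wrap(gus),
                      _["n_mm"] = wrap(mms), _["mm_pos"] = wrap(mmps));
}

// Seed matches: 8mer (WC match to miRNA 2-8 plus target A opposite
// position 1), 7mer-m8 (match 2-8, no A), 7mer-A1 (match 2-7 plus A,
// not extendable to m8).  rc7/rc6 are the site-side (5'->3') perfect
// complements; comp8 is the site base complementary to miRNA position 8.
// Returns start (0-based) and type (1 = 8mer, 2 = 7mer-m8, 3 = 7mer-A1).
// [[Rcpp::export]]
List cpp_scan_seed(IntegerVector enc, IntegerVector rc7, IntegerVector rc6,
                   int comp8) {
  const int L = enc.size();
  std::vector<int> starts, types;
  int r7[7], r6[6];
  for (int k = 0; k < 7; ++k) r7[k] = rc7[k];
  for (int k = 0; k < 6; ++k) r6[k] = rc6[k];
  // 7-mer matches -> 8mer or 7mer-m8
  for (int p = 0; p + 7 <= L; ++p) {
    bool ok = true;
    for (int k = 0; k < 7; ++k)
      if (enc[p + k] != r7[k]) { ok = false; break; }
    if (!ok) continue;
    if (p + 7 < L && enc[p + 7] == 1) {
      starts.push_back(p); types.push_back(1);
    } else {
      starts.push_back(p); types.push_back(2);
    }
  }
  // 6-mer + A, excluding loci already part of an m8 match
  for (int q = 0; q + 7 <= L; ++q) {
    bool ok = true;
    for (int k = 0; k < 6; ++k)
      if (enc[q + k] != r6[k]) { ok = false; break; }
    if (!ok || enc[q + 6] != 1) continue;
    if (q > 0 && enc[q - 1] == comp8) continue;
    starts.push_back(q); types.push_back(3);
  }
  return List::create(_["start"] = wrap(starts), _["type"] = wrap(types));
}
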