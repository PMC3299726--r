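#include <Rcpp.h>
#include <vector>
#include <string>
#include <cctype>
using namespace Rcpp;

// Maximal scoring subsequences (Ruzzo & Tompa 1999) over a +match/-mismatch
// score vector, one unit size at a time. A comparison at position i (0-based)
// tests s[i] == s[i - u]; a maximal subsequence of comparisons [i1, i2] maps
// to the tract [i1 - u, i2] because the seed unit itself is part of the tract.
// The seed unit is credited as matched so that a perfect 7-base tract reaches
// the minimum score at every unit size (match weight 2, minimum score 14).

struct MsSub {
  int start, end;
  long L, R;
};

static inline bool base_ok(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export]]
DataFrame rt_scan_cpp(std::string seq, int max_unit = 5, int min_score = 14,
                      int match_w = 2, int mismatch_w = 5) {
  const int n = (int) seq.size();
  for (int i = 0; i < n; ++i) seq[i] = (char) std::toupper((unsigned char) seq[i]);

  std::vector<int> out_u, out_s, out_e, out_m, out_mm, out_sc;

  for (int u = 1; u <= max_unit; ++u) {
    if (n <= u) continue;
    std::vector<MsSub> stack;
    long cum = 0;
    for (int i = u; i < n; ++i) {
      bool match = base_ok(seq[i]) && base_ok(seq[i - u]) && seq[i] == seq[i - u];
      long x = match ? (long) match_w : -(long) mismatch_w;
      if (x <= 0) { cum += x; continue; }
      MsSub k; k.start = i; k.end = i; k.L = cum; k.R = cum + x;
      cum += x;
      while (true) {
        int j = (int) stack.size() - 1;
        while (j >= 0 && stack[j].L >= k.L) --j;
        if (j < 0 || stack[j].R >= k.R) { // k cannot absorb anything further
          stack.push_back(k);
          break;
        }
        k.start = stack[j].start; // absorb I_j .. top into k and reconsider
        k.L = stack[j].L;
        stack.erase(stack.begin() + j, stack.end());
      }
    }
    for (size_t t = 0; t < stack.size(); ++t) {
      long sc_cmp = stack[t].R - stack[t].L;
      int len_cmp = stack[t].end - stack[t].start + 1;
      // sc_cmp = match_w*m - mismatch_w*mm, m + mm = len_cmp
      int m = (int) ((sc_cmp + (long) mismatch_w * len_cmp) / (match_w + mismatch_w));
      int mm = len_cmp - m;
      int score = (int) sc_cmp + match_w * u; // seed unit credited
      if (score < min_score) continue;
      out_u.push_back(u);
      out_s.push_back(stack[t].start - u);     // 0-based tract start
      out_e.push_back(stack[t].end + 1);       // 0-based exclusive end
      out_m.push_back(m);
      out_mm.push_back(mm);
      out_sc.push_back(score);
    }
  }
  return DataFrame::create(
    _["unit_length"] = out_u, _["start"] = out_s, _["end"] = out_e,
    _["matches"] = out_m, _["mismatches"] = out_mm, _["score"] = out_sc);
}

// Per (read, locus) scoring against one chromosome. All coordinates 1-based:
// lpos/rpos are the flanking anchor positions (last base before the tract,
// first base after it). status: 0 = spans (both anchors aligned), 1 = does
// not span, 2 = unanchored (anchor inside alignment span but gapped/deleted,
// or tract at a sequence edge). Allele length = query distance between the
// anchors minus one, which is invariant to gap placement inside the tract.
// [[Rcpp::export]]
DataFrame score_pairs_cpp(CharacterVector cigar, IntegerVector pos,
                          CharacterVector seq, std::string ref,
                          IntegerVector lpos, IntegerVector rpos) {
  const int np = cigar.size();
  const int refn = (int) ref.size();
  IntegerVector status(np), allele(np), fl(np), fr(np);

  std::vector<int> arefs, aqoff; // aligned (M/=/X) base positions

  for (int p = 0; p < np; ++p) {
    int L = lpos[p], R = rpos[p];
    if (L < 1 || R > refn) { status[p] = 2; allele[p] = NA_INTEGER; fl[p] = 0; fr[p] = 0; continue; }
    std::string cg = as<std::string>(cigar[p]);
    std::string sq = as<std::string>(seq[p]);
    int rp = pos[p], q = 1;
    arefs.clear(); aqoff.clear();
    size_t ci = 0;
    while (ci < cg.size()) {
      long len = 0;
      while (ci < cg.size() && std::isdigit((unsigned char) cg[ci])) {
        len = len * 10 + (cg[ci] - '0'); ++ci;
      }
      if (ci >= cg.size()) break;
      char op = cg[ci++];
      switch (op) {
      case 'M': case '=': case 'X':
        for (long k = 0; k < len; ++k) { arefs.push_back(rp + (int) k); aqoff.push_back(q + (int) k); }
        rp += (int) len; q += (int) len; break;
      case 'I': case 'S': q += (int) len; break;
      case 'D': case 'N': rp += (int) len; break;
      default: break; // H, P consume nothing
      }
    }
    if (arefs.empty()) { status[p] = 1; allele[p] = NA_INTEGER; fl[p] = 0; fr[p] = 0; continue; }
    int ref_lo = arefs.front(), ref_hi = arefs.back();
    // binary search for anchor indices
    int iL = -1, iR = -1;
    {
      int lo = 0, hi = (int) arefs.size() - 1;
      while (lo <= hi) { int mid = (lo + hi) / 2;
        if (arefs[mid] < L) lo = mid + 1; else if (arefs[mid] > L) hi = mid - 1; else { iL = mid; break; } }
      lo = 0; hi = (int) arefs.size() - 1;
      while (lo <= hi) { int mid = (lo + hi) / 2;
        if (arefs[mid] < R) lo = mid + 1; else if (arefs[mid] > R) hi = mid - 1; else { iR = mid; break; } }
    }
    if (iL < 0 || iR < 0) {
      bool inside = (L >= ref_lo && L <= ref_hi && R >= ref_lo && R <= ref_hi);
      status[p] = inside ? 2 : 1;
      allele[p] = NA_INTEGER; fl[p] = 0; fr[p] = 0; continue;
    }
    status[p] = 0;
    allele[p] = aqoff[iR] - aqoff[iL] - 1;
    // flank runs: consecutive aligned, contiguous (no gap on either side),
    // matching positions scanning outward from the anchors
    int k = 0, i = iL;
    while (i >= 0) {
      char rb = (char) std::toupper((unsigned char) ref[arefs[i] - 1]);
      char qb = (char) std::toupper((unsigned char) sq[aqoff[i] - 1]);
      if (!(base_ok(rb) && rb == qb)) break;
      ++k;
      if (i == 0 || arefs[i - 1] != arefs[i] - 1 || aqoff[i - 1] != aqoff[i] - 1) break;
      --i;
    }
    fl[p] = k;
    k = 0; i = iR;
    int na = (int) arefs.size();
    while (i < na) {
      char rb = (char) std::toupper((unsigned char) ref[arefs[i] - 1]);
      char qb = (char) std::toupper((unsigned char) sq[aqoff[i] - 1]);
      if (!(base_ok(rb) && rb == qb)) break;
      ++k;
      if (i == na - 1 || arefs[i + 1] != arefs[i] + 1 || aqoff[i + 1] != aqoff[i] + 1) break;
      ++i;
    }
    fr[p] = k;
  }
  return DataFrame::create(_["status"] = status, _["allele_length"] = allele,
                           _["flank_left"] = fl, _["flank_right"] = fr);
}

// Reference span consumed by each CIGAR (for overlap finding without
// GenomicAlignments' machinery on in-memory tibbles).
// [[Rcpp::export]]
IntegerVector cigar_ref_width_cpp(CharacterVector cigar) {
  int n = cigar.size();
  IntegerVector out(n);
  for (int p = 0; p < n; ++p) {
    std::string cg = as<std::string>(cigar[p]);
    long w = 0; size_t ci = 0;
    while (ci < cg.size()) {
      long len = 0;
      while (ci < cg.size() && std::isdigit((unsigned char) cg[ci])) { len = len * 10 + (cg[ci] - '0'); ++ci; }
      if (ci >= cg.size()) break;
      char op = cg[ci++];
      if (op == 'M' || op == '=' || op == 'X' || op == 'D' || op == 'N') w += len;
    }
    out[p] = (int) w;
  }
  return out;
}
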