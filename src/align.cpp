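#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Affine-gap semi-global alignment of a read against a (bisulfite-converted)
// reference: the read is aligned end to end, reference overhangs on either
// side are free.  Exact DP over three states (M = match/mismatch,
// X = gap-in-reference consuming a read base, Y = gap-in-read consuming a
// reference base).  A gap of length k costs gap_open + (k - 1) * gap_extend.
//
// Tie-breaks, applied identically during the sweep and at the end cell:
// M is preferred over Y (gap-in-read), Y over X, making the reported
// alignment a deterministic function of the inputs.  Scores use rolling
// rows; only the byte-sized traceback matrices are kept in full.

static const int NEG = INT_MIN / 4;

// state codes: 0 = M, 1 = X (gap in ref), 2 = Y (gap in read)

// [[Rcpp::export(name = ".align_semiglobal_cpp")]]
List align_semiglobal_cpp(std::string read, std::string ref,
                          int match, int mismatch,
                          int gap_open, int gap_extend) {
  const int n = (int) read.size();   // rows: read
  const int m = (int) ref.size();    // cols: reference
  if (n == 0 || m == 0) stop("read and reference must be non-empty");

  std::vector<int> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  std::vector<int> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  // traceback: predecessor state for each cell and state; -1 = alignment
  // start (only meaningful for M in row 0)
  std::vector<signed char> tbM((size_t)(n + 1) * (m + 1), -1);
  std::vector<signed char> tbX((size_t)(n + 1) * (m + 1), -1);
  std::vector<signed char> tbY((size_t)(n + 1) * (m + 1), -1);
  #define IDX(i, j) ((size_t)(i) * (m + 1) + (j))

  // row 0: free leading reference gap -- the alignment may start at any
  // reference offset in state M with score 0
  for (int j = 0; j <= m; ++j) { Mp[j] = 0; Xp[j] = NEG; Yp[j] = NEG; }

  for (int i = 1; i <= n; ++i) {
    // column 0: leading gap-in-ref (read bases before any reference base)
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = gap_open + (i - 1) * gap_extend;
    tbX[IDX(i, 0)] = (signed char)(i == 1 ? 0 : 1);
    const char rc = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      // M: consume read[i-1] against ref[j-1]; prefer M, then Y, then X
      int s = (rc == ref[j - 1]) ? match : mismatch;
      int best = Mp[j - 1]; signed char src = 0;
      if (Yp[j - 1] > best) { best = Yp[j - 1]; src = 2; }
      if (Xp[j - 1] > best) { best = Xp[j - 1]; src = 1; }
      if (best > NEG) { Mc[j] = best + s; tbM[IDX(i, j)] = src; }
      else Mc[j] = NEG;
      // Y: gap in read, consume ref[j-1]; prefer opening from M on ties
      int yo = Mc[j - 1] > NEG ? Mc[j - 1] + gap_open : NEG;
      int ye = Yc[j - 1] > NEG ? Yc[j - 1] + gap_extend : NEG;
      if (yo >= ye) { Yc[j] = yo; if (yo > NEG) tbY[IDX(i, j)] = 0; }
      else          { Yc[j] = ye; tbY[IDX(i, j)] = 2; }
      // X: gap in ref, consume read[i-1]; prefer opening from M on ties
      int xo = Mp[j] > NEG ? Mp[j] + gap_open : NEG;
      int xe = Xp[j] > NEG ? Xp[j] + gap_extend : NEG;
      if (xo >= xe) { Xc[j] = xo; if (xo > NEG) tbX[IDX(i, j)] = 0; }
      else          { Xc[j] = xe; tbX[IDX(i, j)] = 1; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  // free trailing reference gap: best cell in the last row, preferring
  // M over Y over X and the leftmost end column on ties
  int best = NEG, bj = 0, bstate = 0;
  for (int j = 0; j <= m; ++j) {
    if (Mp[j] > best) { best = Mp[j]; bj = j; bstate = 0; }
    if (Yp[j] > best) { best = Yp[j]; bj = j; bstate = 2; }
    if (Xp[j] > best) { best = Xp[j]; bj = j; bstate = 1; }
  }

  // traceback from (n, bj, bstate) using the stored predecessor states
  std::string ar, aref;
  int i = n, j = bj, st = bstate;
  while (i > 0 || (st == 2 && j > 0)) {
    if (st == 0) {
      signed char src = tbM[IDX(i, j)];
      if (src < 0) break;  // reached the M[0, j] = 0 start
      ar.push_back(read[i - 1]); aref.push_back(ref[j - 1]);
      --i; --j; st = src;
    } else if (st == 1) {
      signed char src = tbX[IDX(i, j)];
      ar.push_back(read[i - 1]); aref.push_back('-');
      --i; st = src;
    } else {
      signed char src = tbY[IDX(i, j)];
      ar.push_back('-'); aref.push_back(ref[j - 1]);
      --j; st = src;
    }
  }
  int ref_start = j;  // 0-based offset of first aligned ref base
  std::reverse(ar.begin(), ar.end());
  std::reverse(aref.begin(), aref.end());

  int ref_len = 0;
  for (char c : aref) if (c != '-') ++ref_len;

  return List::create(
    _["aln_read"] = ar,
    _["aln_ref"] = aref,
    _["ref_start"] = ref_start + 1,          // 1-based
    _["ref_end"] = ref_start + ref_len,      // 1-based inclusive
    _["score"] = best);
}

// IUPAC nucleotide code -> bitmask over A=1, C=2, G=4, T=8
static int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 1 | 4; case 'Y': return 2 | 8;
    case 'S': return 2 | 4; case 'W': return 1 | 8;
    case 'K': return 4 | 8; case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8; case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8; case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default: return 0;
  }
}

// Minimum unit-cost edit distance between `primer` (aligned end to end,
// IUPAC-aware) and any substring of `window` (window ends free).
// [[Rcpp::export(name = ".primer_edit_distance_cpp")]]
int primer_edit_distance_cpp(std::string window, std::string primer) {
  const int n = (int) window.size(), m = (int) primer.size();
  if (m == 0) stop("primer must be non-empty");
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  int best = prev[m];
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;  // free leading window skip
    int wmask = iupac_mask(window[i - 1]);
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (((iupac_mask(primer[j - 1]) & wmask) != 0) ? 0 : 1);
      int del = prev[j] + 1;     // consume window base
      int ins = cur[j - 1] + 1;  // consume primer base
      int v = sub < del ? sub : del;
      cur[j] = v < ins ? v : ins;
    }
    if (cur[m] < best) best = cur[m];  // free trailing window skip
    std::swap(prev, cur);
  }
  return best;
}
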