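#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

static inline int b2i(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// Local alignment of DNA to a reference protein with codon moves of
// length 1/2/3/4/5 nt. Non-triplet moves change the running frame offset
// and are charged a frameshift penalty; protein gaps and (triplet) DNA
// gaps use affine codon gap costs. Moves are recorded for traceback so
// the caller can count frameshift events and premature stop codons on
// the optimal path. Ties prefer the in-frame (3 nt) move so equal-score
// paths carry the fewest frameshifts.
//
// States: M (codon aligned to residue), X (gap in protein, consumes 3 nt),
// Y (gap in DNA, consumes one residue).
// [[Rcpp::export]]
List cpp_frameshift_align(std::string dna, std::string prot,
                          IntegerMatrix S, CharacterVector codon_table,
                          int gap_open, int gap_extend, int fs_pen) {
  int n = (int)dna.size(), m = (int)prot.size();
  std::string tab(64, 'X');
  for (int i = 0; i < 64; ++i) tab[i] = CHAR(STRING_ELT(codon_table, i))[0];
  // translated char for codon ending at dna position i (1-based end)
  std::vector<char> aa_end(n + 1, 'X');
  for (int i = 3; i <= n; ++i) {
    int a = b2i(dna[i - 3]), b = b2i(dna[i - 2]), c = b2i(dna[i - 1]);
    aa_end[i] = (a < 0 || b < 0 || c < 0) ? 'X' : tab[16 * a + 4 * b + c];
  }
  size_t W = (size_t)(m + 1);
  std::vector<int> M((size_t)(n + 1) * W, NEG), X((size_t)(n + 1) * W, NEG),
      Y((size_t)(n + 1) * W, NEG);
  // move code: 0 none; codon moves 1..5 = consumed nt; 6 X-open, 7 X-ext,
  // 8 Y-open, 9 Y-ext. Predecessor state packed in high bits: 0 fresh,
  // 1 M, 2 X, 3 Y.
  std::vector<unsigned char> mvM((size_t)(n + 1) * W, 0),
      mvX((size_t)(n + 1) * W, 0), mvY((size_t)(n + 1) * W, 0);
  const int codon_lens[5] = {3, 2, 4, 1, 5}; // in-frame first (tie-break)
  int best = 0, bi = 0, bj = 0;
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      size_t at = (size_t)i * W + j;
      if (j >= 1) {
        // M: align a pseudo-codon ending at i to residue j
        int bestv = NEG; unsigned char bestmv = 0;
        for (int c = 0; c < 5; ++c) {
          int len = codon_lens[c];
          if (i < len) continue;
          size_t pr = (size_t)(i - len) * W + (j - 1);
          char aa = (len >= 3) ? aa_end[i] : 'X';
          int sc = S((unsigned char)aa, (unsigned char)prot[j - 1]);
          int pen = (len == 3) ? 0 : fs_pen;
          // predecessor: best of fresh(0), M, X, Y
          int pv = 0; unsigned char ps = 0;
          if (M[pr] > pv) { pv = M[pr]; ps = 1; }
          if (X[pr] > pv) { pv = X[pr]; ps = 2; }
          if (Y[pr] > pv) { pv = Y[pr]; ps = 3; }
          if (len != 3 && ps == 0) continue; // no fresh start on a frameshift
          int v = pv + sc - pen;
          if (v > bestv) { bestv = v; bestmv = (unsigned char)((len << 2) | ps); }
        }
        M[at] = bestv; mvM[at] = bestmv;
        if (bestv > best) { best = bestv; bi = i; bj = j; }
      }
      if (i >= 3) {
        size_t pr = (size_t)(i - 3) * W + j;
        int vo = (M[pr] > NEG) ? M[pr] - gap_open - gap_extend : NEG;
        int ve = (X[pr] > NEG) ? X[pr] - gap_extend : NEG;
        if (vo >= ve) { X[at] = vo; mvX[at] = (unsigned char)((6 << 2) | 1); }
        else { X[at] = ve; mvX[at] = (unsigned char)((7 << 2) | 2); }
      }
      if (j >= 1) {
        size_t pr = (size_t)i * W + (j - 1);
        int vo = (M[pr] > NEG) ? M[pr] - gap_open - gap_extend : NEG;
        int ve = (Y[pr] > NEG) ? Y[pr] - gap_extend : NEG;
        if (vo >= ve) { Y[at] = vo; mvY[at] = (unsigned char)((8 << 2) | 1); }
        else { Y[at] = ve; mvY[at] = (unsigned char)((9 << 2) | 3); }
      }
    }
  }
  // traceback
  std::vector<int> st_len, st_j; std::vector<char> st_aa; std::vector<int> st_state;
  int i = bi, j = bj, state = 1; // end in M
  int dna_start = bi, prot_start = bj;
  if (best > 0) {
    while (state != 0) {
      size_t at = (size_t)i * W + j;
      unsigned char mv = (state == 1) ? mvM[at] : (state == 2) ? mvX[at] : mvY[at];
      int code = mv >> 2, ps = mv & 3;
      if (state == 1) {
        int len = code; // 1..5
        st_len.push_back(len); st_j.push_back(j);
        st_aa.push_back(len >= 3 ? ((i >= 3) ? 0 : 'X') : 'X');
        // recompute aa for len>=3
        if (len >= 3) {
          int a = b2i(dna[i - 3]), b = b2i(dna[i - 2]), c = b2i(dna[i - 1]);
          st_aa.back() = (a < 0 || b < 0 || c < 0) ? 'X' : tab[16 * a + 4 * b + c];
        }
        st_state.push_back(1);
        i -= len; j -= 1;
      } else if (state == 2) {
        st_len.push_back(3); st_j.push_back(j); st_aa.push_back('-');
        st_state.push_back(2);
        i -= 3;
      } else {
        st_len.push_back(0); st_j.push_back(j); st_aa.push_back('.');
        st_state.push_back(3);
        j -= 1;
      }
      state = ps;
      dna_start = i; prot_start = j;
      if (state == 0) break;
    }
  }
  int ns = (int)st_len.size();
  IntegerVector len(ns), pj(ns), stt(ns);
  CharacterVector aa(ns);
  for (int q = 0; q < ns; ++q) {
    int src = ns - 1 - q; // reverse to forward order
    len[q] = st_len[src]; pj[q] = st_j[src]; stt[q] = st_state[src];
    aa[q] = std::string(1, st_aa[src]);
  }
  return List::create(_["score"] = best, _["dna_start"] = dna_start,
                      _["dna_end"] = bi, _["prot_start"] = prot_start,
                      _["prot_end"] = bj,
                      _["steps"] = DataFrame::create(
                          _["state"] = stt, _["nt_len"] = len,
                          _["prot_pos"] = pj, _["aa"] = aa,
                          _["stringsAsFactors"] = false));
}
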