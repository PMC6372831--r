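#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// DNA base -> 2-bit index; anything but ACGT (incl. N) is -1
static inline int b2i(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static std::string codon_table_str(const CharacterVector &codon_table) {
  std::string tab(64, 'X');
  for (int i = 0; i < 64; ++i) tab[i] = CHAR(STRING_ELT(codon_table, i))[0];
  return tab;
}

// [[Rcpp::export]]
std::string cpp_translate(std::string dna, CharacterVector codon_table) {
  std::string tab = codon_table_str(codon_table);
  int n = (int)dna.size() / 3;
  std::string out(n, 'X');
  for (int i = 0; i < n; ++i) {
    int a = b2i(dna[3 * i]), b = b2i(dna[3 * i + 1]), c = b2i(dna[3 * i + 2]);
    out[i] = (a < 0 || b < 0 || c < 0) ? 'X' : tab[16 * a + 4 * b + c];
  }
  return out;
}

struct SwHit {
  int score, sstart, send, pstart, pend;
};

// Smith-Waterman on subj[ws, we) vs probe, affine gaps, origin tracking.
// S is a 128x128 score lookup indexed by ASCII code. Coordinates 0-based
// half-open. Returns the single best local alignment in the window.
static SwHit sw_best(const std::string &subj, int ws, int we,
                     const std::string &probe, const IntegerMatrix &S,
                     int go, int ge) {
  int m = (int)probe.size();
  std::vector<int> H(m + 1, 0), Hss(m + 1, 0), Hps(m + 1, 0);
  std::vector<int> E(m + 1, NEG), Ess(m + 1, 0), Eps(m + 1, 0);
  SwHit best{0, ws, ws, 0, 0};
  for (int j = ws; j < we; ++j) {
    unsigned char sc = (unsigned char)subj[j];
    int diag = 0, dss = j, dps = 0; // H(i-1, j-1) from previous column
    int F = NEG, Fss = 0, Fps = 0;  // gap consuming probe, within column
    for (int i = 1; i <= m; ++i) {
      int s = S((unsigned char)probe[i - 1], sc);
      // E(i,j): gap in probe, from previous column (H[i] not yet updated)
      int eo = H[i] - go - ge, ee = E[i] - ge;
      if (eo >= ee) { E[i] = eo; Ess[i] = Hss[i]; Eps[i] = Hps[i]; }
      else E[i] = ee;
      // diagonal candidate; a zero-score predecessor is a fresh start
      int hdiag = diag + s;
      int hd_ss = (diag == 0) ? j : dss;
      int hd_ps = (diag == 0) ? i - 1 : dps;
      // F(i,j): gap in subject, from current column row i-1 (updated)
      int fo = H[i - 1] - go - ge, fe = F - ge;
      if (fo >= fe) { F = fo; Fss = Hss[i - 1]; Fps = Hps[i - 1]; }
      else F = fe;
      // save previous-column H[i] as next row's diagonal
      int nd = H[i], nd_ss = Hss[i], nd_ps = Hps[i];
      int h = 0, hss = j, hps = i;
      if (hdiag > h) { h = hdiag; hss = hd_ss; hps = hd_ps; }
      if (E[i] > h) { h = E[i]; hss = Ess[i]; hps = Eps[i]; }
      if (F > h) { h = F; hss = Fss; hps = Fps; }
      H[i] = h; Hss[i] = hss; Hps[i] = hps;
      diag = nd; dss = nd_ss; dps = nd_ps;
      if (h > best.score) best = SwHit{h, hss, j + 1, hps, i};
    }
  }
  return best;
}

// Greedy extraction of non-overlapping (in the subject) local alignments
// scoring >= min_score within [ws, we), best first.
static void mine_window(const std::string &subj, int ws, int we,
                        const std::string &probe, const IntegerMatrix &S,
                        int go, int ge, int min_score,
                        std::vector<SwHit> &out) {
  if (we - ws < 1) return;
  SwHit h = sw_best(subj, ws, we, probe, S, go, ge);
  if (h.score < min_score || h.send <= h.sstart) return;
  out.push_back(h);
  mine_window(subj, ws, h.sstart, probe, S, go, ge, min_score, out);
  mine_window(subj, h.send, we, probe, S, go, ge, min_score, out);
}

// Seeded protein-vs-protein search of one translated frame.
// k <= 1 degenerates to exhaustive Smith-Waterman over the whole subject.
// [[Rcpp::export]]
DataFrame cpp_seeded_hits(std::string subject, std::string probe,
                          IntegerMatrix S, int k, int gap_open,
                          int gap_extend, int min_score, int pad) {
  int n = (int)subject.size(), m = (int)probe.size();
  std::vector<std::pair<int, int> > windows;
  if (k <= 1) {
    windows.push_back(std::make_pair(0, n));
  } else {
    // hash probe k-mers (7 bits per residue, k <= 9)
    std::unordered_map<uint64_t, std::vector<int> > idx;
    for (int p = 0; p + k <= m; ++p) {
      uint64_t key = 0;
      for (int t = 0; t < k; ++t) key = (key << 7) | (uint64_t)(unsigned char)probe[p + t];
      idx[key].push_back(p);
    }
    std::vector<std::pair<int, int> > raw;
    if (n >= k) {
      uint64_t key = 0, mask = (k * 7 >= 64) ? ~0ULL : ((1ULL << (7 * k)) - 1);
      for (int j = 0; j < n; ++j) {
        key = ((key << 7) | (uint64_t)(unsigned char)subject[j]) & mask;
        if (j >= k - 1) {
          std::unordered_map<uint64_t, std::vector<int> >::iterator it =
              idx.find(key);
          if (it != idx.end()) {
            int spos = j - k + 1;
            for (size_t q = 0; q < it->second.size(); ++q) {
              int p = it->second[q];
              int ws = spos - p - pad, we = spos + (m - p) + pad;
              raw.push_back(std::make_pair(ws < 0 ? 0 : ws, we > n ? n : we));
            }
          }
        }
      }
    }
    if (raw.empty())
      return DataFrame::create(_["sstart"] = IntegerVector(0),
                               _["send"] = IntegerVector(0),
                               _["pstart"] = IntegerVector(0),
                               _["pend"] = IntegerVector(0),
                               _["score"] = IntegerVector(0));
    std::sort(raw.begin(), raw.end());
    int cs = raw[0].first, ce = raw[0].second;
    for (size_t q = 1; q < raw.size(); ++q) {
      if (raw[q].first <= ce) { if (raw[q].second > ce) ce = raw[q].second; }
      else { windows.push_back(std::make_pair(cs, ce)); cs = raw[q].first; ce = raw[q].second; }
    }
    windows.push_back(std::make_pair(cs, ce));
  }
  std::vector<SwHit> hits;
  for (size_t w = 0; w < windows.size(); ++w)
    mine_window(subject, windows[w].first, windows[w].second, probe, S,
                gap_open, gap_extend, min_score, hits);
  int nh = (int)hits.size();
  IntegerVector ss(nh), se(nh), ps(nh), pe(nh), sco(nh);
  for (int i = 0; i < nh; ++i) {
    ss[i] = hits[i].sstart; se[i] = hits[i].send;
    ps[i] = hits[i].pstart; pe[i] = hits[i].pend; sco[i] = hits[i].score;
  }
  return DataFrame::create(_["sstart"] = ss, _["send"] = se, _["pstart"] = ps,
                           _["pend"] = pe, _["score"] = sco);
}
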