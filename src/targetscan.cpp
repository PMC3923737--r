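#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Expectation scoring of a mature miRNA against every window of a
// transcript. Penalties per aligned column: Watson-Crick pair 0, G:U wobble
// 0.5, mismatch 1, single-nt bulge 2; the penalty is doubled when the
// column's miRNA position (1 = miRNA 5' end) falls in the seed-proximal
// region [seed_from, seed_to]. At most one single-nt bulge (in either
// strand) per site. Sequences are DNA-alphabet uppercase.

static inline bool wc_pair(char q, char t) {
  return (q == 'A' && t == 'T') || (q == 'T' && t == 'A') ||
         (q == 'G' && t == 'C') || (q == 'C' && t == 'G');
}
static inline bool gu_pair(char q, char t) {
  return (q == 'G' && t == 'T') || (q == 'T' && t == 'G');
}

// [[Rcpp::export(name = ".scan_expectation_cpp")]]
NumericMatrix scan_expectation_cpp(std::string mirna, std::string transcript,
                                   double cutoff, int seed_from = 2,
                                   int seed_to = 13) {
  const int m = (int) mirna.size();
  const int L = (int) transcript.size();
  // miRNA written 3' -> 5' so that it lines up with the target 5' -> 3'
  std::string qr(m, 'N');
  for (int j = 0; j < m; ++j) qr[j] = mirna[m - 1 - j];
  // column weight for miRNA position pos (1-based from the 5' end)
  std::vector<double> wt(m + 2, 1.0);
  for (int pos = 1; pos <= m + 1; ++pos)
    if (pos >= seed_from && pos <= seed_to) wt[pos] = 2.0;

  std::vector<double> expct;
  std::vector<int> starts, glens, gkind, gidx, mm911;

  for (int p = 0; p + m <= L; ++p) {
    double best = R_PosInf;
    int bkind = 0, bidx = -1, blen = m;
    // ungapped
    {
      double e = 0.0;
      bool complete = true;
      for (int j = 0; j < m; ++j) {
        char q = qr[j], t = transcript[p + j];
        int pos = m - j;
        if (wc_pair(q, t)) continue;
        e += (gu_pair(q, t) ? 0.5 : 1.0) * wt[pos];
        if (e > cutoff + 4.0) { complete = false; break; } // hopeless
      }
      if (complete && e < best) { best = e; bkind = 0; bidx = -1; blen = m; }
      else if (!complete) best = e; // partial lower bound still prunes gaps
    }
    if (best > 0.0) {
      // one bulged target nt at target-window index g (window length m+1)
      if (p + m + 1 <= L) {
        for (int g = 0; g <= m; ++g) {
          int pos_g = m - g; if (pos_g < 1) pos_g = 1;
          double e = 2.0 * wt[pos_g];
          if (e >= best) continue;
          for (int j = 0; j < m && e < best; ++j) {
            char q = qr[j], t = transcript[p + (j < g ? j : j + 1)];
            int pos = m - j;
            if (wc_pair(q, t)) continue;
            e += (gu_pair(q, t) ? 0.5 : 1.0) * wt[pos];
          }
          if (e < best) { best = e; bkind = 1; bidx = g; blen = m + 1; }
        }
      }
      // one bulged miRNA nt at 3'->5' index g (window length m-1)
      for (int g = 0; g < m; ++g) {
        int pos_g = m - g;
        double e = 2.0 * wt[pos_g];
        if (e >= best) continue;
        for (int j = 0; j < m && e < best; ++j) {
          if (j == g) continue;
          char q = qr[j], t = transcript[p + (j < g ? j : j - 1)];
          int pos = m - j;
          if (wc_pair(q, t)) continue;
          e += (gu_pair(q, t) ? 0.5 : 1.0) * wt[pos];
        }
        if (e < best) { best = e; bkind = 2; bidx = g; blen = m - 1; }
      }
    }
    if (best <= cutoff) {
      // mismatch in the cleavage-deciding positions 9-11 of the best layout?
      int mm = 0;
      for (int j = 0; j < m; ++j) {
        int pos = m - j;
        if (pos < 9 || pos > 11) continue;
        int tj = j;
        if (bkind == 1 && bidx >= 0) tj = (j < bidx ? j : j + 1);
        if (bkind == 2) { if (j == bidx) continue; tj = (j < bidx ? j : j - 1); }
        char q = qr[j], t = transcript[p + tj];
        if (!wc_pair(q, t) && !gu_pair(q, t)) { mm = 1; break; }
      }
      starts.push_back(p);
      expct.push_back(best);
      glens.push_back(blen);
      gkind.push_back(bkind);
      gidx.push_back(bidx);
      mm911.push_back(mm);
    }
  }

  NumericMatrix out((int) starts.size(), 6);
  for (int i = 0; i < (int) starts.size(); ++i) {
    out(i, 0) = starts[i];
    out(i, 1) = starts[i] + glens[i];
    out(i, 2) = expct[i];
    out(i, 3) = gkind[i];
    out(i, 4) = gidx[i];
    out(i, 5) = mm911[i];
  }
  colnames(out) = CharacterVector::create("start", "end", "expectation",
                                          "gap_kind", "gap_index", "mm911");
  return out;
}
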