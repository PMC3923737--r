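#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Lightweight nearest-neighbour-style MFE folder used as the package's
// deterministic default engine. Grammar: stems with bulges/internal loops
// (joint unpaired length <= maxloop) closing hairpin loops; branching is
// allowed only in the exterior loop. Multibranch (internal) loops are not
// representable -- candidate windows are screened for a *single* hairpin,
// so the restriction is part of the screen, not a shortcut around it.

static const double INF = std::numeric_limits<double>::infinity();

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1; // N or other ambiguity: unpairable
  }
}

// pair energies, kcal/mol per closing pair
static inline double pair_energy(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -1.92; // G:C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -0.81; // A:U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return -0.49; // G:U
  return INF;
}

static inline double hairpin_penalty(int size) {
  // size = unpaired nt in the terminal loop, >= 3
  return 4.0 + 0.3 * (size - 3);
}

static inline double interior_penalty(int li, int lj) {
  if (li == 0 && lj == 0) return 0.0;           // stack
  if (li == 0 || lj == 0) return 1.0 * (li + lj); // bulge
  return 0.8 * (li + lj);                        // internal loop
}

struct FoldResult {
  std::string db;
  double mfe;
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq, int min_loop = 3, int max_loop = 10) {
  const int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = base_code(seq[i]);

  if (n == 0) return List::create(_["structure"] = "", _["mfe"] = 0.0);

  // V[i][j]: min energy of a structure closed by pair (i,j)
  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
  // trace: -1 hairpin, otherwise encoded k*n+l interior pair
  std::vector<std::vector<int> > TV(n, std::vector<int>(n, -2));

  for (int span = min_loop + 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      if (s[i] < 0 || s[j] < 0) continue;
      double pe = pair_energy(s[i], s[j]);
      if (pe == INF) continue;
      double best = hairpin_penalty(j - i - 1);
      int tb = -1;
      int kmax = std::min(j - 1, i + 1 + max_loop);
      for (int k = i + 1; k <= kmax; ++k) {
        int li = k - i - 1;
        int lmin = std::max(k + min_loop + 1, j - 1 - (max_loop - li));
        for (int l = j - 1; l >= lmin; --l) {
          if (V[k][l] == INF) continue;
          double e = interior_penalty(li, j - l - 1) + V[k][l];
          if (e < best) { best = e; tb = k * n + l; }
        }
      }
      V[i][j] = pe + best;
      TV[i][j] = tb;
    }
  }

  // exterior loop: W[j] = min energy over prefix [0..j], branching allowed
  std::vector<double> W(n + 1, 0.0);
  std::vector<int> TW(n + 1, -1); // -1: j unpaired; else i: pair (i,j)
  for (int j = 0; j < n; ++j) {
    double best = W[j]; // leave position j unpaired
    int tb = -1;
    for (int i = 0; i + min_loop + 1 <= j; ++i) {
      if (V[i][j] == INF) continue;
      double e = (i > 0 ? W[i] : 0.0) + V[i][j];
      if (e < best) { best = e; tb = i; }
    }
    W[j + 1] = best;
    TW[j + 1] = tb;
  }

  // traceback
  std::string db(n, '.');
  std::vector<std::pair<int, int> > stack;
  int j = n;
  while (j > 0) {
    int i = TW[j];
    if (i < 0) { --j; continue; }
    stack.push_back(std::make_pair(i, j - 1));
    j = i;
  }
  while (!stack.empty()) {
    std::pair<int, int> p = stack.back();
    stack.pop_back();
    int a = p.first, b = p.second;
    db[a] = '(';
    db[b] = ')';
    int tb = TV[a][b];
    if (tb >= 0) stack.push_back(std::make_pair(tb / n, tb % n));
  }

  double mfe = W[n];
  if (mfe > 0) { // empty structure is always available at 0
    mfe = 0.0;
    db.assign(n, '.');
  }
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}
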