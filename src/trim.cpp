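#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// 3' trimming: longest overlap between a suffix of the read and a prefix of
// the adapter, length >= min_overlap, tolerating <= floor(k/10) mismatches
// per overlap length k. 5' trimming mirrors the rule (read prefix vs
// adapter suffix).

static int overlap_len_3p(const std::string &read, const std::string &adapter,
                          int min_overlap) {
  int n = (int) read.size(), m = (int) adapter.size();
  int kmax = std::min(n, m);
  for (int k = kmax; k >= min_overlap; --k) {
    int mm = 0, allowed = k / 10;
    bool ok = true;
    for (int t = 0; t < k; ++t) {
      if (read[n - k + t] != adapter[t] && ++mm > allowed) { ok = false; break; }
    }
    if (ok) return k;
  }
  return 0;
}

static int overlap_len_5p(const std::string &read, const std::string &adapter,
                          int min_overlap) {
  int n = (int) read.size(), m = (int) adapter.size();
  int kmax = std::min(n, m);
  for (int k = kmax; k >= min_overlap; --k) {
    int mm = 0, allowed = k / 10;
    bool ok = true;
    for (int t = 0; t < k; ++t) {
      if (read[t] != adapter[m - k + t] && ++mm > allowed) { ok = false; break; }
    }
    if (ok) return k;
  }
  return 0;
}

// [[Rcpp::export(name = ".trim_overlaps_cpp")]]
IntegerMatrix trim_overlaps_cpp(CharacterVector reads, std::string adapter_3p,
                                std::string adapter_5p, int min_overlap = 6) {
  int n = reads.size();
  IntegerMatrix out(n, 2); // columns: 5p trim length, 3p trim length
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    int t5 = 0, t3 = 0;
    if (!adapter_5p.empty()) t5 = overlap_len_5p(r, adapter_5p, min_overlap);
    if (!adapter_3p.empty() && t5 < (int) r.size())
      t3 = overlap_len_3p(r.substr(t5), adapter_3p, min_overlap);
    out(i, 0) = t5;
    out(i, 1) = t3;
  }
  return out;
}
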