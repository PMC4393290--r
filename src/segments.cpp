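#include <Rcpp.h>
using namespace Rcpp;

// All maximal scoring subsequences (Ruzzo & Tompa) of the weight profile
// t[i] = m[i] ? (1 - purity) : -purity.
// The decomposition is intrinsic to the sequence (scan-direction
// invariant); every reported segment starts and ends on a matching
// position and has total weight > 0, i.e. match fraction >= purity.
// Weights are scaled to exact integers (purity quantized at 1e-6) so tie
// handling is deterministic. Coordinates are 0-based half-open.
// [[Rcpp::export(name = ".max_segments_cpp")]]
DataFrame max_segments_cpp(LogicalVector m, double purity) {
  int n = m.size();
  const long long SCALE = 1000000LL;
  long long wmis = -(long long)(purity * SCALE + 0.5);
  long long wmatch = SCALE + wmis;
  struct Seg { int start, end; long long L, R; int prev; };
  std::vector<Seg> st;
  long long cum = 0;
  for (int i = 0; i < n; ++i) {
    long long s = m[i] ? wmatch : wmis;
    if (s <= 0) { cum += s; continue; }
    Seg k;
    k.start = i; k.end = i + 1; k.L = cum; cum += s; k.R = cum;
    k.prev = -1;
    for (;;) {
      // find the rightmost list entry with L < k.L, following parent
      // pointers (entries skipped over all have L >= k.L), so the whole
      // scan stays amortized linear
      int j = (int)st.size() - 1;
      while (j >= 0 && st[j].L >= k.L) j = st[j].prev;
      if (j < 0) { k.prev = -1; st.push_back(k); break; }
      if (st[j].R >= k.R) { k.prev = j; st.push_back(k); break; }
      k.start = st[j].start; k.L = st[j].L; k.prev = st[j].prev;
      st.resize(j);
    }
  }
  int kk = st.size();
  IntegerVector S(kk), E(kk), NM(kk);
  NumericVector P(kk);
  for (int i = 0; i < kk; ++i) {
    int nm = 0;
    for (int j = st[i].start; j < st[i].end; ++j) if (m[j]) ++nm;
    S[i] = st[i].start; E[i] = st[i].end; NM[i] = nm;
    P[i] = (double)nm / (st[i].end - st[i].start);
  }
  return DataFrame::create(_["start"] = S, _["end"] = E,
                           _["matches"] = NM, _["purity"] = P);
}
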