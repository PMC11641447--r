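// Base-pair-level Monte-Carlo placement oracle.
//
// Breaks are (position, strand) pairs; lesions are connected components of
// the graph linking breaks closer than the clustering window. A component is
// DSB-class iff it contains an opposite-strand pair within the window.
// Placement conventions:
//   0  uniform-bp     position uniform on 1..n_bp, strand fair coin,
//                     re-hits of an occupied site collapse to one break
//   1  site-resolved  uniform over the 2*n_bp strand sites, re-hits collapse
//   2  q-ladder       the clustering ladder realized in position space: a new
//                     break starts a far-away lesion with probability q0(k)
//                     or joins a uniformly chosen existing lesion (fair-coin
//                     strand, fractional offsets inside the window); lesion
//                     anchors are spaced far apart so components and lesions
//                     coincide.
// Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <vector>
using namespace Rcpp;

namespace {

struct BreakBuf {
  std::vector<double> pos;
  std::vector<int> strand;
  void clear() { pos.clear(); strand.clear(); }
  int size() const { return (int)pos.size(); }
  // collapse duplicate (position, strand) sites
  bool add(double p, int s) {
    for (size_t i = 0; i < pos.size(); ++i)
      if (pos[i] == p && strand[i] == s) return false;
    pos.push_back(p);
    strand.push_back(s);
    return true;
  }
};

int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// counts[0..6] = ssb_s, ssb_plus, ssb_pp, ssb_ppp, dsb_s, dsb_plus, dsb_pp
void classify(const BreakBuf& b, double window, int counts[7]) {
  for (int i = 0; i < 7; ++i) counts[i] = 0;
  int n = b.size();
  if (n == 0) return;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (std::abs(b.pos[i] - b.pos[j]) <= window) {
        int ri = find_root(parent, i), rj = find_root(parent, j);
        if (ri != rj) parent[ri] = rj;
      }
  std::vector<int> size(n, 0), dsb(n, 0);
  for (int i = 0; i < n; ++i) size[find_root(parent, i)]++;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (b.strand[i] != b.strand[j] &&
          std::abs(b.pos[i] - b.pos[j]) <= window &&
          find_root(parent, i) == find_root(parent, j))
        dsb[find_root(parent, i)] = 1;
  for (int i = 0; i < n; ++i) {
    if (find_root(parent, i) != i) continue;
    int s = size[i];
    if (dsb[i]) {
      counts[s <= 2 ? 4 : (s == 3 ? 5 : 6)]++;
    } else {
      counts[s == 1 ? 0 : (s == 2 ? 1 : (s == 3 ? 2 : 3))]++;
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".sim_composition_cpp")]]
DataFrame sim_composition_cpp(int j_a, int j_b, int j_c, int n_trials,
                              int convention, int n_bp, double window,
                              NumericVector q0_for_k, double r1, double r2) {
  BreakBuf buf;
  std::vector<double> lesion_anchor;
  std::vector<int> lesion_size;
  const double anchor_step = 1000.0 * (window + 1.0);
  const double off_step = (window > 0 ? window : 1.0) / 16.0;
  std::map<uint64_t, int> tally;
  const int q0n = q0_for_k.size();

  for (int t = 0; t < n_trials; ++t) {
    buf.clear();
    lesion_anchor.clear();
    lesion_size.clear();
    int bd = j_c;

    auto place = [&]() {
      if (convention == 2) {
        int nb = buf.size();
        double q0 = q0_for_k[nb < q0n ? nb : q0n - 1];
        bool fresh = lesion_anchor.empty() || unif_rand() < q0;
        int s = unif_rand() < 0.5 ? 0 : 1;
        if (fresh) {
          double a = lesion_anchor.size() * anchor_step;
          lesion_anchor.push_back(a);
          lesion_size.push_back(1);
          buf.add(a, s);
        } else {
          int L = (int)std::floor(unif_rand() * lesion_anchor.size());
          if (L >= (int)lesion_anchor.size()) L = lesion_anchor.size() - 1;
          buf.add(lesion_anchor[L] + lesion_size[L] * off_step, s);
          lesion_size[L]++;
        }
      } else {
        int p = 1 + (int)std::floor(unif_rand() * n_bp);
        if (p > n_bp) p = n_bp;
        int s = unif_rand() < 0.5 ? 0 : 1;
        buf.add((double)p, s);
      }
    };

    for (int i = 0; i < j_a; ++i) place();
    for (int i = 0; i < j_b; ++i) {
      double u = unif_rand();
      if (u < r1) place();
      else if (u < r1 + r2) bd++;
    }

    int counts[7];
    classify(buf, window, counts);
    uint64_t key = (uint64_t)bd;
    for (int i = 0; i < 7; ++i) key = (key << 7) | (uint64_t)counts[i];
    tally[key]++;
  }

  int m = tally.size();
  IntegerVector ssb_s(m), ssb_plus(m), ssb_pp(m), ssb_ppp(m),
      dsb_s(m), dsb_plus(m), dsb_pp(m), bd_out(m), count(m);
  int i = 0;
  for (auto& kv : tally) {
    uint64_t key = kv.first;
    int c[7];
    for (int j = 6; j >= 0; --j) {
      c[j] = (int)(key & 0x7F);
      key >>= 7;
    }
    ssb_s[i] = c[0]; ssb_plus[i] = c[1]; ssb_pp[i] = c[2]; ssb_ppp[i] = c[3];
    dsb_s[i] = c[4]; dsb_plus[i] = c[5]; dsb_pp[i] = c[6];
    bd_out[i] = (int)key;
    count[i] = kv.second;
    ++i;
  }
  return DataFrame::create(
      Named("ssb_s") = ssb_s, Named("ssb_plus") = ssb_plus,
      Named("ssb_pp") = ssb_pp, Named("ssb_ppp") = ssb_ppp,
      Named("dsb_s") = dsb_s, Named("dsb_plus") = dsb_plus,
      Named("dsb_pp") = dsb_pp, Named("bd") = bd_out,
      Named("count") = count);
}

// [[Rcpp::export(name = ".estimate_q0_cpp")]]
double estimate_q0_cpp(int j, int n_trials, int n_bp, double window) {
  std::vector<double> pos(j);
  long hits = 0;
  for (int t = 0; t < n_trials; ++t) {
    for (int i = 0; i < j; ++i) {
      int p = 1 + (int)std::floor(unif_rand() * n_bp);
      if (p > n_bp) p = n_bp;
      pos[i] = (double)p;
    }
    bool clustered = false;
    for (int i = 0; i < j - 1 && !clustered; ++i)
      if (std::abs(pos[i] - pos[j - 1]) <= window) clustered = true;
    if (!clustered) hits++;
  }
  return (double)hits / (double)n_trials;
}
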