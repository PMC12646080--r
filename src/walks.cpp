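#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// Second-order (node2vec-style) biased random walks on a weighted
// undirected graph. Transition from v (having arrived from u) samples
// neighbor x with unnormalized weight w(v,x) * alpha, where alpha is
// return_w when x == u, 1 when x is adjacent to u, and inout_w otherwise.
// [[Rcpp::export(name = ".biased_walks_cpp")]]
List biased_walks_cpp(List neighbors, List weights, int n_walks,
                      int walk_length, double return_w, double inout_w,
                      double seed) {
  int n = neighbors.size();
  std::vector<std::vector<int> > nb(n);
  std::vector<std::vector<double> > wt(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = neighbors[i];
    NumericVector w = weights[i];
    nb[i].assign(v.begin(), v.end());  // 0-based, sorted
    wt[i].assign(w.begin(), w.end());
  }
  XRng rng((uint64_t)seed);
  List out(n * n_walks);
  std::vector<double> prob;
  int k = 0;
  for (int start = 0; start < n; ++start) {
    for (int r = 0; r < n_walks; ++r) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(start);
      int prev = -1;
      int cur = start;
      while ((int)walk.size() < walk_length) {
        const std::vector<int>& cnb = nb[cur];
        if (cnb.empty()) break;  // dead end: truncate
        const std::vector<double>& cwt = wt[cur];
        prob.resize(cnb.size());
        double total = 0.0;
        if (prev < 0) {
          for (size_t j = 0; j < cnb.size(); ++j) {
            prob[j] = cwt[j];
            total += prob[j];
          }
        } else {
          const std::vector<int>& pnb = nb[prev];
          for (size_t j = 0; j < cnb.size(); ++j) {
            int x = cnb[j];
            double alpha;
            if (x == prev) {
              alpha = return_w;
            } else if (std::binary_search(pnb.begin(), pnb.end(), x)) {
              alpha = 1.0;
            } else {
              alpha = inout_w;
            }
            prob[j] = cwt[j] * alpha;
            total += prob[j];
          }
        }
        if (total <= 0.0) break;
        double u = rng.unif() * total;
        double acc = 0.0;
        size_t pick = cnb.size() - 1;
        for (size_t j = 0; j < cnb.size(); ++j) {
          acc += prob[j];
          if (u < acc) { pick = j; break; }
        }
        prev = cur;
        cur = cnb[pick];
        walk.push_back(cur);
      }
      IntegerVector wv(walk.size());
      for (size_t j = 0; j < walk.size(); ++j) wv[j] = walk[j] + 1;
      out[k++] = wv;
    }
  }
  return out;
}
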