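#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// Skip-gram with negative sampling over node walks (single worker,
// deterministic given the seed). The per-token window is sampled uniformly
// in 1..window as in the reference word2vec implementation; the negative
// sampling table uses the unigram distribution raised to 3/4. Returns the
// input (center) vectors; nodes that never received an update are zeroed
// and flagged in the "trained" attribute.
// [[Rcpp::export(name = ".sgns_train_cpp")]]
NumericMatrix sgns_train_cpp(List walks, int n_nodes, int dims, int window,
                             int epochs, int negative, double alpha0,
                             double seed) {
  const int table_size = 1000000;
  const int sig_size = 1024;
  const double sig_max = 6.0;

  // token counts for the negative-sampling table
  std::vector<double> cnt(n_nodes, 0.0);
  long long total_tokens = 0;
  int n_walks = walks.size();
  std::vector<std::vector<int> > W(n_walks);
  for (int i = 0; i < n_walks; ++i) {
    IntegerVector v = walks[i];
    W[i].assign(v.begin(), v.end());
    for (size_t j = 0; j < W[i].size(); ++j) {
      W[i][j] -= 1;  // to 0-based
      cnt[W[i][j]] += 1.0;
      ++total_tokens;
    }
  }
  std::vector<int> table(table_size);
  {
    double norm = 0.0;
    for (int i = 0; i < n_nodes; ++i) norm += std::pow(cnt[i], 0.75);
    if (norm <= 0) norm = 1.0;
    double acc = std::pow(cnt[0], 0.75) / norm;
    int w = 0;
    for (int i = 0; i < table_size; ++i) {
      table[i] = w;
      if ((double)(i + 1) / table_size > acc && w < n_nodes - 1) {
        ++w;
        acc += std::pow(cnt[w], 0.75) / norm;
      }
    }
  }
  std::vector<double> sig(sig_size);
  for (int i = 0; i < sig_size; ++i) {
    double x = (2.0 * i / sig_size - 1.0) * sig_max;
    sig[i] = 1.0 / (1.0 + std::exp(-x));
  }
  XRng rng((uint64_t)seed);
  std::vector<double> syn0((size_t)n_nodes * dims);
  std::vector<double> syn1((size_t)n_nodes * dims, 0.0);
  std::vector<long long> updates(n_nodes, 0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dims;

  double processed = 0.0;
  double total_work = (double)total_tokens * epochs;
  std::vector<double> grad(dims);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int wi = 0; wi < n_walks; ++wi) {
      const std::vector<int>& walk = W[wi];
      int len = (int)walk.size();
      for (int pos = 0; pos < len; ++pos) {
        double alpha = alpha0 * (1.0 - processed / (total_work + 1.0));
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        processed += 1.0;
        int b = (int)rng.bounded((uint64_t)window);  // in 0..window-1
        int lo = pos - window + b;
        int hi = pos + window - b;
        if (lo < 0) lo = 0;
        if (hi > len - 1) hi = len - 1;
        int center = walk[pos];
        for (int cpos = lo; cpos <= hi; ++cpos) {
          if (cpos == pos) continue;
          int context = walk[cpos];
          double* v_in = &syn0[(size_t)center * dims];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = context;
              label = 1.0;
            } else {
              target = table[rng.bounded(table_size)];
              if (target == context) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * dims];
            double dot = 0.0;
            for (int j = 0; j < dims; ++j) dot += v_in[j] * v_out[j];
            double pred;
            if (dot > sig_max) pred = 1.0;
            else if (dot < -sig_max) pred = 0.0;
            else pred = sig[(int)((dot + sig_max) *
                                  (sig_size / sig_max / 2.0))];
            double g = (label - pred) * alpha;
            for (int j = 0; j < dims; ++j) {
              grad[j] += g * v_out[j];
              v_out[j] += g * v_in[j];
            }
          }
          for (int j = 0; j < dims; ++j) v_in[j] += grad[j];
          ++updates[center];
        }
      }
    }
  }
  NumericMatrix out(n_nodes, dims);
  LogicalVector trained(n_nodes);
  for (int i = 0; i < n_nodes; ++i) {
    trained[i] = updates[i] > 0;
    for (int j = 0; j < dims; ++j)
      out(i, j) = trained[i] ? syn0[(size_t)i * dims + j] : 0.0;
  }
  out.attr("trained") = trained;
  return out;
}
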