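#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Deterministic 64-bit LCG so training is bit-reproducible across
// platforms regardless of R's RNG state.
static inline uint64_t lcg_next(uint64_t &s) {
  s = s * 6364136223846793005ULL + 1442695040888963407ULL;
  return s;
}
static inline double lcg_unif(uint64_t &s) {
  return ((lcg_next(s) >> 11) & 0x1FFFFFFFFFFFFFULL) /
         9007199254740992.0; // 2^53
}

static inline double sigmoid(double x) {
  if (x > 50.0) return 1.0;
  if (x < -50.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Gradient of the per-pair SGNS objective
//   L = sum_i [ y_i log sigma(u_i . v) + (1 - y_i) log sigma(-u_i . v) ]
// with respect to the center vector v and each output vector u_i.
// Exposed for numerical verification against finite differences.
// [[Rcpp::export]]
List sgns_pair_grad_cpp(NumericVector v, NumericMatrix U,
                        IntegerVector labels) {
  int dim = v.size();
  int n = U.nrow();
  if (U.ncol() != dim || labels.size() != n)
    stop("dimension mismatch");
  NumericVector grad_v(dim);
  NumericMatrix grad_U(n, dim);
  for (int i = 0; i < n; ++i) {
    double dot = 0.0;
    for (int d = 0; d < dim; ++d) dot += U(i, d) * v[d];
    // d/dz [y log sigma(z) + (1-y) log sigma(-z)] = y - sigma(z)
    double g = (double)labels[i] - sigmoid(dot);
    for (int d = 0; d < dim; ++d) {
      grad_v[d] += g * U(i, d);
      grad_U(i, d) = g * v[d];
    }
  }
  return List::create(_["grad_v"] = grad_v, _["grad_U"] = grad_U);
}

// Skip-gram negative-sampling trainer. docs hold 0-based token ids;
// freq holds vocabulary frequencies (for the 3/4-power negative table).
// Single-threaded; fixed seed => identical output.
// [[Rcpp::export]]
List sgns_train_cpp(List docs, NumericVector freq, int dim, int window,
                    int negatives, int epochs, double lr0, double seed_d) {
  int vocab = freq.size();
  if (vocab < 2) stop("effective vocabulary must contain >= 2 tokens");
  uint64_t rng = (uint64_t)seed_d * 2654435761ULL + 104729ULL;

  // unigram^(3/4) negative-sampling table
  const int table_size = 100000;
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    std::vector<double> pw(vocab);
    for (int w = 0; w < vocab; ++w) {
      pw[w] = std::pow(freq[w], 0.75);
      total += pw[w];
    }
    int w = 0;
    double cum = pw[0] / total;
    for (int t = 0; t < table_size; ++t) {
      table[t] = w;
      if ((t + 1.0) / table_size > cum && w < vocab - 1) {
        ++w;
        cum += pw[w] / total;
      }
    }
  }

  NumericMatrix W_in(vocab, dim), W_out(vocab, dim);
  for (int w = 0; w < vocab; ++w)
    for (int d = 0; d < dim; ++d)
      W_in(w, d) = (lcg_unif(rng) - 0.5) / dim;
  // W_out starts at zero (word2vec convention)

  long long total_tokens = 0;
  int n_docs = docs.size();
  std::vector<std::vector<int>> enc(n_docs);
  for (int i = 0; i < n_docs; ++i) {
    IntegerVector d = docs[i];
    enc[i].assign(d.begin(), d.end());
    total_tokens += d.size();
  }
  long long budget = total_tokens * (long long)epochs;
  long long processed = 0;
  std::vector<double> gv(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n_docs; ++i) {
      const std::vector<int> &sent = enc[i];
      int slen = (int)sent.size();
      for (int t = 0; t < slen; ++t) {
        double lr = lr0 * (1.0 - (double)processed / (budget + 1));
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        ++processed;
        int center = sent[t];
        // window radius uniform in [1, window]
        int r = 1 + (int)(lcg_next(rng) % (uint64_t)window);
        for (int j = t - r; j <= t + r; ++j) {
          if (j < 0 || j >= slen || j == t) continue;
          int ctx = sent[j];
          std::fill(gv.begin(), gv.end(), 0.0);
          for (int k = 0; k <= negatives; ++k) {
            int target; double label;
            if (k == 0) {
              target = ctx; label = 1.0;
            } else {
              target = table[lcg_next(rng) % (uint64_t)table_size];
              if (target == ctx) continue;
              label = 0.0;
            }
            double dot = 0.0;
            for (int d = 0; d < dim; ++d)
              dot += W_out(target, d) * W_in(center, d);
            double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              gv[d] += g * W_out(target, d);
              W_out(target, d) += g * W_in(center, d);
            }
          }
          for (int d = 0; d < dim; ++d) W_in(center, d) += gv[d];
        }
      }
    }
  }
  return List::create(_["input_vectors"] = W_in,
                      _["output_vectors"] = W_out);
}
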