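// Continuous bag-of-words word2vec with negative sampling, for k-mer
// sentences. Single-threaded and deterministic for a fixed seed.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::uword;

namespace {

inline double sigmoidd(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// sentences: list of integer vectors of 1-based token ids (no OOV here:
// the vocabulary is built from the same corpus). counts: token frequency
// per vocabulary entry. Returns the V x D input-embedding matrix.
// [[Rcpp::export]]
arma::mat cpp_cbow_train(const List& sentences, const IntegerVector& counts,
                         int dim, int window, int negative, int epochs,
                         double lr0, int seed) {
  const int V = counts.size();
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  arma::mat syn0(V, dim), syn1(V, dim, arma::fill::zeros);
  for (int i = 0; i < V; ++i)
    for (int j = 0; j < dim; ++j)
      syn0(i, j) = (unif(rng) - 0.5) / dim;

  // unigram^0.75 table for negative sampling
  const int tableSize = std::max(1000000, V * 8);
  std::vector<int> table(tableSize);
  {
    double total = 0.0;
    for (int i = 0; i < V; ++i) total += std::pow((double)counts[i], 0.75);
    int i = 0;
    double cum = std::pow((double)counts[0], 0.75) / total;
    for (int a = 0; a < tableSize; ++a) {
      table[a] = i;
      if ((double)a / tableSize > cum && i < V - 1) {
        ++i;
        cum += std::pow((double)counts[i], 0.75) / total;
      }
    }
  }

  std::vector<std::vector<int>> sents;
  sents.reserve(sentences.size());
  long long totalWords = 0;
  for (R_xlen_t s = 0; s < sentences.size(); ++s) {
    IntegerVector sv = sentences[s];
    std::vector<int> v(sv.begin(), sv.end());
    totalWords += v.size();
    sents.push_back(std::move(v));
  }

  const long long trainTotal = totalWords * (long long)epochs;
  long long processed = 0;
  double lr = lr0;
  arma::rowvec neu1(dim), neu1e(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t s = 0; s < sents.size(); ++s) {
      const std::vector<int>& sent = sents[s];
      const int len = (int)sent.size();
      for (int pos = 0; pos < len; ++pos) {
        if ((processed % 10000) == 0) {
          lr = lr0 * (1.0 - (double)processed / (double)(trainTotal + 1));
          if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        }
        ++processed;
        const int target = sent[pos] - 1;
        // reduced window, as in canonical word2vec
        int b = (int)(unif(rng) * window);
        int cw = 0;
        neu1.zeros();
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          neu1 += syn0.row(sent[cpos] - 1);
          ++cw;
        }
        if (cw == 0) continue;
        neu1 /= (double)cw;
        neu1e.zeros();
        for (int d = 0; d <= negative; ++d) {
          int lab, tgt;
          if (d == 0) {
            tgt = target; lab = 1;
          } else {
            tgt = table[(int)(unif(rng) * tableSize)];
            if (tgt == target) continue;
            lab = 0;
          }
          double f = arma::dot(neu1, syn1.row(tgt));
          double g = (lab - sigmoidd(f)) * lr;
          neu1e += g * syn1.row(tgt);
          syn1.row(tgt) += g * neu1;
        }
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          syn0.row(sent[cpos] - 1) += neu1e;
        }
      }
      if ((s % 1000) == 0) Rcpp::checkUserInterrupt();
    }
  }
  return syn0;
}
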