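// Negative-sampling SGD trainers for the two embedding models:
//  - Skip-Gram over k-mer sentences (input vectors predict context words);
//  - PV-DM paragraph vectors over per-node documents (mean of paragraph +
//    context word vectors predicts the centre word).
//
// Both run single-threaded with their own mt19937 stream so that a given seed
// reproduces the result bit for bit. The exact-softmax objectives used by the
// tests live on the R side; these trainers only have to improve them.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// cumulative unigram^0.75 table for negative sampling
static std::vector<double> unigram_cdf(const std::vector<double>& counts) {
  std::vector<double> cdf(counts.size());
  double acc = 0.0;
  for (size_t i = 0; i < counts.size(); ++i) {
    acc += std::pow(counts[i], 0.75);
    cdf[i] = acc;
  }
  for (size_t i = 0; i < cdf.size(); ++i) cdf[i] /= acc;
  return cdf;
}

static inline int draw_from_cdf(const std::vector<double>& cdf, double u) {
  return (int)(std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
}

// [[Rcpp::export]]
List sg_train_cpp(const List& sentences, int V, int dim, int window,
                  int negative, int epochs, double lr, double min_lr,
                  int seed) {
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  arma::mat syn0(V, dim), syn1(V, dim, arma::fill::zeros);
  for (arma::uword i = 0; i < syn0.n_elem; ++i)
    syn0(i) = (unif(rng) - 0.5) / dim;

  std::vector<double> counts(V, 0.0);
  long long total_tokens = 0;
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector sen = sentences[s];
    total_tokens += sen.size();
    for (int i = 0; i < sen.size(); ++i) counts[sen[i]] += 1.0;
  }
  std::vector<double> cdf = unigram_cdf(counts);

  const long long total_work = (long long)epochs * std::max(total_tokens, 1LL);
  long long done = 0;
  arma::rowvec neu1e(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sen = sentences[s];
      const int L = sen.size();
      for (int t = 0; t < L; ++t) {
        double alpha = lr + (min_lr - lr) * ((double)done / (double)total_work);
        ++done;
        const int center = sen[t];
        for (int j = std::max(0, t - window); j <= std::min(L - 1, t + window);
             ++j) {
          if (j == t) continue;
          const int ctx = sen[j];
          neu1e.zeros();
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = ctx;
              label = 1.0;
            } else {
              target = draw_from_cdf(cdf, unif(rng));
              if (target == ctx) continue;
              label = 0.0;
            }
            const double f = sigmoid(arma::dot(syn1.row(target), syn0.row(center)));
            const double g = (label - f) * alpha;
            neu1e += g * syn1.row(target);
            syn1.row(target) += g * syn0.row(center);
          }
          syn0.row(center) += neu1e;
        }
      }
    }
  }
  return List::create(_["input"] = syn0, _["output"] = syn1);
}

// [[Rcpp::export]]
List pvdm_train_cpp(const List& docs, int V, int dim, int k, int negative,
                    int epochs, double lr, double min_lr, int seed) {
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  const int D = docs.size();
  arma::mat par(D, dim), win(V, dim), wout(V, dim, arma::fill::zeros);
  for (arma::uword i = 0; i < par.n_elem; ++i) par(i) = (unif(rng) - 0.5) / dim;
  for (arma::uword i = 0; i < win.n_elem; ++i) win(i) = (unif(rng) - 0.5) / dim;

  std::vector<double> counts(V, 0.0);
  long long total_pos = 0;
  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    for (int i = 0; i < doc.size(); ++i) counts[doc[i]] += 1.0;
    total_pos += std::max(0, (int)doc.size() - 2 * k);
  }
  std::vector<double> cdf = unigram_cdf(counts);

  const long long total_work = (long long)epochs * std::max(total_pos, 1LL);
  long long done = 0;
  const double nctx = 2.0 * k + 1.0; // 2k context words + the paragraph vector
  arma::rowvec ctx(dim), neu1e(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < D; ++d) {
      IntegerVector doc = docs[d];
      const int T = doc.size();
      // only centres with a complete window on both sides are predicted
      for (int t = k; t <= T - 1 - k; ++t) {
        double alpha = lr + (min_lr - lr) * ((double)done / (double)total_work);
        ++done;
        ctx = par.row(d);
        for (int j = t - k; j <= t + k; ++j) {
          if (j == t) continue;
          ctx += win.row(doc[j]);
        }
        ctx /= nctx;
        const int center = doc[t];
        neu1e.zeros();
        for (int nd = 0; nd <= negative; ++nd) {
          int target;
          double label;
          if (nd == 0) {
            target = center;
            label = 1.0;
          } else {
            target = draw_from_cdf(cdf, unif(rng));
            if (target == center) continue;
            label = 0.0;
          }
          const double f = sigmoid(arma::dot(wout.row(target), ctx));
          const double g = (label - f) * alpha;
          neu1e += g * wout.row(target);
          wout.row(target) += g * ctx;
        }
        neu1e /= nctx; // mean-combined context: split the gradient
        par.row(d) += neu1e;
        for (int j = t - k; j <= t + k; ++j) {
          if (j == t) continue;
          win.row(doc[j]) += neu1e;
        }
      }
    }
  }
  return List::create(_["paragraph"] = par, _["word"] = win, _["output"] = wout);
}
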