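#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

// one 32-bit draw per uniform (uniform_real_distribution consumes two)
static inline double unif01(std::mt19937 &rng) {
  return rng() * (1.0 / 4294967296.0);
}

// Collapsed Gibbs sampler for latent Dirichlet allocation on a
// documents-by-vocabulary count matrix. Point estimates are posterior means
// of the smoothed document-topic and topic-word proportions over
// post-burn-in sweeps. The log-likelihood trace is the collapsed joint
// log p(w, z) up to terms constant in z. The K = 2 case (the package's
// dysbiotic/normobiotic model) takes a specialized inner loop.
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerMatrix counts, int K, double alpha, double eta,
                   int n_iter, int burn_in, int seed) {
  const int D = counts.nrow();
  const int V = counts.ncol();

  // expand cells into tokens
  std::vector<int> tok_d, tok_w;
  long total = 0;
  for (int d = 0; d < D; ++d)
    for (int w = 0; w < V; ++w) total += counts(d, w);
  tok_d.reserve(total);
  tok_w.reserve(total);
  for (int d = 0; d < D; ++d)
    for (int w = 0; w < V; ++w)
      for (int c = 0; c < counts(d, w); ++c) {
        tok_d.push_back(d);
        tok_w.push_back(w);
      }
  const long N = (long)tok_d.size();

  std::mt19937 rng((unsigned int)seed);

  std::vector<int> z(N);
  std::vector<double> ndk((size_t)D * K, 0.0), nkw((size_t)K * V, 0.0),
      nk(K, 0.0), nd(D, 0.0);
  for (long i = 0; i < N; ++i) {
    int k = (int)(unif01(rng) * K);
    if (k == K) k = K - 1;
    z[i] = k;
    ndk[(size_t)tok_d[i] * K + k] += 1.0;
    nkw[(size_t)k * V + tok_w[i]] += 1.0;
    nk[k] += 1.0;
    nd[tok_d[i]] += 1.0;
  }

  NumericMatrix theta_sum(D, K), phi_sum(K, V);
  NumericVector loglik(n_iter);
  std::vector<double> p(K);
  int kept = 0;
  const double Veta = V * eta;

  for (int it = 0; it < n_iter; ++it) {
    if (K == 2) {
      double *nkw0 = nkw.data(), *nkw1 = nkw.data() + V;
      for (long i = 0; i < N; ++i) {
        const int d = tok_d[i], w = tok_w[i], old = z[i];
        double *nd_ = ndk.data() + (size_t)d * 2;
        if (old == 0) { nd_[0] -= 1.0; nkw0[w] -= 1.0; nk[0] -= 1.0; }
        else          { nd_[1] -= 1.0; nkw1[w] -= 1.0; nk[1] -= 1.0; }
        const double p0 = (nd_[0] + alpha) * (nkw0[w] + eta) / (nk[0] + Veta);
        const double p1 = (nd_[1] + alpha) * (nkw1[w] + eta) / (nk[1] + Veta);
        const int k = (unif01(rng) * (p0 + p1) > p0) ? 1 : 0;
        z[i] = k;
        if (k == 0) { nd_[0] += 1.0; nkw0[w] += 1.0; nk[0] += 1.0; }
        else        { nd_[1] += 1.0; nkw1[w] += 1.0; nk[1] += 1.0; }
      }
    } else {
      for (long i = 0; i < N; ++i) {
        const int d = tok_d[i], w = tok_w[i], old = z[i];
        ndk[(size_t)d * K + old] -= 1.0;
        nkw[(size_t)old * V + w] -= 1.0;
        nk[old] -= 1.0;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          p[k] = (ndk[(size_t)d * K + k] + alpha) *
                 (nkw[(size_t)k * V + w] + eta) / (nk[k] + Veta);
          tot += p[k];
        }
        double u = unif01(rng) * tot;
        int k = 0;
        for (; k < K - 1; ++k) {
          u -= p[k];
          if (u <= 0.0) break;
        }
        z[i] = k;
        ndk[(size_t)d * K + k] += 1.0;
        nkw[(size_t)k * V + w] += 1.0;
        nk[k] += 1.0;
      }
    }

    double ll = 0.0;
    for (int k = 0; k < K; ++k) {
      for (int w = 0; w < V; ++w) ll += std::lgamma(nkw[(size_t)k * V + w] + eta);
      ll -= std::lgamma(nk[k] + Veta);
    }
    for (int d = 0; d < D; ++d) {
      for (int k = 0; k < K; ++k) ll += std::lgamma(ndk[(size_t)d * K + k] + alpha);
      ll -= std::lgamma(nd[d] + K * alpha);
    }
    loglik[it] = ll;

    if (it >= burn_in) {
      ++kept;
      for (int d = 0; d < D; ++d)
        for (int k = 0; k < K; ++k)
          theta_sum(d, k) += (ndk[(size_t)d * K + k] + alpha) / (nd[d] + K * alpha);
      for (int k = 0; k < K; ++k)
        for (int w = 0; w < V; ++w)
          phi_sum(k, w) += (nkw[(size_t)k * V + w] + eta) / (nk[k] + Veta);
    }
  }

  if (kept > 0) {
    for (int d = 0; d < D; ++d)
      for (int k = 0; k < K; ++k) theta_sum(d, k) /= kept;
    for (int k = 0; k < K; ++k)
      for (int w = 0; w < V; ++w) phi_sum(k, w) /= kept;
  }

  return List::create(_["doc_topic"] = theta_sum, _["topic_word"] = phi_sum,
                      _["loglik"] = loglik, _["n_tokens"] = (double)N);
}

// Fold-in: Gibbs sampling of topic assignments for new documents with the
// topic-word distributions held fixed; collapsed only in the document-topic
// proportions. Documents are conditionally independent given phi.
// [[Rcpp::export]]
NumericMatrix lda_fold_in_cpp(IntegerMatrix counts, NumericMatrix phi,
                              double alpha, int n_iter, int burn_in,
                              int seed) {
  const int D = counts.nrow();
  const int V = counts.ncol();
  const int K = phi.nrow();

  std::mt19937 rng((unsigned int)seed);
  NumericMatrix theta_sum(D, K);
  std::vector<double> p(K);

  for (int d = 0; d < D; ++d) {
    std::vector<int> tw, z;
    for (int w = 0; w < V; ++w)
      for (int c = 0; c < counts(d, w); ++c) tw.push_back(w);
    const long n = (long)tw.size();
    std::vector<double> ndk(K, 0.0);
    z.resize(n);
    for (long i = 0; i < n; ++i) {
      int k = (int)(unif01(rng) * K);
      if (k == K) k = K - 1;
      z[i] = k;
      ndk[k] += 1.0;
    }
    int kept = 0;
    for (int it = 0; it < n_iter; ++it) {
      for (long i = 0; i < n; ++i) {
        const int w = tw[i], old = z[i];
        ndk[old] -= 1.0;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          p[k] = (ndk[k] + alpha) * phi(k, w);
          tot += p[k];
        }
        double u = unif01(rng) * tot;
        int k = 0;
        for (; k < K - 1; ++k) {
          u -= p[k];
          if (u <= 0.0) break;
        }
        z[i] = k;
        ndk[k] += 1.0;
      }
      if (it >= burn_in) {
        ++kept;
        for (int k = 0; k < K; ++k)
          theta_sum(d, k) += (ndk[k] + alpha) / (n + K * alpha);
      }
    }
    if (kept > 0)
      for (int k = 0; k < K; ++k) theta_sum(d, k) /= kept;
  }
  return theta_sum;
}
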