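// Latent Dirichlet allocation: collapsed Gibbs estimation over documents and
// a deterministic fixed-point fold-in for sentence-level topic inference.
// Randomness comes from R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// words: 0-based vocabulary ids over all documents, docPtr: offsets per doc.
// [[Rcpp::export(name = ".lda_gibbs")]]
List lda_gibbs(IntegerVector words, IntegerVector docPtr, int K, int V,
               double alpha, double eta, int nIter) {
  const int D = docPtr.size() - 1;
  const int N = words.size();
  std::vector<int> z(N), nkw(K * V, 0), nk(K, 0), ndk(D * K, 0);

  for (int d = 0; d < D; ++d)
    for (int i = docPtr[d]; i < docPtr[d + 1]; ++i) {
      int k = (int)(unif_rand() * K);
      if (k >= K) k = K - 1;
      z[i] = k;
      ++nkw[k + words[i] * K];
      ++nk[k];
      ++ndk[d * K + k];
    }

  std::vector<double> p(K);
  const double Veta = V * eta;
  for (int it = 0; it < nIter; ++it) {
    for (int d = 0; d < D; ++d) {
      int* nd = &ndk[d * K];
      for (int i = docPtr[d]; i < docPtr[d + 1]; ++i) {
        const int wv = words[i];
        int k = z[i];
        --nkw[k + wv * K]; --nk[k]; --nd[k];
        double tot = 0.0;
        const int* col = &nkw[wv * K];
        for (int kk = 0; kk < K; ++kk) {
          p[kk] = (nd[kk] + alpha) * (col[kk] + eta) / (nk[kk] + Veta);
          tot += p[kk];
        }
        double u = unif_rand() * tot, acc = 0.0;
        k = K - 1;
        for (int kk = 0; kk < K; ++kk) {
          acc += p[kk];
          if (u <= acc) { k = kk; break; }
        }
        z[i] = k;
        ++nkw[k + wv * K]; ++nk[k]; ++nd[k];
      }
    }
  }

  NumericMatrix phi(K, V);
  for (int v = 0; v < V; ++v)
    for (int k = 0; k < K; ++k)
      phi(k, v) = (nkw[k + v * K] + eta) / (nk[k] + Veta);
  IntegerMatrix docTopic(D, K);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) docTopic(d, k) = ndk[d * K + k];
  return List::create(_["phi"] = phi, _["docTopic"] = docTopic);
}

// Deterministic fold-in: EM fixed point for the topic mixture of each short
// word-id sequence under fixed topic-word distributions.
// sentWords: list of 0-based in-vocabulary word-id vectors.
// [[Rcpp::export(name = ".lda_infer")]]
NumericMatrix lda_infer(NumericMatrix phi, List sentWords, double alpha,
                        int nIter) {
  const int K = phi.nrow();
  const int nSent = sentWords.size();
  NumericMatrix theta(nSent, K);
  std::vector<double> th(K), acc(K), q(K);
  for (int s = 0; s < nSent; ++s) {
    IntegerVector wv = sentWords[s];
    const int n = wv.size();
    if (n == 0) {
      for (int k = 0; k < K; ++k) theta(s, k) = 1.0 / K;
      continue;
    }
    for (int k = 0; k < K; ++k) th[k] = 1.0 / K;
    for (int it = 0; it < nIter; ++it) {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int t = 0; t < n; ++t) {
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          q[k] = th[k] * phi(k, wv[t]);
          tot += q[k];
        }
        if (tot <= 0) continue;
        for (int k = 0; k < K; ++k) acc[k] += q[k] / tot;
      }
      double tn = 0.0;
      for (int k = 0; k < K; ++k) {
        th[k] = acc[k] + alpha;
        tn += th[k];
      }
      for (int k = 0; k < K; ++k) th[k] /= tn;
    }
    for (int k = 0; k < K; ++k) theta(s, k) = th[k];
  }
  return theta;
}
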