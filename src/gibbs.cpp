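#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA. theta and phi are integrated out; each
// token's topic is resampled from
//   p(z = k) ∝ (n_dk^(-i) + alpha) (n_kw^(-i) + beta) / (n_k^(-i) + V beta).
// Tokens are visited in document order, then token order, both at
// initialization and in every sweep; all randomness comes from R's RNG, so a
// prior set.seed() makes the run bit-reproducible.
//
// doc, word: 0-based parallel token streams.
// [[Rcpp::export]]
List gibbs_lda_cpp(IntegerVector doc, IntegerVector word,
                   int n_docs, int n_vocab, int n_topics,
                   double alpha, double beta, int iterations) {
  const int N = doc.size();
  IntegerVector z(N);
  IntegerMatrix ndk(n_docs, n_topics), nkw(n_topics, n_vocab);
  IntegerVector nk(n_topics), nd(n_docs);
  RNGScope scope;

  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * n_topics);
    if (k == n_topics) k = n_topics - 1;
    z[i] = k;
    ndk(doc[i], k)++; nkw(k, word[i])++; nk[k]++; nd[doc[i]]++;
  }

  std::vector<double> p(n_topics);
  const double vbeta = n_vocab * beta;
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      int k = z[i];
      ndk(d, k)--; nkw(k, w)--; nk[k]--;
      double tot = 0.0;
      for (int t = 0; t < n_topics; ++t) {
        p[t] = (ndk(d, t) + alpha) * (nkw(t, w) + beta) / (nk[t] + vbeta);
        tot += p[t];
      }
      double u = unif_rand() * tot, cum = 0.0;
      k = n_topics - 1;
      for (int t = 0; t < n_topics; ++t) {
        cum += p[t];
        if (u < cum) { k = t; break; }
      }
      z[i] = k;
      ndk(d, k)++; nkw(k, w)++; nk[k]++;
    }
  }

  return List::create(_["z"] = z, _["n_dk"] = ndk, _["n_kw"] = nkw,
                      _["n_k"] = nk, _["n_d"] = nd);
}
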