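#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// xorshift64* PRNG: deterministic across platforms and standard libraries.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  double unif() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    uint64_t x = s * 0x2545F4914F6CDD1DULL;
    return (x >> 11) * (1.0 / 9007199254740992.0);  // [0, 1)
  }
};

static int sample_cat(const std::vector<double>& p, double tot, double u) {
  double cum = 0.0;
  int K = (int)p.size();
  for (int k = 0; k < K; ++k) {
    cum += p[k];
    if (u * tot <= cum) return k;
  }
  return K - 1;
}

// Collapsed Gibbs sampler for LDA. docs: list of 0-based word-id vectors.
// [[Rcpp::export]]
List gibbs_lda_cpp(List docs, int K, int V, double alpha, double beta,
                   int iters, int seed) {
  int M = docs.size();
  XorShift rng((uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL);
  IntegerMatrix nkw(K, V);
  IntegerMatrix ndk(M, K);
  std::vector<int> nk(K, 0);
  std::vector<std::vector<int>> z(M), w(M);
  for (int d = 0; d < M; ++d) {
    IntegerVector wd = docs[d];
    int N = wd.size();
    z[d].resize(N);
    w[d].assign(wd.begin(), wd.end());
    for (int j = 0; j < N; ++j) {
      int t = (int)(rng.unif() * K);
      if (t >= K) t = K - 1;
      z[d][j] = t;
      nkw(t, wd[j])++; ndk(d, t)++; nk[t]++;
    }
  }
  std::vector<double> p(K);
  for (int it = 0; it < iters; ++it) {
    for (int d = 0; d < M; ++d) {
      int N = (int)w[d].size();
      for (int j = 0; j < N; ++j) {
        int wid = w[d][j], t = z[d][j];
        nkw(t, wid)--; ndk(d, t)--; nk[t]--;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          p[k] = (nkw(k, wid) + beta) / (nk[k] + V * beta) *
                 (ndk(d, k) + alpha);
          tot += p[k];
        }
        int t2 = sample_cat(p, tot, rng.unif());
        z[d][j] = t2;
        nkw(t2, wid)++; ndk(d, t2)++; nk[t2]++;
      }
    }
  }
  List zl(M);
  for (int d = 0; d < M; ++d)
    zl[d] = IntegerVector(z[d].begin(), z[d].end());
  return List::create(_["nkw"] = nkw, _["ndk"] = ndk,
                      _["nk"] = IntegerVector(nk.begin(), nk.end()),
                      _["z"] = zl);
}

// Fold-in sampling for held-out documents: topic-word statistics are held
// fixed at the training counts; only document-topic counts are sampled.
// [[Rcpp::export]]
IntegerMatrix gibbs_foldin_cpp(List docs, IntegerMatrix nkw, IntegerVector nk,
                               int K, int V, double alpha, double beta,
                               int iters, int seed) {
  int M = docs.size();
  XorShift rng((uint64_t)seed * 2862933555777941757ULL + 3037000493ULL);
  IntegerMatrix ndk(M, K);
  std::vector<std::vector<int>> z(M), w(M);
  std::vector<double> phi_col(K);
  for (int d = 0; d < M; ++d) {
    IntegerVector wd = docs[d];
    int N = wd.size();
    z[d].resize(N);
    w[d].assign(wd.begin(), wd.end());
    for (int j = 0; j < N; ++j) {
      int t = (int)(rng.unif() * K);
      if (t >= K) t = K - 1;
      z[d][j] = t;
      ndk(d, t)++;
    }
  }
  std::vector<double> p(K);
  for (int it = 0; it < iters; ++it) {
    for (int d = 0; d < M; ++d) {
      int N = (int)w[d].size();
      for (int j = 0; j < N; ++j) {
        int wid = w[d][j], t = z[d][j];
        ndk(d, t)--;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          p[k] = (nkw(k, wid) + beta) / (nk[k] + V * beta) *
                 (ndk(d, k) + alpha);
          tot += p[k];
        }
        int t2 = sample_cat(p, tot, rng.unif());
        z[d][j] = t2;
        ndk(d, t2)++;
      }
    }
  }
  return ndk;
}
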