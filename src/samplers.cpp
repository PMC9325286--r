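// Collapsed Gibbs samplers (LDA topic model, Dirichlet-process multinomial
// mixture), the stochastic-gradient layout optimizer used by the UMAP
// reduction, and PV-DBOW document-embedding training.
//
// All routines use a private xorshift128+ RNG seeded from R so results are
// bit-reproducible and independent of R's global RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct XorShift128 {
  uint64_t s0, s1;
  explicit XorShift128(uint64_t seed) {
    // splitmix64 initialization
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    auto next = [&z]() {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      return t ^ (t >> 31);
    };
    s0 = next();
    s1 = next();
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int unif_int(int n) { return (int)(next() % (uint64_t)n); }
};

int sample_discrete(const std::vector<double>& w, double total,
                    XorShift128& rng) {
  double u = rng.unif() * total;
  double acc = 0.0;
  for (size_t k = 0; k < w.size(); ++k) {
    acc += w[k];
    if (u <= acc) return (int)k;
  }
  return (int)w.size() - 1;
}

} // namespace

// ---------------------------------------------------------------------------
// LDA collapsed Gibbs sampler.
// words/docs: flat token stream (0-based word ids, 0-based doc ids).
// Returns the final document-topic and topic-word count matrices.
// [[Rcpp::export(name = ".lda_gibbs")]]
List lda_gibbs_cpp(IntegerVector words, IntegerVector docs,
                   int n_docs, int vocab_size, int K,
                   double alpha, double beta, int n_iter,
                   int seed) {
  const int N = words.size();
  XorShift128 rng((uint64_t)seed);
  std::vector<int> z(N);
  std::vector<std::vector<int>> ndk(n_docs, std::vector<int>(K, 0));
  std::vector<std::vector<int>> nkw(K, std::vector<int>(vocab_size, 0));
  std::vector<int> nk(K, 0);

  for (int i = 0; i < N; ++i) {
    int t = rng.unif_int(K);
    z[i] = t;
    ndk[docs[i]][t]++;
    nkw[t][words[i]]++;
    nk[t]++;
  }
  std::vector<double> p(K);
  const double Vbeta = vocab_size * beta;
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < N; ++i) {
      const int d = docs[i], w = words[i], old = z[i];
      ndk[d][old]--;
      nkw[old][w]--;
      nk[old]--;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = (ndk[d][k] + alpha) * (nkw[k][w] + beta) / (nk[k] + Vbeta);
        tot += p[k];
      }
      int t = sample_discrete(p, tot, rng);
      z[i] = t;
      ndk[d][t]++;
      nkw[t][w]++;
      nk[t]++;
    }
  }
  IntegerMatrix out(n_docs, K);
  for (int d = 0; d < n_docs; ++d)
    for (int k = 0; k < K; ++k) out(d, k) = ndk[d][k];
  IntegerMatrix tw(K, vocab_size);
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < vocab_size; ++w) tw(k, w) = nkw[k][w];
  return List::create(Named("ndk") = out, Named("nkw") = tw);
}

// ---------------------------------------------------------------------------
// Collapsed Gibbs sampler for the Dirichlet-process multinomial mixture
// (GSDPMM). Documents are bags of (word id, count) pairs in CSR layout.
// A new cluster may be opened at any sweep (capped at K_max); emptied
// clusters are recycled. Returns 0-based cluster labels from the final
// sweep (not compacted).
// [[Rcpp::export(name = ".gsdpmm_gibbs")]]
IntegerVector gsdpmm_gibbs_cpp(IntegerVector doc_ptr, IntegerVector word_id,
                               NumericVector word_ct, int vocab_size,
                               double alpha, double beta, int K_max,
                               int n_iter, int seed) {
  const int D = doc_ptr.size() - 1;
  XorShift128 rng((uint64_t)seed);

  std::vector<int> z(D, -1);
  std::vector<int> m_z(K_max, 0);            // docs per cluster
  std::vector<double> n_z(K_max, 0.0);       // tokens per cluster
  std::vector<std::vector<double>> n_zw(K_max,
                                        std::vector<double>(vocab_size, 0.0));
  std::vector<double> doc_len(D, 0.0);
  for (int d = 0; d < D; ++d)
    for (int j = doc_ptr[d]; j < doc_ptr[d + 1]; ++j)
      doc_len[d] += word_ct[j];

  const double Vbeta = vocab_size * beta;

  auto add_doc = [&](int d, int k, int sign) {
    m_z[k] += sign;
    n_z[k] += sign * doc_len[d];
    for (int j = doc_ptr[d]; j < doc_ptr[d + 1]; ++j)
      n_zw[k][word_id[j]] += sign * word_ct[j];
  };

  // One-cluster initialization: the first sweep then redistributes. This
  // matches the "start with all documents together" variant and makes the
  // identical-documents collapse case exact.
  for (int d = 0; d < D; ++d) {
    z[d] = 0;
    add_doc(d, 0, +1);
  }

  std::vector<double> logp(K_max + 1);
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int d = 0; d < D; ++d) {
      add_doc(d, z[d], -1);
      z[d] = -1;

      int n_occ = 0;
      int free_k = -1;
      for (int k = 0; k < K_max; ++k) {
        if (m_z[k] > 0) n_occ++;
        else if (free_k < 0) free_k = k;
      }
      int n_cand = 0;
      double maxlp = -1e300;
      std::vector<int> cand;
      cand.reserve(K_max + 1);
      for (int k = 0; k < K_max; ++k) {
        if (m_z[k] == 0) continue;
        double lp = std::log((double)m_z[k]);
        for (int j = doc_ptr[d]; j < doc_ptr[d + 1]; ++j) {
          const double base = n_zw[k][word_id[j]] + beta;
          lp += std::lgamma(base + word_ct[j]) - std::lgamma(base);
        }
        lp += std::lgamma(n_z[k] + Vbeta) -
              std::lgamma(n_z[k] + Vbeta + doc_len[d]);
        logp[n_cand] = lp;
        cand.push_back(k);
        if (lp > maxlp) maxlp = lp;
        n_cand++;
      }
      if (free_k >= 0) { // propose a new cluster
        double lp = std::log(alpha);
        for (int j = doc_ptr[d]; j < doc_ptr[d + 1]; ++j)
          lp += std::lgamma(beta + word_ct[j]) - std::lgamma(beta);
        lp += std::lgamma(Vbeta) - std::lgamma(Vbeta + doc_len[d]);
        logp[n_cand] = lp;
        cand.push_back(free_k);
        if (lp > maxlp) maxlp = lp;
        n_cand++;
      }
      std::vector<double> w(n_cand);
      double tot = 0.0;
      for (int c = 0; c < n_cand; ++c) {
        w[c] = std::exp(logp[c] - maxlp);
        tot += w[c];
      }
      int pick = cand[sample_discrete(w, tot, rng)];
      z[d] = pick;
      add_doc(d, pick, +1);
    }
  }
  return IntegerVector(z.begin(), z.end());
}

// ---------------------------------------------------------------------------
// Stochastic-gradient layout optimization for the UMAP reduction:
// attraction along graph edges, repulsion against negative samples.
// emb is modified in place (n x d, row-major access via matrix indexing).
// [[Rcpp::export(name = ".umap_optimize")]]
NumericMatrix umap_optimize_cpp(NumericMatrix emb, IntegerVector head,
                                IntegerVector tail,
                                NumericVector epochs_per_sample,
                                double a, double b, double gamma,
                                double initial_alpha, int n_epochs,
                                int negative_sample_rate, int seed) {
  const int n = emb.nrow(), d = emb.ncol();
  const int n_edges = head.size();
  XorShift128 rng((uint64_t)seed);

  std::vector<double> epoch_of_next_sample(epochs_per_sample.begin(),
                                           epochs_per_sample.end());
  std::vector<double> epochs_per_negative(n_edges);
  std::vector<double> epoch_of_next_negative(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    epochs_per_negative[e] = epochs_per_sample[e] / negative_sample_rate;
    epoch_of_next_negative[e] = epochs_per_negative[e];
  }

  auto clip = [](double v) {
    if (v > 4.0) return 4.0;
    if (v < -4.0) return -4.0;
    return v;
  };

  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    const double alpha =
        initial_alpha * (1.0 - (double)(epoch - 1) / (double)n_epochs);
    for (int e = 0; e < n_edges; ++e) {
      if (epoch_of_next_sample[e] > epoch) continue;
      const int i = head[e], j = tail[e];
      double dist2 = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = emb(i, c) - emb(j, c);
        dist2 += diff * diff;
      }
      double grad_coeff = 0.0;
      if (dist2 > 0.0) {
        grad_coeff = -2.0 * a * b * std::pow(dist2, b - 1.0) /
                     (a * std::pow(dist2, b) + 1.0);
      }
      for (int c = 0; c < d; ++c) {
        const double g = clip(grad_coeff * (emb(i, c) - emb(j, c)));
        emb(i, c) += alpha * g;
        emb(j, c) -= alpha * g;
      }
      epoch_of_next_sample[e] += epochs_per_sample[e];

      int n_neg = (int)((epoch - epoch_of_next_negative[e]) /
                        epochs_per_negative[e]) + 1;
      if (n_neg < 0) n_neg = 0;
      for (int p = 0; p < n_neg; ++p) {
        const int k = rng.unif_int(n);
        if (k == i) continue;
        double nd2 = 0.0;
        for (int c = 0; c < d; ++c) {
          const double diff = emb(i, c) - emb(k, c);
          nd2 += diff * diff;
        }
        double gcoef;
        if (nd2 > 0.0) {
          gcoef = 2.0 * gamma * b /
                  ((0.001 + nd2) * (a * std::pow(nd2, b) + 1.0));
        } else {
          gcoef = 0.0;
        }
        for (int c = 0; c < d; ++c) {
          double g;
          if (gcoef > 0.0) g = clip(gcoef * (emb(i, c) - emb(k, c)));
          else g = 4.0;
          emb(i, c) += alpha * g;
        }
      }
      epoch_of_next_negative[e] += n_neg * epochs_per_negative[e];
    }
  }
  return emb;
}

// ---------------------------------------------------------------------------
// PV-DBOW document-embedding training with negative sampling: the document
// vector predicts each of its words; word output vectors are shared.
// [[Rcpp::export(name = ".doc2vec_train")]]
NumericMatrix doc2vec_train_cpp(IntegerVector words, IntegerVector docs,
                                IntegerVector neg_table, int n_docs,
                                int vocab_size, int dim, int epochs,
                                double alpha0, int negative, int seed) {
  const int N = words.size();
  XorShift128 rng((uint64_t)seed);
  std::vector<double> D((size_t)n_docs * dim);
  std::vector<double> W((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < D.size(); ++i)
    D[i] = (rng.unif() - 0.5) / dim;

  const int table_n = neg_table.size();
  const double alpha_min = 1e-4;
  long long total_steps = (long long)epochs * N, step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < N; ++i, ++step) {
      double alpha = alpha0 * (1.0 - (double)step / (double)total_steps);
      if (alpha < alpha_min) alpha = alpha_min;
      double* dv = &D[(size_t)docs[i] * dim];
      for (int s = 0; s <= negative; ++s) {
        int target;
        double label;
        if (s == 0) {
          target = words[i];
          label = 1.0;
        } else {
          target = neg_table[rng.unif_int(table_n)];
          if (target == words[i]) continue;
          label = 0.0;
        }
        double* wv = &W[(size_t)target * dim];
        double dot = 0.0;
        for (int c = 0; c < dim; ++c) dot += dv[c] * wv[c];
        const double pred = 1.0 / (1.0 + std::exp(-dot));
        const double g = (label - pred) * alpha;
        for (int c = 0; c < dim; ++c) {
          const double dvc = dv[c];
          dv[c] += g * wv[c];
          wv[c] += g * dvc;
        }
      }
    }
  }
  NumericMatrix out(n_docs, dim);
  for (int dcc = 0; dcc < n_docs; ++dcc)
    for (int c = 0; c < dim; ++c) out(dcc, c) = D[(size_t)dcc * dim + c];
  return out;
}
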