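// Two-locus gametic-association test: EM haplotype-frequency estimation
// under linkage vs the product of single-locus frequencies, with a
// permutation null obtained by shuffling one locus's genotypes across
// individuals. Written in C++ because the permutation scan refits the EM
// for every draw.
#include <Rcpp.h>
#include <random>
using namespace Rcpp;

namespace {

struct TwoLocusEM {
  int kA, kB, n;
  // joint genotype category counts: gen1 in [0, kA*(kA+1)/2), gen2 likewise
  std::vector<double> h;      // haplotype freqs, kA x kB (row-major a*kB+b)
  std::vector<double> counts; // work array

  TwoLocusEM(int kA_, int kB_) : kA(kA_), kB(kB_) {}

  // genotypes as 0-based sorted pairs (a<=b), per category with count w
  double loglik(const std::vector<double>& hh,
                const std::vector<std::array<int, 5>>& cats) const {
    double ll = 0.0;
    for (const auto& c : cats) {
      int a = c[0], b = c[1], cc = c[2], d = c[3], w = c[4];
      double p;
      bool het1 = a != b, het2 = cc != d;
      if (het1 && het2)
        p = 2.0 * hh[a * kB + cc] * hh[b * kB + d] +
            2.0 * hh[a * kB + d] * hh[b * kB + cc];
      else if (het1)
        p = 2.0 * hh[a * kB + cc] * hh[b * kB + cc];
      else if (het2)
        p = 2.0 * hh[a * kB + cc] * hh[a * kB + d];
      else
        p = hh[a * kB + cc] * hh[a * kB + cc];
      if (p <= 0) p = 1e-300;
      ll += w * std::log(p);
    }
    return ll;
  }

  // fit by EM from independence start; returns maximized log-likelihood
  double fit(const std::vector<std::array<int, 5>>& cats,
             const std::vector<double>& pA, const std::vector<double>& pB,
             int n_ind, int max_iter = 200, double tol = 1e-10) {
    h.assign(kA * kB, 0.0);
    for (int a = 0; a < kA; ++a)
      for (int b = 0; b < kB; ++b) h[a * kB + b] = pA[a] * pB[b];
    counts.assign(kA * kB, 0.0);
    for (int it = 0; it < max_iter; ++it) {
      std::fill(counts.begin(), counts.end(), 0.0);
      for (const auto& c : cats) {
        int a = c[0], b = c[1], cc = c[2], d = c[3];
        double w = c[4];
        bool het1 = a != b, het2 = cc != d;
        if (het1 && het2) {
          double w1 = h[a * kB + cc] * h[b * kB + d];
          double w2 = h[a * kB + d] * h[b * kB + cc];
          double t = w1 + w2;
          if (t <= 0) { w1 = w2 = 0.5; t = 1.0; }
          counts[a * kB + cc] += w * w1 / t;
          counts[b * kB + d] += w * w1 / t;
          counts[a * kB + d] += w * w2 / t;
          counts[b * kB + cc] += w * w2 / t;
        } else {
          counts[a * kB + cc] += w;
          counts[b * kB + d] += w;
        }
      }
      double maxdiff = 0.0;
      double denom = 2.0 * n_ind;
      for (int i = 0; i < kA * kB; ++i) {
        double nh = counts[i] / denom;
        maxdiff = std::max(maxdiff, std::fabs(nh - h[i]));
        h[i] = nh;
      }
      if (maxdiff < tol) break;
    }
    return loglik(h, cats);
  }
};

// collapse per-individual genotypes into joint categories
void make_cats(const std::vector<int>& a, const std::vector<int>& b,
               const std::vector<int>& c, const std::vector<int>& d,
               const std::vector<int>& order2, int kA, int kB,
               std::vector<std::array<int, 5>>& cats,
               std::vector<int>& key_count) {
  std::fill(key_count.begin(), key_count.end(), 0);
  int n = a.size();
  int span = kB * kB;
  for (int i = 0; i < n; ++i) {
    int j = order2[i];
    int key = ((a[i] * kA + b[i]) * kB + c[j]) * kB + d[j];
    key_count[key]++;
  }
  cats.clear();
  for (size_t key = 0; key < key_count.size(); ++key) {
    if (!key_count[key]) continue;
    int d_ = key % kB, c_ = (key / kB) % kB;
    int b_ = (key / span) % kA, a_ = key / (span * kA);
    cats.push_back({a_, b_, c_, d_, key_count[key]});
  }
}

}  // namespace

// [[Rcpp::export(name = ".ld_perm_cpp")]]
List ld_perm_cpp(IntegerVector g1a, IntegerVector g1b,
                 IntegerVector g2a, IntegerVector g2b,
                 int kA, int kB, int n_perm, int max_exceed,
                 int seed) {
  int n = g1a.size();
  std::vector<int> a(n), b(n), c(n), d(n);
  std::vector<double> pA(kA, 0.0), pB(kB, 0.0);
  for (int i = 0; i < n; ++i) {
    a[i] = std::min(g1a[i], g1b[i]) - 1;
    b[i] = std::max(g1a[i], g1b[i]) - 1;
    c[i] = std::min(g2a[i], g2b[i]) - 1;
    d[i] = std::max(g2a[i], g2b[i]) - 1;
    pA[a[i]] += 1; pA[b[i]] += 1;
    pB[c[i]] += 1; pB[d[i]] += 1;
  }
  for (int j = 0; j < kA; ++j) pA[j] /= 2.0 * n;
  for (int j = 0; j < kB; ++j) pB[j] /= 2.0 * n;

  std::vector<int> order2(n);
  for (int i = 0; i < n; ++i) order2[i] = i;
  std::vector<std::array<int, 5>> cats;
  std::vector<int> key_count(kA * kA * kB * kB, 0);
  TwoLocusEM em(kA, kB);

  make_cats(a, b, c, d, order2, kA, kB, cats, key_count);
  // null log-likelihood: product of single-locus HWE frequencies; its value
  // is permutation-invariant because both margins are preserved
  std::vector<double> h0(kA * kB);
  for (int x = 0; x < kA; ++x)
    for (int y = 0; y < kB; ++y) h0[x * kB + y] = pA[x] * pB[y];
  double ll0 = em.loglik(h0, cats);
  double ll1 = em.fit(cats, pA, pB, n);
  double lr_obs = 2.0 * (ll1 - ll0);

  NumericVector h_obs(kA * kB);
  for (int i = 0; i < kA * kB; ++i) h_obs[i] = em.h[i];

  std::mt19937 rng(seed);
  int exceed = 0, done = 0;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle of locus-2 genotype assignment
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> u(0, i);
      std::swap(order2[i], order2[u(rng)]);
    }
    make_cats(a, b, c, d, order2, kA, kB, cats, key_count);
    double ll0p = em.loglik(h0, cats);
    double lr = 2.0 * (em.fit(cats, pA, pB, n) - ll0p);
    ++done;
    if (lr >= lr_obs - 1e-9) ++exceed;
    if (exceed >= max_exceed) break;
  }
  double pval = (1.0 + exceed) / (done + 1.0);
  return List::create(_["lr"] = lr_obs, _["p"] = pval,
                      _["n_perm_done"] = done, _["exceed"] = exceed,
                      _["haplotype_freqs"] = h_obs);
}
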