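// Latent-ancestry sweep of the admixture-model Gibbs sampler: samples the
// cluster of origin of every observed allele copy given (q, P) and returns
// the per-individual and per-cluster/locus/allele count summaries plus the
// marginal log-likelihood ln Pr(X | P, q). Uses R's RNG so chains are
// reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".admix_zstep_cpp")]]
List admix_zstep(NumericMatrix q, NumericVector P,
                 IntegerMatrix A1, IntegerMatrix A2,
                 LogicalVector upd, int K, int L) {
  int n = q.nrow();
  NumericMatrix Nik(n, K);
  NumericVector m(K * L * 3);  // array dim (K, L, 3), column-major
  double ll = 0.0;
  std::vector<double> w(K);
  RNGScope scope;
  for (int copy = 0; copy < 2; ++copy) {
    const IntegerMatrix& A = copy == 0 ? A1 : A2;
    for (int l = 0; l < L; ++l) {
      for (int i = 0; i < n; ++i) {
        int a = A(i, l);
        if (a == 0) continue;  // missing
        int pbase = K * l + K * L * (a - 1);
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          w[k] = q(i, k) * P[k + pbase];
          tot += w[k];
        }
        ll += std::log(tot);
        double u = unif_rand() * tot;
        int z = 0;
        double acc = w[0];
        while (u > acc && z < K - 1) { ++z; acc += w[z]; }
        Nik(i, z) += 1.0;
        if (upd[i]) m[z + pbase] += 1.0;
      }
    }
  }
  return List::create(_["Nik"] = Nik, _["m"] = m, _["loglik"] = ll);
}
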