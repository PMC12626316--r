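#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the independent-allele-frequency admixture model.
//
// geno: N x (2L) integer matrix of allele indices, 1..A[l] per locus,
//       0 = missing (columns l and L+l are the two copies at locus l).
// Latent origins z for each allele copy are sampled from
//   Pr(z = k) prop. to q_i[k] * P[k][l][a];
// cluster allele frequencies from Dirichlet(lambda + counts), lambda = 1;
// individual ancestry q_i from Dirichlet(alpha + origin counts), alpha = 1.
// Uses R's RNG so results are reproducible under set.seed().

static double rgamma1(double shape) { return R::rgamma(shape, 1.0); }

// [[Rcpp::export(name = ".gibbs_admixture_cpp")]]
List gibbs_admixture_cpp(IntegerMatrix geno, IntegerVector n_alleles,
                         int K, int sweeps, int burnin,
                         double alpha, double lambda) {
  const int N = geno.nrow();
  const int L = n_alleles.size();
  RNGScope scope;

  // allele frequencies P[k][l][a], ragged over loci
  std::vector<std::vector<std::vector<double>>> P(K);
  for (int k = 0; k < K; ++k) {
    P[k].resize(L);
    for (int l = 0; l < L; ++l)
      P[k][l].assign(n_alleles[l], 1.0 / n_alleles[l]);
  }
  NumericMatrix Q(N, K);
  std::fill(Q.begin(), Q.end(), 1.0 / K);
  IntegerMatrix z(N, 2 * L);          // origin of each allele copy
  NumericMatrix Qsum(N, K);
  std::vector<double> lnl;
  lnl.reserve(std::max(sweeps - burnin, 0));
  std::vector<double> prob(K), qacc(K);

  for (int s = 0; s < sweeps; ++s) {
    // 1. sample origins z
    if (K > 1) {
      for (int i = 0; i < N; ++i) {
        for (int c = 0; c < 2 * L; ++c) {
          int a = geno(i, c);
          if (a == 0) continue;
          int l = c % L;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q(i, k) * P[k][l][a - 1];
            tot += prob[k];
          }
          double u = unif_rand() * tot, acc = 0.0;
          int pick = K - 1;
          for (int k = 0; k < K; ++k) {
            acc += prob[k];
            if (u <= acc) { pick = k; break; }
          }
          z(i, c) = pick;
        }
      }
    }
    // 2. sample P | z
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < L; ++l) {
        std::vector<double> cnt(n_alleles[l], lambda);
        for (int i = 0; i < N; ++i) {
          for (int c = l; c < 2 * L; c += L) {
            int a = geno(i, c);
            if (a != 0 && z(i, c) == k) cnt[a - 1] += 1.0;
          }
        }
        double tot = 0.0;
        for (int a = 0; a < n_alleles[l]; ++a) {
          P[k][l][a] = rgamma1(cnt[a]);
          tot += P[k][l][a];
        }
        for (int a = 0; a < n_alleles[l]; ++a) P[k][l][a] /= tot;
      }
    }
    // 3. sample q_i | z
    if (K > 1) {
      for (int i = 0; i < N; ++i) {
        for (int k = 0; k < K; ++k) qacc[k] = alpha;
        for (int c = 0; c < 2 * L; ++c)
          if (geno(i, c) != 0) qacc[z(i, c)] += 1.0;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          prob[k] = rgamma1(qacc[k]);
          tot += prob[k];
        }
        for (int k = 0; k < K; ++k) Q(i, k) = prob[k] / tot;
      }
    }
    // 4. retained sweeps: accumulate Q and the data log-likelihood
    if (s >= burnin) {
      double ll = 0.0;
      for (int i = 0; i < N; ++i) {
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
        for (int c = 0; c < 2 * L; ++c) {
          int a = geno(i, c);
          if (a == 0) continue;
          int l = c % L;
          double m = 0.0;
          for (int k = 0; k < K; ++k) m += Q(i, k) * P[k][l][a - 1];
          ll += std::log(m);
        }
      }
      lnl.push_back(ll);
    }
  }

  int kept = (int)lnl.size();
  NumericMatrix Qmean(N, K);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k)
      Qmean(i, k) = (K == 1) ? 1.0 : Qsum(i, k) / kept;

  // final-state P, flattened to a list of matrices (locus -> allele)
  List Pout(K);
  for (int k = 0; k < K; ++k) {
    List Pk(L);
    for (int l = 0; l < L; ++l) Pk[l] = NumericVector(P[k][l].begin(), P[k][l].end());
    Pout[k] = Pk;
  }
  return List::create(_["Q"] = Qmean, _["P"] = Pout,
                      _["lnl"] = NumericVector(lnl.begin(), lnl.end()));
}
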