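#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the no-LD admixture model (independent allele
// frequencies, symmetric Dirichlet priors):
//   z_ilc | q_i              ~ Categorical(q_i)
//   a_ilc | z_ilc = k        ~ Categorical(p_kl.)
//   p_kl. ~ Dirichlet(lambda), q_i ~ Dirichlet(alpha)
// Allele codes are 0-based per locus; NA = missing call (contributes
// nothing to the likelihood). Uses R's RNG, so set.seed() on the R side
// makes runs reproducible.
// [[Rcpp::export(name = ".admixture_gibbs_cpp")]]
List admixture_gibbs_cpp(IntegerMatrix c1, IntegerMatrix c2,
                         IntegerVector n_alleles, int K,
                         int burnin, int sweeps,
                         double alpha, double lambda) {
  int n = c1.nrow(), L = c1.ncol();
  if (K < 1) stop("K must be >= 1");

  // allele frequencies: per locus a K x A_l matrix (flattened)
  std::vector<NumericMatrix> P(L);
  for (int l = 0; l < L; ++l) {
    P[l] = NumericMatrix(K, n_alleles[l]);
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int a = 0; a < n_alleles[l]; ++a) {
        double g = R::rgamma(lambda, 1.0);
        P[l](k, a) = g; s += g;
      }
      for (int a = 0; a < n_alleles[l]; ++a) P[l](k, a) /= s;
    }
  }
  NumericMatrix Q(n, K);
  std::fill(Q.begin(), Q.end(), 1.0 / K);

  NumericMatrix qsum(n, K);
  std::vector<NumericMatrix> psum(L);
  for (int l = 0; l < L; ++l) psum[l] = NumericMatrix(K, n_alleles[l]);
  int total = burnin + sweeps;
  NumericVector lnl(sweeps);
  std::vector<double> prob(K);
  // latent-origin count buffers
  NumericMatrix qcnt(n, K);
  std::vector<NumericMatrix> pcnt(L);
  for (int l = 0; l < L; ++l) pcnt[l] = NumericMatrix(K, n_alleles[l]);

  for (int it = 0; it < total; ++it) {
    std::fill(qcnt.begin(), qcnt.end(), 0.0);
    for (int l = 0; l < L; ++l)
      std::fill(pcnt[l].begin(), pcnt[l].end(), 0.0);
    bool track = it >= burnin;
    double ll = 0.0;

    // sample latent origins; the categorical normalizer is the per-copy
    // likelihood under the current (P, Q), accumulated for ln P(D)
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int copy = 0; copy < 2; ++copy) {
          int a = (copy == 0) ? c1(i, l) : c2(i, l);
          if (a == NA_INTEGER) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q(i, k) * P[l](k, a);
            s += prob[k];
          }
          if (track) ll += std::log(s);
          double u = unif_rand() * s, acc = 0.0;
          int z = K - 1;
          for (int k = 0; k < K; ++k) {
            acc += prob[k];
            if (u <= acc) { z = k; break; }
          }
          qcnt(i, z) += 1.0;
          pcnt[l](z, a) += 1.0;
        }
      }
    }
    // update allele frequencies
    for (int l = 0; l < L; ++l) {
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int a = 0; a < n_alleles[l]; ++a) {
          double g = R::rgamma(lambda + pcnt[l](k, a), 1.0);
          P[l](k, a) = g; s += g;
        }
        for (int a = 0; a < n_alleles[l]; ++a) P[l](k, a) /= s;
      }
    }
    // update ancestry proportions
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + qcnt(i, k), 1.0);
        Q(i, k) = g; s += g;
      }
      for (int k = 0; k < K; ++k) Q(i, k) /= s;
    }
    if (track) {
      lnl[it - burnin] = ll;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) qsum(i, k) += Q(i, k);
      for (int l = 0; l < L; ++l)
        for (int k = 0; k < K; ++k)
          for (int a = 0; a < n_alleles[l]; ++a)
            psum[l](k, a) += P[l](k, a);
    }
  }
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += qsum(i, k);
    for (int k = 0; k < K; ++k) qsum(i, k) /= s;
  }
  List pmean(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix pm = psum[l];
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < n_alleles[l]; ++a) pm(k, a) /= sweeps;
    pmean[l] = pm;
  }
  return List::create(_["lnl"] = lnl, _["q_mean"] = qsum,
                      _["p_mean"] = pmean);
}
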