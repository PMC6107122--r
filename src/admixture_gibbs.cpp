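// Gibbs sampler for the admixture model with independent Dirichlet(lambda)
// allele-frequency priors: latent allele-origin indicators Z, cluster allele
// frequencies P, per-individual admixture proportions Q, and a Metropolis
// step for the symmetric Dirichlet hyperparameter alpha (uniform prior on
// (0, alpha_max]). Supervised individuals (label > 0) have Z fixed to their
// labeled cluster so their gene copies anchor that cluster's frequencies.
#include <Rcpp.h>
using namespace Rcpp;

static double rgamma_pos(double shape) {
  double x = R::rgamma(shape, 1.0);
  return (x > 1e-300) ? x : 1e-300;
}

// [[Rcpp::export(name = ".admixture_gibbs")]]
List admixture_gibbs(IntegerMatrix geno,     // n x 2L, allele index, 0 = missing
                     IntegerVector n_alleles, // per locus
                     int K, int burnin, int reps, int thin,
                     double lambda, double alpha_init, double alpha_max,
                     double alpha_prop_sd, IntegerVector labels,
                     int alpha_all) {
  const int n = geno.nrow();
  const int L = n_alleles.size();
  if (geno.ncol() != 2 * L) stop("genotype matrix has wrong width");
  if (K < 1) stop("K must be >= 1");
  if (n < 1) stop("empty genotype matrix");

  std::vector<int> offset(L, 0);
  int Atot = 0;
  for (int l = 0; l < L; ++l) { offset[l] = Atot; Atot += n_alleles[l]; }

  // P[k][offset + a], Q(i,k), Z(i, 2l+c)
  std::vector<std::vector<double> > P(K, std::vector<double>(Atot, 0.0));
  NumericMatrix Q(n, K);
  IntegerMatrix Z(n, 2 * L);
  double alpha = alpha_init;

  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;
    for (int j = 0; j < 2 * L; ++j) {
      if (labels[i] > 0) Z(i, j) = labels[i] - 1;
      else Z(i, j) = (int)std::floor(unif_rand() * K) % K;
    }
  }

  std::vector<std::vector<double> > counts(K, std::vector<double>(Atot));
  std::vector<double> qcnt(K), prob(K);
  NumericMatrix Qsum(n, K);
  std::vector<double> lnl_trace;
  lnl_trace.reserve(reps / thin + 1);
  int n_unsup = 0;
  for (int i = 0; i < n; ++i) if (labels[i] == 0) ++n_unsup;

  const int total = burnin + reps;
  for (int sweep = 0; sweep < total; ++sweep) {
    // P update from current Z
    for (int k = 0; k < K; ++k)
      std::fill(counts[k].begin(), counts[k].end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a > 0) counts[Z(i, 2 * l + c)][offset[l] + a - 1] += 1.0;
        }
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double s = 0.0;
        for (int a = 0; a < n_alleles[l]; ++a) {
          double x = rgamma_pos(lambda + counts[k][offset[l] + a]);
          P[k][offset[l] + a] = x; s += x;
        }
        for (int a = 0; a < n_alleles[l]; ++a) P[k][offset[l] + a] /= s;
      }

    // Q update from current Z
    for (int i = 0; i < n; ++i) {
      std::fill(qcnt.begin(), qcnt.end(), 0.0);
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < 2; ++c)
          if (geno(i, 2 * l + c) > 0) qcnt[Z(i, 2 * l + c)] += 1.0;
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double x = rgamma_pos(alpha + qcnt[k]);
        Q(i, k) = x; s += x;
      }
      for (int k = 0; k < K; ++k) Q(i, k) /= s;
    }

    // Z update
    for (int i = 0; i < n; ++i) {
      if (labels[i] > 0) continue;            // anchored gene copies
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a <= 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q(i, k) * P[k][offset[l] + a - 1];
            s += prob[k];
          }
          double u = unif_rand() * s, acc = 0.0;
          int pick = K - 1;
          for (int k = 0; k < K; ++k) {
            acc += prob[k];
            if (u <= acc) { pick = k; break; }
          }
          Z(i, 2 * l + c) = pick;
        }
    }

    // alpha Metropolis step (only meaningful for K > 1)
    if (K > 1 && alpha_prop_sd > 0.0) {
      double alpha_new = alpha + norm_rand() * alpha_prop_sd;
      if (alpha_new > 0.0 && alpha_new <= alpha_max) {
        double logr = 0.0;
        double c_old = R::lgammafn(K * alpha) - K * R::lgammafn(alpha);
        double c_new = R::lgammafn(K * alpha_new) - K * R::lgammafn(alpha_new);
        // by default alpha is informed by the individuals whose ancestry is
        // actually free; anchored reference individuals would drag it to zero
        for (int i = 0; i < n; ++i) {
          if (!alpha_all && n_unsup > 0 && labels[i] != 0) continue;
          double slq = 0.0;
          for (int k = 0; k < K; ++k) slq += std::log(Q(i, k));
          logr += (c_new - c_old) + (alpha_new - alpha) * slq;
        }
        if (std::log(unif_rand()) < logr) alpha = alpha_new;
      }
    }

    if (sweep >= burnin && ((sweep - burnin) % thin == 0)) {
      // mixture log-likelihood of the data given (P, Q)
      double lnl = 0.0;
      for (int i = 0; i < n; ++i)
        for (int l = 0; l < L; ++l)
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a <= 0) continue;
            double s = 0.0;
            for (int k = 0; k < K; ++k)
              s += Q(i, k) * P[k][offset[l] + a - 1];
            lnl += std::log(s > 1e-300 ? s : 1e-300);
          }
      lnl_trace.push_back(lnl);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
    }
  }

  const double m = (double)lnl_trace.size();
  NumericMatrix Qmean(n, K);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { Qmean(i, k) = Qsum(i, k) / m; s += Qmean(i, k); }
    for (int k = 0; k < K; ++k) Qmean(i, k) /= s;
  }
  return List::create(_["Q"] = Qmean,
                      _["lnl_trace"] = NumericVector(lnl_trace.begin(),
                                                     lnl_trace.end()),
                      _["alpha"] = alpha);
}
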