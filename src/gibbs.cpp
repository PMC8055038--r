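// Data-augmentation Gibbs sampler for the probit 2PL deprivation-index
// model. This mirrors the R reference steps (step_latent_utilities,
// step_theta, step_item_params, step_hyper) call for call, consuming R's
// RNG in the same order, so a chain run here is bit-identical to a chain
// run through the R steps at the same seed.

#include <Rcpp.h>
using namespace Rcpp;

// standard-normal draw truncated to (a, Inf); inverse CDF in log space
static inline double rtnorm_lower(double a, double u) {
  double log_sa = R::pnorm(a, 0.0, 1.0, 0, 1);       // log S(a)
  double z = R::qnorm(std::log(u) + log_sa, 0.0, 1.0, 0, 1);
  return z < a ? a : z;
}

// standard-normal draw truncated to (-Inf, b)
static inline double rtnorm_upper(double b, double u) {
  double log_fb = R::pnorm(b, 0.0, 1.0, 1, 1);       // log F(b)
  double z = R::qnorm(std::log(u) + log_fb, 0.0, 1.0, 1, 1);
  return z > b ? b : z;
}

// [[Rcpp::export(name = ".gibbs_chain")]]
List gibbs_chain(IntegerMatrix X, IntegerVector k_idx, int K,
                 NumericMatrix alpha0, NumericMatrix beta0,
                 NumericVector theta0,
                 bool hierarchical,
                 NumericMatrix prior_mean_alpha, NumericMatrix prior_var_alpha,
                 NumericMatrix prior_mean_beta, NumericMatrix prior_var_beta,
                 NumericVector mu_a0, NumericVector tau2_a0,
                 NumericVector mu_b0, NumericVector tau2_b0,
                 double hyper_mean_sd, double tau_shape, double tau_scale,
                 NumericMatrix prop_chol,
                 int iterations, int burn_in, int thin) {
  const int N = X.nrow(), J = X.ncol();
  const int n_keep = (iterations - burn_in) / thin;

  NumericMatrix alpha(clone(alpha0)), beta(clone(beta0));
  NumericVector theta(clone(theta0));
  NumericVector mu_a(clone(mu_a0)), tau2_a(clone(tau2_a0));
  NumericVector mu_b(clone(mu_b0)), tau2_b(clone(tau2_b0));

  NumericVector d_alpha(n_keep * J * K), d_beta(n_keep * J * K);
  NumericMatrix d_theta(n_keep, N);
  NumericMatrix d_mu_a(hierarchical ? n_keep : 0, hierarchical ? J : 0);
  NumericMatrix d_tau2_a(hierarchical ? n_keep : 0, hierarchical ? J : 0);
  NumericMatrix d_mu_b(hierarchical ? n_keep : 0, hierarchical ? J : 0);
  NumericMatrix d_tau2_b(hierarchical ? n_keep : 0, hierarchical ? J : 0);

  std::vector<double> xstar(N * (size_t)J);
  // rowsum() in R accumulates in plain double, unlike rowSums/colSums
  std::vector<double> n_k(K), S1(K), S2(K);
  std::vector<double> Y0(J * (size_t)K), Y1(J * (size_t)K);
  std::vector<double> sumb2(K), sumba(K);

  RNGScope scope;
  int s_out = 0;
  for (int it = 1; it <= iterations; ++it) {
    // ---- latent utilities: column-major, matching runif(N*J) in R ----
    for (int j = 0; j < J; ++j) {
      for (int i = 0; i < N; ++i) {
        int k = k_idx[i] - 1;
        double eta = alpha(j, k) + beta(j, k) * theta[i];
        double u = R::runif(0.0, 1.0);
        double z = (X(i, j) == 1) ? rtnorm_lower(-eta, u)
                                  : rtnorm_upper(-eta, u);
        xstar[i + (size_t)N * j] = eta + z;
      }
    }

    // ---- theta | rest ----
    // long-double accumulation mirrors R's rowSums/colSums internals
    for (int k = 0; k < K; ++k) {
      long double sb2 = 0.0, sba = 0.0;
      for (int j = 0; j < J; ++j) {
        sb2 += beta(j, k) * beta(j, k);
        sba += beta(j, k) * alpha(j, k);
      }
      sumb2[k] = (double)sb2; sumba[k] = (double)sba;
    }
    for (int i = 0; i < N; ++i) {
      int k = k_idx[i] - 1;
      long double acc = 0.0;
      for (int j = 0; j < J; ++j)
        acc += xstar[i + (size_t)N * j] * beta(j, k);
      double s = (double)acc - sumba[k];
      double V = 1.0 / (1.0 + sumb2[k]);
      theta[i] = R::rnorm(V * s, std::sqrt(V));
    }

    // ---- item parameters | rest ----
    std::fill(n_k.begin(), n_k.end(), 0.0);
    std::fill(S1.begin(), S1.end(), 0.0);
    std::fill(S2.begin(), S2.end(), 0.0);
    std::fill(Y0.begin(), Y0.end(), 0.0);
    std::fill(Y1.begin(), Y1.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      int k = k_idx[i] - 1;
      n_k[k] += 1.0; S1[k] += theta[i]; S2[k] += theta[i] * theta[i];
      for (int j = 0; j < J; ++j) {
        double xs = xstar[i + (size_t)N * j];
        Y0[j + (size_t)J * k] += xs;
        Y1[j + (size_t)J * k] += xs * theta[i];
      }
    }
    for (int k = 0; k < K; ++k) {
      double nk = n_k[k], s1 = S1[k], s2 = S2[k];
      if (nk < 2.0) stop("every province needs at least 2 individuals");
      if (s2 - s1 * s1 / nk < 1e-12)
        stop("degenerate design: all traits equal within a province");
      for (int j = 0; j < J; ++j) {
        double ma = hierarchical ? mu_a[j] : prior_mean_alpha(j, k);
        double va = hierarchical ? tau2_a[j] : prior_var_alpha(j, k);
        double mb = hierarchical ? mu_b[j] : prior_mean_beta(j, k);
        double vb = hierarchical ? tau2_b[j] : prior_var_beta(j, k);
        double P11 = nk + 1.0 / va;
        double P22 = s2 + 1.0 / vb;
        double P12 = s1;
        double det = P11 * P22 - P12 * P12;
        double C11 = P22 / det, C22 = P11 / det, C12 = -P12 / det;
        double h1 = Y0[j + (size_t)J * k] + ma / va;
        double h2 = Y1[j + (size_t)J * k] + mb / vb;
        double m1 = C11 * h1 + C12 * h2;
        double m2 = C12 * h1 + C22 * h2;
        // beta from its positive-truncated joint marginal (one runif),
        // then alpha | beta from the exact Gaussian conditional
        double sdb = std::sqrt(C22);
        double u = R::runif(0.0, 1.0);
        double b = m2 + sdb * rtnorm_lower((0.0 - m2) / sdb, u);
        double cm = m1 + C12 / C22 * (b - m2);
        double cv = C11 - C12 * C12 / C22;
        alpha(j, k) = R::rnorm(cm, std::sqrt(cv));
        beta(j, k) = b;
      }
    }

    // ---- marginal refresh of the item parameters (collapsed over x*) ----
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < J; ++j) {
        double z1 = R::norm_rand();
        double z2 = R::norm_rand();
        double u = R::unif_rand();
        double L11 = prop_chol((size_t)k * J + j, 0);
        double L21 = prop_chol((size_t)k * J + j, 1);
        double L22 = prop_chol((size_t)k * J + j, 2);
        double a0c = alpha(j, k), b0c = beta(j, k);
        double a1 = a0c + L11 * z1;
        double b1 = b0c + L21 * z1 + L22 * z2;
        if (b1 <= 0) continue;
        long double ll0 = 0.0, ll1 = 0.0;
        for (int i = 0; i < N; ++i) {
          if (k_idx[i] - 1 != k) continue;
          double s = (X(i, j) == 1) ? 1.0 : -1.0;
          ll0 += R::pnorm(s * (a0c + b0c * theta[i]), 0.0, 1.0, 1, 1);
          ll1 += R::pnorm(s * (a1 + b1 * theta[i]), 0.0, 1.0, 1, 1);
        }
        double ma = hierarchical ? mu_a[j] : prior_mean_alpha(j, k);
        double va = hierarchical ? tau2_a[j] : prior_var_alpha(j, k);
        double mb = hierarchical ? mu_b[j] : prior_mean_beta(j, k);
        double vb = hierarchical ? tau2_b[j] : prior_var_beta(j, k);
        double d0a = a0c - ma, d0b = b0c - mb, d1a = a1 - ma, d1b = b1 - mb;
        double lp0 = -0.5 * (d0a * d0a) / va - 0.5 * (d0b * d0b) / vb;
        double lp1 = -0.5 * (d1a * d1a) / va - 0.5 * (d1b * d1b) / vb;
        if (std::log(u) < ((double)ll1 + lp1) - ((double)ll0 + lp0)) {
          alpha(j, k) = a1;
          beta(j, k) = b1;
        }
      }
    }

    // ---- hyperparameters | rest (hierarchical) ----
    if (hierarchical) {
      for (int rep = 0; rep < 2; ++rep) {
        NumericMatrix &val = rep == 0 ? alpha : beta;
        NumericVector &mu = rep == 0 ? mu_a : mu_b;
        NumericVector &tau2 = rep == 0 ? tau2_a : tau2_b;
        // vectorized rnorm(J) first, then rgamma(J), matching step_hyper
        for (int j = 0; j < J; ++j) {
          long double vacc = 0.0;
          for (int k = 0; k < K; ++k) vacc += val(j, k);
          double vbar = (double)(vacc / K);
          double pv = 1.0 / (K / tau2[j] + 1.0 / (hyper_mean_sd * hyper_mean_sd));
          double pm = pv * (K * vbar / tau2[j]);
          mu[j] = R::rnorm(pm, std::sqrt(pv));
        }
        for (int j = 0; j < J; ++j) {
          long double ssacc = 0.0;
          for (int k = 0; k < K; ++k) {
            double d = val(j, k) - mu[j];
            ssacc += d * d;
          }
          double ss = (double)ssacc;
          // stats::rgamma(shape, rate) == R::rgamma(shape, 1/rate)
          double g = R::rgamma(tau_shape + K / 2.0,
                               1.0 / (tau_scale + ss / 2.0));
          tau2[j] = 1.0 / g;
        }
      }
    }

    // ---- recentering move (translation along the likelihood-invariant
    //      orbit theta -> theta - c, alpha -> alpha + beta c) ----
    {
      long double sb2v = 0.0, sbam = 0.0;
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < J; ++j) {
          double ma = hierarchical ? mu_a[j] : prior_mean_alpha(j, k);
          double va = hierarchical ? tau2_a[j] : prior_var_alpha(j, k);
          sb2v += beta(j, k) * beta(j, k) / va;
          sbam += (beta(j, k) * (alpha(j, k) - ma)) / va;
        }
      long double sth = 0.0;
      for (int i = 0; i < N; ++i) sth += theta[i];
      double P = N + (double)sb2v;
      double muc = ((double)sth - (double)sbam) / P;
      double c0 = R::rnorm(muc, std::sqrt(1.0 / P));
      for (int i = 0; i < N; ++i) theta[i] -= c0;
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < J; ++j) alpha(j, k) += beta(j, k) * c0;
    }

    // ---- scale move (Metropolis along theta -> theta/s, beta -> s beta) ----
    {
      long double sth2 = 0.0;
      for (int i = 0; i < N; ++i) sth2 += theta[i] * theta[i];
      double sum_th2 = (double)sth2;
      double npar = (double)(J * K) - (double)N;
      double t1 = R::rnorm(0.0, 0.1);
      double u = R::runif(0.0, 1.0);
      long double sb1 = 0.0, sb0 = 0.0;
      double s = std::exp(t1);
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < J; ++j) {
          double mb = hierarchical ? mu_b[j] : prior_mean_beta(j, k);
          double vb = hierarchical ? tau2_b[j] : prior_var_beta(j, k);
          double d1 = s * beta(j, k) - mb;
          double d0 = beta(j, k) - mb;
          sb1 += d1 * d1 / vb;
          sb0 += d0 * d0 / vb;
        }
      double lp1 = -0.5 * std::exp(-2.0 * t1) * sum_th2 -
        0.5 * (double)sb1 + npar * t1;
      double lp0 = -0.5 * sum_th2 - 0.5 * (double)sb0;
      if (std::log(u) < lp1 - lp0) {
        for (int i = 0; i < N; ++i) theta[i] /= s;
        for (int k = 0; k < K; ++k)
          for (int j = 0; j < J; ++j) beta(j, k) *= s;
      }
    }

    // ---- record ----
    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < J; ++j) {
          d_alpha[s_out + (size_t)n_keep * (j + (size_t)J * k)] = alpha(j, k);
          d_beta[s_out + (size_t)n_keep * (j + (size_t)J * k)] = beta(j, k);
        }
      for (int i = 0; i < N; ++i) d_theta(s_out, i) = theta[i];
      if (hierarchical) {
        for (int j = 0; j < J; ++j) {
          d_mu_a(s_out, j) = mu_a[j];
          d_tau2_a(s_out, j) = tau2_a[j];
          d_mu_b(s_out, j) = mu_b[j];
          d_tau2_b(s_out, j) = tau2_b[j];
        }
      }
      ++s_out;
    }
  }

  d_alpha.attr("dim") = IntegerVector::create(n_keep, J, K);
  d_beta.attr("dim") = IntegerVector::create(n_keep, J, K);
  List out = List::create(_["alpha"] = d_alpha, _["beta"] = d_beta,
                          _["theta"] = d_theta);
  if (hierarchical) {
    out["mu_alpha"] = d_mu_a; out["tau2_alpha"] = d_tau2_a;
    out["mu_beta"] = d_mu_b; out["tau2_beta"] = d_tau2_b;
  }
  return out;
}
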