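// Gibbs sampler for spike-and-slab (SSVS) Bayesian logistic regression with
// Polya-Gamma data augmentation.  Conditionally on the PG latents phi_i the
// model is Gaussian in the working response kappa_i = y_i - 1/2 with
// per-sample precision phi_i, so each (beta_j, gamma_j) pair has an exact
// spike-and-slab conditional obtained by marginalizing beta_j analytically.
//
// Slab-variance handling (slab_method):
//  0 "marginal":    the Inverse-Gamma(a, b) slab-variance prior is
//                   marginalized out of the inclusion odds as well, using a
//                   quantile discretization of the prior (n_nodes atoms in
//                   precision space); the included coefficient is drawn
//                   conditional on an atom sampled from its inclusion
//                   conditional.  This collapsed update mixes over the
//                   heavy-tailed slab scale instead of conditioning on a
//                   single draw of it.
//  1 "conditional": sigma_j^2 is a state variable, redrawn each sweep from
//                   IG(a + gamma_j/2, b + gamma_j beta_j^2/2) (the prior
//                   when the protein is excluded).
//  2 "shared":      one slab variance pooled across proteins, redrawn from
//                   IG(a + sum gamma/2, b + sum gamma beta^2/2).
// update_sigma2 = false freezes the slab variances at sigma2_init and uses
// the exact fixed-variance conditional (conjugate-oracle test hook).

#include <Rcpp.h>
using namespace Rcpp;

double rpg1(double c); // polya_gamma.cpp

//' @noRd
// [[Rcpp::export(name = ".ssvs_gibbs_cpp")]]
List ssvs_gibbs_cpp(NumericMatrix X, IntegerVector y,
                    double w, double a, double b,
                    int n_iter, int n_burnin, int thin,
                    double intercept_var,
                    Nullable<NumericVector> fixed_phi,
                    bool update_sigma2,
                    NumericVector sigma2_init,
                    int slab_method,
                    int n_nodes,
                    double sigma2_max) {
  // slab-variance prior truncated to (0, sigma2_max]; equivalently the slab
  // precision t = 1/sigma^2 ~ Gamma(a, b) restricted to t >= 1/sigma2_max
  double t_min = (sigma2_max > 0 && std::isfinite(sigma2_max))
                     ? 1.0 / sigma2_max : 0.0;
  double p_lo = (t_min > 0.0) ? R::pgamma(t_min, a, 1.0 / b, 1, 0) : 0.0;
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter");
  int n_keep = (n_iter - n_burnin + thin - 1) / thin;

  std::vector<double> beta(p, 0.0), sigma2(p), eta(n, 0.0), phi(n, 0.25),
      kappa(n);
  std::vector<int> gamma(p, 0);
  double beta0 = 0.0;
  for (int j = 0; j < p; ++j)
    sigma2[j] = sigma2_init[j % sigma2_init.size()];
  for (int i = 0; i < n; ++i) kappa[i] = y[i] - 0.5;

  bool phi_fixed = fixed_phi.isNotNull();
  NumericVector phif;
  if (phi_fixed) {
    phif = as<NumericVector>(fixed_phi);
    if (phif.size() != n) stop("fixed_phi must have one entry per sample");
    for (int i = 0; i < n; ++i) phi[i] = phif[i];
  }

  bool marginal_slab = update_sigma2 && slab_method == 0;
  // quantile atoms of the slab PRECISION prior t = 1/sigma^2 ~ Gamma(a, b)
  std::vector<double> t_nodes;
  if (marginal_slab) {
    t_nodes.resize(n_nodes);
    for (int q = 0; q < n_nodes; ++q) {
      double pr = p_lo + (1.0 - p_lo) * (q + 0.5) / n_nodes;
      t_nodes[q] = R::qgamma(pr, a, 1.0 / b, 1, 0);
    }
  }
  std::vector<double> gq(marginal_slab ? n_nodes : 0);

  NumericMatrix beta_draws(n_keep, p), sigma2_draws(n_keep, p);
  IntegerMatrix gamma_draws(n_keep, p);
  NumericVector beta0_draws(n_keep);

  const double log_w = (w > 0.0) ? std::log(w) : R_NegInf;
  const double log_1mw = (w < 1.0) ? std::log1p(-w) : R_NegInf;

  int keep = 0;
  for (int it = 0; it < n_iter; ++it) {
    // (1) Polya-Gamma latents given the linear predictor
    if (!phi_fixed)
      for (int i = 0; i < n; ++i) phi[i] = rpg1(eta[i]);

    // (2a) intercept from its Gaussian conditional (always in the model)
    {
      double prec = 1.0 / intercept_var, S = 0.0;
      for (int i = 0; i < n; ++i) {
        prec += phi[i];
        S += kappa[i] - phi[i] * (eta[i] - beta0);
      }
      double beta0_new = S / prec + R::norm_rand() / std::sqrt(prec);
      double d = beta0_new - beta0;
      beta0 = beta0_new;
      for (int i = 0; i < n; ++i) eta[i] += d;
    }

    // (2b) feature-by-feature spike-and-slab updates, fixed sweep order
    for (int j = 0; j < p; ++j) {
      double A = 0.0, S = 0.0;
      for (int i = 0; i < n; ++i) {
        double x = X(i, j);
        A += phi[i] * x * x;
        S += x * (kappa[i] - phi[i] * (eta[i] - x * beta[j]));
      }
      int g_new = 0;
      double b_new = 0.0;
      if (marginal_slab) {
        // Bayes factor of inclusion with both beta_j and its slab variance
        // integrated out: R = E_t[ sqrt(t/(t+A)) exp(S^2 / (2(t+A))) ]
        double lmax = -R_PosInf;
        for (int q = 0; q < n_nodes; ++q) {
          double tq = t_nodes[q];
          double lg = 0.5 * (std::log(tq) - std::log(tq + A)) +
                      0.5 * S * S / (tq + A);
          gq[q] = lg;
          if (lg > lmax) lmax = lg;
        }
        double Rsum = 0.0;
        for (int q = 0; q < n_nodes; ++q) {
          gq[q] = std::exp(gq[q] - lmax);
          Rsum += gq[q];
        }
        double logR = lmax + std::log(Rsum / n_nodes);
        if (w <= 0.0) {
          g_new = 0;
        } else if (w >= 1.0) {
          g_new = 1;
        } else {
          double logit = log_w - log_1mw + logR;
          double pr = (logit > 35.0) ? 1.0
                      : (logit < -35.0) ? 0.0
                      : 1.0 / (1.0 + std::exp(-logit));
          g_new = (R::unif_rand() < pr) ? 1 : 0;
        }
        if (g_new == 1) {
          // pick a precision atom from its inclusion conditional, then the
          // Gaussian coefficient draw given that slab precision
          double u = R::unif_rand() * Rsum, acc = 0.0;
          int pick = n_nodes - 1;
          for (int q = 0; q < n_nodes; ++q) {
            acc += gq[q];
            if (u <= acc) { pick = q; break; }
          }
          double prec = t_nodes[pick] + A;
          b_new = S / prec + R::norm_rand() / std::sqrt(prec);
          sigma2[j] = 1.0 / t_nodes[pick];
        } else {
          // truncated-prior draw (bookkeeping only; unused by the updates)
          double u = p_lo + (1.0 - p_lo) * R::unif_rand();
          sigma2[j] = 1.0 / R::qgamma(u, a, 1.0 / b, 1, 0);
        }
      } else {
        double prec = A + 1.0 / sigma2[j];
        if (w <= 0.0) {
          g_new = 0;
        } else if (w >= 1.0) {
          g_new = 1;
        } else {
          // log odds of inclusion after integrating beta_j out of the slab
          double logit = log_w - log_1mw - 0.5 * std::log(sigma2[j]) -
                         0.5 * std::log(prec) + 0.5 * S * S / prec;
          double pr = (logit > 35.0) ? 1.0
                      : (logit < -35.0) ? 0.0
                      : 1.0 / (1.0 + std::exp(-logit));
          g_new = (R::unif_rand() < pr) ? 1 : 0;
        }
        if (g_new == 1) b_new = S / prec + R::norm_rand() / std::sqrt(prec);
      }
      if (b_new != beta[j]) {
        double d = b_new - beta[j];
        for (int i = 0; i < n; ++i) eta[i] += X(i, j) * d;
      }
      beta[j] = b_new;
      gamma[j] = g_new;
    }

    if (!std::isfinite(eta[0]) || !std::isfinite(beta0))
      stop("non-finite linear predictor at iteration %d", it + 1);

    // (3) slab variances for the non-collapsed schemes
    if (update_sigma2 && slab_method == 1) {
      for (int j = 0; j < p; ++j) {
        double shape = a + 0.5 * gamma[j];
        double rate = b + 0.5 * gamma[j] * beta[j] * beta[j];
        double plo_c = (t_min > 0.0)
                           ? R::pgamma(t_min, shape, 1.0 / rate, 1, 0) : 0.0;
        double u = plo_c + (1.0 - plo_c) * R::unif_rand();
        sigma2[j] = 1.0 / R::qgamma(u, shape, 1.0 / rate, 1, 0);
      }
    } else if (update_sigma2 && slab_method == 2) {
      double shape = a, rate = b;
      for (int j = 0; j < p; ++j) {
        shape += 0.5 * gamma[j];
        rate += 0.5 * gamma[j] * beta[j] * beta[j];
      }
      double plo_c = (t_min > 0.0)
                         ? R::pgamma(t_min, shape, 1.0 / rate, 1, 0) : 0.0;
      double u = plo_c + (1.0 - plo_c) * R::unif_rand();
      double v = 1.0 / R::qgamma(u, shape, 1.0 / rate, 1, 0);
      for (int j = 0; j < p; ++j) sigma2[j] = v;
    }

    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      for (int j = 0; j < p; ++j) {
        beta_draws(keep, j) = beta[j];
        gamma_draws(keep, j) = gamma[j];
        sigma2_draws(keep, j) = sigma2[j];
      }
      beta0_draws[keep] = beta0;
      ++keep;
    }
  }

  NumericVector phi_out(n);
  for (int i = 0; i < n; ++i) phi_out[i] = phi[i];
  return List::create(_["beta"] = beta_draws, _["gamma"] = gamma_draws,
                      _["sigma2"] = sigma2_draws, _["beta0"] = beta0_draws,
                      _["phi"] = phi_out, _["n_kept"] = keep);
}
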