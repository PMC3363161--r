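#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled-inverse-chi-square draw: nu * s2 / chisq_nu
static inline double rscinvchisq(double nu, double s2) {
  return nu * s2 / R::rchisq(nu);
}

// log density of N(0, v) at r, up to the common -0.5*log(2*pi)
static inline double ldnorm0(double r, double v) {
  return -0.5 * (std::log(v) + r * r / v);
}

static inline double sample_var(const std::vector<double>& g) {
  const int n = g.size();
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += g[i];
  m /= n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (g[i] - m) * (g[i] - m);
  return ss / (n - 1.0);
}

// One single-site pass over a block of regressors (columns of Xc) with a
// spike-and-slab prior.  For the common-variance model (BayesCpi) the
// indicator is Gibbs-sampled from the collapsed conditional; for the
// per-locus-variance model (BayesB) the (indicator, variance) pair is updated
// by Metropolis-Hastings with the prior as proposal and the effect integrated
// out, followed by a Gibbs refresh of the locus variance given the drawn
// effect.  Returns the number of included loci.
static int update_block(const NumericMatrix& Xc,
                        const std::vector<double>& xx,
                        std::vector<double>& e,
                        std::vector<double>& g,    // running block fit Xc*beta
                        std::vector<double>& beta,
                        std::vector<int>& delta,
                        std::vector<double>& locvar, // per-locus variances (BayesB)
                        double pi, double sigma2_common,
                        bool per_locus_var, double nu_b, double s2_b,
                        double sigma2_e, int n_mh) {
  const int n = Xc.nrow(), k = Xc.ncol();
  int m = 0;
  for (int j = 0; j < k; ++j) {
    if (xx[j] <= 0.0) { continue; } // constant column: effect pinned at 0
    const double* xj = &Xc(0, j);
    // r = x_j' (e + x_j beta_j): data signal with locus j's fit removed
    double r = 0.0;
    for (int i = 0; i < n; ++i) r += xj[i] * e[i];
    r += xx[j] * beta[j];
    const double v0 = xx[j] * sigma2_e;

    double s2j = per_locus_var ? locvar[j] : sigma2_common;
    int dj = delta[j];

    if (!per_locus_var) {
      // collapsed Gibbs on the indicator
      double p1;
      if (pi <= 0.0) p1 = 1.0;
      else if (pi >= 1.0) p1 = 0.0;
      else {
        const double v1 = xx[j] * xx[j] * s2j + v0;
        const double ldiff = ldnorm0(r, v0) - ldnorm0(r, v1);
        p1 = 1.0 / (1.0 + (pi / (1.0 - pi)) * std::exp(ldiff));
      }
      dj = (unif_rand() < p1) ? 1 : 0;
    } else {
      // MH on (indicator, locus variance) with the prior as proposal
      double loglik_cur = dj ? ldnorm0(r, xx[j] * xx[j] * s2j + v0)
                             : ldnorm0(r, v0);
      for (int rep = 0; rep < n_mh; ++rep) {
        const int dprop = (unif_rand() < (1.0 - pi)) ? 1 : 0;
        const double s2prop = dprop ? rscinvchisq(nu_b, s2_b) : 0.0;
        const double loglik_prop = dprop
          ? ldnorm0(r, xx[j] * xx[j] * s2prop + v0)
          : ldnorm0(r, v0);
        if (std::log(unif_rand()) < loglik_prop - loglik_cur) {
          dj = dprop; s2j = s2prop; loglik_cur = loglik_prop;
        }
      }
    }

    double bnew = 0.0;
    if (dj == 1) {
      const double c = xx[j] + sigma2_e / s2j;
      bnew = r / c + norm_rand() * std::sqrt(sigma2_e / c);
      if (per_locus_var) {
        // Gibbs refresh of the locus variance given the effect
        s2j = rscinvchisq(nu_b + 1.0, (nu_b * s2_b + bnew * bnew) / (nu_b + 1.0));
      }
      ++m;
    }
    const double db = beta[j] - bnew;
    if (db != 0.0) {
      for (int i = 0; i < n; ++i) { e[i] += xj[i] * db; g[i] -= xj[i] * db; }
    }
    beta[j] = bnew;
    delta[j] = dj;
    if (per_locus_var) locvar[j] = dj ? s2j : 0.0;
  }
  return m;
}

// Single-site Gibbs sampler for spike-and-slab whole-genome regression.
// Additive-only models: BayesCpi (common effect variance, pi sampled from its
// Beta conditional) and BayesB (per-locus effect variances, pi fixed).
// Xc must be column-centered; y is the phenotype of the training records.
// [[Rcpp::export]]
List wgr_sampler_cpp(const NumericMatrix& Xc, const NumericVector& y,
                     double pi_init, bool sample_pi, bool per_locus_var,
                     double nu_b, double s2_b, double nu_e, double s2_e,
                     bool sample_effect_var, bool sample_resid_var,
                     double effect_var_init, double resid_var_init,
                     int n_iter, int burn_in, int thin, int n_mh,
                     bool store_samples) {
  const int n = Xc.nrow(), k = Xc.ncol();
  std::vector<double> xx(k);
  int k_eff = 0;
  for (int j = 0; j < k; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Xc(i, j) * Xc(i, j);
    xx[j] = s;
    if (s > 0.0) ++k_eff;
  }

  double mu = mean(y);
  double sigma2_b = effect_var_init, sigma2_e = resid_var_init, pi = pi_init;
  std::vector<double> beta(k, 0.0), locvar(k, 0.0), e(n), g(n, 0.0);
  std::vector<int> delta(k, 0);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  const int n_saved = (n_iter - burn_in) / thin;
  NumericVector sum_beta(k), sum_delta(k);
  NumericVector varg_s(n_saved), sige_s(n_saved), pi_s(n_saved), mu_s(n_saved),
                sigb_s(n_saved);
  NumericMatrix beta_store(store_samples ? k : 1, store_samples ? n_saved : 1);

  int saved = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    // intercept (flat prior)
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    const double dmu = ebar + norm_rand() * std::sqrt(sigma2_e / n);
    mu += dmu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;

    const int m = update_block(Xc, xx, e, g, beta, delta, locvar, pi, sigma2_b,
                               per_locus_var, nu_b, s2_b, sigma2_e, n_mh);

    if (!per_locus_var && sample_effect_var) {
      double ssb = 0.0;
      for (int j = 0; j < k; ++j) ssb += beta[j] * beta[j];
      sigma2_b = rscinvchisq(nu_b + m, (nu_b * s2_b + ssb) / (nu_b + m));
    }
    if (sample_pi) pi = R::rbeta(k_eff - m + 1.0, m + 1.0);
    if (sample_resid_var) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma2_e = rscinvchisq(nu_e + n, (nu_e * s2_e + sse) / (nu_e + n));
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      for (int j = 0; j < k; ++j) { sum_beta[j] += beta[j]; sum_delta[j] += delta[j]; }
      varg_s[saved] = sample_var(g);
      sige_s[saved] = sigma2_e;
      pi_s[saved] = pi;
      mu_s[saved] = mu;
      sigb_s[saved] = sigma2_b;
      if (store_samples)
        for (int j = 0; j < k; ++j) beta_store(j, saved) = beta[j];
      ++saved;
    }
  }

  NumericVector effect_mean(k), model_freq(k);
  for (int j = 0; j < k; ++j) {
    effect_mean[j] = sum_beta[j] / n_saved;
    model_freq[j] = sum_delta[j] / n_saved;
  }
  return List::create(
    _["effect_mean"] = effect_mean, _["model_freq"] = model_freq,
    _["var_g"] = varg_s, _["sigma2_e"] = sige_s, _["pi"] = pi_s,
    _["mu"] = mu_s, _["sigma2_b"] = sigb_s,
    _["samples"] = store_samples ? beta_store : NumericMatrix(0, 0),
    _["n_saved"] = n_saved);
}

// Joint additive + dominance BayesCpi: two interleaved single-site blocks
// (additive effects on centered dosages Xc, dominance effects on centered
// heterozygosity indicators Wc), each with its own indicator set, common
// effect variance and sampled pi.
// [[Rcpp::export]]
List wgr_dom_sampler_cpp(const NumericMatrix& Xc, const NumericMatrix& Wc,
                         const NumericVector& y,
                         double pi_a_init, double pi_d_init, bool sample_pi,
                         double nu_a, double s2_a, double nu_d, double s2_d,
                         double nu_e, double s2_e,
                         double var_a_init, double var_d_init,
                         double resid_var_init,
                         int n_iter, int burn_in, int thin,
                         bool store_samples) {
  const int n = Xc.nrow(), k = Xc.ncol();
  std::vector<double> xx(k), ww(k);
  int ka_eff = 0, kd_eff = 0;
  for (int j = 0; j < k; ++j) {
    double sx = 0.0, sw = 0.0;
    for (int i = 0; i < n; ++i) { sx += Xc(i, j) * Xc(i, j); sw += Wc(i, j) * Wc(i, j); }
    xx[j] = sx; ww[j] = sw;
    if (sx > 0.0) ++ka_eff;
    if (sw > 0.0) ++kd_eff;
  }

  double mu = mean(y);
  double sig_a = var_a_init, sig_d = var_d_init, sigma2_e = resid_var_init;
  double pi_a = pi_a_init, pi_d = pi_d_init;
  std::vector<double> a(k, 0.0), d(k, 0.0), dummy(k, 0.0);
  std::vector<double> e(n), ga(n, 0.0), gd(n, 0.0);
  std::vector<int> da(k, 0), dd(k, 0);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  const int n_saved = (n_iter - burn_in) / thin;
  NumericVector sum_a(k), sum_d(k), freq_a(k), freq_d(k);
  NumericVector varga_s(n_saved), vargd_s(n_saved), sige_s(n_saved),
                pia_s(n_saved), pid_s(n_saved), mu_s(n_saved);
  NumericMatrix a_store(store_samples ? k : 1, store_samples ? n_saved : 1);
  NumericMatrix d_store(store_samples ? k : 1, store_samples ? n_saved : 1);

  int saved = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    const double dmu = ebar + norm_rand() * std::sqrt(sigma2_e / n);
    mu += dmu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;

    const int ma = update_block(Xc, xx, e, ga, a, da, dummy, pi_a, sig_a,
                                false, nu_a, s2_a, sigma2_e, 0);
    const int md = update_block(Wc, ww, e, gd, d, dd, dummy, pi_d, sig_d,
                                false, nu_d, s2_d, sigma2_e, 0);

    double ssa = 0.0, ssd = 0.0, sse = 0.0;
    for (int j = 0; j < k; ++j) { ssa += a[j] * a[j]; ssd += d[j] * d[j]; }
    sig_a = rscinvchisq(nu_a + ma, (nu_a * s2_a + ssa) / (nu_a + ma));
    sig_d = rscinvchisq(nu_d + md, (nu_d * s2_d + ssd) / (nu_d + md));
    if (sample_pi) {
      pi_a = R::rbeta(ka_eff - ma + 1.0, ma + 1.0);
      if (kd_eff > 0) pi_d = R::rbeta(kd_eff - md + 1.0, md + 1.0);
    }
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2_e = rscinvchisq(nu_e + n, (nu_e * s2_e + sse) / (nu_e + n));

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      for (int j = 0; j < k; ++j) {
        sum_a[j] += a[j]; sum_d[j] += d[j];
        freq_a[j] += da[j]; freq_d[j] += dd[j];
      }
      varga_s[saved] = sample_var(ga);
      vargd_s[saved] = kd_eff > 0 ? sample_var(gd) : 0.0;
      sige_s[saved] = sigma2_e;
      pia_s[saved] = pi_a; pid_s[saved] = pi_d; mu_s[saved] = mu;
      if (store_samples)
        for (int j = 0; j < k; ++j) {
          a_store(j, saved) = a[j]; d_store(j, saved) = d[j];
        }
      ++saved;
    }
  }

  for (int j = 0; j < k; ++j) {
    sum_a[j] /= n_saved; sum_d[j] /= n_saved;
    freq_a[j] /= n_saved; freq_d[j] /= n_saved;
  }
  return List::create(
    _["effect_mean_a"] = sum_a, _["effect_mean_d"] = sum_d,
    _["model_freq_a"] = freq_a, _["model_freq_d"] = freq_d,
    _["var_ga"] = varga_s, _["var_gd"] = vargd_s, _["sigma2_e"] = sige_s,
    _["pi_a"] = pia_s, _["pi_d"] = pid_s, _["mu"] = mu_s,
    _["samples_a"] = store_samples ? a_store : NumericMatrix(0, 0),
    _["samples_d"] = store_samples ? d_store : NumericMatrix(0, 0),
    _["n_saved"] = n_saved);
}

// Posterior mean of per-window GEBV-variance proportions over retained effect
// samples: for each sample, window variance / total variance of the sampled
// genomic values, averaged over samples.  first/last are 0-based inclusive
// column bounds of each window.
// [[Rcpp::export]]
NumericVector window_var_samples_cpp(const NumericMatrix& Xc,
                                     const NumericMatrix& beta_store,
                                     const IntegerVector& first,
                                     const IntegerVector& last) {
  const int n = Xc.nrow(), k = Xc.ncol(), ns = beta_store.ncol(),
            nw = first.size();
  NumericVector out(nw);
  std::vector<double> contrib(n * k), gw(n), gtot(n);
  int used = 0;
  for (int s = 0; s < ns; ++s) {
    for (int i = 0; i < n; ++i) gtot[i] = 0.0;
    for (int j = 0; j < k; ++j) {
      const double b = beta_store(j, s);
      const double* xj = &Xc(0, j);
      double* cj = &contrib[(size_t)j * n];
      for (int i = 0; i < n; ++i) { cj[i] = xj[i] * b; gtot[i] += cj[i]; }
    }
    const double vtot = sample_var(gtot);
    if (vtot <= 0.0) continue;
    ++used;
    for (int w = 0; w < nw; ++w) {
      for (int i = 0; i < n; ++i) gw[i] = 0.0;
      for (int j = first[w]; j <= last[w]; ++j) {
        const double* cj = &contrib[(size_t)j * n];
        for (int i = 0; i < n; ++i) gw[i] += cj[i];
      }
      out[w] += sample_var(gw) / vtot;
    }
  }
  if (used > 0) for (int w = 0; w < nw; ++w) out[w] /= used;
  return out;
}
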