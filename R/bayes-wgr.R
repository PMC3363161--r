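#' @noRd
validate_wgr_inputs <- function(y, X, W = NULL) {
  if (length(y) < 2) abort("Need at least 2 phenotyped records.")
  if (nrow(X) != length(y)) abort("X rows must match phenotype records.")
  if (anyNA(y) || anyNA(X)) abort("Missing phenotypes/genotypes are not allowed here.")
  if (var1(y) == 0) abort("Phenotype is constant; nothing to fit.")
  if (!is.null(W) && !all(dim(W) == dim(X))) abort("W must match X in dimension.")
  invisible(TRUE)
}

# GenSel-style hyperprior scale: prior scale of the scaled-inverse-chi-square
# on the effect variance such that the implied genetic variance matches
# `var_assumed` given the inclusion rate and the summed column variances.
prior_scale_effect <- function(var_assumed, nu, pi, sum_colvar) {
  inc <- max(1 - pi, 1e-3)
  var_assumed * (nu - 2) / nu / (inc * max(sum_colvar, .Machine$double.eps))
}

prior_scale_var <- function(var_assumed, nu) var_assumed * (nu - 2) / nu

new_wgr_fit <- function(method, effects, varcomp, gebv_train, samples, pars) {
  structure(list(method = method, effects = effects, varcomp = varcomp,
                 gebv = gebv_train, samples = samples, pars = pars),
            class = "wgr_fit")
}

#' Fit BayesCpi by single-site Gibbs sampling
#'
#' Spike-and-slab whole-genome regression with a common effect variance:
#' each SNP effect is zero with probability `pi`, normal otherwise; `pi` is
#' sampled from its Beta conditional `Beta(k - m + 1, m + 1)` (m included
#' SNPs out of k) unless fixed, the common effect variance and the residual
#' variance have scaled-inverse-chi-square priors, and the intercept has a
#' flat prior.  Genotype columns are centered by twice the observed allele
#' frequency before sampling; zero-variance columns are skipped with a
#' warning and their effects fixed at 0.
#'
#' The reported additive genetic variance is the posterior mean, over
#' retained samples, of the variance of the sampled genomic values across the
#' training individuals; heritability is genetic / (genetic + residual).
#'
#' @param y Numeric phenotype vector (training records, no missing values).
#' @param X Dosage matrix (0/1/2), rows matching `y`.
#' @param n_iter,burn_in,thin Chain length (defaults 41000/1000/10).
#' @param pi Initial (or fixed) probability that a SNP has no effect.
#' @param sample_pi Sample `pi` (default `TRUE`)?
#' @param h2_prior Assumed heritability used to derive weakly informative
#'   prior scales from `var(y)` (default 0.5).
#' @param nu_effect,nu_resid Prior degrees of freedom (defaults 4.2 and 4).
#' @param effect_var,resid_var Optional fixed starting values overriding the
#'   derived ones.
#' @param sample_effect_var,sample_resid_var Set to `FALSE` to hold the
#'   corresponding variance fixed (used by the closed-form oracles).
#' @param store_samples Keep retained effect samples (needed for
#'   sample-based window variances)?
#' @param seed Optional integer seed.
#'
#' @return A `wgr_fit`: `effects` tibble (`snp`, `effect_a`, `model_freq_a`),
#'   `varcomp` one-row tibble (genetic, residual, total variance, `h2`,
#'   `pi_mean`), `gebv` for the training rows, retained `samples`, and the
#'   configuration in `pars`.  Use [tidy()], [glance()], [autoplot()].
#' @export
run_bayescpi <- function(y, X, n_iter = 41000, burn_in = 1000, thin = 10,
                         pi = 0.5, sample_pi = TRUE, h2_prior = 0.5,
                         nu_effect = 4.2, nu_resid = 4,
                         effect_var = NULL, resid_var = NULL,
                         sample_effect_var = TRUE, sample_resid_var = TRUE,
                         store_samples = TRUE, seed = NULL) {
  run_wgr(y, X, per_locus_var = FALSE, n_iter = n_iter, burn_in = burn_in,
          thin = thin, pi = pi, sample_pi = sample_pi, h2_prior = h2_prior,
          nu_effect = nu_effect, nu_resid = nu_resid, effect_var = effect_var,
          resid_var = resid_var, sample_effect_var = sample_effect_var,
          sample_resid_var = sample_resid_var, n_mh = 0,
          store_samples = store_samples, seed = seed, method = "bayesCpi")
}

#' Fit BayesB by single-site Gibbs sampling with Metropolis-Hastings
#'
#' As [run_bayescpi()], but `pi` is fixed (default 0.995, never sampled) and
#' every included SNP carries its own effect variance with a
#' scaled-inverse-chi-square prior.  The indicator and locus variance are
#' updated jointly by Metropolis-Hastings with the prior as proposal and the
#' effect integrated out (`n_mh` proposals per locus per iteration), after
#' which the effect is drawn from its normal conditional and the locus
#' variance refreshed from its conditional given the effect.
#'
#' @inheritParams run_bayescpi
#' @param n_mh Metropolis-Hastings proposals per locus per iteration.
#' @return A `wgr_fit`; see [run_bayescpi()].
#' @export
run_bayesb <- function(y, X, n_iter = 41000, burn_in = 1000, thin = 10,
                       pi = 0.995, h2_prior = 0.5,
                       nu_effect = 4.2, nu_resid = 4,
                       effect_var = NULL, resid_var = NULL,
                       sample_effect_var = TRUE, sample_resid_var = TRUE,
                       n_mh = 5, store_samples = TRUE, seed = NULL) {
  run_wgr(y, X, per_locus_var = TRUE, n_iter = n_iter, burn_in = burn_in,
          thin = thin, pi = pi, sample_pi = FALSE, h2_prior = h2_prior,
          nu_effect = nu_effect, nu_resid = nu_resid, effect_var = effect_var,
          resid_var = resid_var, sample_effect_var = sample_effect_var,
          sample_resid_var = sample_resid_var, n_mh = n_mh,
          store_samples = store_samples, seed = seed, method = "bayesB")
}

#' @noRd
run_wgr <- function(y, X, per_locus_var, n_iter, burn_in, thin, pi, sample_pi,
                    h2_prior, nu_effect, nu_resid, effect_var, resid_var,
                    sample_effect_var, sample_resid_var, n_mh, store_samples,
                    seed, method) {
  validate_wgr_inputs(y, X)
  stopifnot(burn_in < n_iter, thin >= 1, pi >= 0, pi <= 1)
  p <- allele_freqs(X)
  Xc <- sweep(X, 2, 2 * p)
  colvar <- apply(Xc, 2, var1)
  if (any(colvar == 0)) {
    warn(sprintf("%d zero-variance SNP column(s) skipped; effects fixed at 0.",
                 sum(colvar == 0)))
  }
  vy <- var1(y)
  var_g <- h2_prior * vy
  var_e <- (1 - h2_prior) * vy
  s2_b <- prior_scale_effect(var_g, nu_effect, pi, sum(colvar))
  s2_e <- prior_scale_var(if (is.null(resid_var)) var_e else resid_var, nu_resid)
  eff_init <- effect_var %||% (nu_effect * s2_b / (nu_effect - 2))
  if (!is.null(effect_var)) s2_b <- prior_scale_var(effect_var, nu_effect)
  res_init <- resid_var %||% var_e

  out <- with_seed(seed,
    wgr_sampler_cpp(Xc, y, pi, sample_pi, per_locus_var,
                    nu_effect, s2_b, nu_resid, s2_e,
                    sample_effect_var, sample_resid_var,
                    eff_init, res_init,
                    as.integer(n_iter), as.integer(burn_in), as.integer(thin),
                    as.integer(n_mh), store_samples))

  effects <- tibble::tibble(snp = seq_len(ncol(X)),
                            effect_a = out$effect_mean,
                            model_freq_a = out$model_freq)
  vg <- mean(out$var_g)
  ve <- mean(out$sigma2_e)
  varcomp <- tibble::tibble(
    method = method, genetic_var = vg, residual_var = ve,
    total_var = vg + ve, h2 = vg / (vg + ve), pi_mean = mean(out$pi))
  gebv <- drop(Xc %*% out$effect_mean)
  gebv <- gebv - mean(gebv)
  samples <- list(effect_a = if (store_samples) out$samples else NULL,
                  var_g = out$var_g, sigma2_e = out$sigma2_e,
                  pi = out$pi, mu = out$mu, n_saved = out$n_saved)
  new_wgr_fit(method, effects, varcomp, gebv, samples,
              list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                   pi = pi, sample_pi = sample_pi, allele_freqs = p,
                   nu_effect = nu_effect, nu_resid = nu_resid,
                   s2_b = s2_b, s2_e = s2_e, seed = seed))
}

#' Fit the joint additive + dominance BayesCpi model
#'
#' Fits `y = mu + sum_j (X_ij a_j + W_ij d_j) + e` where `X` is the allele
#' dosage and `W` the heterozygosity indicator: `a_j` is half the difference
#' between homozygotes and `d_j` the difference between the heterozygote and
#' the homozygote mean.  Both effect sets have their own spike-and-slab
#' mixture with effect-specific inclusion probability (`pi_a`, `pi_d`) and
#' common variance, updated by two interleaved single-site passes per
#' iteration.  The additive genetic variance is the posterior mean of
#' `var(X a)` across training individuals.  The reported dominance variance
#' `dominance_var` is `var(W d_hat)` at the posterior-mean effects: with no
#' dominance signal the per-sample `var(W d)` never falls below a
#' Monte-Carlo floor set by transiently included tiny effects (its posterior
#' mean is kept as `dominance_var_sample`), whereas the point-effect variance
#' behaves like the published dominance rows of variance-component tables.
#'
#' @inheritParams run_bayescpi
#' @param W Heterozygosity indicator matrix (1 = heterozygous), same shape
#'   as `X`.
#' @param pi_a,pi_d Initial inclusion-complement probabilities.
#' @param dom_var_share Assumed dominance share of the genetic variance used
#'   for the dominance prior scale (default 0.25).
#' @return A `wgr_fit` with additional columns `effect_d`, `model_freq_d` in
#'   `effects` and `dominance_var`, `pi_d_mean` in `varcomp`.
#' @export
run_bayescpi_dominance <- function(y, X, W = NULL, n_iter = 41000,
                                   burn_in = 1000, thin = 10,
                                   pi_a = 0.5, pi_d = 0.5, sample_pi = TRUE,
                                   h2_prior = 0.5, dom_var_share = 0.25,
                                   nu_effect = 4.2, nu_resid = 4,
                                   store_samples = TRUE, seed = NULL) {
  if (is.null(W)) W <- (X == 1) * 1L
  validate_wgr_inputs(y, X, W)
  stopifnot(burn_in < n_iter, thin >= 1)
  p <- allele_freqs(X)
  Xc <- sweep(X, 2, 2 * p)
  Wc <- sweep(W, 2, colMeans(W))
  colvar_x <- apply(Xc, 2, var1)
  colvar_w <- apply(Wc, 2, var1)
  if (all(colvar_w == 0)) {
    warn("No heterozygous genotypes in the panel; dominance effects remain 0.")
  }
  vy <- var1(y)
  var_g <- h2_prior * vy
  s2_a <- prior_scale_effect(var_g, nu_effect, pi_a, sum(colvar_x))
  s2_d <- prior_scale_effect(dom_var_share * var_g, nu_effect, pi_d,
                             max(sum(colvar_w), .Machine$double.eps))
  s2_e <- prior_scale_var((1 - h2_prior) * vy, nu_resid)

  out <- with_seed(seed,
    wgr_dom_sampler_cpp(Xc, Wc, y, pi_a, pi_d, sample_pi,
                        nu_effect, s2_a, nu_effect, s2_d, nu_resid, s2_e,
                        nu_effect * s2_a / (nu_effect - 2),
                        nu_effect * s2_d / (nu_effect - 2),
                        (1 - h2_prior) * vy,
                        as.integer(n_iter), as.integer(burn_in),
                        as.integer(thin), store_samples))

  effects <- tibble::tibble(snp = seq_len(ncol(X)),
                            effect_a = out$effect_mean_a,
                            effect_d = out$effect_mean_d,
                            model_freq_a = out$model_freq_a,
                            model_freq_d = out$model_freq_d)
  va <- mean(out$var_ga)
  vd_sample <- mean(out$var_gd)
  vd <- var1(drop(Wc %*% out$effect_mean_d))
  ve <- mean(out$sigma2_e)
  varcomp <- tibble::tibble(
    method = "bayesCpi-dom", genetic_var = va + vd, additive_var = va,
    dominance_var = vd, dominance_var_sample = vd_sample,
    residual_var = ve, total_var = va + vd + ve,
    h2 = va / (va + vd + ve), pi_mean = mean(out$pi_a),
    pi_d_mean = mean(out$pi_d))
  alpha <- out$effect_mean_a + out$effect_mean_d * (1 - 2 * p)
  gebv <- drop(Xc %*% alpha)
  gebv <- gebv - mean(gebv)
  samples <- list(effect_a = if (store_samples) out$samples_a else NULL,
                  effect_d = if (store_samples) out$samples_d else NULL,
                  var_ga = out$var_ga, var_gd = out$var_gd,
                  sigma2_e = out$sigma2_e, pi_a = out$pi_a, pi_d = out$pi_d,
                  mu = out$mu, n_saved = out$n_saved)
  new_wgr_fit("bayesCpi-dom", effects, varcomp, gebv, samples,
              list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                   pi_a = pi_a, pi_d = pi_d, sample_pi = sample_pi,
                   allele_freqs = p, s2_a = s2_a, s2_d = s2_d, s2_e = s2_e,
                   seed = seed))
}

#' Posterior inclusion probabilities (model frequencies)
#'
#' The model frequency of a SNP is the mean of its inclusion indicator over
#' retained MCMC samples, per effect type.
#'
#' @param x A `wgr_fit`, or a 0/1 indicator matrix with samples in rows and
#'   SNPs in columns.
#' @return A tibble with `snp` and one `model_freq_*` column per effect type.
#' @export
model_frequencies <- function(x) {
  if (inherits(x, "wgr_fit")) {
    return(dplyr::select(x$effects, "snp", dplyr::starts_with("model_freq")))
  }
  x <- as.matrix(x)
  if (nrow(x) < 1) abort("Need at least one retained sample.")
  tibble::tibble(snp = seq_len(ncol(x)), model_freq_a = colMeans(x != 0))
}

#' Genomic breeding values from marker effects
#'
#' Additive models: `GEBV_i = sum_j Xc_ij * a_j` on dosages centered by twice
#' the allele frequency.  With dominance effects, the per-SNP allele
#' substitution effect `alpha_j = a_j + d_j * (1 - 2 p_j)` is applied to the
#' centered dosage.  Output is centered to mean 0 over the supplied
#' individuals.
#'
#' @param X Dosage matrix for the individuals to predict.
#' @param effects A `wgr_fit` or a numeric vector of additive effects.
#' @param dominance Optional numeric vector of dominance effects (ignored
#'   when `effects` is a `wgr_fit`, which carries its own).
#' @param freq Allele frequencies for centering/substitution effects;
#'   defaults to the fit's training frequencies or the observed ones.
#' @param center Center the output to mean zero (default `TRUE`)?
#' @return A numeric vector of GEBV, one per row of `X`.
#' @export
gebv_from_effects <- function(X, effects, dominance = NULL, freq = NULL,
                              center = TRUE) {
  if (inherits(effects, "wgr_fit")) {
    fit <- effects
    effects <- fit$effects$effect_a
    dominance <- fit$effects[["effect_d"]]
    freq <- freq %||% fit$pars$allele_freqs
  }
  if (length(effects) != ncol(X)) {
    abort("Effect vector length must equal the number of SNP columns.")
  }
  freq <- freq %||% allele_freqs(X)
  alpha <- if (is.null(dominance)) effects else effects + dominance * (1 - 2 * freq)
  g <- drop(sweep(X, 2, 2 * freq) %*% alpha)
  if (center) g <- g - mean(g)
  g
}

#' @export
print.wgr_fit <- function(x, ...) {
  cat(sprintf("Bayesian whole-genome regression fit (%s)\n", x$method))
  cat(sprintf("  SNPs: %d; retained samples: %d\n",
              nrow(x$effects), x$samples$n_saved))
  print(as.data.frame(x$varcomp), row.names = FALSE)
  invisible(x)
}

#' @describeIn run_bayescpi Per-SNP posterior summaries as a tibble.
#' @param x A `wgr_fit`.
#' @param ... Unused.
#' @export
tidy.wgr_fit <- function(x, ...) x$effects

#' @describeIn run_bayescpi One-row model summary (variance components,
#'   heritability, posterior mean of pi).
#' @export
glance.wgr_fit <- function(x, ...) x$varcomp
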