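# The scaled study shared by the acceptance tests: the full two-generation
# design (20 sires x 10 dams x 15 progeny, 2,000 phenotyped) on a 1,000-SNP
# panel, with 12,000-iteration chains.  Built once per test run and cached.

.study_cache <- new.env(parent = emptyenv())

scaled_study <- function() {
  if (!is.null(.study_cache$study)) return(.study_cache$study)
  pop <- simulate_population(n_snps = 1000, seed = 20110915)
  tr <- pop$phenotypes$role == "training"
  va <- pop$phenotypes$role == "validation"
  X_tr <- pop$genotypes[tr, ]
  y_tr <- pop$phenotypes$y[tr]
  p_tr <- colMeans(X_tr) / 2

  fit_c <- run_bayescpi(y_tr, X_tr, n_iter = 12000, burn_in = 2000, thin = 10,
                        seed = 101)
  fit_b <- run_bayesb(y_tr, X_tr, n_iter = 12000, burn_in = 2000, thin = 10,
                      seed = 102)
  fit_d <- run_bayescpi_dominance(y_tr, X_tr, n_iter = 12000, burn_in = 2000,
                                  thin = 10, seed = 103)

  G <- build_grm(pop$genotypes)
  D <- build_dominance_rm(pop$genotypes)
  y_full <- ifelse(tr, pop$phenotypes$y, NA_real_)
  g1 <- gblup_reml(y_full, list(additive = G), "G1")
  g2 <- gblup_reml(y_full, list(additive = G, dominance = D), "G2")
  mme <- solve_mme(y_full, g1, list(additive = G))
  sig_a <- g1$components$variance[g1$components$term == "additive"]
  alpha <- backsolve_effects(mme$solutions$a_hat, pop$genotypes, G, sig_a)

  gebv <- list(
    bayesCpi = gebv_from_effects(pop$genotypes, fit_c, freq = p_tr),
    bayesB = gebv_from_effects(pop$genotypes, fit_b, freq = p_tr),
    gblup = mme$solutions$a_hat - mean(mme$solutions$a_hat))

  w_c <- window_variances(pop$genotypes, fit_c, pop$map)
  w_b <- window_variances(pop$genotypes, fit_b, pop$map)
  w_g <- window_variances(pop$genotypes, alpha, pop$map)
  calls <- list(
    bayesCpi = call_qtl_bayes(w_c, pop$map, "bayesCpi",
                              pi_hat = glance(fit_c)$pi_mean,
                              method = "bayesCpi"),
    bayesB = call_qtl_bayes(w_b, pop$map, "bayesB", method = "bayesB"),
    gblup = call_qtl_gblup(alpha, pop$map))

  .study_cache$study <- list(
    pop = pop, train = tr, valid = va,
    fits = list(bayesCpi = fit_c, bayesB = fit_b, dom = fit_d,
                G1 = g1, G2 = g2),
    rel = list(additive = G, dominance = D), y_full = y_full,
    alpha = alpha, gebv = gebv,
    windows = list(bayesCpi = w_c, bayesB = w_b, gblup = w_g),
    calls = calls)
  .study_cache$study
}
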