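# Small reusable fixtures, built in code.

# a tiny two-generation population for fast structural tests
tiny_pop <- function(seed = 11, n_snps = 60, n_sires = 3, n_dams = 2,
                     n_prog = 5, n_phen = 3) {
  simulate_population(n_sires = n_sires, n_dams_per_sire = n_dams,
                      n_progeny_per_dam = n_prog, n_snps = n_snps,
                      n_phenotyped_per_family = n_phen, seed = seed)
}

# random dosage matrix with all three genotype classes present
random_dosages <- function(n, k, p = NULL, seed = 1) {
  withr::with_seed(seed, {
    if (is.null(p)) p <- runif(k, 0.2, 0.8)
    matrix(rbinom(n * k, 2, rep(p, each = n)), n, k)
  })
}

# closed-form ridge (SNP-BLUP) solution with an unpenalized intercept
ridge_with_intercept <- function(y, Xc, lambda) {
  k <- ncol(Xc)
  A <- cbind(1, Xc)
  C <- crossprod(A)
  C[-1, -1] <- C[-1, -1] + diag(lambda, k)
  drop(solve(C, crossprod(A, y)))
}
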