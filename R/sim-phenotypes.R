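#' Trait parameters
#'
#' @param mu Population mean (default 0).
#' @param sigma2_a Additive genetic variance the simulation is calibrated to
#'   (default 26.35).
#' @param sigma2_e Residual variance (default 61.49).
#' @param h2 Narrow-sense heritability; if supplied together with the two
#'   variances it must satisfy `h2 = sigma2_a / (sigma2_a + sigma2_e)` to
#'   1e-9, otherwise it is derived.
#' @return A list of class `trait_params`.
#' @export
trait_params <- function(mu = 0, sigma2_a = 26.35, sigma2_e = 61.49,
                         h2 = NULL) {
  if (!(sigma2_a > 0 && sigma2_e > 0)) {
    abort("Variances must be positive.", class = "gpqtl_invalid_design")
  }
  derived <- sigma2_a / (sigma2_a + sigma2_e)
  if (!is.null(h2) && abs(h2 - derived) > 1e-9) {
    abort(sprintf("h2 = %.6f inconsistent with sigma2_a/(sigma2_a + sigma2_e) = %.6f.",
                  h2, derived),
          class = "gpqtl_invalid_design")
  }
  structure(list(mu = mu, sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 h2 = derived),
            class = "trait_params")
}

#' Calibrate QTL effects and assign phenotypes
#'
#' Rescales all QTL effects by one common factor so that the empirical
#' variance of the true breeding values among progeny equals `trait$sigma2_a`
#' exactly (enforced, not estimated), then draws i.i.d. normal residuals with
#' variance `trait$sigma2_e` and assigns phenotypes
#' `y = mu + tbv_total + e` to a random sample of `n_phenotyped_per_family`
#' progeny per full-sib family.  Remaining progeny are flagged as validation
#' individuals with missing phenotype; founders are genotyped but never
#' phenotyped.
#'
#' @param pop A `sim_pop` in progress: list with `pedigree`, `haplotypes`,
#'   `qtl` (see [simulate_population()], which calls this).
#' @param trait [trait_params()].
#' @param n_phenotyped_per_family Phenotyped progeny per full-sib family
#'   (default 10).
#' @param seed Optional integer seed.
#'
#' @return `pop` with rescaled `qtl`, a `tbv` tibble, and a `phenotypes`
#'   tibble (`id`, `y`, `role` in founder/training/validation, `family`).
#' @export
scale_and_phenotype <- function(pop, trait = trait_params(),
                                n_phenotyped_per_family = 10, seed = NULL) {
  ped <- pop$pedigree
  prog <- ped$generation == "progeny"
  fam_sizes <- table(ped$family[prog])
  if (any(fam_sizes < n_phenotyped_per_family)) {
    abort("n_phenotyped_per_family exceeds the full-sib family size.",
          class = "gpqtl_invalid_design")
  }

  gv <- genetic_values(pop$haplotypes, pop$qtl)
  v0 <- var1(gv$tbv_additive[prog])
  if (v0 <= 0 && trait$sigma2_a > 0) {
    abort("Architecture yields zero additive variance; cannot calibrate to sigma2_a > 0.",
          class = "gpqtl_invalid_design")
  }
  fac <- sqrt(trait$sigma2_a / v0)
  pop$qtl$effect <- pop$qtl$effect * fac
  gv <- genetic_values(pop$haplotypes, pop$qtl)

  with_seed(seed, {
    phen_rows <- unlist(lapply(split(which(prog), ped$family[prog]),
                               function(rows) sort(sample(rows, n_phenotyped_per_family))))
    e <- rnorm(nrow(ped), 0, sqrt(trait$sigma2_e))
    y <- rep(NA_real_, nrow(ped))
    y[phen_rows] <- trait$mu + gv$tbv_total[phen_rows] + e[phen_rows]
    role <- ifelse(!prog, "founder",
                   ifelse(seq_len(nrow(ped)) %in% phen_rows,
                          "training", "validation"))
    pop$phenotypes <- tibble::tibble(id = ped$id, y = y, role = role,
                                     family = ped$family)
    pop$residuals <- ifelse(is.na(y), NA_real_, e)
  })
  pop$tbv <- tibble::tibble(id = ped$id, tbv_additive = gv$tbv_additive,
                            tbv_total = gv$tbv_total)
  pop$trait <- trait
  pop
}
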