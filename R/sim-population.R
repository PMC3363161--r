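#' Simulate a complete pedigreed SNP population with known QTL
#'
#' End-to-end generator: builds the mating design, simulates founder
#' haplotypes, enforces the founder linkage phase of linked QTL pairs, drops
#' genes through the pedigree under the Haldane model, computes true genetic
#' values, calibrates the additive variance and assigns phenotypes.  The
#' defaults emulate a two-generation design of 20 sires x 10 dams x 15
#' full-sib progeny, 5 chromosomes of 1 Morgan carrying 1,998 evenly spaced
#' SNPs, an 8-QTL architecture (one major and seven minor loci, one imprinted,
#' two additive-by-additive epistatic, two linked pairs in coupling/repulsion
#' phase), heritability 0.3 with additive variance 26.35 and residual variance
#' 61.49, and phenotypes for 10 progeny per family.
#'
#' @param n_sires,n_dams_per_sire,n_progeny_per_dam Mating design.
#' @param n_chr,chr_length,n_snps Marker map design.
#' @param maf_range Founder allele-frequency range.
#' @param architecture `"qtlmas2011"`, `"none"`, or a custom QTL tibble
#'   (see [qtl_architecture()]).
#' @param trait [trait_params()].
#' @param n_phenotyped_per_family Phenotyped progeny per full-sib family.
#' @param major_ratio,pair_spacing,imprint_parent Architecture tuning, see
#'   [qtl_architecture()].
#' @param hide_qtl If `TRUE`, QTL SNPs are excluded from the analysis panel
#'   (`genotypes`/`heterozygotes`) while remaining part of the truth; by
#'   default QTL are observed panel SNPs.
#' @param seed Integer seed controlling every random draw.
#'
#' @return An object of class `sim_pop`: list with `pedigree`, `map`, `qtl`,
#'   `haplotypes` (`pat`/`mat`), `genotypes` (dosage matrix, rownames = id),
#'   `heterozygotes` (0/1 indicator matrix), `tbv`, `phenotypes`, `trait`,
#'   `panel` (SNP indices of the analysis panel) and `seed`.
#' @examples
#' pop <- simulate_population(n_sires = 2, n_dams_per_sire = 2,
#'                            n_progeny_per_dam = 15, n_snps = 100, seed = 1)
#' table(pop$phenotypes$role)
#' @export
simulate_population <- function(n_sires = 20, n_dams_per_sire = 10,
                                n_progeny_per_dam = 15,
                                n_chr = 5, chr_length = 1, n_snps = 1998,
                                maf_range = c(0.1, 0.5),
                                architecture = "qtlmas2011",
                                trait = trait_params(),
                                n_phenotyped_per_family = 10,
                                major_ratio = 4, pair_spacing = 0.1,
                                imprint_parent = "paternal",
                                hide_qtl = FALSE, seed = NULL) {
  with_seed(seed, {
    ped <- sim_pedigree(n_sires, n_dams_per_sire, n_progeny_per_dam)
    map <- sim_marker_map(n_chr, chr_length, n_snps)
    qtl <- if (is.character(architecture) && architecture == "qtlmas2011") {
      qtl_architecture(map, "qtlmas2011", minor_effect = 1,
                       major_ratio = major_ratio, pair_spacing = pair_spacing,
                       imprint_parent = imprint_parent)
    } else if (is.character(architecture) && architecture == "none") {
      empty_architecture()
    } else {
      qtl_architecture(map, "custom", qtl = architecture)
    }

    n_founders <- sum(ped$generation == "founder")
    founders <- sim_founder_haplotypes(map, n_founders,
                                       maf_range[1], maf_range[2])
    # realize the stated founder linkage phase of linked additive pairs
    for (ph in c("coupling", "repulsion")) {
      rows <- which(!is.na(qtl$phase) & qtl$phase == ph)
      if (length(rows) == 2) {
        p <- runif(1, maf_range[1], maf_range[2])
        founders <- enforce_founder_phase(founders, qtl$snp[rows[1]],
                                          qtl$snp[rows[2]], ph, p)
      }
    }

    haps <- drop_genes(ped, founders, map)
    pop <- list(pedigree = ped, map = map, qtl = qtl, haplotypes = haps,
                founder_freq = founders$freq, seed = seed)

    if (nrow(qtl) > 0) {
      pop <- scale_and_phenotype(pop, trait, n_phenotyped_per_family)
    } else {
      gv <- genetic_values(haps, qtl)
      pop$tbv <- tibble::tibble(id = ped$id, tbv_additive = gv$tbv_additive,
                                tbv_total = gv$tbv_total)
      prog <- ped$generation == "progeny"
      phen_rows <- unlist(lapply(split(which(prog), ped$family[prog]),
                                 function(r) sort(sample(r, min(n_phenotyped_per_family, length(r))))))
      y <- rep(NA_real_, nrow(ped))
      e <- rnorm(nrow(ped), 0, sqrt(trait$sigma2_e))
      y[phen_rows] <- trait$mu + gv$tbv_total[phen_rows] + e[phen_rows]
      pop$phenotypes <- tibble::tibble(
        id = ped$id, y = y,
        role = ifelse(!prog, "founder",
                      ifelse(seq_len(nrow(ped)) %in% phen_rows,
                             "training", "validation")),
        family = ped$family)
      pop$trait <- trait
    }

    X <- pop$haplotypes$pat + pop$haplotypes$mat
    W <- (pop$haplotypes$pat != pop$haplotypes$mat) * 1L
    rownames(X) <- rownames(W) <- ped$id
    panel <- seq_len(n_snps)
    if (hide_qtl && nrow(qtl) > 0) panel <- setdiff(panel, qtl$snp)
    pop$genotypes <- X
    pop$heterozygotes <- W
    pop$panel <- panel
    structure(pop, class = "sim_pop")
  })
}

#' @export
print.sim_pop <- function(x, ...) {
  cat("Simulated population\n")
  cat(sprintf("  individuals: %d (%d founders, %d progeny)\n",
              nrow(x$pedigree), sum(x$pedigree$generation == "founder"),
              sum(x$pedigree$generation == "progeny")))
  cat(sprintf("  SNPs: %d on %d chromosomes (%d in analysis panel)\n",
              nrow(x$map), max(x$map$chromosome), length(x$panel)))
  cat(sprintf("  QTL: %d (%s)\n", nrow(x$qtl),
              if (nrow(x$qtl)) paste(x$qtl$action, collapse = ", ") else "none"))
  cat(sprintf("  phenotyped: %d; validation: %d\n",
              sum(x$phenotypes$role == "training"),
              sum(x$phenotypes$role == "validation")))
  invisible(x)
}
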