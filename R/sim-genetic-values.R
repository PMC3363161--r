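#' Compute true genetic values from haplotypes and a QTL architecture
#'
#' Per-locus contributions to the total genetic value:
#' * additive QTL: `effect * (dosage - 1)` (the effect is half the difference
#'   between the two homozygotes);
#' * imprinted QTL: `effect * s`, where `s = +1/-1` codes the allele inherited
#'   from the expressing parent (only the parental-origin allele matters);
#' * epistatic pair: `effect * (dosage_A - 1) * (dosage_B - 1)`, one
#'   interaction coefficient shared by the pair (counted once).
#'
#' The additive (breeding-value) component sums the additive QTL contributions
#' plus the average-effect part of the non-additive loci, computed from
#' population allele frequencies: an imprinted locus of effect `e` has average
#' effect `e` (half its variance is additive); each member of an epistatic
#' pair with coefficient `w` has average effect `w * (2 * p_partner - 1)`.
#'
#' @param haplotypes List with matrices `pat` and `mat` (individuals x SNPs,
#'   0/1), e.g. from [drop_genes()].
#' @param qtl Architecture tibble from [qtl_architecture()].
#' @param freq Optional allele frequencies used for the average-effect
#'   decomposition; defaults to the observed frequencies of the supplied
#'   individuals.
#'
#' @return A tibble with columns `tbv_additive` (true breeding value) and
#'   `tbv_total` (total genetic value), one row per individual.
#' @export
genetic_values <- function(haplotypes, qtl, freq = NULL) {
  n <- nrow(haplotypes$pat)
  if (nrow(qtl) == 0) {
    return(tibble::tibble(tbv_additive = rep(0, n), tbv_total = rep(0, n)))
  }
  if (any(qtl$snp < 1 | qtl$snp > ncol(haplotypes$pat))) {
    abort("QTL index outside the genotype matrix.", class = "gpqtl_invalid_design")
  }
  X <- haplotypes$pat + haplotypes$mat
  if (is.null(freq)) freq <- allele_freqs(X)

  tbv_a <- numeric(n)
  tbv_t <- numeric(n)
  pair_done <- logical(nrow(qtl))
  for (q in seq_len(nrow(qtl))) {
    j <- qtl$snp[q]
    e <- qtl$effect[q]
    xc <- X[, j] - 1
    switch(qtl$action[q],
      additive = {
        tbv_a <- tbv_a + e * xc
        tbv_t <- tbv_t + e * xc
      },
      imprinted = {
        origin <- if (identical(qtl$parent[q], "maternal")) haplotypes$mat
                  else haplotypes$pat
        tbv_t <- tbv_t + e * (2 * origin[, j] - 1)
        tbv_a <- tbv_a + e * xc              # average effect equals e
      },
      epistatic = {
        jb <- qtl$snp[qtl$partner[q]]
        tbv_a <- tbv_a + e * (2 * freq[jb] - 1) * xc
        if (!pair_done[q]) {                 # interaction term counted once
          tbv_t <- tbv_t + e * xc * (X[, jb] - 1)
          pair_done[q] <- TRUE
          pair_done[qtl$partner[q]] <- TRUE
        }
      },
      abort(sprintf("Unknown QTL action '%s'.", qtl$action[q]))
    )
  }
  tibble::tibble(tbv_additive = tbv_a, tbv_total = tbv_t)
}
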