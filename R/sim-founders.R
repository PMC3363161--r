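#' Simulate founder haplotypes in linkage equilibrium
#'
#' Each founder receives an ordered pair of binary haplotypes (paternal,
#' maternal).  Per-SNP allele frequencies are drawn uniformly in
#' `[maf_low, maf_high]` and alleles are sampled independently per haplotype,
#' so founders are in linkage equilibrium; linkage disequilibrium in the
#' progeny arises from cosegregation during gene dropping.
#'
#' @param map Marker map from [sim_marker_map()].
#' @param n_founders Number of founder individuals.
#' @param maf_low,maf_high Bounds of the uniform allele-frequency draw; must
#'   satisfy `0 < maf_low <= maf_high <= 0.5`.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#'
#' @return A list with integer matrices `pat` and `mat`
#'   (`n_founders` x `nrow(map)`, entries 0/1) and the vector `freq` of
#'   frequencies the alleles were drawn at.
#' @export
sim_founder_haplotypes <- function(map, n_founders, maf_low = 0.1,
                                   maf_high = 0.5, seed = NULL) {
  n_founders <- check_count(n_founders, "n_founders")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    abort("Allele-frequency bounds must satisfy 0 < maf_low <= maf_high <= 0.5.",
          class = "gpqtl_invalid_design")
  }
  k <- nrow(map)
  with_seed(seed, {
    freq <- runif(k, maf_low, maf_high)
    pat <- matrix(rbinom(n_founders * k, 1L, rep(freq, each = n_founders)),
                  n_founders, k)
    mat <- matrix(rbinom(n_founders * k, 1L, rep(freq, each = n_founders)),
                  n_founders, k)
    list(pat = pat, mat = mat, freq = freq)
  })
}

# Overwrite founder haplotypes at a linked QTL pair to realize a stated
# founder linkage phase.  Coupling: the "1" alleles of both loci ride on the
# same haplotype (haplotypes (1,1) with probability p, else (0,0)).
# Repulsion: they ride on opposite haplotypes ((1,0) with probability p,
# else (0,1)), so locus B's "1" allele has frequency 1 - p.
enforce_founder_phase <- function(founders, idx_a, idx_b, phase, p) {
  stopifnot(phase %in% c("coupling", "repulsion"))
  for (h in c("pat", "mat")) {
    z <- rbinom(nrow(founders[[h]]), 1L, p)
    founders[[h]][, idx_a] <- z
    founders[[h]][, idx_b] <- if (phase == "coupling") z else 1L - z
  }
  founders$freq[idx_a] <- p
  founders$freq[idx_b] <- if (phase == "coupling") p else 1 - p
  founders
}
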