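#' Build an evenly spaced marker map
#'
#' Distributes `n_snps` markers over `n_chr` chromosomes of `chr_length`
#' Morgans each.  Chromosomes receive `floor(n_snps / n_chr)` SNPs, with the
#' remainder assigned to the first chromosomes; within a chromosome positions
#' are evenly spaced from 0 to `chr_length` inclusive.
#'
#' @param n_chr Number of chromosomes (default 5).
#' @param chr_length Chromosome length in Morgans (default 1).
#' @param n_snps Total number of SNPs genome-wide (default 1998).
#'
#' @return A tibble with columns `snp` (1-based global index), `chromosome`
#'   and `position` (Morgans).
#' @examples
#' map <- sim_marker_map()
#' table(map$chromosome)
#' @export
sim_marker_map <- function(n_chr = 5, chr_length = 1, n_snps = 1998) {
  n_chr <- check_count(n_chr, "n_chr")
  n_snps <- check_count(n_snps, "n_snps", min = n_chr)
  stopifnot(chr_length >= 0)
  per <- rep(n_snps %/% n_chr, n_chr)
  extra <- n_snps %% n_chr
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  tibble::tibble(
    snp = seq_len(n_snps),
    chromosome = rep(seq_len(n_chr), per),
    position = unlist(lapply(per, function(m) {
      if (m == 1) chr_length / 2 else seq(0, chr_length, length.out = m)
    }))
  )
}
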