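#' Drop founder alleles through a pedigree
#'
#' Propagates founder haplotypes to all descendants by simulating meiosis per
#' chromosome under the Haldane model: the number of crossovers is Poisson
#' with mean equal to the chromosome length in Morgans, crossover positions
#' are uniform, the starting parental strand is chosen fairly, and there is
#' no interference.  Every progeny allele is a copy of a parental allele.
#'
#' @param pedigree Pedigree tibble from [sim_pedigree()]; parents must precede
#'   their offspring.
#' @param founders Founder haplotypes from [sim_founder_haplotypes()]; row `i`
#'   corresponds to the founder with the `i`-th founder id.
#' @param map Marker map from [sim_marker_map()].
#' @param seed Optional integer seed.
#'
#' @return A list with integer matrices `pat` and `mat`
#'   (`nrow(pedigree)` x `nrow(map)`): the paternally and maternally inherited
#'   haplotype of every individual, rows ordered as `pedigree$id`.
#' @export
drop_genes <- function(pedigree, founders, map, seed = NULL) {
  n <- nrow(pedigree)
  k <- nrow(map)
  founder_ids <- pedigree$id[pedigree$generation == "founder"]
  if (nrow(founders$pat) < length(founder_ids)) {
    abort("Founder haplotypes missing for some founders.",
          class = "gpqtl_missing_parent")
  }
  chr_split <- split(seq_len(k), map$chromosome)
  chr_len <- vapply(split(map$position, map$chromosome), max, numeric(1))
  chr_pos <- split(map$position, map$chromosome)

  pat <- matrix(0L, n, k)
  mat <- matrix(0L, n, k)
  row_of <- integer(max(pedigree$id))
  row_of[pedigree$id] <- seq_len(n)

  with_seed(seed, {
    f <- 0L
    for (r in seq_len(n)) {
      if (pedigree$generation[r] == "founder") {
        f <- f + 1L
        pat[r, ] <- founders$pat[f, ]
        mat[r, ] <- founders$mat[f, ]
      } else {
        sr <- pedigree$sire[r]
        dr <- pedigree$dam[r]
        if (sr <= 0 || dr <= 0 || row_of[sr] == 0 || row_of[dr] == 0 ||
            row_of[sr] >= r || row_of[dr] >= r) {
          abort(sprintf("Progeny %d has unknown or later-listed parents.",
                        pedigree$id[r]),
                class = "gpqtl_missing_parent")
        }
        pat[r, ] <- meiosis(pat[row_of[sr], ], mat[row_of[sr], ],
                            chr_split, chr_pos, chr_len)
        mat[r, ] <- meiosis(pat[row_of[dr], ], mat[row_of[dr], ],
                            chr_split, chr_pos, chr_len)
      }
    }
  })
  list(pat = pat, mat = mat)
}

# One gamete from a parent's ordered haplotype pair (Haldane, no interference).
meiosis <- function(hap1, hap2, chr_split, chr_pos, chr_len) {
  gam <- integer(length(hap1))
  for (c in seq_along(chr_split)) {
    idx <- chr_split[[c]]
    nx <- rpois(1, chr_len[c])
    start <- sample(0:1, 1)
    if (nx == 0) {
      strand <- rep(start, length(idx))
    } else {
      xpos <- sort(runif(nx, 0, chr_len[c]))
      strand <- (start + findInterval(chr_pos[[c]], xpos)) %% 2
    }
    gam[idx] <- ifelse(strand == 0, hap1[idx], hap2[idx])
  }
  gam
}
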