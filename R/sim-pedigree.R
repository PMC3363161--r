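#' Build a two-generation full-sib pedigree
#'
#' Constructs the mating design of the simulated population: `n_sires` sires,
#' `n_dams_per_sire` dams each mated to exactly one sire, and
#' `n_progeny_per_dam` full-sib progeny per dam.  Founders (sires and dams)
#' have unknown parents, coded 0.
#'
#' @param n_sires Number of sires (default 20).
#' @param n_dams_per_sire Dams mated to each sire (default 10).
#' @param n_progeny_per_dam Full-sib progeny per dam (default 15).
#'
#' @return A tibble with columns `id`, `sire`, `dam` (0 for unknown),
#'   `generation` (`"founder"` or `"progeny"`) and, for progeny, `family`
#'   (the dam id, identifying the full-sib family).
#'
#' @examples
#' ped <- sim_pedigree(2, 2, 2)
#' nrow(ped) # 2 + 4 + 8
#' @export
sim_pedigree <- function(n_sires = 20, n_dams_per_sire = 10,
                         n_progeny_per_dam = 15) {
  s <- check_count(n_sires, "n_sires")
  d <- check_count(n_dams_per_sire, "n_dams_per_sire")
  p <- check_count(n_progeny_per_dam, "n_progeny_per_dam")

  n_dams <- s * d
  sires <- tibble::tibble(id = seq_len(s), sire = 0L, dam = 0L,
                          generation = "founder", family = NA_integer_)
  dams <- tibble::tibble(id = s + seq_len(n_dams), sire = 0L, dam = 0L,
                         generation = "founder", family = NA_integer_)
  dam_id <- rep(dams$id, each = p)
  sire_id <- rep(rep(seq_len(s), each = d), each = p)
  prog <- tibble::tibble(
    id = s + n_dams + seq_len(n_dams * p),
    sire = sire_id, dam = dam_id,
    generation = "progeny", family = dam_id
  )
  dplyr::bind_rows(sires, dams, prog)
}
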