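#' Define the QTL architecture on a marker map
#'
#' QTL are designated map SNPs.  The default `"qtlmas2011"` preset places
#' 8 QTL on chromosomes 1-5: a major additive locus (chromosome 1, effect
#' `major_ratio` times the minor effect), a linked additive pair in coupling
#' phase (chromosome 2), a linked additive pair in repulsion phase
#' (chromosome 3), one imprinted locus expressing only the paternally
#' inherited allele (chromosome 4, configurable via `imprint_parent`) and one
#' additive-by-additive epistatic pair (chromosome 5).  All seven minor
#' effects have equal magnitude before variance calibration.
#'
#' @param map Marker map tibble.
#' @param preset `"qtlmas2011"` for the default 8-QTL architecture, or
#'   `"custom"` to pass `qtl` directly.
#' @param qtl For `preset = "custom"`: a tibble with columns `snp` (map SNP
#'   index), `action` (`"additive"`, `"imprinted"`, `"epistatic"`), `effect`,
#'   and optionally `partner` (epistatic partner SNP index), `parent`
#'   (`"paternal"`/`"maternal"` for imprinted loci) and `phase`
#'   (`"coupling"`/`"repulsion"` for linked additive pairs, else `NA`).
#' @param minor_effect Minor-effect magnitude before calibration (default 1).
#' @param major_ratio Major/minor effect ratio (default 4).
#' @param pair_spacing Map distance in Morgans between members of the linked
#'   and epistatic pairs (default 0.1), centered on the chromosome midpoint.
#' @param imprint_parent Parent whose transmitted allele is expressed at the
#'   imprinted locus (default `"paternal"`).
#'
#' @return A tibble with columns `qtl_id`, `snp`, `chromosome`, `position`,
#'   `action`, `effect`, `partner`, `parent`, `phase`.
#' @export
qtl_architecture <- function(map, preset = c("qtlmas2011", "custom"),
                             qtl = NULL, minor_effect = 1, major_ratio = 4,
                             pair_spacing = 0.1,
                             imprint_parent = c("paternal", "maternal")) {
  preset <- match.arg(preset)
  imprint_parent <- match.arg(imprint_parent)

  if (preset == "qtlmas2011") {
    if (max(map$chromosome) < 5) {
      abort("The qtlmas2011 preset needs 5 chromosomes.",
            class = "gpqtl_invalid_design")
    }
    mid <- stats::median(range(map$position))
    lo <- mid - pair_spacing / 2
    hi <- mid + pair_spacing / 2
    snp_at <- function(chr, pos) {
      m <- map[map$chromosome == chr, ]
      m$snp[which.min(abs(m$position - pos))]
    }
    e <- minor_effect
    qtl <- tibble::tibble(
      snp = c(snp_at(1, mid), snp_at(2, lo), snp_at(2, hi),
              snp_at(3, lo), snp_at(3, hi), snp_at(4, mid),
              snp_at(5, lo), snp_at(5, hi)),
      action = c("additive", "additive", "additive", "additive", "additive",
                 "imprinted", "epistatic", "epistatic"),
      effect = c(major_ratio * e, e, e, e, e, e, e, e),
      partner = c(NA, NA, NA, NA, NA, NA, 8L, 7L),
      parent = c(NA, NA, NA, NA, NA, imprint_parent, NA, NA),
      phase = c(NA, "coupling", "coupling", "repulsion", "repulsion",
                NA, NA, NA)
    )
    # epistatic partners refer to qtl_id; resolve to snp below
  } else {
    if (is.null(qtl)) {
      return(empty_architecture())
    }
    qtl <- tibble::as_tibble(qtl)
    if (nrow(qtl) == 0) return(empty_architecture())
    stopifnot(all(c("snp", "action", "effect") %in% names(qtl)))
    if (!"partner" %in% names(qtl)) qtl$partner <- NA_integer_
    if (!"parent" %in% names(qtl)) qtl$parent <- NA_character_
    if (!"phase" %in% names(qtl)) qtl$phase <- NA_character_
    if (!all(qtl$snp %in% map$snp)) {
      abort("QTL placed at SNP indices that do not exist on the map.",
            class = "gpqtl_invalid_design")
    }
    # custom specs give `partner` as a SNP index; convert to row index
    qtl$partner <- match(qtl$partner, qtl$snp)
  }

  qtl$qtl_id <- seq_len(nrow(qtl))
  epi <- which(qtl$action == "epistatic")
  # symmetric partnership: partner's partner must point back
  ok <- length(epi) %% 2 == 0 &&
    all(!is.na(qtl$partner[epi])) &&
    all(qtl$partner[epi] %in% epi) &&
    all(qtl$partner[qtl$partner[epi]] == epi)
  if (length(epi) > 0 && !ok) {
    abort("Every epistatic QTL needs exactly one partner and partnership must be symmetric.",
          class = "gpqtl_invalid_design")
  }

  qtl$chromosome <- map$chromosome[match(qtl$snp, map$snp)]
  qtl$position <- map$position[match(qtl$snp, map$snp)]
  qtl[, c("qtl_id", "snp", "chromosome", "position", "action", "effect",
          "partner", "parent", "phase")]
}

empty_architecture <- function() {
  tibble::tibble(qtl_id = integer(), snp = integer(), chromosome = integer(),
                 position = numeric(), action = character(), effect = numeric(),
                 partner = integer(), parent = character(), phase = character())
}
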