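#' Write a simulated dataset to plain-text files
#'
#' Writes `genotypes.txt` (one row per individual: id then 0/1/2 dosages,
#' whitespace-delimited), `pedigree.csv` (`id,sire,dam,generation`; unknown
#' parents are 0), `phenotypes.csv` (`id,trait`, `NA` for missing),
#' `map.tsv` (`snp,chrom,position_morgans`), `qtl_truth.tsv` and `tbv.tsv`.
#' Every file starts with comment headers (`#`) recording the package
#' version, the simulation seed and a hash of the generating configuration.
#'
#' @param pop A `sim_pop`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- dataset_header(pop)
  wv <- function(path, write_fun) {
    writeLines(hdr, path)
    write_fun(path)
  }
  wv(file.path(dir, "genotypes.txt"), function(f) {
    data.table::fwrite(
      data.table::data.table(id = pop$pedigree$id,
                             as.data.table_safe(pop$genotypes)),
      f, sep = " ", col.names = FALSE, append = TRUE)
  })
  wv(file.path(dir, "pedigree.csv"), function(f) {
    data.table::fwrite(pop$pedigree[, c("id", "sire", "dam", "generation")],
                       f, append = TRUE, col.names = TRUE)
  })
  wv(file.path(dir, "phenotypes.csv"), function(f) {
    data.table::fwrite(
      data.frame(id = pop$phenotypes$id, trait = pop$phenotypes$y),
      f, append = TRUE, col.names = TRUE, na = "NA", quote = FALSE)
  })
  wv(file.path(dir, "map.tsv"), function(f) {
    data.table::fwrite(
      data.frame(snp = pop$map$snp, chrom = pop$map$chromosome,
                 position_morgans = pop$map$position),
      f, sep = "\t", append = TRUE, col.names = TRUE)
  })
  wv(file.path(dir, "qtl_truth.tsv"), function(f) {
    q <- pop$qtl
    q$partner_snp <- ifelse(is.na(q$partner), NA_integer_, q$snp[q$partner])
    data.table::fwrite(q[, c("qtl_id", "snp", "chromosome", "position",
                             "action", "effect", "partner_snp", "parent",
                             "phase")],
                       f, sep = "\t", append = TRUE, col.names = TRUE,
                       na = "NA", quote = FALSE)
  })
  wv(file.path(dir, "tbv.tsv"), function(f) {
    data.table::fwrite(pop$tbv, f, sep = "\t", append = TRUE, col.names = TRUE)
  })
  invisible(dir)
}

as.data.table_safe <- function(m) data.table::as.data.table(unclass(m))

dataset_header <- function(pop) {
  cfg <- paste(c(dim(pop$genotypes), nrow(pop$qtl), pop$trait$sigma2_a,
                 pop$trait$sigma2_e, pop$seed %||% "NULL"), collapse = "|")
  c(sprintf("# gpqtl %s", as.character(utils::packageVersion("gpqtl"))),
    sprintf("# seed: %s", pop$seed %||% "NULL"),
    sprintf("# config_hash: %08x", config_hash(cfg)))
}

# small stable string hash (djb2), enough to tie outputs to a config
config_hash <- function(s) {
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^28
  as.integer(h)
}

#' Read a dataset written by [write_dataset()]
#'
#' Validates genotype dosages (must be 0/1/2, errors name the file and line),
#' id consistency across files and map sortedness.  Validation individuals
#' are those genotyped with missing phenotype.
#'
#' @param dir Directory containing the files written by [write_dataset()].
#' @return A list with `genotypes` (matrix, rownames = id), `phenotypes`,
#'   `pedigree`, `map` tibbles, and `qtl`/`tbv` when the truth files exist.
#' @export
read_dataset <- function(dir) {
  fg <- file.path(dir, "genotypes.txt")
  gt <- data.table::fread(fg, header = FALSE, skip = n_comment_lines(fg),
                          data.table = FALSE)
  ids <- gt[[1]]
  X <- as.matrix(gt[, -1, drop = FALSE])
  bad <- which(!(X %in% c(0, 1, 2)))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(X)) + 1
    j <- ((bad[1] - 1) %/% nrow(X)) + 1
    abort(sprintf("Invalid dosage %s in %s (individual row %d, SNP %d).",
                  format(X[i, j]), fg, i, j),
          class = "gpqtl_parse")
  }
  storage.mode(X) <- "integer"
  rownames(X) <- ids

  read_table_file <- function(f, ...) {
    tibble::as_tibble(data.table::fread(f, data.table = FALSE,
                                        skip = n_comment_lines(f), ...))
  }
  ped <- read_table_file(file.path(dir, "pedigree.csv"))
  phen <- read_table_file(file.path(dir, "phenotypes.csv"), na.strings = "NA")
  map <- read_table_file(file.path(dir, "map.tsv"))
  names(map) <- c("snp", "chromosome", "position")

  unknown <- setdiff(phen$id, ids)
  if (length(unknown) > 0) {
    abort(sprintf("Phenotype file %s contains id(s) absent from genotypes: %s.",
                  file.path(dir, "phenotypes.csv"),
                  paste(head(unknown, 5), collapse = ", ")),
          class = "gpqtl_id_mismatch")
  }
  if (is.unsorted(map$snp) ||
      any(unlist(lapply(split(map$position, map$chromosome), is.unsorted)))) {
    abort(sprintf("Map file %s is not sorted by SNP/position.",
                  file.path(dir, "map.tsv")),
          class = "gpqtl_parse")
  }

  out <- list(genotypes = X, pedigree = ped,
              phenotypes = tibble::tibble(
                id = phen$id, y = phen$trait,
                role = ifelse(!is.na(phen$trait), "training",
                              ifelse(ped$generation[match(phen$id, ped$id)] ==
                                       "progeny", "validation", "founder"))),
              map = map)
  ftruth <- file.path(dir, "qtl_truth.tsv")
  if (file.exists(ftruth)) {
    out$qtl <- read_table_file(ftruth, na.strings = "NA")
    out$tbv <- read_table_file(file.path(dir, "tbv.tsv"))
  }
  out
}

n_comment_lines <- function(path) {
  first <- readLines(path, n = 100)
  sum(cumprod(startsWith(first, "#")))
}
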