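#' Genomic relationship matrices
#'
#' `build_grm()` constructs the additive genomic relationship matrix
#' (VanRaden method 1): with observed allele frequencies `p`,
#' `M = X - 2p` column-centered and `G = M M' / (2 * sum(p * (1 - p)))`.
#' Monomorphic SNPs contribute nothing.  The exact formula is stored; a
#' diagonal ridge (attribute `ridge`, default 1e-6) is applied wherever the
#' matrix itself must be inverted.
#'
#' `build_dominance_rm()` uses the heterozygosity coding (1 for
#' heterozygotes, 0 for both homozygotes), columns centered by the expected
#' heterozygosity `2 p q`, and denominator
#' `sum(2 p q * (1 - 2 p q))`.
#'
#' `build_epistasis_rm()` builds the additive-by-additive matrix as the
#' element-wise (Hadamard) square `G * G` by default, or the literal matrix
#' square `G %*% G` with `method = "matrix-square"`.
#'
#' @param X Dosage matrix (individuals x SNPs, 0/1/2).
#' @param ridge Diagonal ridge used when the matrix is inverted downstream.
#' @return A `genomic_rel`: the relationship matrix with attributes `kind`,
#'   `freq` (allele frequencies), `denominator` and `ridge`.
#' @examples
#' X <- rbind(c(0, 0), c(2, 2))
#' unclass(build_grm(X))[1:2, 1:2]
#' @export
build_grm <- function(X, ridge = 1e-6) {
  stopifnot(nrow(X) >= 2)
  p <- allele_freqs(X)
  poly <- p > 0 & p < 1
  if (!any(poly)) {
    abort("All SNPs are monomorphic; the scaling denominator is zero.",
          class = "gpqtl_degenerate")
  }
  M <- sweep(X[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(M) / denom
  new_genomic_rel(G, "additive", p, denom, ridge)
}

#' @rdname build_grm
#' @export
build_dominance_rm <- function(X, ridge = 1e-6) {
  stopifnot(nrow(X) >= 2)
  p <- allele_freqs(X)
  H <- (X == 1) * 1
  if (!any(H == 1)) {
    abort("No heterozygous genotypes; dominance relationships are undefined.",
          class = "gpqtl_degenerate")
  }
  tpq <- 2 * p * (1 - p)
  keep <- tpq > 0
  Hc <- sweep(H[, keep, drop = FALSE], 2, tpq[keep])
  denom <- sum(tpq[keep] * (1 - tpq[keep]))
  D <- tcrossprod(Hc) / denom
  new_genomic_rel(D, "dominance", p, denom, ridge)
}

#' @rdname build_grm
#' @param G An additive `genomic_rel` (or plain square symmetric matrix).
#' @param method `"hadamard"` (default) or `"matrix-square"`.
#' @export
build_epistasis_rm <- function(G, method = c("hadamard", "matrix-square")) {
  method <- match.arg(method)
  if (nrow(G) != ncol(G)) abort("Epistatic construction needs a square matrix.")
  ridge <- attr(G, "ridge") %||% 1e-6
  E <- if (method == "hadamard") unclass(G) * unclass(G)
       else unclass(G) %*% unclass(G)
  new_genomic_rel(E, "epistatic", attr(G, "freq"), attr(G, "denominator"),
                  ridge)
}

new_genomic_rel <- function(mat, kind, freq, denom, ridge) {
  structure(mat, kind = kind, freq = freq, denominator = denom,
            ridge = ridge, class = c("genomic_rel", "matrix", "array"))
}

#' @export
print.genomic_rel <- function(x, ...) {
  cat(sprintf("%s genomic relationship matrix: %d x %d (denominator %.4f, ridge %g)\n",
              attr(x, "kind"), nrow(x), ncol(x), attr(x, "denominator"),
              attr(x, "ridge")))
  invisible(x)
}

# relationship matrix with its ridge applied, as a plain matrix
ridged <- function(K) {
  R <- unclass(K)
  diag(R) <- diag(R) + (attr(K, "ridge") %||% 0)
  R
}
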