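# internal helpers shared across modules

# run `expr` under a fixed RNG seed without disturbing the caller's stream;
# seed = NULL means "use the current stream"
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1)
  withr::with_seed(as.integer(seed), expr)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d (got %s).",
                  name, min, paste(format(x), collapse = ",")),
          class = "gpqtl_invalid_design")
  }
  as.integer(x)
}

# sample variance that tolerates length-1 input
var1 <- function(x) if (length(x) < 2) 0 else stats::var(x)

# observed allele frequency of the "1" allele from a dosage matrix
allele_freqs <- function(X) colMeans(X) / 2
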