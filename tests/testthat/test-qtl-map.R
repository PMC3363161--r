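make_map <- function(n_chr, per_chr, len = 1) {
  tibble::tibble(snp = seq_len(n_chr * per_chr),
                 chromosome = rep(seq_len(n_chr), each = per_chr),
                 position = rep(seq(0, len, length.out = per_chr), n_chr))
}

test_that("window bookkeeping: counts, spans and chromosome boundaries", {
  map <- make_map(2, 30)
  X <- random_dosages(40, 60, seed = 71)
  w <- window_variances(X, rnorm(60, 0, 0.2), map, window_size = 10)
  expect_equal(nrow(w), 2 * (30 - 10 + 1))
  expect_true(all(w$last_snp - w$first_snp == 9))
  expect_true(all(map$chromosome[w$first_snp] == map$chromosome[w$last_snp]))
  # consecutive windows within a chromosome overlap by window_size - 1
  by_chr <- split(w, w$chromosome)
  for (b in by_chr) expect_equal(diff(b$first_snp), rep(1, nrow(b) - 1))
  expect_error(window_variances(X, rnorm(60), map, window_size = 31),
               class = "gpqtl_invalid_design")
})

test_that("zero effects yield an all-zero window table with a warning", {
  map <- make_map(1, 20)
  X <- random_dosages(15, 20, seed = 72)
  expect_warning(w <- window_variances(X, rep(0, 20), map), "zero")
  expect_true(all(w$proportion == 0))
})

test_that("a single active SNP gives proportion 1 exactly in its windows", {
  map <- make_map(1, 25)
  X <- random_dosages(30, 25, seed = 73)
  eff <- rep(0, 25); eff[12] <- 0.8
  w <- window_variances(X, eff, map)
  inside <- w$first_snp <= 12 & w$last_snp >= 12
  expect_equal(w$proportion[inside], rep(1, sum(inside)))
  expect_equal(w$proportion[!inside], rep(0, sum(!inside)))
  expect_true(all(w$peak_snp[inside] == 12))
})

test_that("two independent SNPs split window variance as Var1/(Var1+Var2)", {
  withr::local_seed(74)
  # two uncorrelated loci in disjoint windows
  n <- 400
  x1 <- rbinom(n, 2, 0.5); x2 <- rbinom(n, 2, 0.3)
  X <- cbind(x1, matrix(rbinom(n * 28, 2, 0.4), n, 28), x2)
  map <- make_map(1, 30)
  eff <- rep(0, 30); eff[1] <- 1; eff[30] <- 0.6
  w <- window_variances(X, eff, map)
  v1 <- var(x1) * 1^2; v2 <- var(x2) * 0.6^2
  # empirical covariances make this approximate at finite n
  gebv_var <- var(sweep(X, 2, colMeans(X)) %*% eff)[1]
  first <- w$proportion[w$first_snp == 1]
  last <- w$proportion[w$last_snp == 30]
  expect_equal(first, var(x1) / gebv_var, tolerance = 1e-10)
  expect_equal(last, v2 / gebv_var, tolerance = 1e-10)
  expect_equal(first / (first + last), v1 / (v1 + v2), tolerance = 0.15)
})

test_that("disjoint windows partition the GEBV exactly", {
  map <- make_map(1, 30)
  X <- random_dosages(25, 30, seed = 75)
  eff <- rnorm(30, 0, 0.3)
  p <- colMeans(X) / 2
  Xc <- sweep(X, 2, 2 * p)
  gebv <- drop(Xc %*% eff)
  w <- window_variances(X, eff, map)
  # windows starting at 1, 11, 21 are disjoint and cover the chromosome
  parts <- sapply(c(1, 11, 21), function(f) {
    idx <- f:(f + 9)
    drop(Xc[, idx] %*% eff[idx])
  })
  expect_equal(rowSums(parts), gebv, tolerance = 1e-12)
})

test_that("the BayesCpi quantile rule flags the stated share of windows", {
  withr::local_seed(76)
  map <- make_map(5, 400)
  prop <- runif(5 * 391)  # synthetic window proportions, all distinct
  w <- tibble::tibble(window_id = seq_along(prop),
                      chromosome = rep(1:5, each = 391),
                      first_snp = unlist(lapply(0:4, function(c)
                        c * 400 + 1:391)),
                      last_snp = unlist(lapply(0:4, function(c)
                        c * 400 + 10:400)),
                      proportion = prop)
  attr(w, "snp_share") <- rep(prop, length.out = 2000)[1:2000]
  n_sig <- sum(prop >= quantile(prop, 0.995))
  expect_equal(n_sig, ceiling(0.005 * length(prop)), tolerance = 1)
  calls <- call_qtl_bayes(w, make_map(5, 400), "bayesCpi", pi_hat = 0.995)
  expect_true(nrow(calls) >= 1)
})

test_that("adjacent significant windows merge into one call at the peak share", {
  # two active SNPs five apart: their windows overlap and must merge
  withr::local_seed(77)
  n <- 300
  map <- make_map(1, 40)
  X <- random_dosages(n, 40, seed = 77)
  eff <- rep(0, 40); eff[18] <- 1; eff[23] <- 0.7
  w <- window_variances(X, eff, map)
  calls <- call_qtl_bayes(w, map, "bayesCpi", pi_hat = 0.9)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$snp, 18)   # larger variance share wins within the span
  expect_true(calls$first_snp <= 18 && calls$last_snp >= 23)
})

test_that("calls are invariant to positive rescaling of effects", {
  map <- make_map(2, 30)
  X <- random_dosages(100, 60, seed = 78)
  eff <- rep(0, 60); eff[c(10, 45)] <- c(1, 0.8)
  w1 <- window_variances(X, eff, map)
  w2 <- window_variances(X, 7.3 * eff, map)
  c1 <- call_qtl_bayes(w1, map, "bayesCpi", pi_hat = 0.95)
  c2 <- call_qtl_bayes(w2, map, "bayesCpi", pi_hat = 0.95)
  expect_equal(c1, c2)
  g1 <- call_qtl_gblup(eff, map)
  g2 <- call_qtl_gblup(7.3 * eff, map)
  expect_equal(g1$snp, g2$snp)
})

test_that("GBLUP effect calls flag spikes and merge nearby runs", {
  map <- make_map(1, 100)
  expect_error(call_qtl_gblup(numeric(0), map))
  # all-zero effects: no calls
  expect_equal(nrow(call_qtl_gblup(rep(0, 100), map)), 0)
  # one spike well above background
  withr::local_seed(79)
  a <- rnorm(100, 0, 0.01); a[40] <- 1
  calls <- call_qtl_gblup(a, map)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$snp, 40)
  # two spikes within 10 SNPs merge; the larger wins
  a2 <- rnorm(100, 0, 0.01); a2[40] <- 1; a2[45] <- 0.8
  c2 <- call_qtl_gblup(a2, map)
  expect_equal(nrow(c2), 1)
  expect_equal(c2$snp, 40)
  expect_equal(attr(c2, "n_flagged"), 2)
})

test_that("call scoring credits each QTL once (brute-force assignment oracle)", {
  truth <- tibble::tibble(qtl_id = 1:2, chromosome = c(1L, 2L),
                          position = c(0.5, 0.5),
                          action = c("additive", "additive"))
  mk_calls <- function(chr, pos) {
    tibble::tibble(method = "m", chromosome = chr, snp = seq_along(chr),
                   position = pos, variance_share = 1,
                   first_snp = 1L, last_snp = 1L, n_windows = 1L)
  }
  # perfect single call
  ev <- evaluate_calls(mk_calls(1L, 0.5), truth)
  expect_equal(ev$summary$tp, 1); expect_equal(ev$summary$fp, 0)
  # call on an empty chromosome
  ev2 <- evaluate_calls(mk_calls(3L, 0.2), truth)
  expect_equal(ev2$summary$tp, 0); expect_equal(ev2$summary$fp, 1)
  # two calls near one QTL: single crediting
  ev3 <- evaluate_calls(mk_calls(c(1L, 1L), c(0.49, 0.52)), truth)
  expect_equal(ev3$summary$tp, 1); expect_equal(ev3$summary$fp, 1)
  # the closer call is the one credited
  expect_equal(ev3$detections$distance[1], 0.01, tolerance = 1e-9)
  # brute-force check over all assignments for a 3-call configuration
  calls <- mk_calls(c(1L, 1L, 2L), c(0.48, 0.54, 0.51))
  ev4 <- evaluate_calls(calls, truth)
  # enumeration: best assignment pairs one chr1 call with QTL1, chr2 with QTL2
  expect_equal(ev4$summary$tp, 2); expect_equal(ev4$summary$fp, 1)
  # beyond tolerance: no credit
  ev5 <- evaluate_calls(mk_calls(1L, 0.58), truth, tolerance_morgans = 0.05)
  expect_equal(ev5$summary$tp, 0)
})
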