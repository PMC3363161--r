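# Oracle tests for the single-site Gibbs samplers: closed-form ridge,
# numerical quadrature and exhaustive enumeration, plus structural contracts.

test_that("noiseless single-active-SNP data is identified by both samplers", {
  X <- random_dosages(80, 6, seed = 31)
  a_true <- 1.5
  y <- a_true * (X[, 3] - mean(X[, 3]))  # zero noise
  y <- y + rnorm(length(y), 0, 1e-6)

  for (fit in list(
    run_bayescpi(y, X, n_iter = 3000, burn_in = 500, thin = 2, seed = 1),
    run_bayesb(y, X, n_iter = 3000, burn_in = 500, thin = 2, pi = 0.5, seed = 2))) {
    eff <- tidy(fit)
    expect_gt(eff$model_freq_a[3], 0.95)
    expect_equal(eff$effect_a[3], a_true, tolerance = 0.05)
    expect_true(all(abs(eff$effect_a[-3]) < 0.1))
  }
})

test_that("BayesCpi with pi = 0 and fixed variances matches the ridge closed form", {
  withr::local_seed(32)
  n <- 40; k <- 8
  X <- random_dosages(n, k, seed = 32)
  beta_true <- rnorm(k, 0, 0.4)
  y <- drop(X %*% beta_true) + rnorm(n, 0, 1)
  s2b <- 0.2; s2e <- 1.0
  fit <- run_bayescpi(y, X, n_iter = 20000, burn_in = 2000, thin = 2,
                      pi = 0, sample_pi = FALSE,
                      effect_var = s2b, resid_var = s2e,
                      sample_effect_var = FALSE, sample_resid_var = FALSE,
                      seed = 3)
  p <- colMeans(X) / 2
  Xc <- sweep(X, 2, 2 * p)
  sol <- ridge_with_intercept(y, Xc, lambda = s2e / s2b)[-1]
  mcse <- apply(fit$samples$effect_a, 1, sd) / sqrt(fit$samples$n_saved)
  # single-site Gibbs draws are autocorrelated; allow a generous ESS deflation
  expect_true(all(abs(tidy(fit)$effect_a - sol) < pmax(3 * 5 * mcse, 0.02)))
})

test_that("a 1-SNP toy posterior matches 2-D numerical quadrature", {
  withr::local_seed(33)
  n <- 8
  x <- c(0, 1, 2, 1, 0, 2, 1, 1)
  y <- c(1.2, 0.3, -0.8, 0.5, 1.9, -1.1, 0.2, 0.0)
  pi0 <- 0.3; s2b <- 0.5; resid_var <- 1.0; nu_e <- 4
  fit <- run_bayescpi(y, cbind(x), n_iter = 200000, burn_in = 5000, thin = 10,
                      pi = pi0, sample_pi = FALSE,
                      effect_var = s2b, sample_effect_var = FALSE,
                      resid_var = resid_var, nu_resid = nu_e,
                      seed = 4)

  # quadrature oracle: integrate the intercept analytically (flat prior),
  # grid over (beta, sigma2_e) with the spike handled as a point mass
  xc <- x - mean(x)
  yc <- y - mean(y)
  s2_e_scale <- resid_var * (nu_e - 2) / nu_e
  loglik <- function(b, s2) {
    r <- yc - xc * b
    -0.5 * ((n - 1) * log(2 * pi * s2) + log(n) + sum(r^2) / s2)
  }
  ld_sinvchisq <- function(s2, nu, s0) {
    0.5 * nu * log(nu * s0 / 2) - lgamma(nu / 2) -
      (nu / 2 + 1) * log(s2) - nu * s0 / (2 * s2)
  }
  bg <- seq(-3, 3, length.out = 601)
  sg <- exp(seq(log(0.05), log(30), length.out = 601))
  ds <- c(diff(sg), 0)
  db <- bg[2] - bg[1]
  wslab <- outer(bg, sg, Vectorize(function(b, s2) {
    exp(loglik(b, s2) + dnorm(b, 0, sqrt(s2b), log = TRUE) +
          ld_sinvchisq(s2, nu_e, s2_e_scale) + log(1 - pi0))
  }))
  wspike <- exp(vapply(sg, function(s2) loglik(0, s2), numeric(1)) +
                  ld_sinvchisq(sg, nu_e, s2_e_scale) + log(pi0))
  z_slab <- sum(wslab %*% ds) * db
  z_spike <- sum(wspike * ds)
  z <- z_slab + z_spike
  e_beta <- sum((bg * wslab) %*% ds) * db / z
  e_s2 <- (sum(wslab %*% (sg * ds)) * db + sum(wspike * sg * ds)) / z
  p_incl <- z_slab / z

  expect_equal(tidy(fit)$effect_a[1], e_beta, tolerance = 0.01)
  expect_equal(mean(fit$samples$sigma2_e), e_s2, tolerance = 0.05)
  expect_equal(tidy(fit)$model_freq_a[1], p_incl, tolerance = 0.02)
})

test_that("BayesB inclusion probabilities match exhaustive enumeration", {
  withr::local_seed(34)
  n <- 12; k <- 3
  X <- random_dosages(n, k, seed = 34)
  y <- 1.0 * (X[, 2] - mean(X[, 2])) + rnorm(n, 0, 0.8)
  pi0 <- 0.5; nu_b <- 4.2; effect_var <- 0.5; resid_var <- 0.64
  fit <- run_bayesb(y, X, n_iter = 150000, burn_in = 5000, thin = 10,
                    pi = pi0, nu_effect = nu_b,
                    effect_var = effect_var,
                    resid_var = resid_var, sample_resid_var = FALSE,
                    n_mh = 10, seed = 5)

  # enumeration oracle: for each of the 2^3 inclusion patterns integrate the
  # effects analytically given the locus variances, the locus variances
  # numerically over their scaled-inverse-chi-square prior, and the
  # intercept analytically (flat prior)
  s2_b_scale <- effect_var * (nu_b - 2) / nu_b
  p <- colMeans(X) / 2
  Xc <- sweep(X, 2, 2 * p)
  ones <- rep(1, n)
  marg_pattern <- function(active) {
    # Gauss-type grid on the prior quantile scale per active locus
    m <- length(active)
    if (m == 0) return(mloglik_cov(diag(resid_var, n)))
    qs <- (seq_len(25) - 0.5) / 25
    grids <- lapply(seq_len(m), function(i) nu_b * s2_b_scale / qchisq(1 - qs, nu_b))
    idx <- do.call(expand.grid, lapply(grids, seq_along))
    tot <- 0
    for (r in seq_len(nrow(idx))) {
      V <- diag(resid_var, n)
      for (i in seq_len(m)) {
        s2 <- grids[[i]][idx[r, i]]
        xj <- Xc[, active[i]]
        V <- V + s2 * tcrossprod(xj)
      }
      tot <- tot + exp(mloglik_cov(V))
    }
    log(tot / nrow(idx))
  }
  mloglik_cov <- function(V) {
    Vi <- solve(V)
    s <- sum(Vi %*% ones)
    Q <- Vi - (Vi %*% ones %*% t(ones) %*% Vi) / s
    -0.5 * (determinant(V)$modulus + log(s) + drop(t(y) %*% Q %*% y))
  }
  patterns <- expand.grid(rep(list(0:1), k))
  lw <- apply(patterns, 1, function(g) {
    act <- which(g == 1)
    sum(g) * log(1 - pi0) + (k - sum(g)) * log(pi0) + marg_pattern(act)
  })
  w <- exp(lw - max(lw)); w <- w / sum(w)
  p_incl <- vapply(seq_len(k), function(j) sum(w[patterns[, j] == 1]), numeric(1))

  expect_true(all(abs(tidy(fit)$model_freq_a - p_incl) < 0.03))
})

test_that("BayesB on pure noise keeps model frequencies near the prior", {
  withr::local_seed(35)
  X <- random_dosages(100, 200, seed = 35)
  y <- rnorm(100)
  fit <- run_bayesb(y, X, n_iter = 4000, burn_in = 1000, thin = 2,
                    pi = 0.995, seed = 6)
  expect_lt(mean(tidy(fit)$model_freq_a), 5 * (1 - 0.995))
})

test_that("indicator-effect conservation: excluded SNPs carry exactly zero effect", {
  X <- random_dosages(50, 20, seed = 36)
  y <- drop(X %*% rnorm(20, 0, 0.3)) + rnorm(50)
  fit <- run_bayescpi(y, X, n_iter = 2000, burn_in = 500, thin = 2, seed = 7)
  zero_rate <- rowMeans(fit$samples$effect_a == 0)
  expect_equal(unname(zero_rate), 1 - tidy(fit)$model_freq_a, tolerance = 1e-12)
})

test_that("chains are reproducible under a fixed seed", {
  X <- random_dosages(30, 10, seed = 37)
  y <- rnorm(30)
  f1 <- run_bayescpi(y, X, n_iter = 500, burn_in = 100, thin = 2, seed = 11)
  f2 <- run_bayescpi(y, X, n_iter = 500, burn_in = 100, thin = 2, seed = 11)
  expect_identical(f1$effects, f2$effects)
  expect_identical(f1$samples$sigma2_e, f2$samples$sigma2_e)
})

test_that("degenerate inputs are rejected or handled", {
  X <- random_dosages(20, 5, seed = 38)
  expect_error(run_bayescpi(rep(1, 20), X, n_iter = 100, burn_in = 10))
  expect_error(run_bayescpi(rnorm(10), X, n_iter = 100, burn_in = 10))
  Xz <- cbind(X, 1L)  # constant column
  expect_warning(
    fit <- run_bayescpi(rnorm(20), Xz, n_iter = 200, burn_in = 50, seed = 1),
    "zero-variance")
  expect_equal(tidy(fit)$effect_a[6], 0)
})
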