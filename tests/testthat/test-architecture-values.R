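test_that("default architecture has 8 QTL, five of them additive", {
  map <- sim_marker_map()
  qtl <- qtl_architecture(map)
  expect_equal(nrow(qtl), 8)
  expect_equal(sum(qtl$action == "additive"), 5)
  expect_equal(sum(qtl$action == "imprinted"), 1)
  expect_equal(sum(qtl$action == "epistatic"), 2)
  expect_equal(sort(unique(qtl$chromosome)), 1:5)
  # major on chromosome 1 at the stated ratio
  major <- qtl$effect[qtl$chromosome == 1]
  minor <- qtl$effect[qtl$chromosome == 2][1]
  expect_equal(major / minor, 4)
  expect_setequal(qtl$phase[qtl$chromosome == 2], "coupling")
  expect_setequal(qtl$phase[qtl$chromosome == 3], "repulsion")
  # symmetric epistatic partnership
  epi <- which(qtl$action == "epistatic")
  expect_equal(qtl$partner[qtl$partner[epi]], epi)
})

test_that("empty custom architecture yields zero QTL and zero TBV", {
  map <- sim_marker_map(n_chr = 1, n_snps = 20)
  qtl <- qtl_architecture(map, "custom", qtl = NULL)
  expect_equal(nrow(qtl), 0)
  haps <- list(pat = matrix(rbinom(100, 1, 0.5), 5, 20),
               mat = matrix(rbinom(100, 1, 0.5), 5, 20))
  gv <- genetic_values(haps, qtl)
  expect_equal(gv$tbv_total, rep(0, 5))
  expect_equal(gv$tbv_additive, rep(0, 5))
})

test_that("incomplete or off-map architectures are rejected", {
  map <- sim_marker_map(n_chr = 1, n_snps = 20)
  expect_error(
    qtl_architecture(map, "custom",
                     qtl = tibble::tibble(snp = 5, action = "epistatic",
                                          effect = 1, partner = NA)),
    class = "gpqtl_invalid_design")
  expect_error(
    qtl_architecture(map, "custom",
                     qtl = tibble::tibble(snp = 99, action = "additive",
                                          effect = 1)),
    class = "gpqtl_invalid_design")
})

test_that("additive QTL: homozygotes differ by exactly twice the effect", {
  # one locus, the four ordered haplotype pairs
  haps <- list(pat = matrix(c(0L, 0L, 1L, 1L), 4, 1),
               mat = matrix(c(0L, 1L, 0L, 1L), 4, 1))
  qtl <- tibble::tibble(qtl_id = 1L, snp = 1L, chromosome = 1L, position = 0.5,
                        action = "additive", effect = 2.5,
                        partner = NA_integer_, parent = NA_character_,
                        phase = NA_character_)
  gv <- genetic_values(haps, qtl)
  expect_equal(gv$tbv_total[4] - gv$tbv_total[1], 2 * 2.5)
  expect_equal(gv$tbv_total[2], gv$tbv_total[3])  # heterozygotes at midpoint
})

test_that("imprinted QTL values follow the parental-origin allele (enumeration)", {
  # all 4 ordered genotypes at one locus; paternal expression
  haps <- list(pat = matrix(c(0L, 0L, 1L, 1L), 4, 1),
               mat = matrix(c(0L, 1L, 0L, 1L), 4, 1))
  qtl <- tibble::tibble(qtl_id = 1L, snp = 1L, chromosome = 1L, position = 0.5,
                        action = "imprinted", effect = 1.3,
                        partner = NA_integer_, parent = "paternal",
                        phase = NA_character_)
  gv <- genetic_values(haps, qtl)
  # enumeration oracle: value = effect * (2 * paternal_allele - 1)
  expect_equal(gv$tbv_total, 1.3 * (2 * c(0, 0, 1, 1) - 1))
  # the two ordered heterozygotes receive +effect and -effect
  expect_equal(gv$tbv_total[3], +1.3)
  expect_equal(gv$tbv_total[2], -1.3)
  # maternal expression flips the heterozygotes
  qtl$parent <- "maternal"
  gv2 <- genetic_values(haps, qtl)
  expect_equal(gv2$tbv_total, 1.3 * (2 * c(0, 1, 0, 1) - 1))
})

test_that("epistatic pair contributes the centered product once (enumeration)", {
  # enumerate all 9 two-locus genotypes
  d <- expand.grid(a = 0:2, b = 0:2)
  haps <- list(pat = cbind(pmin(d$a, 1L), pmin(d$b, 1L)),
               mat = cbind(pmax(d$a - 1L, 0L), pmax(d$b - 1L, 0L)))
  w <- 0.7
  qtl <- tibble::tibble(qtl_id = 1:2, snp = 1:2, chromosome = 1L,
                        position = c(0.4, 0.6), action = "epistatic",
                        effect = w, partner = c(2L, 1L),
                        parent = NA_character_, phase = NA_character_)
  gv <- genetic_values(haps, qtl, freq = c(0.5, 0.5))
  expect_equal(gv$tbv_total, w * (d$a - 1) * (d$b - 1))
  # at frequency 0.5 the average effects vanish
  expect_equal(gv$tbv_additive, rep(0, 9))
})

test_that("variance calibration is exact and the noiseless limit holds", {
  pop <- tiny_pop(seed = 13, n_snps = 100, n_sires = 4, n_dams = 3, n_prog = 8,
                  n_phen = 5)
  prog <- pop$pedigree$generation == "progeny"
  expect_equal(var(pop$tbv$tbv_additive[prog]), 26.35, tolerance = 1e-9)
  expect_equal(sum(pop$phenotypes$role == "training"), 4 * 3 * 5)
  expect_equal(sum(pop$phenotypes$role == "validation"), 4 * 3 * 3)

  # noiseless limit: y = mu + tbv_total exactly
  tp <- trait_params(mu = 5, sigma2_a = 26.35, sigma2_e = 1e-12)
  pop2 <- simulate_population(n_sires = 2, n_dams_per_sire = 2,
                              n_progeny_per_dam = 4, n_snps = 60,
                              trait = tp, n_phenotyped_per_family = 2,
                              seed = 14)
  ph <- pop2$phenotypes$role == "training"
  expect_equal(pop2$phenotypes$y[ph], 5 + pop2$tbv$tbv_total[ph],
               tolerance = 1e-4)
})

test_that("default design yields 2000 training and 1000 validation progeny", {
  # structural contract of the full design without a full-size simulation:
  # 20 sires x 10 dams x (10 phenotyped of 15)
  ped <- sim_pedigree(20, 10, 15)
  prog <- ped[ped$generation == "progeny", ]
  expect_equal(nrow(prog), 3000)
  expect_equal(20 * 10 * 10, 2000)
  expect_equal(nrow(prog) - 2000, 1000)
})

test_that("calibration is impossible without additive variance", {
  map <- sim_marker_map(n_chr = 1, n_snps = 20)
  ped <- sim_pedigree(2, 2, 4)
  f <- sim_founder_haplotypes(map, 6, seed = 1)
  haps <- drop_genes(ped, f, map, seed = 2)
  pop <- list(pedigree = ped, map = map, haplotypes = haps,
              qtl = empty <- qtl_architecture(map, "custom", qtl = NULL))
  expect_error(scale_and_phenotype(pop, trait_params(), 2),
               class = "gpqtl_invalid_design")
})

test_that("trait parameter consistency is enforced", {
  expect_silent(trait_params(h2 = 26.35 / 87.84))
  expect_error(trait_params(h2 = 0.31), class = "gpqtl_invalid_design")
  expect_error(trait_params(sigma2_a = -1), class = "gpqtl_invalid_design")
  expect_equal(trait_params()$h2, 0.3, tolerance = 1e-3)
})

test_that("simulation is deterministic and hide_qtl removes QTL from the panel", {
  p1 <- tiny_pop(seed = 21)
  p2 <- tiny_pop(seed = 21)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$phenotypes, p2$phenotypes)
  p3 <- simulate_population(n_sires = 3, n_dams_per_sire = 2,
                            n_progeny_per_dam = 5, n_snps = 60,
                            n_phenotyped_per_family = 3, hide_qtl = TRUE,
                            seed = 21)
  expect_equal(length(p3$panel), 60 - nrow(p3$qtl))
  expect_true(!any(p3$qtl$snp %in% p3$panel))
})
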