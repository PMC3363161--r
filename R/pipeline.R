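#' Validation accuracy of GEBV
#'
#' Pearson correlation between predicted and true breeding values.
#'
#' @param gebv,tbv Aligned numeric vectors (at least 3 records).
#' @return A single correlation.
#' @export
accuracy <- function(gebv, tbv) {
  if (length(gebv) != length(tbv) || length(gebv) < 3) {
    abort("Need at least 3 aligned records.")
  }
  if (var1(gebv) == 0 || var1(tbv) == 0) {
    abort("Correlation undefined: zero variance.", class = "gpqtl_degenerate")
  }
  stats::cor(gebv, tbv)
}

#' Pairwise correlations among methods' GEBV
#'
#' @param gebv_by_method Named list of aligned GEBV vectors (>= 2 methods).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
method_correlations <- function(gebv_by_method) {
  if (length(gebv_by_method) < 2) abort("Need at least 2 methods.")
  n <- lengths(gebv_by_method)
  if (length(unique(n)) != 1) abort("GEBV vectors must be aligned.")
  if (any(vapply(gebv_by_method, var1, numeric(1)) == 0)) {
    abort("Correlation undefined: zero variance.", class = "gpqtl_degenerate")
  }
  M <- stats::cor(do.call(cbind, gebv_by_method))
  M <- (M + t(M)) / 2
  diag(M) <- 1
  M
}

#' Default pipeline configuration
#'
#' All tunable parameters of the full workflow, grouped into `simulation`,
#' `analysis` and `mapping` blocks.  Pass a modified copy (or a YAML file
#' with the same structure) to [run_all()]; unknown keys are rejected.
#'
#' @param seed Master seed.
#' @return A nested list.
#' @export
default_config <- function(seed = 1) {
  list(
    simulation = list(
      n_sires = 20, n_dams_per_sire = 10, n_progeny_per_dam = 15,
      n_chr = 5, chr_length = 1, n_snps = 1998,
      maf_low = 0.1, maf_high = 0.5,
      architecture = "qtlmas2011", major_ratio = 4, pair_spacing = 0.1,
      imprint_parent = "paternal", hide_qtl = FALSE,
      mu = 0, sigma2_a = 26.35, sigma2_e = 61.49,
      n_phenotyped_per_family = 10, seed = seed),
    analysis = list(
      methods = c("bayesCpi", "bayesB", "G1"),
      n_iter = 41000, burn_in = 1000, thin = 10,
      pi_bayesb = 0.995, n_mh = 5, h2_prior = 0.5,
      reml_tol = 1e-8, reml_max_iter = 200,
      epistasis = "hadamard", seed = seed + 1),
    mapping = list(
      window_size = 10, use_samples = FALSE,
      bayesb_multiplier = 10, gblup_k_sd = 4, merge_within = 10,
      tolerance_morgans = 0.05),
    out_dir = NULL)
}

check_config <- function(config) {
  ref <- default_config()
  bad <- setdiff(names(config), names(ref))
  if (length(bad) > 0) {
    abort(sprintf("Unknown config block(s): %s.", paste(bad, collapse = ", ")))
  }
  for (blk in intersect(names(config), c("simulation", "analysis", "mapping"))) {
    bad <- setdiff(names(config[[blk]]), names(ref[[blk]]))
    if (length(bad) > 0) {
      abort(sprintf("Unknown key(s) in config$%s: %s.", blk,
                    paste(bad, collapse = ", ")))
    }
    config[[blk]] <- utils::modifyList(ref[[blk]], config[[blk]])
  }
  utils::modifyList(ref, config)
}

#' Run the full simulation-analysis-mapping-evaluation workflow
#'
#' Simulates a population (or reuses one), fits the requested methods
#' (`bayesCpi`, `bayesB`, `bayesCpi-dom`, `G1`, `G2`, `G3`), predicts GEBV
#' for all individuals, maps QTL per method, and evaluates against the
#' simulated truth.  When `config$out_dir` is set, dataset and result tables
#' are written as TSV with provenance headers.
#'
#' @param config Nested list as from [default_config()], or a path to a YAML
#'   file with the same structure.
#' @param pop Optional pre-simulated `sim_pop` (skips simulation).
#' @return An `eval_report`: `accuracy` tibble, `correlations` matrix,
#'   `varcomp` tibble (one row per fitted model), `detection`
#'   (summary + per-QTL flags), `calls`, `windows`, `gebv` tibble and the
#'   population in `pop`.
#' @export
run_all <- function(config = default_config(), pop = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- check_config(config)
  sim <- cfg$simulation
  ana <- cfg$analysis
  mp <- cfg$mapping

  if (is.null(pop)) {
    pop <- simulate_population(
      n_sires = sim$n_sires, n_dams_per_sire = sim$n_dams_per_sire,
      n_progeny_per_dam = sim$n_progeny_per_dam, n_chr = sim$n_chr,
      chr_length = sim$chr_length, n_snps = sim$n_snps,
      maf_range = c(sim$maf_low, sim$maf_high),
      architecture = sim$architecture,
      trait = trait_params(sim$mu, sim$sigma2_a, sim$sigma2_e),
      n_phenotyped_per_family = sim$n_phenotyped_per_family,
      major_ratio = sim$major_ratio, pair_spacing = sim$pair_spacing,
      imprint_parent = sim$imprint_parent, hide_qtl = sim$hide_qtl,
      seed = sim$seed)
  }
  train <- pop$phenotypes$role == "training"
  valid <- pop$phenotypes$role == "validation"
  panel <- pop$panel
  X_all <- pop$genotypes[, panel, drop = FALSE]
  X_tr <- X_all[train, , drop = FALSE]
  y_tr <- pop$phenotypes$y[train]
  map_panel <- pop$map[panel, ]
  p_tr <- allele_freqs(X_tr)

  gebv <- list()
  fits <- list()
  varcomp <- list()
  calls <- list()
  windows <- list()
  methods <- ana$methods %||% character(0)
  bayes_methods <- intersect(methods, c("bayesCpi", "bayesB", "bayesCpi-dom"))
  gblup_models <- intersect(methods, c("G1", "G2", "G3"))
  seed_i <- ana$seed

  for (m in bayes_methods) {
    seed_i <- seed_i + 1
    fit <- switch(m,
      bayesCpi = run_bayescpi(y_tr, X_tr, n_iter = ana$n_iter,
                              burn_in = ana$burn_in, thin = ana$thin,
                              h2_prior = ana$h2_prior, seed = seed_i),
      bayesB = run_bayesb(y_tr, X_tr, n_iter = ana$n_iter,
                          burn_in = ana$burn_in, thin = ana$thin,
                          pi = ana$pi_bayesb, n_mh = ana$n_mh,
                          h2_prior = ana$h2_prior, seed = seed_i),
      `bayesCpi-dom` = run_bayescpi_dominance(
        y_tr, X_tr, n_iter = ana$n_iter, burn_in = ana$burn_in,
        thin = ana$thin, h2_prior = ana$h2_prior, seed = seed_i))
    fits[[m]] <- fit
    varcomp[[m]] <- glance(fit)
    gebv[[m]] <- gebv_from_effects(X_all, fit, freq = p_tr)
    w <- window_variances(X_all, fit, map_panel,
                          window_size = mp$window_size,
                          use_samples = mp$use_samples)
    windows[[m]] <- w
    calls[[m]] <- if (m == "bayesB") {
      call_qtl_bayes(w, map_panel, mode = "bayesB",
                     bayesb_multiplier = mp$bayesb_multiplier, method = m)
    } else {
      call_qtl_bayes(w, map_panel, mode = "bayesCpi",
                     pi_hat = glance(fit)$pi_mean, method = m)
    }
  }

  if (length(gblup_models) > 0) {
    rel <- list(additive = build_grm(X_all))
    if ("G2" %in% gblup_models) rel$dominance <- build_dominance_rm(X_all)
    if ("G3" %in% gblup_models) {
      rel$epistatic <- build_epistasis_rm(rel$additive, method = cfg$analysis$epistasis)
    }
    y_full <- ifelse(train, pop$phenotypes$y, NA_real_)
    for (m in gblup_models) {
      fit <- gblup_reml(y_full, rel, model = m, tol = ana$reml_tol,
                        max_iter = ana$reml_max_iter)
      fits[[m]] <- fit
      varcomp[[m]] <- glance(fit)
      need <- switch(m, G1 = "additive", G2 = c("additive", "dominance"),
                     G3 = c("additive", "epistatic"))
      mme <- solve_mme(y_full, fit, rel[need])
      gebv[[m]] <- mme$solutions$a_hat - mean(mme$solutions$a_hat)
      if (m == "G1") {
        sig_a <- fit$components$variance[fit$components$term == "additive"]
        alpha <- backsolve_effects(mme$solutions$a_hat, X_all, rel$additive,
                                   sigma2_a = sig_a)
        calls[["gblup"]] <- call_qtl_gblup(alpha, map_panel,
                                           k_sd = mp$gblup_k_sd,
                                           merge_within = mp$merge_within)
        fits[["gblup_alpha"]] <- alpha
      }
    }
  }

  acc <- tibble::tibble(method = names(gebv),
                        accuracy = vapply(gebv, function(g) {
                          accuracy(g[valid], pop$tbv$tbv_additive[valid])
                        }, numeric(1)))
  correlations <- if (length(gebv) >= 2) {
    method_correlations(lapply(gebv, function(g) g[valid]))
  } else NULL
  all_calls <- dplyr::bind_rows(calls)
  detection <- if (nrow(all_calls) > 0 && nrow(pop$qtl) > 0) {
    evaluate_calls(all_calls, pop$qtl, mp$tolerance_morgans)
  } else NULL

  gebv_tbl <- tibble::tibble(id = pop$pedigree$id, role = pop$phenotypes$role)
  for (m in names(gebv)) gebv_tbl[[m]] <- gebv[[m]]

  report <- structure(list(
    accuracy = acc, correlations = correlations,
    varcomp = dplyr::bind_rows(lapply(varcomp, function(v) {
      v$model <- NULL; v
    }), .id = "model"),
    detection = detection, calls = all_calls, windows = windows,
    gebv = gebv_tbl, fits = fits, pop = pop, config = cfg),
    class = "eval_report")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report\n")
  if (nrow(x$accuracy) > 0) {
    cat("Validation accuracy (cor(GEBV, TBV)):\n")
    print(as.data.frame(x$accuracy), row.names = FALSE)
  }
  if (!is.null(x$detection)) {
    cat("QTL detection:\n")
    print(as.data.frame(x$detection$summary), row.names = FALSE)
  }
  invisible(x)
}

# result TSVs with the same provenance headers as the dataset files
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- dataset_header(report$pop)
  wt <- function(df, name) {
    f <- file.path(dir, name)
    writeLines(hdr, f)
    data.table::fwrite(df, f, sep = "\t", append = TRUE, col.names = TRUE,
                       na = "NA", quote = FALSE)
  }
  wt(report$accuracy, "accuracy.tsv")
  wt(report$varcomp, "variance_components.tsv")
  wt(report$gebv, "gebv.tsv")
  if (nrow(report$calls) > 0) wt(report$calls, "qtl_calls.tsv")
  if (!is.null(report$detection)) wt(report$detection$detections, "detection.tsv")
  for (m in names(report$windows)) {
    wt(tibble::as_tibble(report$windows[[m]]), paste0("windows_", m, ".tsv"))
  }
  if (!is.null(report$correlations)) {
    wt(tibble::as_tibble(report$correlations, rownames = "method"),
       "method_correlations.tsv")
  }
  write_dataset(report$pop, file.path(dir, "dataset"))
  invisible(dir)
}
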