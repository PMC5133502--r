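# Shared engine for level and power experiments: fixed pedigree and
# genotypes (as in the evaluation design: real genotypes, many simulated
# phenotype replicates), one fresh trait per replicate through the full
# pipeline.
run_experiment <- function(kind, cfg, replicates, alpha, m, seed,
                           tests, ...) {
  stopifnot(inherits(cfg, "fam_sim_config"), replicates >= 50,
            alpha > 0, alpha <= 1)
  t0 <- proc.time()[["elapsed"]]

  ped <- simulate_pedigrees(cfg)
  gene <- gene_drop(ped, cfg, gene_id = "gene1",
                    seed = gene_seed(seed, "genotypes"))
  poly <- gene$maf > 0
  if (any(!poly)) {  # fix the analysable variant set once, up front
    gene$G <- gene$G[poly, , drop = FALSE]
    gene$maf <- gene$maf[poly]
    gene$variant_ids <- gene$variant_ids[poly]
  }
  K <- kinship_matrix(ped)
  kd <- kinship_decomposition(K)
  factors <- if (cfg$h2 > 0) polygenic_factors(ped) else NULL

  trait_gene <- if (kind == "level") NULL else gene
  rows <- purrr::map(seq_len(replicates), function(rep) {
    rep_seed <- gene_seed(seed, paste0("replicate", rep))
    tr <- simulate_trait(ped, trait_gene, cfg, factors = factors,
                         seed = rep_seed)
    fit <- fit_null_model(tr$pheno, kd, trait = "y", covariates = "x1",
                          keep_sigma_inv = FALSE)
    res <- run_gene(gene, fit, m = m, seed = rep_seed, tests = tests, ...)
    res$replicate <- rep
    res
  })
  pvalues <- dplyr::bind_rows(rows)

  p_cols <- c(paste0("p_", tests), "combined_p")
  rates <- purrr::map_dfr(p_cols, function(col) {
    rej <- sum(pvalues[[col]] <= alpha)
    ci <- stats::binom.test(rej, replicates, conf.level = 0.99)$conf.int
    tibble::tibble(
      test = sub("^p_", "", sub("^combined_p$", "combined", col)),
      rejections = rej, rate = rej / replicates,
      ci_lower = ci[1], ci_upper = ci[2]
    )
  })

  structure(list(
    kind = kind, rates = rates, pvalues = pvalues, alpha = alpha,
    replicates = replicates, m = m, seed = seed, tests = tests, cfg = cfg,
    n_samples = nrow(ped), n_variants = nrow(gene$G),
    elapsed_sec = proc.time()[["elapsed"]] - t0
  ), class = "fam_experiment")
}

#' Type-I-error (level) experiment
#'
#' Simulates a pedigree and gene once, then for each replicate draws a
#' fresh heritable but genotype-independent trait, fits the polygenic null
#' model, runs the combined permutation test, and records rejection at
#' `alpha` for every individual test and the combined test, with exact
#' binomial 99% confidence intervals.
#'
#' @param cfg A [sim_config()].
#' @param replicates Number of trait replicates (>= 50).
#' @param alpha Nominal significance level.
#' @param m Permutations per test.
#' @param seed Master seed; every source of randomness in the experiment
#'   derives from it.
#' @param tests Tests to combine (default all eight).
#' @param ... Further arguments to [run_gene()].
#' @return A `fam_experiment` object; see [tidy.fam_experiment()] and
#'   [autoplot.fam_experiment()].
#' @export
run_level_experiment <- function(cfg, replicates = 200, alpha = 0.05,
                                 m = 1000, seed = 1, tests = fam_tests(),
                                 ...) {
  run_experiment("level", cfg, replicates, alpha, m, seed, tests, ...)
}

#' Power experiment
#'
#' As [run_level_experiment()], but each replicate trait carries genetic
#' effects at the causal variants defined by `cfg` (causal fraction, pool,
#' effect directions, genic variance), so rejection rates estimate power.
#'
#' @inheritParams run_level_experiment
#' @return A `fam_experiment` object.
#' @export
run_power_experiment <- function(cfg, replicates = 200, alpha = 0.05,
                                 m = 1000, seed = 1, tests = fam_tests(),
                                 ...) {
  run_experiment("power", cfg, replicates, alpha, m, seed, tests, ...)
}

#' @export
print.fam_experiment <- function(x, ...) {
  cat(switch(x$kind, level = "Type-I-error", power = "Power"),
      " experiment: ", x$replicates, " replicates, m = ", x$m,
      " permutations, alpha = ", x$alpha, "\n", sep = "")
  cat("  ", x$n_samples, " individuals, ", x$n_variants,
      " polymorphic variants, seed ", x$seed, "\n", sep = "")
  print(as.data.frame(x$rates), row.names = FALSE)
  invisible(x)
}

#' Rejection rates of an experiment, one row per test
#'
#' @param x A `fam_experiment`.
#' @param ... Unused.
#' @return Tibble with `test`, `rejections`, `rate`, `ci_lower`,
#'   `ci_upper` (exact binomial 99% CI).
#' @method tidy fam_experiment
#' @export
tidy.fam_experiment <- function(x, ...) x$rates

#' One-row experiment summary
#'
#' @param x A `fam_experiment`.
#' @param ... Unused.
#' @return Tibble with the experiment's design and the combined test's
#'   rejection rate.
#' @method glance fam_experiment
#' @export
glance.fam_experiment <- function(x, ...) {
  comb <- x$rates[x$rates$test == "combined", ]
  tibble::tibble(kind = x$kind, replicates = x$replicates, m = x$m,
                 alpha = x$alpha, n_samples = x$n_samples,
                 n_variants = x$n_variants,
                 combined_rate = comb$rate,
                 combined_ci_lower = comb$ci_lower,
                 combined_ci_upper = comb$ci_upper,
                 elapsed_sec = x$elapsed_sec)
}

#' Pairwise correlation of per-test p-values across replicates
#'
#' Pearson correlations between the empirical p-values of the individual
#' tests over the replicates of an experiment — high values mean the
#' combined test is paying a small multiplicity price for carrying many
#' near-redundant tests.
#'
#' @param results A `fam_experiment` or a data frame containing `p_<test>`
#'   columns with one row per replicate (>= 30 replicates).
#' @return Symmetric correlation matrix with unit diagonal. Constant
#'   columns produce `NA` entries with a warning, never a silent zero.
#' @export
pvalue_correlations <- function(results) {
  df <- if (inherits(results, "fam_experiment")) results$pvalues else
    tibble::as_tibble(results)
  cols <- grep("^p_", names(df), value = TRUE)
  stopifnot(length(cols) >= 2)
  if (nrow(df) < 30) stop("need at least 30 replicates", call. = FALSE)
  P <- as.matrix(df[cols])
  colnames(P) <- sub("^p_", "", cols)
  const <- apply(P, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("constant p-value column(s): ",
            paste(colnames(P)[const], collapse = ", "),
            "; correlations set to NA", call. = FALSE)
  }
  suppressWarnings(cm <- stats::cor(P))
  diag(cm) <- 1
  cm
}

#' Mean off-diagonal p-value correlation
#'
#' @param results As in [pvalue_correlations()].
#' @return Scalar mean of the upper-triangle correlations (`NA` entries
#'   removed).
#' @export
mean_pvalue_correlation <- function(results) {
  cm <- pvalue_correlations(results)
  mean(cm[upper.tri(cm)], na.rm = TRUE)
}
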