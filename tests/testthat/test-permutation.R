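test_that("permute_residuals conserves entries, is seeded and prefix-stable", {
  expect_equal(permute_residuals(c(7), m = 4, seed = 1),
               matrix(7, 1, 4))

  e <- rnorm(30)
  P <- permute_residuals(e, m = 25, seed = 99)
  expect_equal(colSums(P), rep(sum(e), 25))
  expect_equal(apply(P, 2, sort), matrix(sort(e), 30, 25))

  expect_identical(P, permute_residuals(e, m = 25, seed = 99))
  expect_false(identical(P, permute_residuals(e, m = 25, seed = 100)))

  # growing m extends the stream without changing earlier permutations
  P2 <- permute_residuals(e, m = 60, seed = 99)
  expect_identical(P2[, 1:25], P)
})

test_that("empirical p-values follow the rank conventions", {
  col <- matrix(c(5, 3, 1), ncol = 1)  # observed 5, m = 2 permutations
  expect_equal(drop(empirical_pvalues(col, "joint")), c(1, 2, 3) / 3)
  expect_equal(drop(empirical_pvalues(col, "paper")), c(1 / 2, 1, 1))

  # total tie is maximally conservative under either convention
  ties <- matrix(2, nrow = 5, ncol = 2)
  expect_true(all(empirical_pvalues(ties, "joint") == 1))
  expect_true(all(empirical_pvalues(ties, "paper") == 1))

  # distinct values give a permutation of the rank grid (sort oracle)
  set.seed(31)
  col <- matrix(runif(1001), ncol = 1)
  p <- drop(empirical_pvalues(col, "joint"))
  expect_equal(sort(p), (1:1001) / 1001)
  expect_equal(order(p), order(-col))  # largest statistic = smallest p
})

test_that("min-p combination and its significance count behave exactly", {
  expect_equal(combine_minp(c(0.2, 0.05, 0.5)), 0.05)
  expect_equal(combine_minp(0.3), 0.3)
  expect_equal(combine_minp(rep(0.1, 8)), 0.1)
  expect_error(combine_minp(numeric(0)), "empty")

  expect_equal(combined_significance(0.05, c(0.01, 0.2, 0.5, 0.9)),
               (1 + 1) / 5)
  expect_equal(combined_significance(0.001, c(0.1, 0.2, 0.3)), 1 / 4)
  expect_equal(combined_significance(0.9, c(0.1, 0.2, 0.3)), 1)
  # literal "greater" direction flips the extremeness
  expect_equal(combined_significance(0.001, c(0.1, 0.2, 0.3),
                                     direction = "greater"), 1)
})

# Small end-to-end fixture reused below.
perm_fixture <- function(seed = 1, h2 = 0.3) {
  cfg <- sim_config(n_families = 2, h2 = h2, seed = seed)
  ped <- simulate_pedigrees(cfg)
  gene <- gene_drop(ped, cfg)
  tr <- simulate_trait(ped, NULL, cfg)
  fit <- fit_null_model(tr$pheno, kinship_matrix(ped),
                        trait = "y", covariates = "x1")
  list(gene = gene, fit = fit)
}

test_that("run_gene degenerates to the single test when k = 1", {
  fx <- perm_fixture(seed = 41)
  res <- suppressWarnings(run_gene(fx$gene, fx$fit, m = 200, seed = 5,
                                   tests = "Q2"))
  # with one test, min-p combination must agree with the test's own
  # empirical p up to one rank unit
  expect_lte(abs(res$combined_p - res$p_Q2), 1 / 201 + 1e-12)
})

test_that("run_gene is bit-reproducible and order-independent per gene", {
  fx <- perm_fixture(seed = 42)
  r1 <- suppressWarnings(run_gene(fx$gene, fx$fit, m = 150, seed = 9,
                                  keep_table = TRUE))
  r2 <- suppressWarnings(run_gene(fx$gene, fx$fit, m = 150, seed = 9,
                                  keep_table = TRUE))
  expect_identical(r1, r2)

  # the same gene analysed in a batch gets the same answer: child seeds
  # hang off the gene label, not the analysis order
  other <- fx$gene
  other$gene_id <- "decoy"
  batch <- suppressWarnings(run_genes(list(other, fx$gene), fx$fit,
                                      m = 150, seed = 9))
  expect_equal(batch[batch$gene_id == fx$gene$gene_id, ],
               r1, ignore_attr = TRUE)
})

test_that("observed scores reproduce the quadratic form through row 0", {
  fx <- perm_fixture(seed = 43)
  res <- suppressWarnings(run_gene(fx$gene, fx$fit, m = 100, seed = 2,
                                   residual_kind = "conditional",
                                   keep_table = TRUE))
  tab <- attr(res, "perm_table")
  gene <- suppressWarnings(famcombine:::drop_monomorphic(fx$gene))
  U0 <- score_vector(decorrelated_residuals(fx$fit, "conditional"),
                     sigma_inv(fx$fit), gene)
  w <- variant_weights(gene$maf, weight_scheme("wu_beta"))
  ws <- variant_weights(gene$maf, weight_scheme("price"))
  expect_equal(tab$Q[1, ], gene_statistics(U0, w, ws)[colnames(tab$Q)],
               tolerance = 1e-12)
})

test_that("min-p through shared permutations absorbs the multiplicity of
           eight independent tests, unlike naive thresholding", {
  set.seed(44)
  R <- 1500
  m <- 199
  alpha <- 0.05
  naive <- combined <- logical(R)
  for (i in seq_len(R)) {
    Q <- matrix(rchisq((m + 1) * 8, df = 1), m + 1, 8)
    pv <- empirical_pvalues(Q)
    S <- apply(pv, 1, min)
    combined[i] <- combined_significance(S[1], S[-1]) <= alpha
    naive[i] <- S[1] <= alpha
  }
  band <- qbinom(c(0.005, 0.995), R, alpha) / R
  expect_gte(mean(combined), band[1])
  expect_lte(mean(combined), band[2])
  # 1 - 0.95^8 is about 0.34 for independent tests
  expect_gt(mean(naive), 0.25)
})

test_that("combined p-values respect their permutation floor", {
  fx <- perm_fixture(seed = 45)
  res <- suppressWarnings(run_gene(fx$gene, fx$fit, m = 120, seed = 3))
  expect_gte(res$combined_p, 1 / 121)
  expect_lte(res$combined_p, 1)
  p_cols <- unlist(res[grep("^p_", names(res))])
  expect_true(all(p_cols > 0 & p_cols <= 1))
  expect_equal(res$S_observed, min(p_cols), ignore_attr = TRUE)
})

test_that("run_gene warns below the recommended permutation count and
           errors cleanly on degenerate genes", {
  fx <- perm_fixture(seed = 46)
  clean <- suppressWarnings(famcombine:::drop_monomorphic(fx$gene))
  expect_warning(run_gene(clean, fx$fit, m = 50, seed = 1),
                 "below the recommended")
  mono <- gene_genotypes(matrix(0, 2, fx$fit$n,
                                dimnames = list(c("a", "b"), fx$fit$ids)),
                         "allzero")
  expect_error(suppressWarnings(run_gene(mono, fx$fit, m = 120, seed = 1)),
               "no polymorphic")
})
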