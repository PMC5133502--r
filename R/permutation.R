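# Deterministic per-gene child seed: polynomial hash of the gene label
# folded into the master seed, kept inside the 32-bit signed range so it
# is a valid set.seed() argument. Genes are thereby independently
# reproducible regardless of analysis order.
gene_seed <- function(master_seed, gene_id) {
  h <- as.numeric(master_seed) %% 2147483647
  for (ch in utf8ToInt(as.character(gene_id))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate fn with a private RNG stream so callers' .Random.seed is
# untouched.
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Permute a residual vector
#'
#' Draws `m` independent uniformly random permutations of the input,
#' reproducibly from `seed`. Permutations are drawn sequentially from one
#' seeded stream, so the first `m'` columns are identical for any two
#' calls sharing a seed with `m >= m'` (a run can be extended without
#' invalidating earlier permutations). The identity permutation is never
#' emitted on purpose: the observed row of a permutation table comes from
#' the unpermuted residual.
#'
#' @param residual Numeric vector.
#' @param m Number of permutations (`>= 1`).
#' @param seed Integer seed.
#' @return An `n x m` matrix whose columns are permuted copies of
#'   `residual`.
#' @export
permute_residuals <- function(residual, m, seed) {
  stopifnot(m >= 1)
  n <- length(residual)
  idx <- with_seed(seed, function() {
    vapply(seq_len(m), function(j) sample.int(n), integer(n))
  })
  matrix(residual[idx], nrow = n, ncol = m)
}

#' Empirical rank p-values of a permutation table
#'
#' Within each test's column, statistics are ranked in descending order
#' (every statistic is a nonnegative magnitude, so the largest value is
#' the most extreme and gets rank 1); ties all receive the largest rank in
#' their tie group, the conservative choice. Under the default `"joint"`
#' convention the observed and permuted rows are ranked together and
#' `p = rank / (m + 1)`, which guarantees `p >= 1/(m+1)` and exact
#' validity of the downstream permutation test. The `"paper"` convention
#' uses the literal `p = rank / m` (capped at 1).
#'
#' @param table A `fam_perm_table` (from [run_gene()]) or a numeric
#'   `(m+1) x k` matrix whose first row holds the observed statistics.
#' @param convention `"joint"` (default) or `"paper"`.
#' @return An `(m+1) x k` matrix of p-values in `(0, 1]`.
#' @export
empirical_pvalues <- function(table, convention = c("joint", "paper")) {
  convention <- match.arg(convention)
  Q <- if (inherits(table, "fam_perm_table")) table$Q else as.matrix(table)
  m <- nrow(Q) - 1L
  stopifnot(m >= 1, all(is.finite(Q)))
  ranks <- apply(Q, 2, function(col) rank(-col, ties.method = "max"))
  if (convention == "joint") ranks / (m + 1) else pmin(1, ranks / m)
}

#' Min-p combination of a vector of p-values
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`, one per test.
#' @return The minimum entry — the summary statistic `S`.
#' @export
combine_minp <- function(pvals) {
  if (length(pvals) == 0) stop("cannot combine an empty p-value vector",
                               call. = FALSE)
  stopifnot(all(pvals > 0 & pvals <= 1))
  min(pvals)
}

#' Significance of the observed min-p summary
#'
#' The observed summary is extreme when it is small, so the default
#' direction counts permuted summaries less than or equal to it:
#' `combined_p = (1 + #\{S^(j) <= S^(0)\}) / (m + 1)`. `direction =
#' "greater"` gives the literal proportion of permuted summaries greater
#' than the observed, out of `m` (in which case extreme observations get
#' values near 1).
#'
#' @param S_observed Observed summary statistic `S^(0)`.
#' @param S_permuted Numeric vector of `m` permuted summaries.
#' @param direction `"leq"` (default) or `"greater"`.
#' @return The combined p-value.
#' @export
combined_significance <- function(S_observed, S_permuted,
                                  direction = c("leq", "greater")) {
  direction <- match.arg(direction)
  m <- length(S_permuted)
  stopifnot(m >= 1)
  if (direction == "leq") {
    (1 + sum(S_permuted <= S_observed)) / (m + 1)
  } else {
    sum(S_permuted > S_observed) / m
  }
}

# Linear operator mapping a (permuted) exchangeable residual to the
# per-variant score vector, chosen so the identity permutation reproduces
# the observed scores G' Sigma^-1 (y - X beta):
#   whitened     T = G Sigma^(-1/2) / sqrt(sigma_g2 + sigma_e2)
#                (permuted whitened residuals are implicitly coloured back
#                 to the trait scale before scoring)
#   conditional  T = G Sigma^-1 (scores of the permuted conditional
#                 residuals themselves)
score_transform <- function(gene, fit, residual_kind) {
  if (residual_kind == "whitened") {
    GU <- gene$G %*% fit$U
    sweep(GU, 2, sqrt(fit$omega), "/") %*% t(fit$U) /
      sqrt(fit$sigma_g2 + fit$sigma_e2)
  } else {
    gene$G %*% sigma_inv(fit)
  }
}

# (m+1) x k statistic matrix from the variant x (m+1) score matrix.
statistics_from_scores <- function(Umat, w, w_star, tests) {
  WU <- w * Umat
  WS <- w_star * Umat
  cols <- list(
    Q1 = function() abs(.colSums(WU, nrow(WU), ncol(WU))),
    Q1s = function() abs(.colSums(WS, nrow(WS), ncol(WS))),
    Q2 = function() .colSums(WU^2, nrow(WU), ncol(WU)),
    Q2s = function() .colSums(WS^2, nrow(WS), ncol(WS)),
    Q3 = function() abs(.colSums(WU^3, nrow(WU), ncol(WU))),
    Q3s = function() abs(.colSums(WS^3, nrow(WS), ncol(WS))),
    Q4 = function() .colSums(WU^4, nrow(WU), ncol(WU)),
    Q4s = function() .colSums(WS^4, nrow(WS), ncol(WS))
  )
  Q <- vapply(tests, function(t) cols[[t]](), numeric(ncol(Umat)))
  colnames(Q) <- tests
  Q
}

#' Combined permutation test for one gene
#'
#' Runs the full combination procedure: computes the observed vector of
#' test statistics, recomputes it under `m` permutations of the
#' exchangeable residuals (all tests share each permutation, which is what
#' lets the min-p null capture the correlation between tests), converts
#' every row of the resulting table to empirical rank p-values, summarises
#' each row by its minimum, and reports the significance of the observed
#' minimum among the permuted minima. The fitted null quantities
#' (`beta_hat`, `Sigma_inv`, weights, MAFs) are reused across
#' permutations; only the residual vector changes, so each permutation
#' costs one matrix-vector product.
#'
#' @param gene A `fam_gene` (see [gene_genotypes()]) or a dosage matrix.
#'   Monomorphic variants are dropped with a warning.
#' @param fit A `fam_null_fit` from [fit_null_model()].
#' @param m Number of permutations (>= 100 recommended; fewer draws a
#'   warning).
#' @param seed Master integer seed; the gene's own stream is derived from
#'   it and the gene label, so per-gene results do not depend on analysis
#'   order.
#' @param tests Subset of [fam_tests()] to combine.
#' @param wu_scheme,price_scheme Weighting schemes for the plain and
#'   starred tests (defaults Beta(1, 25) and `1/sqrt(p(1-p))`).
#' @param residual_kind Passed to [decorrelated_residuals()].
#' @param convention Rank convention for [empirical_pvalues()].
#' @param direction Extremeness direction for [combined_significance()].
#' @param max_maf Optional MAF ceiling; variants above it are excluded
#'   before testing (default: none, common variants retained).
#' @param keep_table Attach the full `fam_perm_table` as attribute
#'   `"perm_table"` for audit.
#' @return A one-row tibble: `gene_id`, `n_variants`, one `p_<test>`
#'   column per test (the observed empirical p-values), `S_observed`,
#'   `combined_p`, `m`, `seed`.
#' @export
run_gene <- function(gene, fit, m = 1000, seed = 1, tests = fam_tests(),
                     wu_scheme = weight_scheme("wu_beta"),
                     price_scheme = weight_scheme("price"),
                     residual_kind = c("whitened", "conditional"),
                     convention = c("joint", "paper"),
                     direction = c("leq", "greater"),
                     max_maf = NULL, keep_table = FALSE) {
  residual_kind <- match.arg(residual_kind)
  convention <- match.arg(convention)
  direction <- match.arg(direction)
  tests <- match.arg(tests, fam_tests(), several.ok = TRUE)
  stopifnot(inherits(fit, "fam_null_fit"), m >= 1)
  if (m < 100) warning("m = ", m, " permutations is below the recommended ",
                       "minimum of 100; p-values will be coarse",
                       call. = FALSE)
  if (!inherits(gene, "fam_gene")) gene <- gene_genotypes(gene)

  if (!is.null(colnames(gene$G))) {
    if (!setequal(colnames(gene$G), fit$ids)) {
      stop("gene ", gene$gene_id, ": genotype samples do not match the ",
           "null-model samples", call. = FALSE)
    }
    gene$G <- gene$G[, fit$ids, drop = FALSE]
  } else if (ncol(gene$G) != fit$n) {
    stop("gene ", gene$gene_id, ": ", ncol(gene$G),
         " genotype columns for ", fit$n, " samples", call. = FALSE)
  }

  gene <- drop_monomorphic(gene)
  if (!is.null(max_maf)) {
    keep <- gene$maf <= max_maf
    if (!any(keep)) stop("gene ", gene$gene_id,
                         ": no variants at or below max_maf", call. = FALSE)
    gene$G <- gene$G[keep, , drop = FALSE]
    gene$maf <- gene$maf[keep]
    gene$variant_ids <- gene$variant_ids[keep]
  }

  w <- variant_weights(gene$maf, wu_scheme)
  w_star <- variant_weights(gene$maf, price_scheme)

  e <- decorrelated_residuals(fit, residual_kind)
  seed_g <- gene_seed(seed, gene$gene_id)
  E <- cbind(unname(e), permute_residuals(e, m, seed_g))
  Tr <- score_transform(gene, fit, residual_kind)
  Umat <- Tr %*% E

  Q <- statistics_from_scores(Umat, w, w_star, tests)
  table <- structure(list(Q = Q, m = m, seed = seed_g, test_names = tests),
                     class = "fam_perm_table")
  pv <- empirical_pvalues(table, convention)
  S <- apply(pv, 1, min)
  combined_p <- combined_significance(S[1], S[-1], direction)

  res <- tibble::tibble(gene_id = gene$gene_id, n_variants = nrow(gene$G))
  obs <- as.list(stats::setNames(pv[1, ], paste0("p_", tests)))
  res <- dplyr::bind_cols(res, tibble::as_tibble(obs))
  res$S_observed <- unname(S[1])
  res$combined_p <- combined_p
  res$m <- m
  res$seed <- seed
  if (keep_table) attr(res, "perm_table") <- table
  res
}

#' Combined permutation test for many genes
#'
#' @param genes List of `fam_gene` objects (or dosage matrices).
#' @param fit,... Passed to [run_gene()].
#' @return A tibble with one row per gene. Genes whose test errors out
#'   (e.g. no polymorphic variants) are skipped with a warning.
#' @export
run_genes <- function(genes, fit, ...) {
  rows <- purrr::imap(genes, function(g, nm) {
    tryCatch(run_gene(g, fit, ...), error = function(e) {
      warning("skipping gene ", if (inherits(g, "fam_gene")) g$gene_id else nm,
              ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
  })
  dplyr::bind_rows(rows)
}
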