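#' Bundle a gene's dosage matrix with its allele frequencies
#'
#' Wraps a variant-by-sample matrix of minor-allele counts (0/1/2) with
#' per-variant minor-allele frequencies. Dosages are oriented to the minor
#' allele: variants whose sample frequency exceeds 0.5 are flipped
#' (`2 - G`), which affects the sign of burden-type statistics but not the
#' even-power tests. Frequencies are computed from all samples in the
#' matrix; missing entries are mean-imputed per variant (with a message).
#'
#' @param G Numeric matrix, variants in rows, samples in columns, with
#'   variant and sample IDs as dimnames.
#' @param gene_id Gene label.
#' @return A `fam_gene` object: `gene_id`, `G`, `variant_ids`, `maf`.
#' @export
gene_genotypes <- function(G, gene_id = "gene") {
  stopifnot(is.matrix(G))
  if (is.null(rownames(G))) rownames(G) <- paste0("v", seq_len(nrow(G)))
  if (anyNA(G)) {
    n_miss <- sum(is.na(G))
    message("mean-imputing ", n_miss, " missing genotype call(s) in ", gene_id)
    for (i in seq_len(nrow(G))) {
      miss <- is.na(G[i, ])
      if (any(miss)) G[i, miss] <- mean(G[i, !miss])
    }
  }
  af <- rowMeans(G) / 2
  flip <- af > 0.5
  if (any(flip)) {
    G[flip, ] <- 2 - G[flip, , drop = FALSE]
    af[flip] <- 1 - af[flip]
  }
  structure(list(gene_id = gene_id, G = G, variant_ids = rownames(G),
                 maf = stats::setNames(af, rownames(G))),
            class = "fam_gene")
}

#' @export
print.fam_gene <- function(x, ...) {
  cat("Gene ", x$gene_id, ": ", nrow(x$G), " variants x ", ncol(x$G),
      " samples; MAF range [", signif(min(x$maf), 3), ", ",
      signif(max(x$maf), 3), "]\n", sep = "")
  invisible(x)
}

# Drop monomorphic variants before weighting; errors if nothing is left.
drop_monomorphic <- function(gene) {
  mono <- gene$maf <= 0
  if (any(mono)) {
    warning("dropping ", sum(mono), " monomorphic variant(s) in gene ",
            gene$gene_id, call. = FALSE)
    gene$G <- gene$G[!mono, , drop = FALSE]
    gene$maf <- gene$maf[!mono]
    gene$variant_ids <- gene$variant_ids[!mono]
  }
  if (nrow(gene$G) == 0) {
    stop("gene ", gene$gene_id, " has no polymorphic variants; skipping",
         call. = FALSE)
  }
  gene
}

#' Per-variant score statistics
#'
#' Computes `U_i = r' Sigma_inv g_i` for every variant `i`, where `r` is
#' the phenotype residual vector under the null model (for permutation
#' replicates, the permuted residual vector is substituted) and `g_i` the
#' variant's dosage vector.
#'
#' @param residual Numeric residual vector (length n).
#' @param Sigma_inv Inverse covariance matrix of the fitted null model
#'   (n x n); see [sigma_inv()].
#' @param G A `fam_gene` or a variant-by-sample dosage matrix.
#' @return Named numeric vector of scores, one per variant.
#' @export
score_vector <- function(residual, Sigma_inv, G) {
  Gm <- if (inherits(G, "fam_gene")) G$G else G
  stopifnot(is.matrix(Gm), is.matrix(Sigma_inv))
  n <- length(residual)
  if (ncol(Gm) != n || any(dim(Sigma_inv) != n)) {
    stop("dimension mismatch: residual length ", n, ", Sigma_inv ",
         nrow(Sigma_inv), "x", ncol(Sigma_inv), ", genotypes ",
         nrow(Gm), "x", ncol(Gm), call. = FALSE)
  }
  drop(Gm %*% (Sigma_inv %*% residual))
}

#' Variant weighting schemes
#'
#' @param kind `"wu_beta"` — the SKAT convention, the Beta(a1, a2) density
#'   evaluated at the variant's MAF, sharply downweighting common variants
#'   at the default Beta(1, 25); or `"price"` — `1 / sqrt(p (1 - p))`, a
#'   milder penalty.
#' @param a1,a2 Beta shape parameters (used by `"wu_beta"` only).
#' @return A `fam_weight_scheme` list.
#' @export
weight_scheme <- function(kind = c("wu_beta", "price"), a1 = 1, a2 = 25) {
  kind <- match.arg(kind)
  stopifnot(a1 > 0, a2 > 0)
  structure(list(kind = kind, a1 = a1, a2 = a2), class = "fam_weight_scheme")
}

#' Compute per-variant weights
#'
#' @param maf Numeric vector of minor-allele frequencies in `[0, 1]`.
#' @param scheme A [weight_scheme()].
#' @return Numeric weight vector. Under `"price"`, variants with MAF
#'   exactly 0 or 1 get `NA` with a warning (the weight is unbounded
#'   there); callers exclude them.
#' @export
#' @examples
#' variant_weights(c(0.01, 0.5), weight_scheme("price"))
#' variant_weights(0.5, weight_scheme("wu_beta"))  # 25 * 0.5^24
variant_weights <- function(maf, scheme = weight_scheme()) {
  stopifnot(inherits(scheme, "fam_weight_scheme"),
            all(maf >= 0 & maf <= 1))
  if (scheme$kind == "wu_beta") {
    return(stats::dbeta(maf, scheme$a1, scheme$a2))
  }
  out <- rep(NA_real_, length(maf))
  ok <- maf > 0 & maf < 1
  if (any(!ok)) {
    warning(sum(!ok), " variant(s) with MAF of 0 or 1 excluded from ",
            "price weighting", call. = FALSE)
  }
  out[ok] <- 1 / sqrt(maf[ok] * (1 - maf[ok]))
  out
}

# Canonical test names: burden tests (odd powers, absolute value of the
# weighted sum) and variance-component tests (even powers, sum of powers);
# the "s" suffix marks the starred (price-weighted) variant.
FAM_TESTS <- c("Q2", "Q2s", "Q1", "Q1s", "Q4", "Q4s", "Q3", "Q3s")

#' All eight combinable test names
#'
#' `Q1`-`Q4` use Wu-style Beta weights; the `s`-suffixed ("starred")
#' versions use Price-style frequency weights. Odd powers are burden-type
#' (signal adds across variants with consistent direction), even powers
#' variance-component-type (direction-agnostic).
#'
#' @return Character vector of the eight test names.
#' @export
fam_tests <- function() FAM_TESTS

#' Gene-level weighted score test statistics
#'
#' For power `d` and weights `w`, the burden-type statistics are
#' `Q_d = | sum_i (w_i U_i)^d |` for odd `d` and the variance-component
#' statistics `Q_d = sum_i (w_i U_i)^d` for even `d`; starred statistics
#' substitute the price weights `w*`. All eight are nonnegative, so larger
#' values are always more extreme.
#'
#' @param U Per-variant score vector from [score_vector()].
#' @param w Wu-style Beta weights (used by `Q1`-`Q4`).
#' @param w_star Price-style weights (used by `Q1s`-`Q4s`).
#' @param tests Which statistics to compute (subset of [fam_tests()]).
#' @return Named nonnegative numeric vector, in the order of `tests`.
#' @export
#' @examples
#' gene_statistics(U = c(2, -2), w = c(1, 1), w_star = c(1, 1),
#'                 tests = c("Q1", "Q2"))  # burden cancels, VC does not
gene_statistics <- function(U, w, w_star, tests = fam_tests()) {
  stopifnot(length(U) >= 1, length(w) == length(U),
            length(w_star) == length(U))
  tests <- match.arg(tests, FAM_TESTS, several.ok = TRUE)
  wu <- w * U
  ws <- w_star * U
  all_stats <- c(
    Q1 = abs(sum(wu)), Q1s = abs(sum(ws)),
    Q2 = sum(wu^2),    Q2s = sum(ws^2),
    Q3 = abs(sum(wu^3)), Q3s = abs(sum(ws^3)),
    Q4 = sum(wu^4),    Q4s = sum(ws^4)
  )
  all_stats[tests]
}
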