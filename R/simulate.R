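#' Configuration for the study simulator
#'
#' Defaults emulate the scale and statistical structure of the extended
#' Mexican American pedigrees used to evaluate the method: 20
#' three-generation families of 42 members (840 individuals), one gene of
#' 30 variants with mostly rare minor-allele frequencies, a quantitative
#' trait with polygenic heritability 0.3, and covariates consisting of an
#' intercept plus one standard-normal covariate.
#'
#' @param n_families Number of disjoint families.
#' @param family_template `"three_generation"` (42 members: a founder
#'   couple, five married children, six grandchildren per branch),
#'   `"nuclear"` (two founders plus `n_offspring` children), or a list
#'   `list(kind = "custom", branching = c(...))` giving the number of
#'   children per couple in each successive generation.
#' @param n_offspring Offspring per nuclear family.
#' @param n_variants Variants per gene.
#' @param maf_range Range of the uniform distribution rare variant MAFs
#'   are drawn from.
#' @param common_fraction Fraction of variants drawn instead from
#'   `common_range` (common variants are not excluded from testing).
#' @param common_range MAF range for common variants.
#' @param h2 Polygenic heritability of the non-genic trait variance, in
#'   `[0, 1)`.
#' @param causal_fraction Fraction of the gene's variants given effects
#'   when a genotype-linked trait is simulated.
#' @param causal_pool Which variants effects may land on: `"all"`,
#'   `"rare"` (MAF < `rare_threshold`) or `"common"`.
#' @param rare_threshold MAF below which a variant counts as rare.
#' @param effect_model `"same_direction"` (all causal effects
#'   trait-increasing) or `"mixed_direction"` (random signs).
#' @param genic_variance Target fraction of trait variance explained by
#'   the causal variants (effect sizes `beta_v = c * |log10 maf_v|` with
#'   `c` calibrated against the population dosage variance
#'   `2 p (1 - p)`).
#' @param trait_sd Total trait standard deviation (trait units).
#' @param covariate_beta Fixed effect of the simulated covariate.
#' @param seed Integer seed used by default by the generators.
#' @return A `fam_sim_config` list.
#' @export
sim_config <- function(n_families = 20, family_template = "three_generation",
                       n_offspring = 2, n_variants = 30,
                       maf_range = c(0.001, 0.05), common_fraction = 0.1,
                       common_range = c(0.05, 0.5), h2 = 0.3,
                       causal_fraction = 0.2, causal_pool = "all",
                       rare_threshold = 0.05,
                       effect_model = "same_direction",
                       genic_variance = 0.05, trait_sd = 1,
                       covariate_beta = 0.5, seed = 1) {
  stopifnot(n_families >= 1, n_variants >= 1, h2 >= 0, h2 < 1,
            causal_fraction >= 0, causal_fraction <= 1,
            common_fraction >= 0, common_fraction <= 1,
            genic_variance >= 0, genic_variance < 1, trait_sd > 0)
  effect_model <- match.arg(effect_model, c("same_direction",
                                            "mixed_direction"))
  causal_pool <- match.arg(causal_pool, c("all", "rare", "common"))
  structure(as.list(environment()), class = "fam_sim_config")
}

# Branching plan of one family for a template.
template_branching <- function(cfg) {
  tpl <- cfg$family_template
  if (is.list(tpl)) {
    stopifnot(identical(tpl$kind, "custom"), length(tpl$branching) >= 1)
    return(tpl$branching)
  }
  switch(tpl,
    three_generation = c(5, 6),
    nuclear = cfg$n_offspring,
    stop("unknown family template: ", tpl, call. = FALSE)
  )
}

# One family: a founder couple, then `branching[g]` children per couple in
# generation g; children in non-terminal generations marry a founder
# spouse. Deterministic structure; sexes alternate.
build_family <- function(fid, branching) {
  rows <- list()
  counter <- 0
  nid <- function() {
    counter <<- counter + 1
    sprintf("%s_i%03d", fid, counter)
  }
  add <- function(iid, father, mother, sex) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      fid = fid, iid = iid, father = father, mother = mother, sex = sex)
  }
  p1 <- nid(); add(p1, NA, NA, "male")
  p2 <- nid(); add(p2, NA, NA, "female")
  couples <- list(c(p1, p2))
  for (g in seq_along(branching)) {
    terminal <- g == length(branching)
    next_couples <- list()
    for (cp in couples) {
      for (k in seq_len(branching[g])) {
        sex <- if (k %% 2 == 1) "male" else "female"
        child <- nid(); add(child, cp[1], cp[2], sex)
        if (!terminal) {
          spouse_sex <- if (sex == "male") "female" else "male"
          spouse <- nid(); add(spouse, NA, NA, spouse_sex)
          next_couples[[length(next_couples) + 1]] <-
            if (sex == "male") c(child, spouse) else c(spouse, child)
        }
      }
    }
    couples <- next_couples
  }
  dplyr::bind_rows(rows)
}

#' Simulate a set of disjoint pedigrees
#'
#' @param cfg A [sim_config()].
#' @return A `fam_pedigree` tibble covering `n_families` families.
#' @export
#' @examples
#' ped <- simulate_pedigrees(sim_config(n_families = 2))
#' table(ped$fid)
simulate_pedigrees <- function(cfg) {
  stopifnot(inherits(cfg, "fam_sim_config"))
  branching <- template_branching(cfg)
  fams <- purrr::map(seq_len(cfg$n_families), function(i) {
    build_family(sprintf("fam%02d", i), branching)
  })
  new_pedigree(dplyr::bind_rows(fams))
}

#' Gene-drop genotypes through a pedigree
#'
#' Draws each founder allele independently as Bernoulli(MAF) and transmits
#' alleles to offspring by Mendelian sampling (one uniformly chosen allele
#' per parent per variant). Variants are independent (no linkage
#' disequilibrium, no recombination model). Dosage is the minor-allele
#' count, so genotypes are Mendelian-consistent by construction.
#'
#' @param ped A `fam_pedigree`.
#' @param cfg A [sim_config()] (variant count and MAF distribution).
#' @param gene_id Gene label.
#' @param seed Seed for this gene; defaults to a stream derived from
#'   `cfg$seed` and `gene_id`.
#' @param maf Optional vector of variant MAFs, overriding the config's
#'   MAF distribution.
#' @return A `fam_gene`; `attr(, "maf_true")` records the population MAFs
#'   the founder alleles were drawn from (the object's `maf` field holds
#'   realised sample frequencies).
#' @export
gene_drop <- function(ped, cfg, gene_id = "gene1", seed = NULL,
                      maf = NULL) {
  stopifnot(inherits(cfg, "fam_sim_config"))
  if (is.null(seed)) seed <- gene_seed(cfg$seed, gene_id)
  k <- if (is.null(maf)) cfg$n_variants else length(maf)
  n <- nrow(ped)
  fa <- match(ped$father, ped$iid)
  mo <- match(ped$mother, ped$iid)
  ord <- topo_order(ped)

  out <- with_seed(seed, function() {
    if (is.null(maf)) {
      maf <- stats::runif(k, cfg$maf_range[1], cfg$maf_range[2])
      n_common <- round(cfg$common_fraction * k)
      if (n_common > 0) {
        pos <- sample.int(k, n_common)
        maf[pos] <- stats::runif(n_common, cfg$common_range[1],
                                 cfg$common_range[2])
      }
    }
    A1 <- matrix(0L, n, k)
    A2 <- matrix(0L, n, k)
    draw_parent <- function(p) {
      if (is.na(p)) return(stats::rbinom(k, 1L, maf))
      pick <- stats::runif(k) < 0.5
      ifelse(pick, A1[p, ], A2[p, ])
    }
    for (i in ord) {
      if (is.na(fa[i]) && is.na(mo[i])) {
        A1[i, ] <- stats::rbinom(k, 1L, maf)
        A2[i, ] <- stats::rbinom(k, 1L, maf)
      } else {
        A1[i, ] <- draw_parent(fa[i])
        A2[i, ] <- draw_parent(mo[i])
      }
    }
    list(G = t(A1 + A2), maf = maf)
  })
  dimnames(out$G) <- list(sprintf("%s_v%03d", gene_id, seq_len(k)), ped$iid)
  gene <- gene_genotypes(out$G, gene_id)
  attr(gene, "maf_true") <- stats::setNames(out$maf, rownames(out$G))
  gene
}

#' Per-family factors of the additive relationship matrix
#'
#' The polygenic trait component has covariance `sigma_g2 * 2 Phi`, which
#' is block-diagonal by family; drawing it family by family through small
#' Cholesky factors keeps trait simulation cheap for arbitrarily many
#' families. Precompute once when simulating many traits on a fixed
#' pedigree.
#'
#' @param ped A `fam_pedigree`.
#' @return A `fam_polygenic_factors` object.
#' @export
polygenic_factors <- function(ped) {
  fids <- unique(ped$fid)
  factors <- purrr::map(fids, function(f) {
    sub <- ped[ped$fid == f, , drop = FALSE]
    A <- 2 * kinship_matrix(sub)
    list(ids = sub$iid,
         L = t(chol(A + diag(1e-10, nrow(A)))))
  })
  structure(list(factors = factors, ids = ped$iid),
            class = "fam_polygenic_factors")
}

#' Simulate a quantitative trait on a pedigree
#'
#' Generates `y = X beta + sum_v beta_v g_v + a + e` with polygenic
#' component `a ~ N(0, sigma_g2 * 2 Phi)` and noise `e ~ N(0, sigma_e2 *
#' I)`. Variances are scaled so that the polygenic share of the non-genic
#' variance equals `cfg$h2` and the causal variants explain
#' `cfg$genic_variance` of the total (population approximation). With
#' `genotypes = NULL` the trait is heritable but genotype-independent —
#' the null trait used for type-I-error experiments. Covariates are an
#' intercept plus one standard-normal covariate with effect
#' `cfg$covariate_beta`.
#'
#' @param ped A `fam_pedigree`.
#' @param genotypes A `fam_gene` carrying the causal candidates, or `NULL`
#'   for the null trait.
#' @param cfg A [sim_config()].
#' @param factors Optional precomputed [polygenic_factors()].
#' @param seed Seed; defaults to `cfg$seed`.
#' @return A list: `pheno` (tibble `iid`, `y`, `x1`) and `truth` (tibble
#'   `variant_id`, `maf`, `causal`, `beta`; empty for the null trait).
#' @export
simulate_trait <- function(ped, genotypes = NULL, cfg, factors = NULL,
                           seed = NULL) {
  stopifnot(inherits(cfg, "fam_sim_config"))
  if (is.null(seed)) seed <- cfg$seed
  n <- nrow(ped)
  use_genic <- !is.null(genotypes) && cfg$causal_fraction > 0 &&
    cfg$genic_variance > 0
  if (cfg$h2 > 0 && is.null(factors)) factors <- polygenic_factors(ped)

  with_seed(seed, function() {
    x1 <- stats::rnorm(n)
    truth <- tibble::tibble(variant_id = character(), maf = numeric(),
                            causal = logical(), beta = numeric())
    genic <- rep(0, n)
    genic_frac <- 0
    if (use_genic) {
      maf <- genotypes$maf
      pool <- switch(cfg$causal_pool,
        all = seq_along(maf),
        rare = which(maf < cfg$rare_threshold),
        common = which(maf >= cfg$rare_threshold)
      )
      pool <- pool[maf[pool] > 0]  # monomorphic variants carry no signal
      if (length(pool) == 0) {
        stop("no variants in the requested causal pool", call. = FALSE)
      }
      n_causal <- max(1, round(cfg$causal_fraction * length(maf)))
      n_causal <- min(n_causal, length(pool))
      causal <- sort(sample(pool, n_causal))
      raw <- abs(log10(maf[causal]))
      scale_c <- sqrt(cfg$genic_variance * cfg$trait_sd^2 /
                        sum(raw^2 * 2 * maf[causal] * (1 - maf[causal])))
      sgn <- if (cfg$effect_model == "mixed_direction") {
        sample(c(-1, 1), n_causal, replace = TRUE)
      } else rep(1, n_causal)
      beta_v <- scale_c * raw * sgn
      genic <- drop(crossprod(genotypes$G[causal, , drop = FALSE], beta_v))
      genic <- genic[ped$iid]
      genic_frac <- cfg$genic_variance
      truth <- tibble::tibble(
        variant_id = genotypes$variant_ids,
        maf = unname(maf),
        causal = seq_along(maf) %in% causal,
        beta = replace(rep(0, length(maf)), causal, beta_v)
      )
    }
    var_rem <- cfg$trait_sd^2 * (1 - genic_frac)
    sigma_g2 <- cfg$h2 * var_rem
    sigma_e2 <- (1 - cfg$h2) * var_rem
    a <- rep(0, n)
    if (sigma_g2 > 0) {
      names(a) <- ped$iid
      for (f in factors$factors) {
        a[f$ids] <- sqrt(sigma_g2) * drop(f$L %*% stats::rnorm(length(f$ids)))
      }
      a <- unname(a)
    }
    e <- stats::rnorm(n, 0, sqrt(sigma_e2))
    y <- cfg$covariate_beta * x1 + genic + a + e
    list(pheno = tibble::tibble(iid = ped$iid, y = y, x1 = x1),
         truth = truth)
  })
}

#' Simulate a complete study
#'
#' Pedigree, gene-dropped genotypes and a trait in one call.
#'
#' @param cfg A [sim_config()].
#' @param null_trait Simulate the heritable genotype-independent trait
#'   (type-I-error design) instead of the genotype-linked one.
#' @return A list: `pedigree`, `gene` (a `fam_gene`), `trait` (see
#'   [simulate_trait()]).
#' @export
simulate_study <- function(cfg, null_trait = FALSE) {
  ped <- simulate_pedigrees(cfg)
  gene <- gene_drop(ped, cfg)
  trait <- simulate_trait(ped, if (null_trait) NULL else gene, cfg)
  list(pedigree = ped, gene = gene, trait = trait)
}

#' Mean arterial pressure from diastolic and systolic readings
#'
#' `MAP = (2/3) DBP + (1/3) SBP`, the usual transform for users carrying
#' real blood-pressure columns; the simulator emits a single quantitative
#' trait directly.
#'
#' @param dbp,sbp Numeric vectors (mmHg).
#' @return Numeric vector (mmHg).
#' @export
mean_arterial_pressure <- function(dbp, sbp) {
  2 / 3 * dbp + 1 / 3 * sbp
}
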