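# Shared fixture: a few related families with a heritable trait.
sim_fit_data <- function(n_families = 5, h2 = 0.5, seed = 1,
                         template = "three_generation") {
  cfg <- sim_config(n_families = n_families, family_template = template,
                    h2 = h2, seed = seed)
  ped <- simulate_pedigrees(cfg)
  tr <- simulate_trait(ped, NULL, cfg, seed = seed)
  list(ped = ped, pheno = tr$pheno, K = kinship_matrix(ped))
}

test_that("with unrelated founders the fit reduces to OLS", {
  set.seed(4)
  n <- 60
  ids <- paste0("s", 1:n)
  K <- diag(0.5, n)
  dimnames(K) <- list(ids, ids)
  dat <- tibble::tibble(iid = ids, x1 = rnorm(n),
                        y = 1.5 + 2 * x1 + rnorm(n))
  fit <- fit_null_model(dat, K, trait = "y", covariates = "x1")
  ols <- lm(y ~ x1, data = dat)
  expect_equal(unname(fit$beta_hat), unname(coef(ols)), tolerance = 1e-6)
  # 2*Phi = I makes only the total variance identifiable; ML scaling
  expect_equal(fit$sigma_g2 + fit$sigma_e2,
               sum(residuals(ols)^2) / n, tolerance = 1e-4)
})

test_that("a noiseless trait recovers the coefficients to 6 decimals", {
  d <- sim_fit_data(n_families = 2, h2 = 0, seed = 2)
  beta_true <- c(3, -1.25)
  set.seed(9)
  d$pheno$y <- beta_true[1] + beta_true[2] * d$pheno$x1 +
    rnorm(nrow(d$pheno), 0, 1e-10)
  fit <- fit_null_model(d$pheno, d$K, trait = "y", covariates = "x1")
  expect_equal(unname(fit$beta_hat), beta_true, tolerance = 1e-6)
})

test_that("the profiled optimum matches a dense-likelihood oracle", {
  d <- sim_fit_data(n_families = 2, h2 = 0.6, seed = 3)
  fit <- fit_null_model(d$pheno, d$K, trait = "y", covariates = "x1")
  X <- cbind(1, d$pheno$x1)
  deltas <- exp(seq(log(1e-4), log(1e4), length.out = 400))
  oracle <- vapply(deltas, function(dl) {
    dense_profile_loglik(d$pheno$y, X, d$K, dl)$loglik
  }, numeric(1))
  # never beaten by the dense grid, and equal to its best within grid error
  expect_gte(fit$loglik, max(oracle) - 1e-6)
  expect_lt(fit$loglik - max(oracle), 1e-3)
  best <- dense_profile_loglik(d$pheno$y, X, d$K,
                               fit$sigma_g2 / fit$sigma_e2)
  expect_equal(unname(fit$beta_hat), unname(best$beta), tolerance = 1e-6)
  expect_equal(fit$loglik, best$loglik, tolerance = 1e-8)
})

test_that("Sigma_inv inverts the fitted covariance and OLS never wins", {
  d <- sim_fit_data(seed = 5)
  fit <- fit_null_model(d$pheno, d$K, trait = "y", covariates = "x1")
  Sigma <- fit$sigma_g2 * 2 * d$K + diag(fit$sigma_e2, fit$n)
  expect_lt(max(abs(fit$Sigma_inv %*% Sigma - diag(fit$n))), 1e-6)

  ols <- lm(d$pheno$y ~ d$pheno$x1)
  ll_ols <- -0.5 * fit$n * (log(2 * pi * sum(residuals(ols)^2) / fit$n) + 1)
  expect_gte(fit$loglik, ll_ols - 1e-6)
})

test_that("the fit is invariant under joint sample reordering", {
  d <- sim_fit_data(n_families = 3, seed = 6)
  fit <- fit_null_model(d$pheno, d$K, trait = "y", covariates = "x1")
  set.seed(1)
  perm <- sample(nrow(d$pheno))
  fit_p <- fit_null_model(d$pheno[perm, ], d$K[perm, perm],
                          trait = "y", covariates = "x1")
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-6)
  expect_equal(fit_p$sigma_g2, fit$sigma_g2, tolerance = 1e-6)
  expect_equal(fit_p$beta_hat, fit$beta_hat, tolerance = 1e-6)
  expect_equal(fit_p$marginal_residuals[order(perm)],
               fit$marginal_residuals, tolerance = 1e-6)
})

test_that("whitened residuals are centred, trait-scaled and decorrelated", {
  # unrelated founders, intercept only: whitened == mean-centred trait
  set.seed(8)
  n <- 40
  ids <- paste0("s", 1:n)
  K <- diag(0.5, n)
  dimnames(K) <- list(ids, ids)
  dat <- tibble::tibble(iid = ids, y = rnorm(n))
  fit <- fit_null_model(dat, K, trait = "y")
  expect_equal(unname(decorrelated_residuals(fit)), dat$y - mean(dat$y),
               tolerance = 1e-8)

  # strong kinship: Moran autocorrelation of whitened residuals sits in
  # the permutation null band, while the raw marginal residuals do not
  d <- sim_fit_data(h2 = 0.8, seed = 9)
  fit <- fit_null_model(d$pheno, d$K, trait = "y", covariates = "x1")
  A <- 2 * d$K
  e <- decorrelated_residuals(fit, "whitened")
  expect_lt(abs(mean(e)), 1e-8)
  set.seed(10)
  null_band <- quantile(replicate(1000, moran_I(sample(e), A)),
                        c(0.005, 0.995))
  I_white <- moran_I(e, A)
  expect_gt(I_white, null_band[1])
  expect_lt(I_white, null_band[2])
  expect_gt(moran_I(fit$marginal_residuals, A), null_band[2])

  # conditional residuals: exactly uncorrelated with the covariates
  cond <- decorrelated_residuals(fit, "conditional")
  expect_lt(abs(mean(cond)), 1e-8)
  expect_lt(abs(cor(cond, d$pheno$x1)), 1e-6)

  # zero-variance trait degenerates to a zero residual vector
  dat0 <- tibble::tibble(iid = rownames(d$K), y = 5)
  fit0 <- fit_null_model(dat0, d$K, trait = "y")
  expect_equal(unname(decorrelated_residuals(fit0)), rep(0, fit0$n))
})

test_that("REML matches the textbook unbiased scaling in the OLS limit", {
  set.seed(11)
  n <- 50
  ids <- paste0("s", 1:n)
  K <- diag(0.5, n)
  dimnames(K) <- list(ids, ids)
  dat <- tibble::tibble(iid = ids, x1 = rnorm(n), y = 1 + x1 + rnorm(n))
  fit <- fit_null_model(dat, K, trait = "y", covariates = "x1",
                        method = "REML")
  expect_equal(fit$sigma_g2 + fit$sigma_e2,
               summary(lm(y ~ x1, dat))$sigma^2, tolerance = 1e-4)

  d <- sim_fit_data(seed = 12)
  fr <- fit_null_model(d$pheno, d$K, trait = "y", covariates = "x1",
                       method = "REML")
  expect_gte(fr$h2, 0)
  expect_lt(fr$h2, 1)
  expect_true(is.finite(fr$loglik))
})

test_that("missing phenotype rows are dropped listwise with a message", {
  d <- sim_fit_data(n_families = 2, seed = 13)
  d$pheno$y[3] <- NA
  keep <- d$pheno$iid[-3]
  expect_error(
    suppressMessages(fit_null_model(d$pheno, d$K, trait = "y",
                                    covariates = "x1")),
    "missing from the phenotype"
  )
  expect_message(
    fit <- fit_null_model(d$pheno, d$K[keep, keep], trait = "y",
                          covariates = "x1"),
    "dropping 1 sample"
  )
  expect_identical(fit$n, length(keep))
})

test_that("tidy and glance expose the fitted quantities", {
  d <- sim_fit_data(n_families = 2, seed = 14)
  fit <- fit_null_model(d$pheno, d$K, trait = "y", covariates = "x1")
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "x1"))
  gl <- glance(fit)
  expect_identical(gl$n, fit$n)
  expect_equal(gl$h2, fit$sigma_g2 / (fit$sigma_g2 + fit$sigma_e2))
})
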