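#' Precompute the spectral decomposition of the relationship matrix
#'
#' The variance-component fit profiles the likelihood on the eigenbasis of
#' the additive relationship matrix `2 * Phi`. When many traits are fitted
#' against the same pedigree (e.g. replicate experiments), decomposing once
#' and passing the result to [fit_null_model()] removes the only O(n^3)
#' step from each fit.
#'
#' @param K Kinship matrix `Phi` (symmetric, ID dimnames), as returned by
#'   [kinship_matrix()].
#' @return A `fam_kinship_eigen` object: eigenvectors `U`, eigenvalues
#'   `lambda` of `2 * Phi` (negatives from round-off floored at zero), and
#'   `ids`.
#' @export
kinship_decomposition <- function(K) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (is.null(rownames(K))) {
    stop("kinship matrix must carry individual IDs as dimnames", call. = FALSE)
  }
  if (max(abs(K - t(K))) > 1e-8) {
    stop("kinship matrix must be symmetric", call. = FALSE)
  }
  eig <- eigen(2 * K, symmetric = TRUE)
  structure(
    list(U = eig$vectors, lambda = pmax(eig$values, 0), ids = rownames(K)),
    class = "fam_kinship_eigen"
  )
}

# Profile log-likelihood machinery on the rotated scale.
# yt, Xt are U' y and U' X; delta = sigma_g2 / sigma_e2.
profile_fit <- function(yt, Xt, lambda, delta, reml = FALSE) {
  n <- length(yt)
  c_ <- ncol(Xt)
  d <- delta * lambda + 1
  w <- 1 / d
  XtW <- Xt * w
  XtWX <- crossprod(Xt, XtW)
  beta <- solve(XtWX, crossprod(XtW, yt))
  resid_t <- yt - drop(Xt %*% beta)
  rss <- max(sum(resid_t^2 * w), 1e-300)  # guard the zero-variance trait
  if (reml) {
    sigma_e2 <- rss / (n - c_)
    ll <- -0.5 * ((n - c_) * (log(2 * pi * sigma_e2) + 1) + sum(log(d)) +
                    determinant(XtWX, logarithm = TRUE)$modulus -
                    determinant(crossprod(Xt), logarithm = TRUE)$modulus)
  } else {
    sigma_e2 <- rss / n
    ll <- -0.5 * (n * (log(2 * pi * sigma_e2) + 1) + sum(log(d)))
  }
  list(beta = drop(beta), sigma_e2 = sigma_e2, loglik = as.numeric(ll))
}

#' Fit the polygenic null model
#'
#' Fits the linear mixed model `y = X B + g + e` with `g ~ N(0, sigma_g2 *
#' 2 Phi)` and `e ~ N(0, sigma_e2 * I)` by maximum likelihood (or REML),
#' profiling the likelihood over the variance ratio `delta = sigma_g2 /
#' sigma_e2` on the eigenbasis of `2 Phi`, so each candidate ratio costs
#' O(n). The ratio is searched on the log scale over [1e-6, 1e6] (plus the
#' `sigma_g2 = 0` boundary) with a coarse grid followed by Brent refinement
#' to tolerance 1e-8.
#'
#' Rows of `data` are aligned to the kinship IDs; rows with missing trait
#' or covariate values are dropped listwise with a message.
#'
#' @param data Data frame with an ID column, the trait column, and any
#'   covariate columns. An intercept is always included.
#' @param kinship Kinship matrix `Phi` from [kinship_matrix()], or a
#'   precomputed [kinship_decomposition()].
#' @param trait Name of the trait column (character).
#' @param covariates Character vector of covariate column names (default
#'   none: intercept-only model).
#' @param id Name of the ID column (default `"iid"`).
#' @param method `"ML"` (default) or `"REML"`.
#' @param keep_sigma_inv Keep the dense `n x n` inverse covariance matrix
#'   in the returned object (default `TRUE`; replicate drivers switch it
#'   off and rely on the spectral components).
#' @return A `fam_null_fit` object with elements `beta_hat`, `sigma_g2`,
#'   `sigma_e2`, `h2`, `loglik`, `Sigma_inv` (when kept),
#'   `marginal_residuals` (`y - X beta_hat`), `conditional_residuals`
#'   (`y - X beta_hat - BLUP`), the model frame pieces `y`, `X`, `ids`,
#'   and the spectral components (`U`, `lambda`, `omega = sigma_g2 *
#'   lambda + sigma_e2`) the permutation engine reuses.
#' @seealso [decorrelated_residuals()], [tidy.fam_null_fit()],
#'   [glance.fam_null_fit()]
#' @export
fit_null_model <- function(data, kinship, trait, covariates = character(),
                           id = "iid", method = c("ML", "REML"),
                           keep_sigma_inv = TRUE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), trait %in% names(data),
            all(covariates %in% names(data)), id %in% names(data))
  kd <- if (inherits(kinship, "fam_kinship_eigen")) kinship
        else kinship_decomposition(kinship)

  keep <- stats::complete.cases(data[, c(trait, covariates)])
  if (any(!keep)) {
    message("dropping ", sum(!keep), " sample(s) with missing trait/covariate values")
    data <- data[keep, , drop = FALSE]
  }
  idx <- match(kd$ids, data[[id]])
  if (anyNA(idx)) {
    stop(sum(is.na(idx)), " kinship sample(s) missing from the phenotype table; ",
         "subset the kinship matrix first", call. = FALSE)
  }
  data <- data[idx, , drop = FALSE]

  y <- as.numeric(data[[trait]])
  X <- cbind("(Intercept)" = 1,
             as.matrix(data[, covariates, drop = FALSE]))
  n <- length(y)
  c_ <- ncol(X)
  if (n < c_ + 2) stop("need at least ", c_ + 2, " samples", call. = FALSE)
  if (qr(X)$rank < c_) stop("covariate matrix is rank deficient", call. = FALSE)

  yt <- drop(crossprod(kd$U, y))
  Xt <- crossprod(kd$U, X)
  reml <- method == "REML"

  obj <- function(log_delta) {
    profile_fit(yt, Xt, kd$lambda, exp(log_delta), reml)$loglik
  }
  grid <- seq(log(1e-6), log(1e6), length.out = 25)
  ll_grid <- vapply(grid, obj, numeric(1))
  i_best <- which.max(ll_grid)
  lo <- grid[max(1, i_best - 1)]
  hi <- grid[min(length(grid), i_best + 1)]
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-8)
  # sigma_g2 = 0 boundary (OLS) competes with the interior optimum
  fit0 <- profile_fit(yt, Xt, kd$lambda, 0, reml)
  if (fit0$loglik >= opt$objective) {
    delta <- 0
    best <- fit0
  } else {
    delta <- exp(opt$maximum)
    best <- profile_fit(yt, Xt, kd$lambda, delta, reml)
  }
  if (!all(is.finite(best$beta)) || !is.finite(best$loglik)) {
    stop("null model fit failed to converge (non-finite likelihood); ",
         "check trait scaling and kinship conditioning", call. = FALSE)
  }

  sigma_e2 <- max(best$sigma_e2, 1e-300)
  sigma_g2 <- delta * sigma_e2
  omega <- sigma_g2 * kd$lambda + sigma_e2   # eigenvalues of Sigma-hat
  beta_hat <- stats::setNames(best$beta, colnames(X))
  r <- y - drop(X %*% beta_hat)
  rt <- drop(crossprod(kd$U, r))
  # BLUP of g: sigma_g2 * 2Phi * Sigma^-1 r; conditional = sigma_e2 * Sigma^-1 r
  conditional <- drop(kd$U %*% (sigma_e2 / omega * rt))
  Sigma_inv <- if (keep_sigma_inv) {
    SI <- kd$U %*% (t(kd$U) / omega)
    dimnames(SI) <- list(kd$ids, kd$ids)
    (SI + t(SI)) / 2
  } else NULL

  structure(list(
    beta_hat = beta_hat, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
    h2 = sigma_g2 / (sigma_g2 + sigma_e2), loglik = best$loglik,
    method = method, n = n,
    Sigma_inv = Sigma_inv,
    marginal_residuals = r, conditional_residuals = conditional,
    y = y, X = X, ids = kd$ids,
    U = kd$U, lambda = kd$lambda, omega = omega
  ), class = "fam_null_fit")
}

#' @export
print.fam_null_fit <- function(x, ...) {
  cat("Polygenic null model (", x$method, "), n = ", x$n, "\n", sep = "")
  cat("  sigma_g2 = ", signif(x$sigma_g2, 4),
      ", sigma_e2 = ", signif(x$sigma_e2, 4),
      ", h2 = ", signif(x$h2, 3), "\n", sep = "")
  cat("  log-likelihood = ", signif(x$loglik, 6), "\n", sep = "")
  cat("  fixed effects:\n")
  print(signif(x$beta_hat, 4))
  invisible(x)
}

#' Inverse of the fitted trait covariance matrix
#'
#' Reconstructs `Sigma_inv = (sigma_g2 * 2 Phi + sigma_e2 * I)^-1` from the
#' spectral components if the fit was run with `keep_sigma_inv = FALSE`.
#'
#' @param fit A `fam_null_fit`.
#' @return Symmetric n x n matrix.
#' @export
sigma_inv <- function(fit) {
  stopifnot(inherits(fit, "fam_null_fit"))
  if (!is.null(fit$Sigma_inv)) return(fit$Sigma_inv)
  SI <- fit$U %*% (t(fit$U) / fit$omega)
  dimnames(SI) <- list(fit$ids, fit$ids)
  (SI + t(SI)) / 2
}

#' Exchangeable residuals for permutation
#'
#' Returns the residual vector treated as exchangeable across individuals
#' by the permutation engine. The default, `"whitened"`, decorrelates the
#' marginal residuals with the symmetric inverse square root of the fitted
#' covariance, `Sigma^(-1/2) (y - X beta_hat)`, rescales by
#' `sqrt(sigma_g2 + sigma_e2)` to keep the trait's scale, and mean-centres;
#' under the fitted model these entries are exactly uncorrelated with equal
#' variance. `"conditional"` returns the raw conditional residuals
#' `y - X beta_hat - BLUP`, the looser reading in which subtracting the
#' predicted polygenic value is taken to remove the familial correlation.
#'
#' @param fit A `fam_null_fit`.
#' @param kind `"whitened"` (default) or `"conditional"`.
#' @return Named numeric vector aligned with `fit$ids`, mean zero.
#' @export
decorrelated_residuals <- function(fit, kind = c("whitened", "conditional")) {
  kind <- match.arg(kind)
  stopifnot(inherits(fit, "fam_null_fit"))
  if (kind == "conditional") {
    e <- fit$conditional_residuals
  } else {
    rt <- drop(crossprod(fit$U, fit$marginal_residuals))
    e <- drop(fit$U %*% (rt / sqrt(fit$omega))) *
      sqrt(fit$sigma_g2 + fit$sigma_e2)
    e <- e - mean(e)
  }
  stats::setNames(e, fit$ids)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed-effect estimates of a polygenic null fit
#'
#' @param x A `fam_null_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy fam_null_fit
#' @export
tidy.fam_null_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta_hat), estimate = unname(x$beta_hat))
}

#' One-row model summary of a polygenic null fit
#'
#' @param x A `fam_null_fit`.
#' @param ... Unused.
#' @return A tibble with `sigma_g2`, `sigma_e2`, `h2`, `loglik`, `n`,
#'   `method`.
#' @method glance fam_null_fit
#' @export
glance.fam_null_fit <- function(x, ...) {
  tibble::tibble(sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2, h2 = x$h2,
                 loglik = x$loglik, n = x$n, method = x$method)
}
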