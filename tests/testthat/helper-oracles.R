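# Independent brute-force oracles and small pedigree fixtures, kept free
# of the implementation paths they check.

make_ped <- function(iid, father, mother, fid = "F1", sex = NULL) {
  new_pedigree(tibble::tibble(
    fid = fid, iid = iid, father = father, mother = mother,
    sex = if (is.null(sex)) "unknown" else sex
  ))
}

ped_trio <- function() {
  make_ped(c("F", "M", "C"), c(NA, NA, "F"), c(NA, NA, "M"),
           sex = c("male", "female", "male"))
}

# Ten members over three generations: founder couple, two married
# children plus one unmarried, three grandchildren.
ped_ten <- function() {
  make_ped(
    iid    = c("gp1", "gp2", "c1", "c2", "c3", "s1", "s2", "g1", "g2", "g3"),
    father = c(NA,    NA,    "gp1", "gp1", "gp1", NA,  NA,  "c1", "c1", "c2"),
    mother = c(NA,    NA,    "gp2", "gp2", "gp2", NA,  NA,  "s1", "s1", "s2")
  )
}

# Eleven members with a consanguineous mating: h is the child of first
# cousins g1 and g2 (inbreeding coefficient 1/16).
ped_inbred <- function() {
  make_ped(
    iid    = c("gp1", "gp2", "c1", "c2", "s1", "s2", "g1", "g2", "h",
               "x1", "x2"),
    father = c(NA, NA, "gp1", "gp1", NA, NA, "c1", "c2", "g1", NA, NA),
    mother = c(NA, NA, "gp2", "gp2", NA, NA, "s1", "s2", "g2", NA, NA)
  )
}

# Monte-Carlo IBD estimate of pairwise kinship by dropping uniquely
# labelled founder alleles through the pedigree. Returns the estimate and
# its per-pair Monte-Carlo standard error.
ibd_drop_oracle <- function(ped, n_drops = 1e5, seed = 42) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$iid)
  mo <- match(ped$mother, ped$iid)
  founder_label <- 0L
  set.seed(seed)
  A1 <- matrix(0L, n, n_drops)
  A2 <- matrix(0L, n, n_drops)
  # process in listed order assuming parents precede children (fixtures
  # are written that way); verify to be safe
  for (i in seq_len(n)) {
    if (is.na(fa[i]) && is.na(mo[i])) {
      A1[i, ] <- founder_label + 1L
      A2[i, ] <- founder_label + 2L
      founder_label <- founder_label + 2L
    } else {
      stopifnot(fa[i] < i, mo[i] < i)
      pick_f <- stats::runif(n_drops) < 0.5
      pick_m <- stats::runif(n_drops) < 0.5
      A1[i, ] <- ifelse(pick_f, A1[fa[i], ], A2[fa[i], ])
      A2[i, ] <- ifelse(pick_m, A1[mo[i], ], A2[mo[i], ])
    }
  }
  phi_hat <- matrix(0, n, n, dimnames = list(ped$iid, ped$iid))
  phi_se <- matrix(0, n, n, dimnames = list(ped$iid, ped$iid))
  for (i in seq_len(n)) {
    for (j in i:n) {
      share <- ((A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
                  (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])) / 4
      phi_hat[i, j] <- phi_hat[j, i] <- mean(share)
      phi_se[i, j] <- phi_se[j, i] <- stats::sd(share) / sqrt(n_drops)
    }
  }
  list(phi = phi_hat, se = phi_se)
}

# Profile Gaussian log-likelihood by dense linear algebra (no
# eigendecomposition shortcut): Sigma = sigma_e2 (delta * 2K + I).
dense_profile_loglik <- function(y, X, K, delta) {
  n <- length(y)
  Sigma0 <- delta * 2 * K + diag(n)
  S0inv <- solve(Sigma0)
  XtSX <- t(X) %*% S0inv %*% X
  beta <- solve(XtSX, t(X) %*% S0inv %*% y)
  r <- y - drop(X %*% beta)
  rss <- drop(t(r) %*% S0inv %*% r)
  sigma_e2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma_e2) +
                  determinant(Sigma0, logarithm = TRUE)$modulus + n)
  list(loglik = as.numeric(ll), beta = drop(beta), sigma_e2 = sigma_e2)
}

# Element-wise triple-loop score statistics.
brute_scores <- function(r, Sinv, G) {
  k <- nrow(G)
  n <- length(r)
  U <- numeric(k)
  for (i in seq_len(k)) {
    acc <- 0
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        acc <- acc + r[a] * Sinv[a, b] * G[i, b]
      }
    }
    U[i] <- acc
  }
  U
}

# Straightforward loop re-implementation of the eight statistics.
brute_gene_stats <- function(U, w, ws) {
  k <- length(U)
  s1 <- s2 <- s3 <- s4 <- t1 <- t2 <- t3 <- t4 <- 0
  for (i in seq_len(k)) {
    s1 <- s1 + w[i] * U[i]
    s2 <- s2 + (w[i] * U[i])^2
    s3 <- s3 + (w[i] * U[i])^3
    s4 <- s4 + (w[i] * U[i])^4
    t1 <- t1 + ws[i] * U[i]
    t2 <- t2 + (ws[i] * U[i])^2
    t3 <- t3 + (ws[i] * U[i])^3
    t4 <- t4 + (ws[i] * U[i])^4
  }
  c(Q1 = abs(s1), Q1s = abs(t1), Q2 = s2, Q2s = t2,
    Q3 = abs(s3), Q3s = abs(t3), Q4 = s4, Q4s = t4)
}

# Random symmetric positive-definite matrix.
random_spd <- function(n) {
  M <- matrix(stats::rnorm(n * n), n)
  crossprod(M) / n + diag(n)
}

# Moran-style autocorrelation of a vector with respect to a relationship
# matrix (off-diagonal weights only).
moran_I <- function(e, A) {
  W <- A
  diag(W) <- 0
  n <- length(e)
  z <- e - mean(e)
  n / sum(W) * drop(z %*% W %*% z) / sum(z^2)
}
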