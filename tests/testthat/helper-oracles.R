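# Independent dense oracles, coded directly from the model definitions with
# solve()/determinant() (no Cholesky shortcuts, no code shared with the
# package internals), plus small simulation helpers.

# Explicit projection-matrix REML log-likelihood for the bivariate model.
dense_restricted_loglik <- function(pars, K, y, X, sex) {
  n <- length(y)
  c12 <- if (!is.null(pars$cov_g)) pars$cov_g else
    pars$rho * sqrt(pars$sigma2_g_m * pars$sigma2_g_f)
  cc <- matrix(c(pars$sigma2_g_m, c12, c12, pars$sigma2_g_f), 2, 2)
  si <- ifelse(sex == "M", 1L, 2L)
  v <- K * cc[si, si] + diag(c(pars$sigma2_e_m, pars$sigma2_e_f)[si])
  vi <- solve(v)
  xtvix <- t(X) %*% vi %*% X
  p_mat <- vi - vi %*% X %*% solve(xtvix) %*% t(X) %*% vi
  as.numeric(-0.5 * (determinant(v)$modulus +
                       determinant(xtvix)$modulus +
                       t(y) %*% p_mat %*% y +
                       (n - ncol(X)) * log(2 * pi)))
}

# Stratified (per-sex blocks) fixed-effect design built longhand.
dense_design <- function(cohort) {
  male <- cohort$sex == "M"
  w <- cohort$covariates
  x <- cbind(as.numeric(male), as.numeric(!male))
  if (!is.null(w)) {
    for (j in seq_len(ncol(w))) {
      x <- cbind(x, w[, j] * male, w[, j] * !male)
    }
  }
  x
}

# Dense GBLUP oracle: a = Cov(a, y) V^-1 (y - X b), with b the GLS
# estimate, everything via solve().
dense_blup <- function(pars, Z, y, X, sex) {
  m <- ncol(Z)
  c12 <- pars$rho * sqrt(pars$sigma2_g_m * pars$sigma2_g_f)
  cc <- matrix(c(pars$sigma2_g_m, c12, c12, pars$sigma2_g_f), 2, 2)
  si <- ifelse(sex == "M", 1L, 2L)
  K <- tcrossprod(Z) / m
  v <- K * cc[si, si] + diag(c(pars$sigma2_e_m, pars$sigma2_e_f)[si])
  vi <- solve(v)
  b <- solve(t(X) %*% vi %*% X, t(X) %*% vi %*% y)
  u <- vi %*% (y - X %*% b)
  zm <- Z * (sex == "M")
  zf <- Z * (sex == "F")
  # Cov(a_m, y) = (c11 Z_m' | c12 Z_f') etc., each scaled by 1/M
  a_m <- (cc[1, 1] * t(zm) %*% u + cc[1, 2] * t(zf) %*% u) / m
  a_f <- (cc[2, 1] * t(zm) %*% u + cc[2, 2] * t(zf) %*% u) / m
  cbind(male = as.numeric(a_m), female = as.numeric(a_f))
}

# Simulate a full small dataset: genotypes, phenotypes, GRM.
sim_dataset <- function(..., platforms = NULL) {
  truth <- gxs_truth(...)
  geno <- simulate_genotypes(truth, platforms = platforms)
  cohort <- simulate_phenotypes(geno, truth)
  std <- suppressWarnings(standardize_genotypes(geno))
  grm <- compute_grm(std)
  list(truth = truth, geno = geno, cohort = cohort, std = std, grm = grm)
}

# Build a gxs_grm directly from a relatedness matrix (for pruning tests).
toy_grm <- function(k, ids = LETTERS[seq_len(nrow(k))]) {
  dimnames(k) <- list(ids, ids)
  structure(list(ids = ids, K = k, n_snps = 100L), class = "gxs_grm")
}

# Build a gxs_geno from a raw count matrix (NA = missing).
toy_geno <- function(counts, platform = NULL) {
  n <- nrow(counts)
  m <- ncol(counts)
  g <- structure(list(
    counts = counts,
    ids = sprintf("I%03d", seq_len(n)),
    snp_ids = sprintf("s%03d", seq_len(m)),
    true_p = NULL, platform = platform, bim = NULL
  ), class = "gxs_geno")
  dimnames(g$counts) <- list(g$ids, g$snp_ids)
  g
}

toy_cohort <- function(y, sex, covariates = NULL,
                       ids = sprintf("I%03d", seq_along(y))) {
  gxsreml::subset_cohort(
    structure(list(ids = ids, sex = factor(sex, levels = c("M", "F")),
                   y = as.numeric(y), covariates = covariates,
                   truth = NULL, latent = NULL), class = "gxs_cohort"),
    ids)
}
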