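# Synthetic cohorts with known gene-by-sex architecture.
#
# The generator mirrors the estimation model exactly: causal SNP effects for
# the two sexes are drawn from a zero-mean bivariate normal whose variances
# are sigma2_g_x / n_causal on *standardized* genotypes, so the total
# additive genetic variance per sex equals sigma2_g_x regardless of the MAF
# spectrum, and the cross-sex effect correlation equals rho.

#' Specify a true gene-by-sex architecture
#'
#' Bundles every parameter of the synthetic-cohort generator: cohort sizes,
#' SNP panel, the causal architecture (sex-specific genetic variances and the
#' cross-sex genetic correlation of causal effects), sex-specific residual
#' variances, fixed-effect coefficients for a generated age-like covariate,
#' genotype missingness, and the master seed.
#'
#' Defaults describe the package's canonical simulation condition: 1500
#' males and 1500 females, 2000 SNPs of which 500 are causal, MAF uniform on
#' \[0.05, 0.5\], unit phenotypic variance per sex with heritabilities 0.3
#' (males) and 0.4 (females), and cross-sex genetic correlation 0.7.
#'
#' @param n_male,n_female Individuals per sex.
#' @param n_snps Number of simulated autosomal SNPs (M).
#' @param n_causal Number of causal SNPs (must not exceed `n_snps`).
#' @param maf_low,maf_high Allele-frequency bounds in (0, 0.5]; per-SNP
#'   frequencies are drawn uniformly between them.
#' @param sigma2_g_m,sigma2_g_f Total additive genetic variance per sex.
#' @param rho Cross-sex genetic correlation of causal effects, in \[-1, 1\].
#' @param sigma2_e_m,sigma2_e_f Residual variance per sex.
#' @param covariate_effects List with elements `male` and `female`: numeric
#'   coefficient vectors (one per generated covariate; the default generates
#'   a single standardized age-like covariate).
#' @param missing_rate Probability each genotype call is missing.
#' @param seed Master integer seed; the generator consumes a documented
#'   stream order (allele frequencies, genotypes, missingness mask, causal
#'   selection, effects, covariates, residuals).
#' @return An object of class `gxs_truth`.
#' @export
gxs_truth <- function(n_male = 1500L, n_female = 1500L,
                      n_snps = 2000L, n_causal = 500L,
                      maf_low = 0.05, maf_high = 0.5,
                      sigma2_g_m = 0.3, sigma2_g_f = 0.4,
                      rho = 0.7,
                      sigma2_e_m = 0.7, sigma2_e_f = 0.6,
                      covariate_effects = list(male = 0.1, female = 0.1),
                      missing_rate = 0, seed = 1L) {
  assert_that(n_male >= 1 && n_female >= 1, "need at least one individual per sex")
  assert_that(n_snps >= 1, "n_snps must be positive")
  assert_that(n_causal >= 1 && n_causal <= n_snps,
              "n_causal must be in [1, n_snps]")
  assert_that(maf_low > 0 && maf_high <= 0.5 && maf_low <= maf_high,
              "require 0 < maf_low <= maf_high <= 0.5")
  assert_that(all(c(sigma2_g_m, sigma2_g_f, sigma2_e_m, sigma2_e_f) >= 0),
              "variances must be non-negative")
  assert_that(abs(rho) <= 1, "|rho| must not exceed 1")
  assert_that(missing_rate >= 0 && missing_rate <= 1,
              "missing_rate must be in [0, 1]")
  assert_that(is.list(covariate_effects) &&
                all(c("male", "female") %in% names(covariate_effects)) &&
                length(covariate_effects$male) == length(covariate_effects$female),
              "covariate_effects needs equal-length $male and $female vectors")
  structure(list(
    n_male = as.integer(n_male), n_female = as.integer(n_female),
    n_snps = as.integer(n_snps), n_causal = as.integer(n_causal),
    maf_low = maf_low, maf_high = maf_high,
    sigma2_g_m = sigma2_g_m, sigma2_g_f = sigma2_g_f, rho = rho,
    sigma2_e_m = sigma2_e_m, sigma2_e_f = sigma2_e_f,
    covariate_effects = covariate_effects,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "gxs_truth")
}

new_geno <- function(counts, ids, snp_ids, true_p = NULL, platform = NULL,
                     bim = NULL) {
  dimnames(counts) <- list(ids, snp_ids)
  structure(list(counts = counts, ids = ids, snp_ids = snp_ids,
                 true_p = true_p, platform = platform, bim = bim),
            class = "gxs_geno")
}

#' @export
print.gxs_geno <- function(x, ...) {
  cat(sprintf("gxs_geno: %d individuals x %d SNPs, %.2f%% missing\n",
              length(x$ids), length(x$snp_ids),
              100 * mean(is.na(x$counts))))
  invisible(x)
}

#' Subset a genotype matrix by individuals and/or SNPs
#'
#' @param geno A `gxs_geno` object.
#' @param ids,snps Identifiers to retain (default: all).
#' @return A `gxs_geno` restricted to the requested rows/columns.
#' @export
subset_geno <- function(geno, ids = geno$ids, snps = geno$snp_ids) {
  ri <- match(ids, geno$ids)
  ci <- match(snps, geno$snp_ids)
  assert_that(!anyNA(ri) && !anyNA(ci), "unknown individual or SNP identifiers")
  new_geno(geno$counts[ri, ci, drop = FALSE], ids, snps,
           true_p = geno$true_p[ci],
           platform = geno$platform[ri],
           bim = geno$bim[ci, , drop = FALSE])
}

#' Simulate genotypes under a true architecture
#'
#' Draws each SNP's reference-allele frequency uniformly on
#' \[`maf_low`, `maf_high`\], then draws allele counts as two independent
#' Bernoulli trials per individual (Hardy-Weinberg, no linkage
#' disequilibrium), and finally masks calls missing with probability
#' `missing_rate`. The drawn frequencies are retained in `$true_p` so the
#' phenotype generator can standardize causal genotypes by their true
#' moments.
#'
#' @param truth A [gxs_truth()] object.
#' @param platforms Optional: either a character vector of per-individual
#'   platform labels, or a single fraction in (0,1) assigning the first part
#'   of the cohort to platform "A" and the rest to "B".
#' @return A `gxs_geno` object.
#' @export
simulate_genotypes <- function(truth, platforms = NULL) {
  stopifnot(inherits(truth, "gxs_truth"))
  n <- truth$n_male + truth$n_female
  m <- truth$n_snps
  ids <- sprintf("ID%05d", seq_len(n))
  snp_ids <- sprintf("snp%05d", seq_len(m))
  geno <- with_seed(truth$seed, {
    p <- runif(m, truth$maf_low, truth$maf_high)
    counts <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
    if (truth$missing_rate > 0) {
      counts[runif(n * m) < truth$missing_rate] <- NA_integer_
    }
    list(p = p, counts = counts)
  })
  platform <- NULL
  if (!is.null(platforms)) {
    if (is.numeric(platforms) && length(platforms) == 1L) {
      n_a <- round(platforms * n)
      platform <- rep(c("A", "B"), c(n_a, n - n_a))
    } else {
      assert_that(length(platforms) == n, "platforms must have one label per individual")
      platform <- as.character(platforms)
    }
  }
  bim <- data.frame(chr = 1L, snp = snp_ids, cm = 0,
                    pos = seq_len(m), a1 = "A", a2 = "B",
                    stringsAsFactors = FALSE)
  new_geno(geno$counts, ids, snp_ids, true_p = geno$p,
           platform = platform, bim = bim)
}

new_cohort <- function(ids, sex, y, covariates = NULL, truth = NULL,
                       latent = NULL) {
  sex <- factor(sex, levels = c("M", "F"))
  stopifnot(!anyNA(sex), length(sex) == length(ids), length(y) == length(ids))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == length(ids))
    rownames(covariates) <- ids
  }
  structure(list(ids = ids, sex = sex, y = as.numeric(y),
                 covariates = covariates, truth = truth, latent = latent),
            class = "gxs_cohort")
}

#' @export
print.gxs_cohort <- function(x, ...) {
  cat(sprintf("gxs_cohort: %d individuals (%d M / %d F), %d covariate(s)\n",
              length(x$ids), sum(x$sex == "M"), sum(x$sex == "F"),
              if (is.null(x$covariates)) 0L else ncol(x$covariates)))
  invisible(x)
}

#' Subset a cohort by individual identifiers
#'
#' @param cohort A `gxs_cohort`.
#' @param ids Identifiers to retain, in the requested order.
#' @return The restricted `gxs_cohort`.
#' @export
subset_cohort <- function(cohort, ids) {
  i <- match(ids, cohort$ids)
  assert_that(!anyNA(i), "unknown individual identifiers")
  new_cohort(ids, cohort$sex[i], cohort$y[i],
             covariates = if (is.null(cohort$covariates)) NULL
                          else cohort$covariates[i, , drop = FALSE],
             truth = cohort$truth,
             latent = cohort$latent[i])
}

#' Simulate phenotypes with sex-specific genetic effects
#'
#' Selects `n_causal` SNPs, draws per-SNP male/female effect pairs from a
#' zero-mean bivariate normal with variances `sigma2_g_x / n_causal` and
#' correlation `rho`, and builds each individual's genetic value as the dot
#' product of its standardized causal genotypes (standardized by the *true*
#' allele frequency, missing calls contributing zero) with the sex-matched
#' effect vector. An age-like covariate is generated and its per-sex
#' coefficient added, plus sex-specific normal residuals. Sex is assigned
#' deterministically: the first `n_male` individuals are male.
#'
#' @param geno A `gxs_geno` from [simulate_genotypes()].
#' @param truth The same [gxs_truth()] used to generate `geno`.
#' @return A `gxs_cohort` whose `$truth` records the generating
#'   architecture, the causal SNP identifiers, the drawn effect pairs and
#'   the realized genetic values.
#' @export
simulate_phenotypes <- function(geno, truth) {
  stopifnot(inherits(geno, "gxs_geno"), inherits(truth, "gxs_truth"))
  m <- length(geno$snp_ids)
  assert_that(truth$n_causal <= m, "n_causal exceeds available SNPs")
  n <- length(geno$ids)
  stopifnot(n == truth$n_male + truth$n_female)
  sex <- rep(c("M", "F"), c(truth$n_male, truth$n_female))
  n_cov <- length(truth$covariate_effects$male)

  out <- with_seed(truth$seed + 1L, {
    causal <- sort(sample.int(m, truth$n_causal))
    # effect pairs: rows ~ N(0, C / n_causal), C the 2x2 genetic covariance
    sm <- truth$sigma2_g_m / truth$n_causal
    sf <- truth$sigma2_g_f / truth$n_causal
    z1 <- rnorm(truth$n_causal)
    z2 <- rnorm(truth$n_causal)
    a_m <- sqrt(sm) * z1
    a_f <- sqrt(sf) * (truth$rho * z1 + sqrt(1 - truth$rho^2) * z2)
    p <- geno$true_p[causal]
    zc <- sweep(geno$counts[, causal, drop = FALSE], 2L, 2 * p, "-")
    zc <- sweep(zc, 2L, sqrt(2 * p * (1 - p)), "/")
    zc[is.na(zc)] <- 0
    g_m <- as.numeric(zc %*% a_m)
    g_f <- as.numeric(zc %*% a_f)
    g <- ifelse(sex == "M", g_m, g_f)
    covariates <- NULL
    cov_term <- 0
    if (n_cov > 0L) {
      covariates <- matrix(rnorm(n * n_cov), nrow = n)
      colnames(covariates) <- if (n_cov == 1L) "age" else
        c("age", sprintf("cov%d", seq_len(n_cov - 1L)))
      beta_cov <- rbind(truth$covariate_effects$male,
                        truth$covariate_effects$female)
      sex_row <- ifelse(sex == "M", 1L, 2L)
      cov_term <- rowSums(covariates * beta_cov[sex_row, , drop = FALSE])
    }
    e <- rnorm(n, 0, ifelse(sex == "M", sqrt(truth$sigma2_e_m),
                            sqrt(truth$sigma2_e_f)))
    list(causal = causal, a_m = a_m, a_f = a_f, g = g,
         covariates = covariates, y = g + cov_term + e)
  })

  truth_rec <- truth
  truth_rec$causal_snps <- geno$snp_ids[out$causal]
  truth_rec$effects <- cbind(male = out$a_m, female = out$a_f)
  truth_rec$genetic_values <- out$g
  new_cohort(geno$ids, sex, out$y, covariates = out$covariates,
             truth = truth_rec)
}

#' Discretize a phenotype at sex-specific thresholds
#'
#' Replaces the (latent) quantitative phenotype with ordinal category
#' indices `1..k+1` obtained by cutting at strictly increasing per-sex
#' thresholds; the latent values are retained in `$latent` for truth checks.
#'
#' @param cohort A `gxs_cohort`.
#' @param cuts_male,cuts_female Strictly increasing threshold vectors.
#' @return The cohort with categorical `$y` and the former `$y` in `$latent`.
#' @export
simulate_categorical <- function(cohort, cuts_male, cuts_female) {
  stopifnot(inherits(cohort, "gxs_cohort"))
  assert_that(length(cuts_male) >= 1 && length(cuts_female) >= 1 &&
                !is.unsorted(cuts_male, strictly = TRUE) &&
                !is.unsorted(cuts_female, strictly = TRUE),
              "thresholds must be strictly increasing")
  latent <- cohort$y
  y <- ifelse(cohort$sex == "M",
              findInterval(latent, cuts_male),
              findInterval(latent, cuts_female)) + 1L
  out <- cohort
  out$y <- as.numeric(y)
  out$latent <- latent
  out
}

#' Split a cohort and its genotypes into training and test sets
#'
#' Samples the test set within each sex separately (so both sexes are
#' represented on both sides). The overall test size is
#' `round(test_fraction * n)`, allocated to the sexes proportionally
#' (largest-remainder rule, ties resolved in sex-level order). The
#' partition is disjoint and deterministic given `seed`.
#'
#' @param cohort A `gxs_cohort`.
#' @param geno The matching `gxs_geno`.
#' @param test_fraction Fraction held out, in (0, 1).
#' @param seed Integer seed for the draw.
#' @return A list with elements `train` and `test`, each a list with
#'   `cohort` and `geno`.
#' @export
split_train_test <- function(cohort, geno, test_fraction, seed = 1L) {
  stopifnot(inherits(cohort, "gxs_cohort"), inherits(geno, "gxs_geno"))
  assert_that(test_fraction > 0 && test_fraction < 1,
              "test_fraction must be in (0, 1)")
  by_sex <- split(cohort$ids, cohort$sex)
  n_total <- length(cohort$ids)
  k_total <- round(test_fraction * n_total)
  raw <- vapply(by_sex, length, 0L) * test_fraction
  k_sex <- floor(raw)
  short <- k_total - sum(k_sex)
  if (short > 0) {
    extra <- order(raw - k_sex, decreasing = TRUE)[seq_len(short)]
    k_sex[extra] <- k_sex[extra] + 1L
  }
  test_ids <- with_seed(seed, {
    unlist(lapply(seq_along(by_sex), function(i) {
      sample(by_sex[[i]], k_sex[i])
    }), use.names = FALSE)
  })
  train_ids <- setdiff(cohort$ids, test_ids)
  for (part in list(train_ids, test_ids)) {
    sexes <- cohort$sex[match(part, cohort$ids)]
    assert_that(sum(sexes == "M") >= 2 && sum(sexes == "F") >= 2,
                "each split needs at least 2 individuals of each sex")
  }
  list(
    train = list(cohort = subset_cohort(cohort, train_ids),
                 geno = subset_geno(geno, ids = train_ids)),
    test = list(cohort = subset_cohort(cohort, test_ids),
                geno = subset_geno(geno, ids = test_ids))
  )
}
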