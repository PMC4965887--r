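# GBLUP: back-solving per-SNP effects and genomic prediction.
#
# At the REML optimum, SNP effects are estimated by their posterior mean
# with variance and fixed-effect parameters fixed:
#   a = Cov(a, y) V^-1 (y - X beta_hat).
# In the univariate model every SNP effect has prior variance sigma2_g / M,
# so a = (sigma2_g / M) Z' V^-1 r. In the bivariate model the sex-specific
# vectors use the cross-sex covariance blocks, so each sex's effects borrow
# information from both sexes' residuals:
#   a_m = (1/M) [ c_mm Z_m' u_m + c_mf Z_f' u_f ],   u = V^-1 r.

#' Back-solve per-SNP effects from a REML fit
#'
#' @param fit A converged `gxs_reml_fit` (bivariate or univariate).
#' @param std Training-population standardized genotypes from
#'   [standardize_genotypes()]; must cover the fit's individuals in the
#'   fit's order.
#' @param cohort The training `gxs_cohort` the fit was computed on.
#' @return An object of class `gxs_effects`: `snp_ids`, `effects` (M x 2
#'   matrix with columns `male`, `female` for the bivariate model; M x 1
#'   column `shared` for the univariate model), the training
#'   standardization statistics `mu`, `sigma`, the SNP count `n_snps`, and
#'   the source `model`.
#' @export
blup_effects <- function(fit, std, cohort) {
  stopifnot(inherits(fit, "gxs_reml_fit"), inherits(std, "gxs_std"),
            inherits(cohort, "gxs_cohort"))
  if (!fit$converged) stop("refusing to back-solve effects from an unconverged fit")
  ri <- match(fit$ids, rownames(std$Z))
  assert_that(!anyNA(ri), "standardized genotypes must cover the fitted individuals")
  z <- std$Z[ri, , drop = FALSE]
  m <- ncol(z)
  u <- fit$Py # V^-1 (y - X beta_hat) at the REML estimates
  sex <- cohort$sex[match(fit$ids, cohort$ids)]
  mi <- which(sex == "M")
  fi <- which(sex == "F")
  p <- fit$params
  if (fit$model == "univariate") {
    a <- drop(crossprod(z, u)) * p$sigma2_g / m
    eff <- matrix(a, ncol = 1, dimnames = list(std$snp_ids, "shared"))
  } else {
    ztu_m <- drop(crossprod(z[mi, , drop = FALSE], u[mi]))
    ztu_f <- drop(crossprod(z[fi, , drop = FALSE], u[fi]))
    a_m <- (p$sigma2_g_m * ztu_m + p$cov_g * ztu_f) / m
    a_f <- (p$cov_g * ztu_m + p$sigma2_g_f * ztu_f) / m
    eff <- cbind(male = a_m, female = a_f)
    rownames(eff) <- std$snp_ids
  }
  structure(list(snp_ids = std$snp_ids, effects = eff,
                 mu = std$mu, sigma = std$sigma,
                 n_snps = m, model = fit$model),
            class = "gxs_effects")
}

#' @export
print.gxs_effects <- function(x, ...) {
  cat(sprintf("gxs_effects (%s model): %d SNPs, columns: %s\n",
              x$model, x$n_snps, paste(colnames(x$effects), collapse = ", ")))
  invisible(x)
}

#' Score test individuals with back-solved SNP effects
#'
#' `yhat_i = sum_j (s_ij - mu_j) / sigma_j * a_j` over the SNPs shared
#' between the effect set and the test genotypes (matched by identifier;
#' a warning reports any loss). Standardization uses the *training*
#' statistics, so missing test genotypes contribute exactly zero. Under the
#' bivariate model each individual is scored with the effect vector of its
#' own sex.
#'
#' @param effects A `gxs_effects`.
#' @param geno Test `gxs_geno`.
#' @param sex Factor/character of "M"/"F" per test individual (required for
#'   bivariate effect sets; ignored for univariate ones).
#' @return Named numeric vector of predicted additive genetic values.
#' @export
score_genotypes <- function(effects, geno, sex = NULL) {
  stopifnot(inherits(effects, "gxs_effects"), inherits(geno, "gxs_geno"))
  shared <- intersect(effects$snp_ids, geno$snp_ids)
  assert_that(length(shared) > 0, "no SNPs shared between effects and test genotypes")
  if (length(shared) < length(effects$snp_ids)) {
    warning(sprintf("scoring uses %d of %d effect SNPs present in test genotypes",
                    length(shared), length(effects$snp_ids)))
  }
  ei <- match(shared, effects$snp_ids)
  gi <- match(shared, geno$snp_ids)
  z <- sweep(geno$counts[, gi, drop = FALSE], 2L, effects$mu[ei], "-")
  z <- sweep(z, 2L, effects$sigma[ei], "/")
  z[is.na(z)] <- 0
  if (effects$model == "univariate") {
    yhat <- drop(z %*% effects$effects[ei, 1L])
  } else {
    assert_that(!is.null(sex), "sex labels are required for bivariate scoring")
    sex <- factor(as.character(sex), levels = c("M", "F"))
    assert_that(!anyNA(sex) && length(sex) == length(geno$ids),
                "need one M/F label per test individual")
    ym <- drop(z %*% effects$effects[ei, "male"])
    yf <- drop(z %*% effects$effects[ei, "female"])
    yhat <- ifelse(sex == "M", ym, yf)
  }
  setNames(yhat, geno$ids)
}

#' Prediction accuracy against fixed-effect-adjusted phenotypes
#'
#' Adjusts the test phenotype with the *training* fixed-effect estimates
#' (`y - X beta_hat`, with X built from the test covariates under each
#' model's own design) and reports the Pearson correlation between
#' predicted and adjusted phenotypes, pooled over both sexes and per sex.
#' When both a sex-specific ("bivariate") and a sex-agnostic
#' ("univariate") prediction are supplied, the relative improvement
#' `(acc_specific - acc_agnostic) / acc_agnostic * 100` is derived from the
#' pooled accuracies.
#'
#' @param predictions Named list of predicted-value vectors (names matching
#'   `fits`), each named by individual ID.
#' @param cohort Test `gxs_cohort`.
#' @param fits Named list of the training `gxs_reml_fit`s that produced the
#'   predictions (supplying `beta` and the design type).
#' @return An object of class `gxs_prediction`: per-model pooled and
#'   per-sex accuracies, and `relative_improvement_pct` when both
#'   `bivariate` and `univariate` entries are present.
#' @export
prediction_accuracy <- function(predictions, cohort, fits) {
  stopifnot(is.list(predictions), is.list(fits),
            all(names(predictions) %in% names(fits)))
  acc <- lapply(names(predictions), function(nm) {
    fit <- fits[[nm]]
    pred <- predictions[[nm]][cohort$ids]
    assert_that(!anyNA(pred), "predictions must cover every test individual")
    x <- build_design(cohort, fit$design)
    assert_that(identical(colnames(x), names(fit$beta)),
                "test covariates do not match the training design")
    adj <- cohort$y - drop(x %*% fit$beta)
    pool <- function(i) {
      if (sd(pred[i]) == 0 || sd(adj[i]) == 0) {
        warning("zero variance in predictions or adjusted phenotype; accuracy undefined")
        return(NA_real_)
      }
      cor(pred[i], adj[i])
    }
    list(accuracy = pool(seq_along(adj)),
         accuracy_male = pool(which(cohort$sex == "M")),
         accuracy_female = pool(which(cohort$sex == "F")))
  })
  names(acc) <- names(predictions)
  rel <- NULL
  if (all(c("bivariate", "univariate") %in% names(acc))) {
    a_s <- acc$bivariate$accuracy
    a_a <- acc$univariate$accuracy
    rel <- (a_s - a_a) / a_a * 100
  }
  structure(list(models = acc, relative_improvement_pct = rel),
            class = "gxs_prediction")
}

#' @export
print.gxs_prediction <- function(x, ...) {
  for (nm in names(x$models)) {
    a <- x$models[[nm]]
    cat(sprintf("  %-10s accuracy = %.4f (M %.4f / F %.4f)\n", nm,
                a$accuracy, a$accuracy_male, a$accuracy_female))
  }
  if (!is.null(x$relative_improvement_pct)) {
    cat(sprintf("  relative improvement (sex-specific vs agnostic): %.2f%%\n",
                x$relative_improvement_pct))
  }
  invisible(x)
}

#' Write back-solved SNP effects as TSV
#'
#' Layout: snp_id, allele, effect (one column per effect vector), matching
#' common polygenic-score tooling conventions.
#'
#' @param effects A `gxs_effects`.
#' @param path Output file.
#' @param allele Reference-allele label written for every SNP.
#' @return `path`, invisibly.
#' @export
write_effects <- function(effects, path, allele = "A") {
  df <- data.frame(snp_id = effects$snp_ids, allele = allele,
                   effects$effects, check.names = FALSE)
  write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
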