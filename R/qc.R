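# Genotype and phenotype quality control.
#
# Defaults mirror the thresholds of the source cohort protocol: SNP
# missingness 2%, platform-bias Fisher P < 1e-100, individual missingness
# 5%, Hardy-Weinberg P < 1e-50 in the unrelated reference, MAF band
# (0.05, 0.5] for the common-variant analysis, relatedness pruning at
# 0.0625, +/-3 SD ancestry window on 20 principal components, per-sex
# +/-3 SD phenotype outliers, 5 SD pre-exclusion for the composite
# cognitive score, and an offspring-count cap of 15.

snp_missing_rate <- function(geno) colMeans(is.na(geno$counts))
ind_missing_rate <- function(geno) rowMeans(is.na(geno$counts))

#' Remove SNPs with excess missingness
#'
#' @param geno A `gxs_geno`.
#' @param max_rate Maximum tolerated missing fraction; SNPs strictly above
#'   it are removed.
#' @return List with elements `geno` and `report` (a [qc_report()]).
#' @export
filter_snp_missingness <- function(geno, max_rate = 0.02) {
  assert_that(max_rate >= 0 && max_rate <= 1, "max_rate must be in [0, 1]")
  rate <- snp_missing_rate(geno)
  drop <- rate > max_rate
  assert_that(!all(drop), "no SNPs left after missingness filter")
  list(geno = subset_geno(geno, snps = geno$snp_ids[!drop]),
       report = qc_report("snp_missingness", "snp", length(drop), sum(drop),
                          max_rate, removed = geno$snp_ids[drop]))
}

#' Remove individuals with excess missingness
#'
#' @param geno A `gxs_geno`.
#' @param max_rate Maximum tolerated missing fraction per individual.
#' @return List with elements `geno` and `report`.
#' @export
filter_individual_missingness <- function(geno, max_rate = 0.05) {
  assert_that(max_rate >= 0 && max_rate <= 1, "max_rate must be in [0, 1]")
  rate <- ind_missing_rate(geno)
  drop <- rate > max_rate
  assert_that(!all(drop), "no individuals left after missingness filter")
  list(geno = subset_geno(geno, ids = geno$ids[!drop]),
       report = qc_report("individual_missingness", "individual",
                          length(drop), sum(drop), max_rate,
                          removed = geno$ids[drop]))
}

#' Remove SNPs with platform-biased missingness
#'
#' Per SNP, a two-sided Fisher's exact test on the 2x2 table of
#' missing/observed calls by genotyping platform; SNPs with P below the
#' threshold are removed. Requires exactly two platforms with every
#' individual labelled.
#'
#' @param geno A `gxs_geno` with `$platform` labels.
#' @param p_threshold Removal threshold on the Fisher P value.
#' @return List with elements `geno` and `report`.
#' @export
platform_bias_filter <- function(geno, p_threshold = 1e-100) {
  assert_that(!is.null(geno$platform) && !anyNA(geno$platform),
              "every individual needs a platform label")
  plat <- factor(geno$platform)
  assert_that(nlevels(plat) == 2, "exactly two platforms are required")
  n_by <- table(plat)
  miss <- rowsum(is.na(geno$counts) + 0, plat) # 2 x M missing counts
  pvals <- vapply(seq_along(geno$snp_ids), function(j) {
    tab <- rbind(miss[, j], as.numeric(n_by) - miss[, j])
    if (all(tab[1, ] == 0)) return(1) # no missingness at all
    fisher.test(tab)$p.value
  }, numeric(1))
  drop <- pvals < p_threshold
  list(geno = subset_geno(geno, snps = geno$snp_ids[!drop]),
       report = qc_report("platform_bias", "snp", length(drop), sum(drop),
                          p_threshold, removed = geno$snp_ids[drop]))
}

# 1-df chi-square goodness-of-fit P value for Hardy-Weinberg proportions
# from genotype counts (n0, n1, n2 copies of the reference allele).
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  if (p <= 0 || p >= 1) return(1) # monomorphic
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((c(n0, n1, n2) - e)^2 / e)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Remove SNPs departing from Hardy-Weinberg equilibrium
#'
#' A 1-df chi-square goodness-of-fit statistic comparing observed genotype
#' counts with expectations under the sample allele frequency, computed on
#' the designated (unrelated) reference individuals only. Monomorphic SNPs
#' are kept with P = 1 and flagged in the report notes.
#'
#' @param geno A `gxs_geno`.
#' @param p_threshold Removal threshold.
#' @param reference_ids Individuals on which the test is computed.
#' @return List with elements `geno` and `report`.
#' @export
hwe_filter <- function(geno, p_threshold = 1e-50, reference_ids = geno$ids) {
  assert_that(length(reference_ids) > 0, "reference_ids must be nonempty")
  ri <- match(reference_ids, geno$ids)
  assert_that(!anyNA(ri), "reference_ids must be a subset of genotype ids")
  cnt <- geno$counts[ri, , drop = FALSE]
  mono <- character(0)
  pvals <- vapply(seq_along(geno$snp_ids), function(j) {
    x <- cnt[, j]
    n0 <- sum(x == 0L, na.rm = TRUE)
    n1 <- sum(x == 1L, na.rm = TRUE)
    n2 <- sum(x == 2L, na.rm = TRUE)
    hwe_chisq_p(n0, n1, n2)
  }, numeric(1))
  freq <- colMeans(cnt, na.rm = TRUE) / 2
  mono <- geno$snp_ids[freq %in% c(0, 1)]
  drop <- pvals < p_threshold
  list(geno = subset_geno(geno, snps = geno$snp_ids[!drop]),
       report = qc_report("hwe", "snp", length(drop), sum(drop), p_threshold,
                          removed = geno$snp_ids[drop],
                          notes = if (length(mono))
                            paste0("monomorphic, kept with P=1: ",
                                   paste(mono, collapse = ","))))
}

#' Retain SNPs within a minor-allele-frequency band
#'
#' Keeps SNPs with sample MAF in `(low, high]`. The common-variant analysis
#' uses `(0.05, 0.5]`; the combined common-plus-rare analysis uses
#' `(0.0037, 0.5]`.
#'
#' @param geno A `gxs_geno`.
#' @param low,high Band bounds, `0 <= low < high <= 0.5`.
#' @return List with elements `geno` and `report`.
#' @export
maf_band_filter <- function(geno, low = 0.05, high = 0.5) {
  assert_that(low >= 0 && low < high && high <= 0.5,
              "require 0 <= low < high <= 0.5")
  p <- colMeans(geno$counts, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf > low & maf <= high
  list(geno = subset_geno(geno, snps = geno$snp_ids[keep]),
       report = qc_report("maf_band", "snp", length(keep), sum(!keep),
                          c(low = low, high = high),
                          removed = geno$snp_ids[!keep]))
}

#' Prune related individuals from a GRM
#'
#' Greedy scheme: while any off-diagonal GRM entry exceeds the threshold,
#' remove the individual involved in the most such pairs (ties broken by
#' the lexicographically smallest ID). Guarantees no kept pair exceeds the
#' threshold; the removal set is deterministic but not necessarily minimal.
#'
#' @param grm A `gxs_grm`.
#' @param threshold Relatedness cut-off (0.0625 corresponds to roughly
#'   second-degree relatives).
#' @return List with `kept`, `removed` (ID vectors) and `report`.
#' @export
relatedness_prune <- function(grm, threshold = 0.0625) {
  stopifnot(inherits(grm, "gxs_grm"))
  k <- grm$K
  diag(k) <- -Inf
  adj <- k > threshold
  removed <- character(0)
  active <- rep(TRUE, length(grm$ids))
  names(active) <- grm$ids
  deg <- rowSums(adj)
  while (any(deg[active] > 0)) {
    cand <- names(which(active))[deg[active] == max(deg[active])]
    victim <- sort(cand)[1]
    vi <- match(victim, grm$ids)
    active[victim] <- FALSE
    removed <- c(removed, victim)
    # removing the victim lowers its partners' degrees
    partners <- which(adj[vi, ] & active)
    deg[partners] <- deg[partners] - 1L
    deg[vi] <- 0L
    adj[vi, ] <- FALSE
    adj[, vi] <- FALSE
  }
  kept <- grm$ids[active[grm$ids]]
  list(kept = kept, removed = removed,
       report = qc_report("relatedness_prune", "individual",
                          length(grm$ids), length(removed), threshold,
                          removed = removed))
}

#' Extract the related cohort from a GRM
#'
#' Returns the individuals that have at least one partner with relatedness
#' above the threshold.
#'
#' @param grm A `gxs_grm`.
#' @param threshold Relatedness cut-off.
#' @return Character vector of IDs.
#' @export
extract_related_cohort <- function(grm, threshold = 0.0625) {
  stopifnot(inherits(grm, "gxs_grm"))
  k <- grm$K
  diag(k) <- -Inf
  grm$ids[rowSums(k > threshold) > 0]
}

# Fix each component's sign so its largest-|value| SNP loading is positive.
fix_signs <- function(scores, loadings) {
  for (k in seq_len(ncol(scores))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      scores[, k] <- -scores[, k]
      loadings[, k] <- -loadings[, k]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Leading genomic principal components
#'
#' Scores of the k leading principal components of the standardized (and
#' mean-imputed) genotype matrix. Signs are fixed by making each
#' component's largest-magnitude SNP loading positive, so scores are
#' reproducible across linear-algebra backends.
#'
#' @param geno A `gxs_geno`.
#' @param k Number of components (default 20).
#' @return n x k matrix of scores with individual IDs as rownames.
#' @export
compute_pcs <- function(geno, k = 20L) {
  std <- standardize_genotypes(geno)
  assert_that(k >= 1 && k <= min(dim(std$Z)),
              "k must not exceed min(n individuals, n SNPs)")
  sv <- svd(std$Z, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  fixed <- fix_signs(scores, sv$v)
  scores <- fixed$scores
  dimnames(scores) <- list(geno$ids, paste0("PC", seq_len(k)))
  scores
}

#' Ancestry window on principal-component scores
#'
#' Keeps individuals whose score lies within `sd_multiplier` standard
#' deviations of the mean on *every* component; the complement forms the
#' prediction test cohort.
#'
#' @param pcs Score matrix from [compute_pcs()] (IDs as rownames).
#' @param sd_multiplier Width of the window in SDs (default 3).
#' @return Character vector of kept IDs.
#' @export
ancestry_window_filter <- function(pcs, sd_multiplier = 3) {
  mu <- colMeans(pcs)
  s <- apply(pcs, 2L, sd)
  dev <- sweep(abs(sweep(pcs, 2L, mu, "-")), 2L, s, "/")
  rownames(pcs)[apply(dev <= sd_multiplier, 1L, all)]
}

#' Remove per-sex phenotype outliers
#'
#' Removes individuals whose phenotype deviates more than `sd` standard
#' deviations from their own sex's mean. Means and SDs are computed once on
#' the full pre-filter cohort (no iteration).
#'
#' @param cohort A `gxs_cohort`.
#' @param sd Number of SDs defining an outlier (default 3).
#' @return List with elements `cohort` and `report`.
#' @export
per_sex_outlier_removal <- function(cohort, sd = 3) {
  stats_by <- lapply(split(cohort$y, cohort$sex), function(y)
    c(mean(y), stats::sd(y)))
  mu <- vapply(as.character(cohort$sex), function(s) stats_by[[s]][1], 0)
  s <- vapply(as.character(cohort$sex), function(s) stats_by[[s]][2], 0)
  out <- abs(cohort$y - mu) > sd * s
  out[is.na(out)] <- FALSE # zero-SD sex: nothing removed
  list(cohort = subset_cohort(cohort, cohort$ids[!out]),
       report = qc_report("per_sex_outliers", "individual", length(out),
                          sum(out), sd, removed = cohort$ids[out]))
}

#' Ratio phenotype from two cohorts
#'
#' Elementwise ratio of two phenotypes (e.g. waist-to-hip ratio, FEV1/FVC)
#' over the individuals present in both cohorts.
#'
#' @param cohort_num,cohort_den Cohorts carrying numerator and denominator
#'   phenotypes; IDs are matched and must overlap.
#' @return A `gxs_cohort` with the ratio phenotype.
#' @export
derive_ratio <- function(cohort_num, cohort_den) {
  ids <- intersect(cohort_num$ids, cohort_den$ids)
  assert_that(length(ids) > 0, "no shared individuals")
  num <- subset_cohort(cohort_num, ids)
  den <- subset_cohort(cohort_den, ids)
  assert_that(all(den$y != 0), "zero denominator phenotype")
  num$y <- num$y / den$y
  num
}

#' Rescale a phenotype to unit standard deviation
#'
#' Divides by the whole-cohort SD without centering (used for phenotypes
#' whose raw scale causes numerical trouble in model fitting).
#'
#' @param cohort A `gxs_cohort`.
#' @return The rescaled cohort.
#' @export
rescale_unit_sd <- function(cohort) {
  s <- sd(cohort$y)
  assert_that(is.finite(s) && s > 0, "phenotype is constant; cannot rescale")
  cohort$y <- cohort$y / s
  cohort
}

#' Composite score as the first principal component of several measures
#'
#' Excludes individuals more than `exclusion_sd` SDs from the population
#' mean on any measure, then standardizes the remaining measures and
#' returns first-principal-component scores (sign fixed as in
#' [compute_pcs()]).
#'
#' @param measure_table Numeric matrix of measures (>= 2 columns) with
#'   individual IDs as rownames.
#' @param exclusion_sd Pre-PCA exclusion threshold (default 5).
#' @return List with `ids`, `score`, and `excluded`.
#' @export
composite_pc_score <- function(measure_table, exclusion_sd = 5) {
  x <- as.matrix(measure_table)
  assert_that(ncol(x) >= 2, "need at least two measures")
  assert_that(!is.null(rownames(x)), "measure_table needs IDs as rownames")
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  dev <- sweep(abs(sweep(x, 2L, mu, "-")), 2L, s, "/")
  ok <- apply(dev <= exclusion_sd, 1L, all)
  xk <- scale(x[ok, , drop = FALSE])
  sv <- svd(xk, nu = 1L, nv = 1L)
  fixed <- fix_signs(sv$u * sv$d[1], sv$v)
  list(ids = rownames(x)[ok], score = as.numeric(fixed$scores),
       excluded = rownames(x)[!ok])
}

#' Cap a count phenotype by exclusion
#'
#' Removes (does not truncate) individuals whose count phenotype is in
#' excess of `max_value`; a value equal to `max_value` is kept.
#'
#' @param cohort A `gxs_cohort`.
#' @param max_value Largest admissible count (default 15).
#' @return List with elements `cohort` and `report`.
#' @export
cap_count_phenotype <- function(cohort, max_value = 15) {
  drop <- cohort$y > max_value
  list(cohort = subset_cohort(cohort, cohort$ids[!drop]),
       report = qc_report("count_cap", "individual", length(drop),
                          sum(drop), max_value, removed = cohort$ids[drop]))
}

rint_vec <- function(y) {
  r <- rank(y, ties.method = "average")
  qnorm((r - 0.5) / length(y))
}

#' Rank-based inverse normal transformation
#'
#' Replaces the phenotype by `qnorm((rank - 0.5) / n)` with average ranks
#' for ties, optionally within each sex separately.
#'
#' @param cohort A `gxs_cohort`.
#' @param within_sex Transform within each sex separately?
#' @return The transformed cohort.
#' @export
rank_inverse_normal <- function(cohort, within_sex = FALSE) {
  if (within_sex) {
    for (s in levels(cohort$sex)) {
      i <- cohort$sex == s
      if (any(i)) cohort$y[i] <- rint_vec(cohort$y[i])
    }
  } else {
    cohort$y <- rint_vec(cohort$y)
  }
  cohort
}

#' Match categorical phenotype distributions between the sexes
#'
#' Stratifies individuals within each sex by the (categorical) phenotype
#' value; per stratum, keeps every individual of the minority sex and a
#' seeded uniform random sample of equal size from the majority sex.
#' Strata with zero individuals of one sex are dropped entirely and
#' reported. The resulting per-sex phenotype distributions are identical.
#'
#' @param cohort A `gxs_cohort` with a finite-valued phenotype.
#' @param seed Seed for the majority-sex subsample.
#' @return List with `ids` (kept) and `report`.
#' @export
match_distributions <- function(cohort, seed = 1L) {
  strata <- split(seq_along(cohort$ids), cohort$y)
  dropped <- character(0)
  kept <- with_seed(seed, {
    unlist(lapply(strata, function(i) {
      im <- i[cohort$sex[i] == "M"]
      ifm <- i[cohort$sex[i] == "F"]
      if (length(im) == 0L || length(ifm) == 0L) {
        dropped <<- c(dropped, as.character(cohort$y[i[1]]))
        return(integer(0))
      }
      k <- min(length(im), length(ifm))
      c(if (length(im) > k) sample(im, k) else im,
        if (length(ifm) > k) sample(ifm, k) else ifm)
    }), use.names = FALSE)
  })
  kept <- sort(kept)
  list(ids = cohort$ids[kept],
       report = qc_report("match_distributions", "individual",
                          length(cohort$ids),
                          length(cohort$ids) - length(kept),
                          threshold = NA,
                          notes = if (length(dropped))
                            paste0("strata dropped (one sex absent): ",
                                   paste(dropped, collapse = ","))))
}
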