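make_missing_geno <- function(miss_per_snp, n = 100) {
  m <- length(miss_per_snp)
  counts <- matrix(1L, n, m)
  for (j in seq_len(m)) {
    if (miss_per_snp[j] > 0) counts[seq_len(miss_per_snp[j]), j] <- NA_integer_
  }
  toy_geno(counts)
}

test_that("SNP missingness filter removes rates strictly above threshold", {
  g <- make_missing_geno(c(0, 1, 2, 3, 4))
  res <- filter_snp_missingness(g, 0.02)
  expect_equal(length(res$geno$snp_ids), 3) # 0,1,2 missing of 100 kept
  expect_equal(res$report$n_removed, 2)
  expect_equal(res$report$n_in - res$report$n_removed, res$report$n_out)
})

test_that("individual missingness filter removes rates strictly above threshold", {
  counts <- matrix(0L, 3, 100)
  counts[2, 1:5] <- NA_integer_ # exactly 5%
  counts[3, 1:6] <- NA_integer_ # 6%
  g <- toy_geno(counts)
  res <- filter_individual_missingness(g, 0.05)
  expect_equal(res$geno$ids, g$ids[1:2])
})

test_that("platform bias filter applies the two-sided Fisher exact test", {
  platform <- rep(c("A", "B"), each = 50)
  # SNP 1: all of platform A missing, none of B -> table [[50,0],[0,50]]
  # SNP 2: 1 vs 2 missing -> P ~ 1
  # SNP 3: no missingness -> P = 1
  counts <- matrix(1L, 100, 3)
  counts[1:50, 1] <- NA_integer_
  counts[c(1, 51, 52), 2] <- NA_integer_
  g <- toy_geno(counts, platform = platform)
  p_extreme <- fisher.test(matrix(c(50, 0, 0, 50), 2))$p.value
  res <- filter_strict <- platform_bias_filter(g, p_threshold = p_extreme * 2)
  expect_equal(res$geno$snp_ids, g$snp_ids[2:3])
  # at the protocol threshold of 1e-100 even the extreme SNP survives a
  # 100-individual table (its exact P is ~1e-29)
  res2 <- platform_bias_filter(g, p_threshold = 1e-100)
  expect_equal(length(res2$geno$snp_ids), 3)
  expect_error(platform_bias_filter(toy_geno(counts)), "platform")
})

test_that("HWE filter matches an independently coded chi-square formula", {
  # exact HWE proportions: statistic 0, P = 1
  counts <- matrix(c(rep(0L, 25), rep(1L, 50), rep(2L, 25)), ncol = 1)
  g <- toy_geno(counts)
  res <- hwe_filter(g, p_threshold = 0.999)
  expect_equal(length(res$geno$snp_ids), 1)

  # total heterozygote deficit: removed at any sane threshold
  counts2 <- matrix(c(rep(0L, 50), rep(2L, 50)), ncol = 1)
  res2 <- hwe_filter(toy_geno(counts2), p_threshold = 1e-10)
  expect_equal(length(res2$geno$snp_ids), 0)

  # (30, 40, 30): compare against the formula coded longhand
  n0 <- 30; n1 <- 40; n2 <- 30
  p <- (2 * n2 + n1) / 200
  e <- 100 * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((c(n0, n1, n2) - e)^2 / e)
  p_hand <- pchisq(stat, 1, lower.tail = FALSE)
  counts3 <- matrix(c(rep(0L, 30), rep(1L, 40), rep(2L, 30)), ncol = 1)
  kept_above <- hwe_filter(toy_geno(counts3), p_threshold = p_hand * 0.999)
  removed_below <- hwe_filter(toy_geno(counts3), p_threshold = p_hand * 1.001)
  expect_equal(length(kept_above$geno$snp_ids), 1)
  expect_equal(length(removed_below$geno$snp_ids), 0)

  # monomorphic SNP: kept with P = 1 and flagged
  counts4 <- cbind(counts3[, 1], rep(2L, 100))
  res4 <- hwe_filter(toy_geno(counts4), p_threshold = 0.5)
  expect_true("s002" %in% res4$geno$snp_ids)
  expect_match(res4$report$notes, "monomorphic")
})

test_that("MAF band filter keeps (low, high]", {
  # MAFs 0.003, 0.02, 0.3, 0.5 via count means
  mk <- function(maf, n = 1000) {
    k <- round(2 * n * maf)
    c(rep(1L, k), rep(0L, n - k))
  }
  counts <- cbind(mk(0.003), mk(0.02), mk(0.3), mk(0.5))
  g <- toy_geno(counts)
  res_common <- maf_band_filter(g, 0.05, 0.5)
  expect_equal(res_common$geno$snp_ids, g$snp_ids[3:4]) # 0.5 kept: band is (low, high]
  res_comb <- maf_band_filter(g, 0.0037, 0.5)
  expect_equal(res_comb$geno$snp_ids, g$snp_ids[2:4])
})

test_that("relatedness pruning removes hubs greedily and resolves all pairs", {
  k <- diag(6) * 1
  ids <- LETTERS[1:6]
  # star: C related to D, E, F; plus no other pairs
  for (pair in list(c(3, 4), c(3, 5), c(3, 6))) {
    k[pair[1], pair[2]] <- k[pair[2], pair[1]] <- 0.2
  }
  grm <- toy_grm(k, ids)
  res <- relatedness_prune(grm, 0.0625)
  expect_equal(res$removed, "C") # hub removal resolves everything
  expect_equal(sort(res$kept), setdiff(ids, "C"))

  # single pair: exactly one removed (lexicographic tie-break -> A)
  k2 <- diag(2); k2[1, 2] <- k2[2, 1] <- 0.1
  res2 <- relatedness_prune(toy_grm(k2, c("B", "A")), 0.0625)
  expect_equal(res2$removed, "A")

  # nothing above threshold: all kept
  res3 <- relatedness_prune(toy_grm(diag(4)), 0.0625)
  expect_length(res3$removed, 0)

  # postcondition on random graphs: no kept pair above threshold, and the
  # removal count never beats the exhaustive minimum vertex cover by less
  # (greedy may exceed it)
  set.seed(1)
  for (i in 1:5) {
    n <- 8
    adj <- matrix(rbinom(n * n, 1, 0.2) * 0.2, n)
    adj[lower.tri(adj, diag = TRUE)] <- 0
    km <- adj + t(adj) + diag(n)
    grm_i <- toy_grm(km, sprintf("V%d", 1:n))
    res_i <- relatedness_prune(grm_i, 0.0625)
    keep_i <- match(res_i$kept, grm_i$ids)
    kk <- km[keep_i, keep_i]
    diag(kk) <- 0
    expect_true(all(kk <= 0.0625))
    # exhaustive minimal removal count
    edges <- which(km > 0.0625 & upper.tri(km), arr.ind = TRUE)
    if (nrow(edges) > 0) {
      best <- n
      for (sz in 0:n) {
        combs <- combn(n, sz)
        covered <- apply(combs, 2, function(rm)
          all(edges[, 1] %in% rm | edges[, 2] %in% rm))
        if (any(covered)) { best <- sz; break }
      }
      expect_lte(length(res_i$removed), best + 2) # documented greedy slack
    }
  }
})

test_that("related-cohort extraction returns all members of related pairs", {
  expect_length(extract_related_cohort(toy_grm(diag(4))), 0)
  k <- diag(6)
  k[1, 2] <- k[2, 1] <- 0.2
  k[4, 5] <- k[5, 4] <- 0.1
  expect_equal(sort(extract_related_cohort(toy_grm(k))),
               c("A", "B", "D", "E"))
})

test_that("principal-component scores match a dense eigendecomposition", {
  d <- sim_dataset(n_male = 25, n_female = 25, n_snps = 100, n_causal = 10,
                   seed = 21)
  scores <- compute_pcs(d$geno, k = 5)
  z <- d$std$Z
  eig <- eigen(tcrossprod(z), symmetric = TRUE)
  for (k in 1:5) {
    sc <- eig$vectors[, k] * sqrt(eig$values[k])
    loading <- crossprod(z, eig$vectors[, k]) / sqrt(eig$values[k])
    if (loading[which.max(abs(loading))] < 0) sc <- -sc
    expect_equal(unname(scores[, k]), sc, tolerance = 1e-8)
  }
  # identical individuals get identical score rows
  g2 <- toy_geno(rbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L),
                       c(2L, 0L, 0L, 1L), c(1L, 2L, 1L, 0L)))
  s2 <- compute_pcs(g2, k = 2)
  expect_equal(s2[1, ], s2[2, ], tolerance = 1e-10)
  expect_error(compute_pcs(d$geno, k = 1000), "k must not")
})

test_that("ancestry window keeps individuals within k SD on every component", {
  set.seed(22)
  pcs <- matrix(rnorm(150), 50, 3, dimnames = list(sprintf("I%02d", 1:50), NULL))
  pcs[50, 2] <- mean(pcs[1:49, 2]) + 100 # far out on PC2 only
  kept <- ancestry_window_filter(pcs, 3)
  expect_false("I50" %in% kept)
  # hand-filtered oracle
  dev_ok <- apply(abs(scale(pcs)) <= 3, 1, all)
  expect_equal(kept, rownames(pcs)[dev_ok])
  # everyone essentially at the mean: all kept
  flat <- matrix(rnorm(10, 0, 1e-9), 5, 2,
                 dimnames = list(sprintf("I%d", 1:5), NULL))
  expect_equal(ancestry_window_filter(flat, 3), rownames(flat))
})

test_that("per-sex outlier removal uses single-pass per-sex moments", {
  y <- c(10, 11, 12, 11, 10, 50, 1, 1.1, 0.9, 1, 1.05, 1)
  sex <- rep(c("M", "F"), each = 6)
  coh <- toy_cohort(y, sex)
  stats_m <- c(mean(y[1:6]), sd(y[1:6]))
  stats_f <- c(mean(y[7:12]), sd(y[7:12]))
  out_hand <- c(abs(y[1:6] - stats_m[1]) > 3 * stats_m[2],
                abs(y[7:12] - stats_f[1]) > 3 * stats_f[2])
  res <- per_sex_outlier_removal(coh, 3)
  expect_equal(res$cohort$ids, coh$ids[!out_hand])
  # all equal: nothing removed
  res2 <- per_sex_outlier_removal(toy_cohort(rep(1, 8), rep(c("M", "F"), 4)))
  expect_equal(res2$report$n_removed, 0)
})

test_that("ratio, rescaling and count-cap transforms are exact", {
  num <- toy_cohort(c(2, 3, 4, 6), c("M", "M", "F", "F"))
  den <- toy_cohort(c(1, 2, 2, 3), c("M", "M", "F", "F"))
  expect_equal(derive_ratio(num, den)$y, c(2, 1.5, 2, 2))
  expect_equal(derive_ratio(num, num)$y, rep(1, 4))

  y <- c(3, 9, 27, 81)
  r <- rescale_unit_sd(toy_cohort(y, c("M", "M", "F", "F")))
  expect_equal(sd(r$y), 1)
  expect_equal(r$y, y / sd(y))
  expect_error(rescale_unit_sd(toy_cohort(rep(2, 4), c("M", "M", "F", "F"))),
               "constant")

  cc <- cap_count_phenotype(toy_cohort(c(0, 3, 15, 16, 20),
                                       c("M", "M", "F", "F", "M")), 15)
  expect_equal(length(cc$cohort$ids), 3) # 15 itself is kept ("in excess of")
  expect_equal(cc$cohort$y, c(0, 3, 15))
})

test_that("composite score is the first PC after 5 SD pre-exclusion", {
  set.seed(31)
  base <- rnorm(40)
  x <- cbind(m1 = base + rnorm(40, 0, 0.01),
             m2 = 2 * base + rnorm(40, 0, 0.01),
             m3 = -base + rnorm(40, 0, 0.01))
  rownames(x) <- sprintf("I%02d", 1:40)
  x[40, 1] <- mean(x[1:39, 1]) + 30 * sd(x[1:39, 1])
  res <- composite_pc_score(x, 5)
  expect_equal(res$excluded, "I40")
  # near-collinear measures: score proportional to the common factor
  expect_gt(abs(cor(res$score, base[1:39])), 0.999)
  # dense eigensolve oracle on the standardized kept block
  xs <- scale(x[res$ids, ])
  eig <- eigen(tcrossprod(xs), symmetric = TRUE)
  sc <- eig$vectors[, 1] * sqrt(eig$values[1])
  loading <- crossprod(xs, eig$vectors[, 1]) / sqrt(eig$values[1])
  if (loading[which.max(abs(loading))] < 0) sc <- -sc
  expect_equal(res$score, sc, tolerance = 1e-8)
})

test_that("rank-based inverse normal transform has the closed quantile form", {
  coh <- toy_cohort(c(5, 1), c("M", "F"))
  r <- rank_inverse_normal(coh)
  expect_equal(r$y, c(qnorm(0.75), qnorm(0.25)))
  # monotone in the input
  set.seed(41)
  y <- rnorm(200)
  coh2 <- toy_cohort(y, rep(c("M", "F"), 100))
  r2 <- rank_inverse_normal(coh2)
  expect_equal(order(r2$y), order(y))
  expect_lt(abs(mean(r2$y)), 0.05)
  expect_lt(abs(sd(r2$y) - 1), 0.05)
  # within-sex: each sex is separately standard-normal-ish
  r3 <- rank_inverse_normal(coh2, within_sex = TRUE)
  for (s in c("M", "F")) {
    expect_lt(abs(mean(r3$y[r3$sex == s])), 0.08)
  }
})

test_that("distribution matching keeps stratum-wise minima per sex", {
  y <- c(rep("A", 10), rep("B", 5),   # males
         rep("A", 6), rep("B", 8))    # females
  sex <- rep(c("M", "F"), c(15, 14))
  coh <- toy_cohort(as.numeric(factor(y)), sex)
  res <- match_distributions(coh, seed = 2)
  kept <- subset_cohort(coh, res$ids)
  tab <- table(kept$y, kept$sex)
  expect_equal(as.numeric(tab[, "M"]), c(6, 5))
  expect_equal(as.numeric(tab[, "F"]), c(6, 5))
  expect_equal(length(res$ids), 22)
  # resulting sex x stratum table has chi-square statistic exactly 0
  expect_equal(unname(suppressWarnings(chisq.test(tab)$statistic)), 0)

  # already equal: everyone kept
  coh2 <- toy_cohort(rep(c(1, 2), 10), rep(c("M", "F"), each = 10))
  res2 <- match_distributions(coh2, seed = 3)
  expect_equal(length(res2$ids), 20)

  # stratum with one sex absent is dropped and reported
  coh3 <- toy_cohort(c(1, 1, 2, 1, 1), c("M", "M", "M", "F", "F"))
  res3 <- match_distributions(coh3, seed = 4)
  expect_false(any(subset_cohort(coh3, res3$ids)$y == 2))
  expect_match(res3$report$notes, "dropped")
})

test_that("QC filters are idempotent", {
  set.seed(51)
  counts <- matrix(rbinom(200 * 50, 2, 0.3), 200, 50)
  counts[sample(length(counts), 250)] <- NA_integer_
  g <- toy_geno(counts)
  once <- filter_snp_missingness(g, 0.03)$geno
  twice <- filter_snp_missingness(once, 0.03)$geno
  expect_identical(once$counts, twice$counts)

  once_i <- filter_individual_missingness(g, 0.04)$geno
  twice_i <- filter_individual_missingness(once_i, 0.04)$geno
  expect_identical(once_i$counts, twice_i$counts)

  once_m <- maf_band_filter(g, 0.05, 0.5)$geno
  twice_m <- maf_band_filter(once_m, 0.05, 0.5)$geno
  expect_identical(once_m$counts, twice_m$counts)

  once_h <- hwe_filter(g, 1e-4)$geno
  twice_h <- hwe_filter(once_h, 1e-4)$geno
  expect_identical(once_h$counts, twice_h$counts)
})
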