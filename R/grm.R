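# Genotype standardization and the genomic relationship matrix.
#
# K = Z Z' / M over the M retained SNPs, with Z the matrix of allele counts
# standardized by reference-population sample statistics and missing calls
# mean-imputed (hence contributing exactly zero). Division is by M, not by
# per-pair non-missing counts, which keeps the GRM model and the equivalent
# per-SNP-effect model exactly interchangeable.

#' Standardize allele counts by reference-population statistics
#'
#' Per SNP j, computes the mean `mu_j` and standard deviation `sigma_j`
#' (population form, denominator n) of the reference-allele count over the
#' designated reference individuals, mean-imputes missing calls, and returns
#' `(s_ij - mu_j) / sigma_j`. SNPs monomorphic in the reference
#' (`sigma_j = 0`) or with no observed reference call are dropped with a
#' warning.
#'
#' @param geno A `gxs_geno`.
#' @param reference_ids Individuals defining the standardization statistics
#'   (default: all). Must be a subset of `geno$ids`.
#' @return A list of class `gxs_std`: `Z` (n x M standardized matrix over
#'   all individuals in `geno`), `mu`, `sigma`, `snp_ids`, `dropped`.
#' @export
standardize_genotypes <- function(geno, reference_ids = geno$ids) {
  stopifnot(inherits(geno, "gxs_geno"))
  ri <- match(reference_ids, geno$ids)
  assert_that(!anyNA(ri), "reference_ids must be a subset of genotype ids")
  cnt <- geno$counts
  ref <- cnt[ri, , drop = FALSE]
  mu <- colMeans(ref, na.rm = TRUE)
  # population-form SD (denominator n over non-missing reference calls)
  ex2 <- colMeans(ref * ref, na.rm = TRUE)
  sigma <- sqrt(pmax(ex2 - mu^2, 0))
  bad <- !is.finite(mu) | !is.finite(sigma) | sigma == 0
  if (any(bad)) {
    warning(sprintf("dropping %d SNP(s) monomorphic or unobserved in the reference",
                    sum(bad)))
  }
  keep <- which(!bad)
  z <- sweep(cnt[, keep, drop = FALSE], 2L, mu[keep], "-")
  z <- sweep(z, 2L, sigma[keep], "/")
  z[is.na(z)] <- 0
  rownames(z) <- geno$ids
  structure(list(Z = z, mu = mu[keep], sigma = sigma[keep],
                 snp_ids = geno$snp_ids[keep],
                 dropped = geno$snp_ids[bad]),
            class = "gxs_std")
}

#' Compute the genomic relationship matrix
#'
#' `K = Z Z' / M` from a standardized genotype matrix (see
#' [standardize_genotypes()]). Under Hardy-Weinberg genotypes standardized
#' by their own sample statistics the expected diagonal is 1.
#'
#' @param std A `gxs_std` object, or a bare numeric matrix of standardized
#'   genotypes with individual ids as rownames.
#' @return An object of class `gxs_grm`: `ids`, `K` (symmetric n x n),
#'   `n_snps`.
#' @export
compute_grm <- function(std) {
  z <- if (inherits(std, "gxs_std")) std$Z else as.matrix(std)
  m <- ncol(z)
  assert_that(m >= 1, "no SNPs available to build a GRM")
  k <- tcrossprod(z) / m
  ids <- rownames(z) %||% sprintf("ID%05d", seq_len(nrow(z)))
  dimnames(k) <- list(ids, ids)
  structure(list(ids = ids, K = k, n_snps = m), class = "gxs_grm")
}

#' @export
print.gxs_grm <- function(x, ...) {
  cat(sprintf("gxs_grm: %d individuals, %d SNPs, mean diagonal %.3f\n",
              length(x$ids), x$n_snps, mean(diag(x$K))))
  invisible(x)
}

#' Reorder / subset a GRM by individual identifiers
#'
#' @param grm A `gxs_grm`.
#' @param ids Identifiers to retain, in the requested order.
#' @return The restricted `gxs_grm`.
#' @export
subset_grm <- function(grm, ids) {
  i <- match(ids, grm$ids)
  assert_that(!anyNA(i), "unknown individual identifiers in GRM subset")
  structure(list(ids = ids, K = grm$K[i, i, drop = FALSE],
                 n_snps = grm$n_snps), class = "gxs_grm")
}

#' Write a GRM as a GCTA binary triplet
#'
#' Writes `<prefix>.grm.bin` (float32 lower triangle, row-wise, diagonal
#' included), `<prefix>.grm.id` (FID/IID, tab-separated) and
#' `<prefix>.grm.N.bin` (float32 per-pair SNP counts; here the constant
#' `n_snps`).
#'
#' @param grm A `gxs_grm`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "gxs_grm"))
  n <- length(grm$ids)
  lt <- grm$K[upper.tri(grm$K, diag = TRUE)] # column-wise upper == row-wise lower
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lt), con, size = 4L)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_snps), length(lt)), con, size = 4L)
  close(con)
  write.table(data.frame(grm$ids, grm$ids), paste0(prefix, ".grm.id"),
              quote = FALSE, row.names = FALSE, col.names = FALSE,
              sep = "\t")
  invisible(prefix)
}

#' Read a GRM from a GCTA binary triplet
#'
#' @param prefix Path prefix of the `.grm.bin` / `.grm.id` /
#'   `.grm.N.bin` triplet.
#' @return A `gxs_grm`. The SNP count is taken from the first entry of
#'   `.grm.N.bin` when present.
#' @export
read_grm <- function(prefix) {
  idf <- read.table(paste0(prefix, ".grm.id"), header = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(idf[[2]])
  n <- length(ids)
  n_el <- n * (n + 1) / 2
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  vals <- readBin(con, numeric(), n = n_el + 1L, size = 4L)
  close(con)
  if (length(vals) != n_el) {
    stop(sprintf("GRM payload has %d elements; id file implies %d",
                 length(vals), n_el))
  }
  k <- matrix(0, n, n)
  k[upper.tri(k, diag = TRUE)] <- vals
  k <- k + t(k) - diag(diag(k))
  dimnames(k) <- list(ids, ids)
  n_snps <- NA_integer_
  nfile <- paste0(prefix, ".grm.N.bin")
  if (file.exists(nfile)) {
    con <- file(nfile, "rb")
    n_snps <- as.integer(readBin(con, numeric(), n = 1L, size = 4L))
    close(con)
  }
  structure(list(ids = ids, K = k, n_snps = n_snps), class = "gxs_grm")
}
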