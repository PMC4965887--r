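# PLINK bed/bim/fam and phenotype-table I/O.
#
# bed layout: 3 magic bytes (0x6c 0x1b 0x01 = SNP-major), then one
# SNP-major block per variant of ceil(n/4) bytes; two bits per individual,
# 00 = homozygous A1, 10 = heterozygous, 11 = homozygous A2, 01 = missing.
# Counts stored here are copies of the A1 (reference) allele.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

#' Write genotypes as PLINK bed/bim/fam
#'
#' @param geno A `gxs_geno`. Synthetic but valid chromosome/position fields
#'   are generated when `geno$bim` is absent.
#' @param prefix Output path prefix.
#' @param sex Optional factor/character of "M"/"F" per individual for the
#'   fam sex column (1 = male, 2 = female; 0 = unknown).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix, sex = NULL) {
  stopifnot(inherits(geno, "gxs_geno"))
  n <- length(geno$ids)
  m <- length(geno$snp_ids)
  bim <- geno$bim %||% data.frame(chr = 1L, snp = geno$snp_ids, cm = 0,
                                  pos = seq_len(m), a1 = "A", a2 = "B")
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  sex_code <- if (is.null(sex)) rep(0L, n) else
    ifelse(as.character(sex) == "M", 1L, 2L)
  fam <- data.frame(fid = geno$ids, iid = geno$ids, pat = 0L, mat = 0L,
                    sex = sex_code, phe = -9)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  # 2-bit codes indexed by A1 count + 1 (NA -> 01)
  code_for <- c(3L, 2L, 0L) # counts 0,1,2 -> raw codes 11, 10, 00
  bpb <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  idx4 <- rep(seq_len(bpb), each = 4L)[seq_len(n)]
  shift <- rep(c(0L, 2L, 4L, 6L), length.out = n)
  for (j in seq_len(m)) {
    cnt <- geno$counts[, j]
    code <- ifelse(is.na(cnt), 1L, code_for[cnt + 1L])
    bytes <- vapply(split(bitwShiftL(code, shift), idx4), sum, numeric(1))
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read genotypes from PLINK bed/bim/fam
#'
#' @param prefix Path prefix of the `.bed` / `.bim` / `.fam` triplet.
#' @return A `gxs_geno`; counts are copies of the A1 allele, missing calls
#'   are `NA`.
#' @export
read_plink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chr", "snp", "cm", "pos", "a1", "a2"))
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(fam[[2]])
  n <- length(ids)
  m <- nrow(bim)
  bpb <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 3L + bpb * m)
  if (!identical(raw[1:3], .bed_magic)) {
    stop("not a SNP-major PLINK bed file: ", prefix, ".bed")
  }
  body <- as.integer(raw[-(1:3)])
  if (length(body) != bpb * m) stop("bed payload size mismatch")
  # counts of A1 per 2-bit code: 00->2, 10->1, 11->0, 01->NA
  count_for <- c(2L, NA_integer_, 1L, 0L)
  counts <- matrix(NA_integer_, n, m)
  shift <- rep(c(0L, 2L, 4L, 6L), length.out = n)
  offs <- rep(seq_len(bpb), each = 4L)[seq_len(n)]
  for (j in seq_len(m)) {
    bytes <- body[(j - 1L) * bpb + offs]
    code <- bitwAnd(bitwShiftR(bytes, shift), 3L)
    counts[, j] <- count_for[code + 1L]
  }
  new_geno(counts, ids, as.character(bim$snp), bim = bim)
}

#' Write a phenotype/covariate table
#'
#' TSV with columns FID, IID, sex (M/F), phenotype and any covariates.
#'
#' @param cohort A `gxs_cohort`.
#' @param path Output file.
#' @param phenotype_name Column name for the phenotype.
#' @return `path`, invisibly.
#' @export
write_pheno <- function(cohort, path, phenotype_name = "phenotype") {
  df <- data.frame(FID = cohort$ids, IID = cohort$ids,
                   sex = as.character(cohort$sex),
                   y = cohort$y, check.names = FALSE)
  names(df)[4] <- phenotype_name
  if (!is.null(cohort$covariates)) df <- cbind(df, cohort$covariates)
  write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Expects the layout written by [write_pheno()]: FID, IID, sex, one
#' phenotype column, then covariates.
#'
#' @param path TSV file.
#' @param phenotype_name Phenotype column (default: fourth column).
#' @return A `gxs_cohort`.
#' @export
read_pheno <- function(path, phenotype_name = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  phenotype_name <- phenotype_name %||% names(df)[4]
  covar_cols <- setdiff(names(df), c("FID", "IID", "sex", phenotype_name))
  new_cohort(as.character(df$IID), df$sex, df[[phenotype_name]],
             covariates = if (length(covar_cols))
               as.matrix(df[covar_cols]) else NULL)
}
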