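# End-to-end orchestration: simulate -> qc -> grm -> fit -> predict,
# plus the calibration (null LRT) and prediction-improvement experiment
# suites. Stage artifacts are files, so each stage is independently
# restartable; every stage writes a manifest recording inputs, a config
# hash and the seed. Replicate r of an experiment uses seed
# base_seed + r, so partial reruns are consistent.

#' Default run configuration
#'
#' All QC thresholds default to the protocol values (SNP missingness 2%,
#' platform Fisher P 1e-100, individual missingness 5%, HWE P 1e-50, MAF
#' band (0.05, 0.5], relatedness 0.0625, ancestry window 3 SD on 20 PCs,
#' per-sex phenotype outliers 3 SD, composite-score pre-exclusion 5 SD,
#' offspring cap 15).
#'
#' @param ... Named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return A nested list of class `gxs_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    stages = list(simulate = TRUE, qc = TRUE, grm = TRUE, fit = TRUE,
                  predict = FALSE),
    truth = list(),   # overrides for gxs_truth()
    qc = list(snp_missingness = 0.02,
              platform_p = 1e-100,
              individual_missingness = 0.05,
              hwe_p = 1e-50,
              maf_low = 0.05, maf_high = 0.5,
              relatedness = 0.0625,
              ancestry_sd = 3, n_pcs = 20L,
              outlier_sd = 3, composite_sd = 5, count_cap = 15),
    reml = list(max_iter = 200L, tol_obj = 1e-8, tol_par = 1e-6),
    predict = list(test_fraction = 0.25),
    calibration = list(n_replicates = 10L, grid = list(list())),
    prediction_experiment = list(n_replicates = 5L,
                                 n_test = 500L, truths = list(list()))
  )
  over <- list(...)
  structure(modifyList(cfg, over), class = "gxs_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return For `read_config`, a `gxs_config` (defaults filled in); for
#'   `write_config`, `path` invisibly.
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  structure(modifyList(default_config(), over), class = "gxs_config")
}

#' @rdname read_config
#' @param config A `gxs_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_truth <- function(config) {
  do.call(gxs_truth, modifyList(list(seed = config$seed), config$truth))
}

write_manifest <- function(outdir, stage, config, inputs, outputs) {
  manifest <- list(stage = stage,
                   config_hash = rlang::hash(unclass(config)),
                   seed = config$seed,
                   inputs = inputs, outputs = outputs,
                   package_version = as.character(utils::packageVersion("gxsreml")))
  jsonlite::write_json(manifest,
                       file.path(outdir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes the enabled stages in order (simulate, qc, grm, fit, predict),
#' writing each stage's artifacts and manifest under `outdir`. A stage
#' whose outputs already exist is skipped unless `force`, so a run is
#' resumable from any completed stage; a disabled stage whose artifacts
#' are needed downstream raises an error naming the stage to run.
#'
#' @param config A `gxs_config` (see [default_config()]).
#' @param outdir Output directory (created if needed).
#' @param force Recompute stages whose artifacts already exist?
#' @return Invisibly, a list with the paths of the main artifacts and (when
#'   the fit stage ran) the `gxs_result`.
#' @export
run_pipeline <- function(config = default_config(), outdir, force = FALSE) {
  stopifnot(inherits(config, "gxs_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    plink = file.path(outdir, "cohort"),
    pheno = file.path(outdir, "phenotypes.tsv"),
    truth = file.path(outdir, "truth.json"),
    qc_plink = file.path(outdir, "cohort_qc"),
    qc_report = file.path(outdir, "qc_report.json"),
    grm = file.path(outdir, "cohort"),
    fit = file.path(outdir, "gxs_result.json"),
    fit_table = file.path(outdir, "gxs_result.tsv"),
    pred = file.path(outdir, "predictions.tsv"),
    pred_summary = file.path(outdir, "prediction_summary.json")
  )
  st <- config$stages
  result <- NULL

  if (isTRUE(st$simulate) &&
      (force || !file.exists(paste0(paths$plink, ".bed")))) {
    truth <- config_truth(config)
    geno <- simulate_genotypes(truth)
    cohort <- simulate_phenotypes(geno, truth)
    write_plink(geno, paths$plink, sex = cohort$sex)
    write_pheno(cohort, paths$pheno)
    jsonlite::write_json(truth[setdiff(names(truth),
                                       c("effects", "genetic_values"))],
                         paths$truth, auto_unbox = TRUE, pretty = TRUE)
    write_manifest(outdir, "simulate", config, list(),
                   list(paths$plink, paths$pheno, paths$truth))
  }

  if (isTRUE(st$qc) && (force || !file.exists(paste0(paths$qc_plink, ".bed")))) {
    if (!file.exists(paste0(paths$plink, ".bed"))) {
      stop("qc stage needs genotypes; run the 'simulate' stage first or place ",
           paths$plink, ".bed/.bim/.fam")
    }
    geno <- read_plink(paths$plink)
    q <- config$qc
    reports <- list()
    s1 <- filter_snp_missingness(geno, q$snp_missingness)
    reports$snp_missingness <- s1$report
    s2 <- filter_individual_missingness(s1$geno, q$individual_missingness)
    reports$individual_missingness <- s2$report
    s3 <- hwe_filter(s2$geno, q$hwe_p)
    reports$hwe <- s3$report
    s4 <- maf_band_filter(s3$geno, q$maf_low, q$maf_high)
    reports$maf_band <- s4$report
    cohort <- read_pheno(paths$pheno)
    cohort <- subset_cohort(cohort,
                            intersect(cohort$ids, s4$geno$ids))
    write_plink(s4$geno, paths$qc_plink, sex = cohort$sex)
    jsonlite::write_json(
      lapply(reports, function(r) r[c("stage", "unit", "n_in", "n_removed",
                                      "n_out", "threshold")]),
      paths$qc_report, auto_unbox = TRUE, pretty = TRUE)
    write_manifest(outdir, "qc", config, list(paths$plink),
                   list(paths$qc_plink, paths$qc_report))
  }

  if (isTRUE(st$grm) && (force || !file.exists(paste0(paths$grm, ".grm.bin")))) {
    src <- if (file.exists(paste0(paths$qc_plink, ".bed"))) paths$qc_plink
           else paths$plink
    if (!file.exists(paste0(src, ".bed"))) {
      stop("grm stage needs QC'd genotypes; run the 'qc' stage first")
    }
    geno <- read_plink(src)
    grm <- compute_grm(standardize_genotypes(geno))
    write_grm(grm, paths$grm)
    write_manifest(outdir, "grm", config, list(src), list(paths$grm))
  }

  if (isTRUE(st$fit) && (force || !file.exists(paths$fit))) {
    if (!file.exists(paste0(paths$grm, ".grm.bin"))) {
      stop("fit stage needs a GRM; run the 'grm' stage first")
    }
    grm <- read_grm(paths$grm)
    cohort <- read_pheno(paths$pheno)
    cohort <- subset_cohort(cohort, intersect(cohort$ids, grm$ids))
    result <- gxs_report(grm, cohort, options = config$reml)
    df <- as.data.frame(result)
    jsonlite::write_json(as.list(df), paths$fit, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    write.table(df, paths$fit_table, quote = FALSE, sep = "\t",
                row.names = FALSE)
    write_manifest(outdir, "fit", config, list(paths$grm, paths$pheno),
                   list(paths$fit, paths$fit_table))
  }

  if (isTRUE(st$predict) && (force || !file.exists(paths$pred))) {
    src <- if (file.exists(paste0(paths$qc_plink, ".bed"))) paths$qc_plink
           else paths$plink
    geno <- read_plink(src)
    cohort <- read_pheno(paths$pheno)
    cohort <- subset_cohort(cohort, intersect(cohort$ids, geno$ids))
    geno <- subset_geno(geno, ids = cohort$ids)
    sp <- split_train_test(cohort, geno, config$predict$test_fraction,
                           seed = config$seed)
    res <- prediction_run(sp$train, sp$test, options = config$reml)
    preds <- data.frame(FID = sp$test$cohort$ids, IID = sp$test$cohort$ids,
                        sex = as.character(sp$test$cohort$sex),
                        yhat_bivariate = res$pred$bivariate,
                        yhat_univariate = res$pred$univariate)
    write.table(preds, paths$pred, quote = FALSE, sep = "\t",
                row.names = FALSE)
    jsonlite::write_json(list(
      accuracy_bivariate = res$outcome$models$bivariate$accuracy,
      accuracy_univariate = res$outcome$models$univariate$accuracy,
      relative_improvement_pct = res$outcome$relative_improvement_pct),
      paths$pred_summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(outdir, "predict", config, list(src, paths$pheno),
                   list(paths$pred, paths$pred_summary))
  }

  invisible(list(paths = paths, result = result))
}

# Fit both models on the training half, back-solve effects, score the test
# half, and measure accuracy. Shared by run_pipeline and the prediction
# experiment.
prediction_run <- function(train, test, options = list()) {
  std <- standardize_genotypes(train$geno)
  grm <- compute_grm(std)
  fit_b <- fit_bivariate(grm, train$cohort, options = options)
  fit_u <- fit_univariate(grm, train$cohort, options = options)
  eff_b <- blup_effects(fit_b, std, train$cohort)
  eff_u <- blup_effects(fit_u, std, train$cohort)
  pred_b <- score_genotypes(eff_b, test$geno, sex = test$cohort$sex)
  pred_u <- score_genotypes(eff_u, test$geno)
  outcome <- prediction_accuracy(
    list(bivariate = pred_b, univariate = pred_u),
    test$cohort, list(bivariate = fit_b, univariate = fit_u))
  list(pred = list(bivariate = pred_b, univariate = pred_u),
       outcome = outcome, fits = list(bivariate = fit_b, univariate = fit_u))
}

replicate_truth <- function(config, overrides, rep_seed) {
  args <- modifyList(config$truth, overrides)
  do.call(gxs_truth, modifyList(list(seed = rep_seed), args))
}

#' Null-calibration experiment for the two likelihood ratio tests
#'
#' For each cell of a grid of generating architectures (all expected to
#' have genetic correlation one if used for null calibration), simulates
#' `n_replicates` cohorts, runs the full gene-by-sex analysis on each, and
#' tabulates the alpha = 0.05 rejection rates of both tests together with
#' the mean estimates and their bias against the generating values.
#' Replicate failures are caught, excluded and counted.
#'
#' @param config A `gxs_config`; `config$calibration$grid` is a list of
#'   truth-override lists, `config$calibration$n_replicates` the replicate
#'   count. Replicate r uses seed `config$seed + r`.
#' @return A data.frame with one row per grid cell: rejection rates,
#'   mean/SD of the r_g and h2 estimates, mean reported SE of r_g, and the
#'   failure count. The per-replicate results are attached as the
#'   `"replicates"` attribute.
#' @export
run_calibration <- function(config = default_config()) {
  grid <- config$calibration$grid
  nrep <- config$calibration$n_replicates
  all_reps <- list()
  rows <- lapply(seq_along(grid), function(ci) {
    truth0 <- replicate_truth(config, grid[[ci]], config$seed)
    reps <- lapply(seq_len(nrep), function(r) {
      tryCatch({
        truth <- replicate_truth(config, grid[[ci]], config$seed + r)
        geno <- simulate_genotypes(truth)
        cohort <- simulate_phenotypes(geno, truth)
        grm <- compute_grm(standardize_genotypes(geno))
        res <- gxs_report(grm, cohort, options = config$reml)
        cbind(cell = ci, replicate = r, as.data.frame(res))
      }, error = function(e) NULL)
    })
    ok <- !vapply(reps, is.null, logical(1))
    df <- do.call(rbind, reps[ok])
    all_reps[[ci]] <<- df
    data.frame(
      cell = ci,
      n_replicates = sum(ok),
      n_failed = sum(!ok),
      reject_rg = mean(df$p_rg < 0.05),
      reject_h2 = mean(df$p_h2 < 0.05),
      mean_rg = mean(df$rg), sd_rg = sd(df$rg),
      mean_se_rg = mean(df$se_rg),
      mean_h2_m = mean(df$h2_m), mean_h2_f = mean(df$h2_f),
      bias_h2_m = mean(df$h2_m) -
        truth0$sigma2_g_m / (truth0$sigma2_g_m + truth0$sigma2_e_m),
      bias_h2_f = mean(df$h2_f) -
        truth0$sigma2_g_f / (truth0$sigma2_g_f + truth0$sigma2_e_f)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- do.call(rbind, all_reps)
  out
}

#' Replicate train/test prediction experiment
#'
#' For each configured generating architecture, repeatedly simulates a
#' cohort, holds out `n_test` individuals, fits the sex-specific and
#' sex-agnostic models on the training part, scores the test part with
#' back-solved SNP effects and records both accuracies and the relative
#' improvement. Replicate r uses seed `config$seed + r`.
#'
#' @param config A `gxs_config`; `config$prediction_experiment` holds
#'   `truths` (list of truth-override lists), `n_replicates` and `n_test`.
#' @return A data.frame with one row per truth: mean/SD of both accuracies
#'   and of the relative improvement. Per-replicate rows are attached as
#'   the `"replicates"` attribute.
#' @export
run_prediction_experiment <- function(config = default_config()) {
  pe <- config$prediction_experiment
  all_reps <- list()
  rows <- lapply(seq_along(pe$truths), function(ti) {
    reps <- lapply(seq_len(pe$n_replicates), function(r) {
      truth <- replicate_truth(config, pe$truths[[ti]], config$seed + r)
      geno <- simulate_genotypes(truth)
      cohort <- simulate_phenotypes(geno, truth)
      frac <- pe$n_test / (truth$n_male + truth$n_female)
      sp <- split_train_test(cohort, geno, frac, seed = config$seed + r)
      res <- prediction_run(sp$train, sp$test, options = config$reml)
      data.frame(truth = ti, replicate = r,
                 accuracy_bivariate = res$outcome$models$bivariate$accuracy,
                 accuracy_univariate = res$outcome$models$univariate$accuracy,
                 relative_improvement_pct = res$outcome$relative_improvement_pct)
    })
    df <- do.call(rbind, reps)
    all_reps[[ti]] <<- df
    data.frame(
      truth = ti, n_replicates = nrow(df),
      mean_accuracy_bivariate = mean(df$accuracy_bivariate),
      mean_accuracy_univariate = mean(df$accuracy_univariate),
      mean_improvement_pct = mean(df$relative_improvement_pct),
      sd_improvement_pct = sd(df$relative_improvement_pct)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- do.call(rbind, all_reps)
  out
}
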