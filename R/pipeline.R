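## End-to-end orchestration: simulate (or load) -> QC -> harmonize -> clump
## -> threshold optimization -> scoring -> epidemiological models -> MR
## estimators -> sensitivity analyses, with a consolidated, deterministic
## report.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] to generate inputs, or NULL when reading
#'   from files.
#' @param input_prefix PLINK prefix of target genotypes (used when `sim` is
#'   NULL).
#' @param base_gwas_path,phenotype_path input files (when `sim` is NULL).
#' @param qc a [qc_thresholds()].
#' @param clump a [clump_params()].
#' @param grid p-value threshold grid.
#' @param n_perm permutations for the empirical p (default 10000; reduce
#'   for desk-scale runs).
#' @param n_pcs genetic principal components used as population
#'   stratification covariates (default 3).
#' @param estimators continuous-outcome estimators to run.
#' @param strata strata to run.
#' @param adjustments adjustment sets to run.
#' @param n_boot bootstrap resamples for binary two-stage SEs (0 = model
#'   SE).
#' @param seed master seed; a run is reproducible from config + seed.
#' @param outdir output directory (NULL suppresses file output).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_prefix = NULL,
                            base_gwas_path = NULL, phenotype_path = NULL,
                            qc = qc_thresholds(), clump = clump_params(),
                            grid = DEFAULT_GRID, n_perm = 10000L,
                            n_pcs = 3L,
                            estimators = c("tsls", "gmm"),
                            strata = STRATA,
                            adjustments = c("partial", "full"),
                            n_boot = 0L, seed = 1L, outdir = NULL) {
  if (is.null(sim) &&
      (is.null(input_prefix) || is.null(base_gwas_path) ||
       is.null(phenotype_path)))
    stop_config("either a simulation config or all three input paths ",
                "are required")
  structure(list(sim = sim, input_prefix = input_prefix,
                 base_gwas_path = base_gwas_path,
                 phenotype_path = phenotype_path, qc = qc, clump = clump,
                 grid = grid, n_perm = as.integer(n_perm),
                 n_pcs = as.integer(n_pcs), estimators = estimators,
                 strata = strata, adjustments = adjustments,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 outdir = outdir), class = "pipeline_config")
}

estimate_row <- function(e, outcome) {
  if (is.null(e$available) || !isTRUE(e$available))
    return(data.frame(outcome = outcome, stratum = e$stratum %||% NA,
                      method = NA, adjustment = NA, estimate = NA_real_,
                      se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_, n = NA_integer_, f_stat = NA_real_,
                      available = FALSE,
                      note = e$reason %||% "unavailable",
                      stringsAsFactors = FALSE))
  data.frame(outcome = outcome, stratum = e$stratum, method = e$method,
             adjustment = e$adjustment, estimate = e$estimate, se = e$se,
             ci_low = e$ci95[1], ci_high = e$ci95[2], p = e$p, n = e$n,
             f_stat = e$f_stat, available = TRUE,
             note = e$note %||% "", stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: input simulation or loading; variant QC and
#' harmonization with the base GWAS; sample QC, relatedness pruning and
#' genetic PCs; LD clumping and p-value-threshold optimization with the
#' permutation empirical p; observational association models; IV estimation
#' (2SLS/GMM for continuous outcomes, two-stage-logistic/GMM-logistic for
#' binary) across strata and adjustment sets; confounder balance and
#' pleiotropy scatter sensitivity checks. Identical config + seed gives
#' identical estimate tables.
#'
#' @param config a [pipeline_config()].
#' @return object of class `analysis_report`: qc_report,
#'   harmonization_report, prs (the selected `prs_model` summary),
#'   first_stage, estimates (data.frame, one row per outcome x stratum x
#'   method x adjustment), observational (data.frame), balance, scatter
#'   (per-outcome list), descriptives, provenance. Written as JSON + TSV +
#'   log under `config$outdir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  logf <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
  }

  ## --- stage: inputs ---
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- derive_seed(config$seed, 11L)
    class(sim) <- "sim_config"
    study <- simulate_study(sim)
    logf("simulated study: ", nrow(study$cohort), " samples, ",
         nrow(study$variants), " variants, seed ", sim$seed)
  } else {
    if (!file.exists(paste0(config$input_prefix, ".bed")))
      stop_data("missing bed file: ", config$input_prefix, ".bed")
    pl <- read_plink(config$input_prefix)
    cohort <- read_phenotypes(config$phenotype_path)
    study <- list(dosages = pl$dosages, variants = pl$variants,
                  base_gwas = read_base_gwas(config$base_gwas_path),
                  cohort = cohort, true_params = NULL)
    logf("loaded study from ", config$input_prefix)
  }
  dosages <- study$dosages; variants <- study$variants
  cohort <- study$cohort

  ## --- stage: variant QC ---
  fv <- filter_variants(dosages, variants, config$qc)
  logf("variant QC: ", fv$report$n_input, " -> ", fv$report$n_surviving,
       " (removed: ", paste(names(fv$report$removed), unlist(fv$report$removed),
                            sep = "=", collapse = ", "), ")")
  dosages <- fv$dosages; variants <- fv$variants

  ## --- stage: harmonization ---
  hz <- harmonize_variants(study$base_gwas, variants)
  logf("harmonization: matched=", hz$report$n_matched, " flipped=",
       hz$report$n_flipped, " ambiguous=", hz$report$n_dropped_ambiguous,
       " duplicate=", hz$report$n_dropped_duplicate, " mismatch=",
       hz$report$n_dropped_mismatch)
  keep_ids <- hz$harmonized$SNP
  dosages <- dosages[, keep_ids, drop = FALSE]
  variants <- variants[match(keep_ids, variants$snp_id), , drop = FALSE]

  ## --- stage: sample QC, relatedness, PCs ---
  sq <- sample_qc(dosages, config$qc)
  logf("sample QC removed ", sum(!sq$keep), " of ", nrow(dosages))
  keep_s <- sq$keep
  if (ncol(dosages) >= 200) {
    rel <- remove_related(dosages[keep_s, , drop = FALSE], config$qc)
    logf("relatedness pruning removed ", length(rel$removed))
  } else {
    rel <- list(keep = rep(TRUE, sum(keep_s)), removed = character(0))
    logf("relatedness pruning skipped: fewer than 200 variants")
  }
  keep_ids_s <- rownames(dosages)[keep_s][rel$keep]
  dosages <- dosages[keep_ids_s, , drop = FALSE]
  cohort <- cohort[match(keep_ids_s, cohort$sample_id), , drop = FALSE]
  pcs <- compute_pcs(dosages, config$n_pcs)$scores
  qc_report <- list(variant = fv$report,
                    sample = list(
                      n_input = length(keep_s),
                      removed_missing_het = sum(!keep_s),
                      removed_related = length(rel$removed),
                      n_surviving = nrow(dosages)))

  ## --- stage: exposure + clumping + threshold optimization ---
  exposure <- zstandardize(cohort$adiponectin, log_first = TRUE)
  cov_partial <- cbind(age = cohort$age, sex = cohort$sex, pcs)
  clumped <- clump(hz$harmonized, dosages, config$clump)
  logf("clumping retained ", nrow(clumped), " index SNPs")
  seed_perm <- derive_seed(config$seed, 13L)
  prs_model <- empirical_pvalue(clumped, dosages, exposure, cov_partial,
                                config$grid, variants,
                                n_perm = config$n_perm, seed = seed_perm)
  logf("PRS: threshold=", format(prs_model$threshold), " n_snps=",
       prs_model$n_snps, " fit_r2=", signif(prs_model$fit_r2, 4),
       " empirical_p=", signif(prs_model$empirical_p, 4))
  score <- prs_model$score
  fs_crude <- first_stage_f(exposure, score, NULL)
  fs_adj <- first_stage_f(exposure, score, cov_partial)
  logf("first-stage F: crude=", signif(fs_crude$f_stat, 5), " adjusted=",
       signif(fs_adj$f_stat, 5))

  ## --- stage: epi + MR across outcomes/strata/methods/adjustments ---
  observational <- list(); est_rows <- list(); scatter <- list()
  for (outc in ALL_OUTCOMES) {
    binary <- outc %in% BINARY_OUTCOMES
    methods <- if (binary)
      ifelse(config$estimators == "tsls", "two_stage_logistic",
             "gmm_logistic")
    else config$estimators
    for (adj in config$adjustments) {
      observational[[paste(outc, adj, sep = ".")]] <-
        tryCatch(observational_assoc(cohort, outc, adjustment = adj,
                                     pcs = pcs),
                 error = function(e) list(outcome = outc, adjustment = adj,
                                          available = FALSE,
                                          reason = conditionMessage(e)))
      fr <- analysis_frame(cohort, outc, adj, pcs)
      rows_keep <- fr$keep
      y <- if (binary) cohort[[outc]] else
        zstandardize(cohort[[outc]], log_first = outc %in% LOG_OUTCOMES)
      for (met in methods) {
        st <- run_stratified(cohort[rows_keep, , drop = FALSE],
                             y[rows_keep], exposure[rows_keep],
                             score[rows_keep],
                             as.matrix(fr$covariates)[rows_keep, ,
                                                      drop = FALSE],
                             estimator = met, strata = config$strata,
                             adjustment = adj)
        for (s in names(st)) {
          if (is.null(st[[s]]$stratum)) st[[s]]$stratum <- s
          est_rows[[length(est_rows) + 1]] <- estimate_row(st[[s]], outc)
        }
      }
    }
    ## pleiotropy scatter on the fully adjusted standardized outcome
    scatter[[outc]] <- tryCatch({
      yz <- if (binary) cohort[[outc]] else
        zstandardize(cohort[[outc]], log_first = outc %in% LOG_OUTCOMES)
      ok <- !is.na(yz)
      pleiotropy_scatter(prs_model, dosages[ok, , drop = FALSE],
                         exposure[ok], yz[ok], pcs[ok, , drop = FALSE])
    }, error = function(e) NULL)
  }
  estimates <- do.call(rbind, est_rows)
  balance <- confounder_balance(score, cohort)
  descr <- descriptive_table(cohort, grouping = "weight_status")

  report <- structure(list(
    qc_report = qc_report, harmonization_report = hz$report,
    prs = list(threshold = prs_model$threshold, n_snps = prs_model$n_snps,
               fit_r2 = prs_model$fit_r2,
               empirical_p = prs_model$empirical_p,
               grid_fit = prs_model$grid_fit,
               weights = prs_model$weights),
    first_stage = list(crude = fs_crude, adjusted = fs_adj),
    estimates = estimates, observational = observational,
    balance = balance, scatter = scatter, descriptives = descr,
    provenance = list(package = "adipomr",
                      version = as.character(utils::packageVersion("adipomr")),
                      seed = config$seed, n_perm = config$n_perm,
                      timestamp = format(Sys.time())),
    log = log_lines), class = "analysis_report")

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' Write an analysis report to disk (JSON + TSV + log)
#'
#' @param report an `analysis_report`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_report <- function(report, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok) stop_data("unwritable directory: ", outdir)
  est <- file.path(outdir, "estimates.tsv")
  utils::write.table(report$estimates, est, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(outdir, "report.json")
  slim <- report
  slim$scatter <- lapply(report$scatter, function(s)
    if (is.null(s)) NULL else s)
  jsonlite::write_json(unclass(slim), js, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  lg <- file.path(outdir, "pipeline.log")
  writeLines(report$log, lg)
  invisible(c(estimates = est, report = js, log = lg))
}
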