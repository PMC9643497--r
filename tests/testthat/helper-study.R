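# Lean simulated-study builders shared across tests. All paths go through
# the package generator; the true-weight instrument is the PRS built from
# the simulated per-variant effects.

quick_config <- function(n = 1000, m = 60, blocks = 30, ivf = 0.05,
                         causal_beta = 0.5, conf_x = 0.5, conf_y = 0.5,
                         case_fraction = NA, seed = 1, ...) {
  sim_config(n_samples = n, n_variants = m, n_blocks = blocks,
             n_instrument_snps = blocks, instrument_variance_fraction = ivf,
             causal_beta = causal_beta,
             confounder_effect_exposure = conf_x,
             confounder_effect_outcome = conf_y,
             case_fraction = case_fraction, n_subpops = 1L,
             missing_rate = 0, seed = seed, ...)
}

# genotypes + cohort + true-weight PRS + standardized exposure/outcome
make_study <- function(cfg, outcome = "ldl") {
  geno <- simulate_genotypes(cfg)
  sim <- simulate_cohort(cfg, geno)
  dos <- geno$dosages[sim$rows, , drop = FALSE]
  tp <- sim$true_params
  w <- data.frame(snp_id = tp$instrument_snps,
                  effect_allele = geno$variants$a1[tp$instrument_idx],
                  beta = tp$variant_beta[tp$instrument_idx])
  z <- prs_score(dos, w, geno$variants)
  x <- zstandardize(sim$cohort$adiponectin, log_first = TRUE)
  y <- if (outcome %in% c("t2d", "hypertension")) sim$cohort[[outcome]]
  else zstandardize(sim$cohort[[outcome]],
                    log_first = outcome %in% c("homa_ir", "triglycerides"))
  covs <- cbind(age = sim$cohort$age, sex = sim$cohort$sex,
                bmi = sim$cohort$bmi)
  list(cohort = sim$cohort, dosages = dos, variants = geno$variants,
       true = tp, z = z, x = x, y = y, covs = covs)
}
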