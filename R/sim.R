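## Synthetic study generator: LD-structured genotypes, a base GWAS of the
## exposure, and a target cohort with known causal architecture. The design
## emulates a one-sample MR study of circulating adiponectin against
## cardiometabolic outcomes in a T2D case-control cohort: a log-normal
## exposure partly determined by a sparse set of variants, confounded
## outcomes, population structure, and case-control ascertainment of T2D.

CONTINUOUS_OUTCOMES <- c("homa_ir", "hdl", "ldl", "total_cholesterol",
                         "triglycerides", "sbp", "dbp")
BINARY_OUTCOMES <- c("t2d", "hypertension")
ALL_OUTCOMES <- c(CONTINUOUS_OUTCOMES, BINARY_OUTCOMES)

#' Simulation configuration
#'
#' Defines the synthetic study: genotype panel dimensions and LD, the sparse
#' genetic architecture of the (log-normal) exposure, causal effects of the
#' standardized log exposure on each outcome, shared unobserved confounding,
#' optional direct (pleiotropic) variant effects on outcomes, the size of the
#' external base GWAS, and T2D case-control ascertainment.
#'
#' @param n_samples number of cohort samples to simulate.
#' @param n_variants number of variants.
#' @param n_blocks number of independent LD blocks; variants are split evenly
#'   across blocks and blocks across autosomes.
#' @param maf_range length-2 numeric in (0, 0.5]; each block draws its minor
#'   allele frequency uniformly from this range.
#' @param target_adjacent_r2 target squared correlation between adjacent
#'   variants within a block, in \[0, 1).
#' @param n_instrument_snps number of variants with true effects on the
#'   exposure (at most one per block so that clumping is meaningful).
#' @param instrument_variance_fraction fraction of exposure variance explained
#'   by the instrument variants, in \[0, 1). Default 0.03, a realistic share
#'   for an adipokine polygenic score.
#' @param causal_beta causal effect of 1 SD log-exposure on each outcome:
#'   SD units for continuous outcomes, log-odds for binary. A single number is
#'   recycled to all nine outcomes; a named vector overrides per outcome.
#' @param confounder_effect_exposure,confounder_effect_outcome SD-unit
#'   loadings of the latent confounder U on the exposure and on every outcome.
#' @param pleiotropy_fraction fraction of instrument variants given direct
#'   outcome effects bypassing the exposure.
#' @param pleiotropy_effect direct effect size (SD units per allele) of each
#'   pleiotropic variant.
#' @param base_gwas_n sample size of the simulated base GWAS (default 29347,
#'   the size of the adiponectin meta-analysis being emulated).
#' @param case_fraction target T2D case share after case-control subsampling
#'   (default 0.48); NA disables ascertainment.
#' @param n_subpops number of subpopulations (allele-frequency divergence
#'   makes genetic PCs informative); 1 disables structure.
#' @param fst Wright's fixation index controlling subpopulation divergence.
#' @param missing_rate genotype missingness rate (default 0.005).
#' @param seed integer seed; identical configs + seed give identical output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 2000L, n_variants = 2000L, n_blocks = 80L,
                       maf_range = c(0.05, 0.5), target_adjacent_r2 = 0.5,
                       n_instrument_snps = 30L,
                       instrument_variance_fraction = 0.03,
                       causal_beta = c(homa_ir = -0.10, hdl = 0.16, ldl = 0.55,
                                       total_cholesterol = 0.08,
                                       triglycerides = -0.14, sbp = 0.05,
                                       dbp = 0.05, t2d = -0.30,
                                       hypertension = 0.00),
                       confounder_effect_exposure = 0.3,
                       confounder_effect_outcome = 0.3,
                       pleiotropy_fraction = 0, pleiotropy_effect = 0,
                       base_gwas_n = 29347L, case_fraction = 0.48,
                       n_subpops = 2L, fst = 0.02, missing_rate = 0.005,
                       seed = 1L) {
  if (n_samples < 1 || n_variants < 1 || n_blocks < 1)
    stop_config("n_samples, n_variants and n_blocks must be positive")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop_config("maf_range must be an increasing pair in (0, 0.5]")
  if (target_adjacent_r2 < 0 || target_adjacent_r2 >= 1)
    stop_config("target_adjacent_r2 must be in [0, 1)")
  if (n_instrument_snps > n_variants)
    stop_config("n_instrument_snps exceeds n_variants")
  if (instrument_variance_fraction < 0 || instrument_variance_fraction >= 1)
    stop_config("instrument_variance_fraction must be in [0, 1)")
  if (pleiotropy_fraction < 0 || pleiotropy_fraction > 1)
    stop_config("pleiotropy_fraction must be in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_config("missing_rate must be in [0, 1)")
  if (base_gwas_n <= 0) stop_config("base_gwas_n must be positive")
  if (!is.na(case_fraction) && (case_fraction <= 0 || case_fraction >= 1))
    stop_config("case_fraction must be in (0, 1) or NA")

  if (length(causal_beta) == 1 && is.null(names(causal_beta)))
    causal_beta <- stats::setNames(rep(causal_beta, length(ALL_OUTCOMES)),
                                   ALL_OUTCOMES)
  cb <- stats::setNames(rep(0, length(ALL_OUTCOMES)), ALL_OUTCOMES)
  if (is.null(names(causal_beta)))
    stop_config("causal_beta must be a scalar or a named vector")
  bad <- setdiff(names(causal_beta), ALL_OUTCOMES)
  if (length(bad)) stop_config("unknown outcomes in causal_beta: ",
                               paste(bad, collapse = ", "))
  cb[names(causal_beta)] <- causal_beta

  structure(list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    n_blocks = as.integer(n_blocks), maf_range = maf_range,
    target_adjacent_r2 = target_adjacent_r2,
    n_instrument_snps = as.integer(n_instrument_snps),
    instrument_variance_fraction = instrument_variance_fraction,
    causal_beta = cb,
    confounder_effect_exposure = confounder_effect_exposure,
    confounder_effect_outcome = confounder_effect_outcome,
    pleiotropy_fraction = pleiotropy_fraction,
    pleiotropy_effect = pleiotropy_effect,
    base_gwas_n = as.integer(base_gwas_n), case_fraction = case_fraction,
    n_subpops = as.integer(n_subpops), fst = fst,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

ALLELE_PAIRS <- rbind(
  c("A", "G"), c("A", "C"), c("A", "T"), c("C", "G"),
  c("C", "T"), c("G", "T"), c("G", "A"), c("C", "A"),
  c("T", "A"), c("G", "C"), c("T", "C"), c("T", "G"))

#' Simulate LD-structured diploid genotypes
#'
#' Haplotypes are generated blockwise by an allele-copying Markov chain: each
#' successive variant copies the previous haplotype allele with probability
#' `sqrt(target_adjacent_r2)` and otherwise draws a fresh allele, so the
#' adjacent-pair genotype correlation equals `sqrt(target_adjacent_r2)`
#' exactly in expectation while marginal frequencies are preserved. Blocks
#' are mutually independent. Subpopulation allele frequencies diverge by a
#' Balding-Nichols beta model with the configured Fst.
#'
#' @param config a [sim_config()].
#' @return list with `dosages` (n x m matrix of 0/1/2 counts of the a1
#'   allele, `NA` for missing, dimnames sample/variant ids), `variants`
#'   (data.frame: snp_id, chrom, pos, a1, a2, block, maf, info), and
#'   `subpop` (integer subpopulation label per sample).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_samples; m <- config$n_variants; B <- config$n_blocks
  block <- sort(rep_len(seq_len(B), m))
  copy_p <- sqrt(config$target_adjacent_r2)

  ## block -> chromosome layout: blocks spread over up to 22 autosomes,
  ## positions 5 kb apart so a 250 kb clumping window spans ~50 variants.
  n_chr <- min(22L, B)
  chrom_of_block <- rep_len(seq_len(n_chr), B)
  chrom <- chrom_of_block[block]
  pos <- integer(m)
  for (cc in seq_len(n_chr)) {
    idx <- which(chrom == cc)
    pos[idx] <- 50000L + 5000L * seq_along(idx)
  }

  subpop <- if (config$n_subpops > 1)
    sample(rep_len(seq_len(config$n_subpops), n)) else rep(1L, n)

  maf_block <- stats::runif(B, config$maf_range[1], config$maf_range[2])
  ## Balding-Nichols divergence per block x subpopulation
  pmat <- matrix(maf_block, B, config$n_subpops)
  if (config$n_subpops > 1 && config$fst > 0) {
    a <- maf_block * (1 - config$fst) / config$fst
    b <- (1 - maf_block) * (1 - config$fst) / config$fst
    for (k in seq_len(config$n_subpops))
      pmat[, k] <- pmin(0.99, pmax(0.01, stats::rbeta(B, a, b)))
  }

  G <- matrix(0L, n, m)
  p_row <- function(bk) pmat[bk, subpop]   # length-n freq vector
  for (bk in seq_len(B)) {
    cols <- which(block == bk)
    p <- p_row(bk)
    h1 <- matrix(0L, n, length(cols)); h2 <- h1
    h1[, 1] <- stats::rbinom(n, 1, p); h2[, 1] <- stats::rbinom(n, 1, p)
    if (length(cols) > 1) for (j in 2:length(cols)) {
      keep1 <- stats::runif(n) < copy_p
      keep2 <- stats::runif(n) < copy_p
      h1[, j] <- ifelse(keep1, h1[, j - 1], stats::rbinom(n, 1, p))
      h2[, j] <- ifelse(keep2, h2[, j - 1], stats::rbinom(n, 1, p))
    }
    G[, cols] <- h1 + h2
  }

  if (config$missing_rate > 0) {
    nmiss <- stats::rbinom(1, n * m, config$missing_rate)
    if (nmiss > 0) G[sample.int(n * m, nmiss)] <- NA_integer_
  }

  pair <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), m, replace = TRUE), ,
                       drop = FALSE]
  snp_id <- sprintf("rs%07d", seq_len(m) * 13L + 100000L)
  sample_id <- sprintf("S%05d", seq_len(n))
  dimnames(G) <- list(sample_id, snp_id)

  variants <- data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos,
    a1 = pair[, 1], a2 = pair[, 2], block = block,
    maf = maf_block[block],
    ## imputation quality skewed high, as on real imputed panels; ~12%
    ## fall below the 0.8 filter so it has work to do without gutting
    ## the panel
    info = ifelse(stats::runif(m) < 0.85, stats::runif(m, 0.9, 1),
                  stats::runif(m, 0.3, 0.9)),
    stringsAsFactors = FALSE)
  ## order variants by chrom/pos (and columns to match)
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  rownames(variants) <- NULL
  G <- G[, variants$snp_id, drop = FALSE]
  list(dosages = G, variants = variants, subpop = subpop)
}

#' Simulate base GWAS summary statistics for the exposure
#'
#' Emulates an external meta-analysis of a standardized trait: for each
#' variant, `se = 1/sqrt(2 n eaf (1-eaf))`, the observed beta is the true
#' per-allele effect plus normal noise with that SE, and p is the two-sided
#' normal test. INFO scores are drawn uniformly on \[0.3, 1\] so that the
#' INFO < 0.8 filter is exercised downstream.
#'
#' @param config a [sim_config()].
#' @param variants variant metadata from [simulate_genotypes()].
#' @param true_effects numeric vector of true per-allele effects of the a1
#'   allele on the standardized log exposure, aligned with `variants`.
#' @return data.frame with columns SNP, CHR, BP, A1, A2, EAF, BETA, SE, P,
#'   N, INFO (one row per variant; effect allele = A1).
#' @export
simulate_base_gwas <- function(config, variants, true_effects) {
  stopifnot(inherits(config, "sim_config"),
            length(true_effects) == nrow(variants))
  if (config$base_gwas_n <= 0) stop_config("base_gwas_n must be positive")
  set.seed(derive_seed(config$seed, 2L))
  eaf <- pmin(pmax(variants$maf, 1e-3), 1 - 1e-3)
  n <- config$base_gwas_n
  se <- 1 / sqrt(2 * n * eaf * (1 - eaf))
  beta <- true_effects + stats::rnorm(length(se), 0, se)
  p <- 2 * stats::pnorm(-abs(beta / se))
  ## ~5% of records are reported on the opposite strand, as in real
  ## cross-consortium data, so harmonization's strand-flip path is exercised
  a1 <- variants$a1; a2 <- variants$a2
  opp <- stats::runif(length(a1)) < 0.05
  a1[opp] <- COMPLEMENT[a1[opp]]; a2[opp] <- COMPLEMENT[a2[opp]]
  data.frame(SNP = variants$snp_id, CHR = variants$chrom, BP = variants$pos,
             A1 = a1, A2 = a2, EAF = eaf,
             BETA = beta, SE = se, P = p, N = n,
             INFO = stats::runif(length(se), 0.3, 1),
             stringsAsFactors = FALSE)
}

## Natural-unit anchors for the simulated cohort, chosen to match the
## population being emulated (sub-Saharan African adults in a T2D
## case-control design): medians/means and spreads of each trait.
TRAIT_SCALE <- list(
  adiponectin = c(mu = log(7549), sigma = 1.05),   # ng/ml, log-normal
  homa_ir = c(mu = log(1.23), sigma = 0.85),       # log-normal index
  triglycerides = c(mu = log(98), sigma = 0.45),   # mg/dl, log-normal
  hdl = c(mean = 42.9, sd = 13), ldl = c(mean = 132.1, sd = 36),
  total_cholesterol = c(mean = 203.3, sd = 42),
  sbp = c(mean = 138.2, sd = 22), dbp = c(mean = 82.8, sd = 12))

#' Simulate the target cohort
#'
#' Builds the structural model: standardized log exposure
#' `X = G b + a_x U + covariate and subpopulation terms + e`, scaled so the
#' instrument variants explain `instrument_variance_fraction` of var(X);
#' continuous outcomes `Y = beta X + a_y U + covariate terms + pleiotropy +
#' e` (reported in natural units); T2D from a logistic liability on X and U
#' with fasting glucose simulated consistently with the >= 7.0 mmol/L
#' diagnostic rule; hypertension from the rule SBP >= 130 or DBP >= 80 or
#' antihypertensive medication. When `case_fraction` is set, cases are
#' oversampled from the simulated population (all cases kept, controls
#' subsampled) to emulate case-control ascertainment.
#'
#' @param config a [sim_config()].
#' @param geno output of [simulate_genotypes()].
#' @return list with `cohort` (data.frame, one row per retained sample;
#'   column `sample_id` indexes rows of `geno$dosages`), `true_params`
#'   (ground truth: per-variant effects, causal betas, confounder loadings,
#'   pleiotropic variants, variance components), and `rows` (indices of
#'   retained samples in the input dosage matrix).
#' @export
simulate_cohort <- function(config, geno) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 3L))
  G <- geno$dosages; variants <- geno$variants
  n <- nrow(G); m <- ncol(G)

  ## --- instrument architecture: one causal variant per block (up to k) ---
  blocks <- unique(variants$block)
  k <- config$n_instrument_snps
  if (k > 0) {
    bsel <- if (length(blocks) >= k) sample(blocks, k) else
      sample(blocks, k, replace = TRUE)
    inst_idx <- vapply(bsel, function(b) {
      cand <- which(variants$block == b)
      cand[sample.int(length(cand), 1)]
    }, integer(1))
    inst_idx <- unique(inst_idx)
  } else inst_idx <- integer(0)

  b <- numeric(m)
  if (length(inst_idx)) {
    p <- variants$maf[inst_idx]
    raw <- sample(c(-1, 1), length(inst_idx), TRUE) *
      stats::runif(length(inst_idx), 0.5, 1.5)
    v_raw <- sum(raw^2 * 2 * p * (1 - p))
    b[inst_idx] <- raw * sqrt(config$instrument_variance_fraction /
                                max(v_raw, 1e-12))
  }
  Gc <- G; Gc[is.na(Gc)] <- 0  # missing dosages contribute nothing to truth
  gscore <- as.vector(Gc %*% b)
  gscore <- gscore - mean(gscore)

  ## --- covariates ---
  U <- stats::rnorm(n)
  age <- round(pmax(20, stats::rnorm(n, 54.2, 10.5)))
  sex <- stats::rbinom(n, 1, 0.62)        # 1 = female
  smoke_cat <- sample(c("never", "current", "former"), n, TRUE,
                      prob = c(1 - 0.037 - 0.116, 0.037, 0.116))
  smoking_current <- as.integer(smoke_cat == "current")
  smoking_former <- as.integer(smoke_cat == "former")
  alcohol <- stats::rbinom(n, 1, 0.272)
  bmi <- pmax(15, stats::rnorm(n, 27.4, 4.3))
  bmi_std <- (bmi - 27.4) / 4.3
  lipid_med <- stats::rbinom(n, 1, 0.012)

  ## subpopulation shifts make PC adjustment meaningful
  spop_eff <- if (config$n_subpops > 1)
    (geno$subpop - mean(geno$subpop)) * 0.2 else rep(0, n)

  ## --- exposure: standardized log adiponectin ---
  a_x <- config$confounder_effect_exposure
  b_bmi_x <- -0.15; b_sex_x <- 0.25
  v_known <- config$instrument_variance_fraction + a_x^2 + b_bmi_x^2 +
    b_sex_x^2 * stats::var(sex) + stats::var(spop_eff)
  if (v_known >= 1)
    stop_config("variance components of the exposure exceed 1")
  e_x <- stats::rnorm(n, 0, sqrt(1 - v_known))
  X <- gscore + a_x * U + b_bmi_x * bmi_std + b_sex_x * (sex - 0.62) +
    spop_eff + e_x
  adiponectin <- exp(TRAIT_SCALE$adiponectin["mu"] +
                       TRAIT_SCALE$adiponectin["sigma"] * X)

  ## --- pleiotropy: direct variant effects on outcomes ---
  n_pleio <- round(config$pleiotropy_fraction * length(inst_idx))
  pleio_idx <- if (n_pleio > 0) sample(inst_idx, n_pleio) else integer(0)
  pleio_term <- if (length(pleio_idx))
    as.vector(scale(Gc[, pleio_idx, drop = FALSE] %*%
                      rep(config$pleiotropy_effect, length(pleio_idx)),
                    scale = FALSE)) else rep(0, n)

  ## --- continuous outcomes (standardized latent, then natural units) ---
  a_y <- config$confounder_effect_outcome
  cb <- config$causal_beta
  var_sex <- 0.62 * 0.38
  ## latent standardized outcome with unit total variance, so causal_beta is
  ## exactly the effect per outcome SD: the residual absorbs what the
  ## structural terms (including the X-U and X-covariate covariances, since
  ## X itself carries the confounder and covariate loadings) do not explain
  lat <- function(beta) {
    v <- beta^2 + a_y^2 + 0.01 * (2 + var_sex) +
      2 * beta * (a_y * a_x + 0.1 * b_sex_x * var_sex + 0.1 * b_bmi_x)
    if (v >= 1) stop_config("outcome variance components exceed 1 for beta=",
                            beta)
    beta * X + a_y * U + 0.1 * (age - 54.2) / 10.5 + 0.1 * (sex - 0.62) +
      0.1 * bmi_std + pleio_term + stats::rnorm(n, 0, sqrt(1 - v))
  }
  hdl <- TRAIT_SCALE$hdl["mean"] + TRAIT_SCALE$hdl["sd"] * lat(cb["hdl"])
  ldl <- TRAIT_SCALE$ldl["mean"] + TRAIT_SCALE$ldl["sd"] * lat(cb["ldl"])
  tc <- TRAIT_SCALE$total_cholesterol["mean"] +
    TRAIT_SCALE$total_cholesterol["sd"] * lat(cb["total_cholesterol"])
  tg <- exp(TRAIT_SCALE$triglycerides["mu"] +
              TRAIT_SCALE$triglycerides["sigma"] * lat(cb["triglycerides"]))
  sbp <- TRAIT_SCALE$sbp["mean"] + TRAIT_SCALE$sbp["sd"] * lat(cb["sbp"])
  dbp <- TRAIT_SCALE$dbp["mean"] + TRAIT_SCALE$dbp["sd"] * lat(cb["dbp"])
  homa_std <- lat(cb["homa_ir"])
  homa_ir <- exp(TRAIT_SCALE$homa_ir["mu"] +
                   TRAIT_SCALE$homa_ir["sigma"] * homa_std)

  ## blood-pressure medication depends on (untreated) SBP; hypertension rule
  bp_med <- stats::rbinom(n, 1, expit(-2.2 + 0.05 * (sbp - 138.2)))
  hypertension <- as.integer(sbp >= 130 | dbp >= 80 | bp_med == 1)

  ## --- T2D: logistic liability, intercept solved for base prevalence ---
  base_prev <- 0.25
  lin_t2d <- cb["t2d"] * X + a_y * U + 0.25 * bmi_std +
    0.2 * (age - 54.2) / 10.5
  alpha <- stats::uniroot(function(a) mean(expit(a + lin_t2d)) - base_prev,
                          c(-15, 15))$root
  t2d <- stats::rbinom(n, 1, expit(alpha + lin_t2d))
  glucose_med <- ifelse(t2d == 1, stats::rbinom(n, 1, 0.4), 0L)
  ## fasting glucose consistent with the diagnostic rule: untreated cases
  ## >= 7.0 mmol/L; treated cases may be controlled; controls < 7.0
  glucose <- numeric(n)
  ctrl <- t2d == 0
  glucose[ctrl] <- pmin(6.9, exp(stats::rnorm(sum(ctrl), log(5.2), 0.1)))
  case_untr <- t2d == 1 & glucose_med == 0
  glucose[case_untr] <- 7.0 + stats::rexp(sum(case_untr), 1 / 2.5)
  case_tr <- t2d == 1 & glucose_med == 1
  glucose[case_tr] <- exp(stats::rnorm(sum(case_tr), log(6.8), 0.25))
  insulin <- homa_ir * 22.5 / glucose

  cohort <- data.frame(
    sample_id = rownames(G), adiponectin = as.numeric(adiponectin),
    homa_ir = as.numeric(homa_ir), hdl = as.numeric(hdl),
    ldl = as.numeric(ldl), total_cholesterol = as.numeric(tc),
    triglycerides = as.numeric(tg), sbp = as.numeric(sbp),
    dbp = as.numeric(dbp), t2d = t2d, hypertension = hypertension,
    glucose = glucose, insulin = insulin,
    age = age, sex = sex, bmi = bmi, alcohol = alcohol,
    smoking_current = smoking_current, smoking_former = smoking_former,
    bp_med = bp_med, glucose_med = glucose_med, lipid_med = lipid_med,
    subpop = geno$subpop, stringsAsFactors = FALSE)

  ## --- case-control ascertainment ---
  rows <- seq_len(n)
  if (!is.na(config$case_fraction)) {
    cf <- config$case_fraction
    cases <- which(t2d == 1); ctrls <- which(t2d == 0)
    target <- min(config$n_samples, n)
    n_case <- round(cf * target); n_ctrl <- target - n_case
    if (length(cases) < n_case) {   # keep all cases, shrink to keep ratio
      n_case <- length(cases)
      n_ctrl <- round(n_case * (1 - cf) / cf)
      if (n_case == 0 || length(ctrls) < n_ctrl)
        stop_data("requested case_fraction unreachable given effect sizes")
    }
    if (length(ctrls) < n_ctrl)
      stop_data("requested case_fraction unreachable given effect sizes")
    rows <- sort(c(sample(cases, n_case), sample(ctrls, n_ctrl)))
    cohort <- cohort[rows, , drop = FALSE]
    rownames(cohort) <- NULL
  }

  true_params <- list(
    variant_beta = b, instrument_idx = inst_idx,
    instrument_snps = variants$snp_id[inst_idx],
    causal_beta = cb,
    confounder_effect_exposure = a_x, confounder_effect_outcome = a_y,
    pleiotropic_snps = variants$snp_id[pleio_idx],
    exposure_scale = TRAIT_SCALE$adiponectin,
    variance_components = c(
      genetic = config$instrument_variance_fraction, confounder = a_x^2,
      bmi = b_bmi_x^2, sex = b_sex_x^2 * stats::var(sex),
      subpop = stats::var(spop_eff), residual = 1 - v_known),
    t2d_intercept = alpha, base_prevalence = base_prev)

  list(cohort = cohort, true_params = true_params, rows = rows)
}

#' Simulate a complete study (genotypes, base GWAS, ascertained cohort)
#'
#' Convenience wrapper that simulates a source population large enough that
#' case-control subsampling returns approximately `n_samples` cohort members
#' at the configured case fraction, then aligns dosages with the retained
#' samples.
#'
#' @param config a [sim_config()].
#' @return list with `dosages`, `variants`, `base_gwas`, `cohort`,
#'   `true_params`, `subpop`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg_pop <- config
  if (!is.na(config$case_fraction)) {
    ## base prevalence 0.25: inflate the source population so that the
    ## requested case share is reachable, with 30% head-room
    infl <- max(config$case_fraction / 0.25,
                (1 - config$case_fraction) / 0.75) * 1.3
    cfg_pop$n_samples <- as.integer(ceiling(config$n_samples * infl))
  }
  geno <- simulate_genotypes(cfg_pop)
  ## phenotype model sees the full source population; the original config's
  ## n_samples is the post-ascertainment target size
  sim <- simulate_cohort(config, geno)
  dos <- geno$dosages[sim$rows, , drop = FALSE]
  base_gwas <- simulate_base_gwas(config, geno$variants,
                                  sim$true_params$variant_beta)
  list(dosages = dos, variants = geno$variants, base_gwas = base_gwas,
       cohort = sim$cohort, true_params = sim$true_params,
       subpop = geno$subpop[sim$rows])
}
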