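test_that("ld_r2 matches the Pearson formula and rejects degenerate input", {
  expect_equal(ld_r2(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0)), 1)
  expect_equal(ld_r2(c(0, 2, 0, 2), c(0, 0, 2, 2)), 0)
  x <- c(0, 1, 2, 1, 0); y <- c(0, 1, 1, 1, 0)
  byhand <- (mean(x * y) - mean(x) * mean(y))^2 /
    ((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
  expect_equal(ld_r2(x, y), byhand, tolerance = 1e-12)
  expect_error(ld_r2(c(1, 1, 1), c(0, 1, 2)), "zero variance")
  expect_error(ld_r2(c(NA, NA, 1), c(0, 1, NA)), "non-missing")
})

test_that("clumping keeps independent SNPs and prefers the smaller p in LD", {
  set.seed(20)
  n <- 400
  ## three variants: v1-v2 perfectly correlated 10 kb apart, v3 independent
  g1 <- rbinom(n, 2, 0.3)
  dos <- cbind(v1 = g1, v2 = g1, v3 = rbinom(n, 2, 0.3))
  st <- data.frame(SNP = c("v1", "v2", "v3"), CHR = 1,
                   BP = c(100000, 110000, 500000),
                   P = c(1e-8, 1e-4, 0.5), stringsAsFactors = FALSE)
  out <- clump(st, dos)
  expect_setequal(out$SNP, c("v1", "v3"))

  ## mutually uncorrelated variants are all retained
  dos2 <- sapply(1:6, function(i) rbinom(n, 2, 0.3))
  colnames(dos2) <- paste0("u", 1:6)
  st2 <- data.frame(SNP = paste0("u", 1:6), CHR = 1, BP = 1:6 * 1e6,
                    P = runif(6), stringsAsFactors = FALSE)
  expect_equal(nrow(clump(st2, dos2)), 6)
  expect_error(clump(st2[0, ], dos2), "empty")
})

test_that("no retained clump pair within the window exceeds the r2 ceiling", {
  set.seed(21)
  cfg <- sim_config(n_samples = 500, n_variants = 80, n_blocks = 8,
                    n_instrument_snps = 8, target_adjacent_r2 = 0.7,
                    n_subpops = 1, seed = 22)
  g <- simulate_genotypes(cfg)
  st <- data.frame(SNP = g$variants$snp_id, CHR = g$variants$chrom,
                   BP = g$variants$pos, P = runif(80),
                   stringsAsFactors = FALSE)
  pr <- clump_params(r2_max = 0.2, window_kb = 100)
  out <- clump(st, g$dosages, pr)
  for (i in seq_len(nrow(out) - 1)) for (j in (i + 1):nrow(out)) {
    if (out$CHR[i] == out$CHR[j] &&
        abs(out$BP[i] - out$BP[j]) <= 100000) {
      expect_lte(ld_r2(g$dosages[, out$SNP[i]], g$dosages[, out$SNP[j]]),
                 0.2 + 1e-9)
    }
  }
})

test_that("scoring is a weighted allele sum with mean imputation", {
  dos <- cbind(v1 = c(0, 1, 2), v2 = c(2, NA, 0))
  w <- data.frame(snp_id = "v1", effect_allele = "A", beta = 0.5)
  v <- data.frame(snp_id = c("v1", "v2"), a1 = c("A", "C"),
                  a2 = c("G", "T"), stringsAsFactors = FALSE)
  expect_equal(prs_score(dos, w, v), c(0, 0.5, 1.0))
  w0 <- data.frame(snp_id = c("v1", "v2"), effect_allele = c("A", "C"),
                   beta = c(0, 0))
  expect_equal(prs_score(dos, w0, v), c(0, 0, 0))
  ## missing dosage imputed at twice the non-missing effect-allele frequency
  w2 <- data.frame(snp_id = "v2", effect_allele = "C", beta = 1)
  expect_equal(prs_score(dos, w2, v), c(2, 1, 0))
  expect_error(prs_score(dos, data.frame(snp_id = "zz", effect_allele = "A",
                                         beta = 1), v), "absent")
})

test_that("allele recoding leaves scores shifted by a constant and fits unchanged", {
  set.seed(23)
  cfg <- quick_config(n = 400, m = 40, blocks = 20, seed = 24)
  st <- make_study(cfg)
  w <- data.frame(snp_id = st$true$instrument_snps,
                  effect_allele = st$variants$a1[st$true$instrument_idx],
                  beta = st$true$variant_beta[st$true$instrument_idx])
  s1 <- prs_score(st$dosages, w, st$variants)
  ## recode every variant: effect allele -> a2, beta -> -beta
  w2 <- w
  w2$effect_allele <- st$variants$a2[st$true$instrument_idx]
  w2$beta <- -w$beta
  s2 <- prs_score(st$dosages, w2, st$variants)
  expect_equal(s2 - s1, rep(2 * sum(w2$beta), length(s1)), tolerance = 1e-12)
  expect_equal(cor(s1, st$x), cor(s2, st$x), tolerance = 1e-12)
  f1 <- lm(st$x ~ s1 + st$covs); f2 <- lm(st$x ~ s2 + st$covs)
  expect_equal(unname(coef(f1)[2]), unname(coef(f2)[2]), tolerance = 1e-12)
  expect_equal(fitted(f1), fitted(f2), tolerance = 1e-12)
})

test_that("threshold optimization selects planted signal and honors ties", {
  set.seed(25)
  n <- 1500; m <- 120
  dos <- sapply(runif(m, 0.2, 0.5), function(p) rbinom(n, 2, p))
  colnames(dos) <- paste0("v", 1:m)
  ## signal: SNPs with base p < 1e-4 truly drive the exposure
  p_base <- c(runif(15, 1e-8, 1e-4), runif(m - 15, 0.2, 1))
  beta <- c(rep(0.12, 15), rep(0, m - 15))
  expo <- as.vector(scale(dos %*% beta + rnorm(n)))
  st <- data.frame(SNP = colnames(dos), CHR = 1, BP = 1:m * 1e6,
                   A1 = "A", BETA = beta + rnorm(m, 0, 0.01), P = p_base,
                   stringsAsFactors = FALSE)
  grid <- c(1e-6, 1e-4, 1e-2, 1)
  mod <- optimize_threshold(st, dos, expo, covariates = NULL, grid = grid)
  expect_true(mod$threshold %in% c(1e-4, 1e-2))
  expect_equal(mod$n_snps, sum(p_base <= mod$threshold))
  expect_true(all(mod$weights$p <= mod$threshold))
  expect_gt(mod$fit_r2, 0.05)

  single <- optimize_threshold(st, dos, expo, grid = 0.5)
  expect_equal(single$threshold, 0.5)
  expect_error(optimize_threshold(st, dos, expo, grid = numeric(0)),
               "empty")
})

test_that("incremental fit is invariant to affine rescaling of the score", {
  set.seed(26)
  n <- 300
  dos <- cbind(v1 = rbinom(n, 2, 0.3))
  expo <- 0.3 * dos[, 1] + rnorm(n)
  covs <- cbind(age = rnorm(n))
  st1 <- data.frame(SNP = "v1", CHR = 1, BP = 1, A1 = "A", BETA = 0.3,
                    P = 1e-5, stringsAsFactors = FALSE)
  st2 <- st1; st2$BETA <- 30
  m1 <- optimize_threshold(st1, dos, expo, covs, grid = 1)
  m2 <- optimize_threshold(st2, dos, expo, covs, grid = 1)
  expect_gte(m1$fit_r2, 0)
  expect_equal(m1$fit_r2, m2$fit_r2, tolerance = 1e-12)
})

test_that("null exposures yield negligible incremental fit", {
  set.seed(27)
  best <- replicate(10, {
    n <- 800; m <- 200
    dos <- sapply(runif(m, 0.2, 0.5), function(p) rbinom(n, 2, p))
    colnames(dos) <- paste0("v", 1:m)
    st <- data.frame(SNP = colnames(dos), CHR = 1, BP = 1:m * 1e6,
                     A1 = "A", BETA = rnorm(m, 0, 0.05), P = runif(m),
                     stringsAsFactors = FALSE)
    optimize_threshold(st, dos, rnorm(n),
                       grid = c(1e-4, 1e-2, 0.1, 1))$fit_r2
  })
  expect_lt(mean(best), 0.01)
})

test_that("empirical p respects its bounds and detects strong signal", {
  set.seed(28)
  n <- 400; m <- 30
  dos <- sapply(runif(m, 0.2, 0.5), function(p) rbinom(n, 2, p))
  colnames(dos) <- paste0("v", 1:m)
  beta <- rnorm(m, 0, 0.2)
  expo <- as.vector(scale(dos %*% beta + rnorm(n, 0, 0.5)))
  st <- data.frame(SNP = colnames(dos), CHR = 1, BP = 1:m * 1e6, A1 = "A",
                   BETA = beta, P = runif(m, 0, 1e-4),
                   stringsAsFactors = FALSE)
  mod <- empirical_pvalue(st, dos, expo, grid = c(1e-4, 1), n_perm = 199,
                          seed = 3)
  expect_equal(mod$empirical_p, 1 / 200)
  expect_gte(mod$empirical_p, 1 / (199 + 1))
  expect_lte(mod$empirical_p, 1)
  expect_error(empirical_pvalue(st, dos, expo, n_perm = 0), "n_perm")
})

test_that("gene-region SNP counting uses inclusive flanked boundaries", {
  v <- data.frame(snp_id = c("a", "b", "c", "d"), chrom = c(3, 3, 3, 4),
                  pos = c(750000, 749999, 2000000, 1000000))
  model <- list(weights = data.frame(SNP = c("a", "b", "c", "d")))
  ## region 1,000,000-1,500,000 with 250 kb flank: [750,000, 1,750,000]
  expect_equal(count_snps_near_gene(model, v, chrom = 3, start = 1e6,
                                    end = 1.5e6), 1)
  model2 <- list(weights = data.frame(SNP = "d"))
  expect_equal(count_snps_near_gene(model2, v, chrom = 3, start = 1e6,
                                    end = 1.5e6), 0)
  ## brute-force interval scan on random SNPs
  set.seed(29)
  v2 <- data.frame(snp_id = sprintf("s%03d", 1:500),
                   chrom = sample(1:5, 500, TRUE),
                   pos = sample.int(5e6, 500))
  m2 <- list(weights = data.frame(SNP = v2$snp_id))
  oracle <- sum(v2$chrom == 2 & v2$pos >= 2e6 - 250000 &
                  v2$pos <= 3e6 + 250000)
  expect_equal(count_snps_near_gene(m2, v2, 2, 2e6, 3e6), oracle)
  expect_error(count_snps_near_gene(m2, v2, 2, 3e6, 2e6), "start exceeds")
})
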