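base_rec <- function(snp, a1, a2, beta = 0.1, eaf = 0.3, p = 1e-5) {
  data.frame(SNP = snp, CHR = 1, BP = seq_along(snp) * 1000, A1 = a1,
             A2 = a2, EAF = eaf, BETA = beta, SE = 0.02, P = p,
             stringsAsFactors = FALSE)
}
target_rec <- function(snp, a1, a2) {
  data.frame(snp_id = snp, chrom = 1, pos = seq_along(snp) * 1000,
             a1 = a1, a2 = a2, stringsAsFactors = FALSE)
}

test_that("harmonization classifies identity, strand flip, swap and ambiguity", {
  base <- base_rec(c("s1", "s2", "s3", "s4", "s5"),
                   c("A", "A", "A", "A", "A"),
                   c("G", "G", "T", "G", "G"),
                   beta = c(0.1, 0.2, 0.3, 0.4, 0.5))
  target <- target_rec(c("s1", "s2", "s3", "s4", "s5"),
                       c("A", "T", "A", "G", "A"),
                       c("G", "C", "T", "A", "C"))
  hz <- harmonize_variants(base, target)
  r <- hz$report
  expect_equal(r$n_matched, 2)            # s1 identity, s4 allele swap
  expect_equal(r$n_flipped, 1)            # s2 via strand complement
  expect_equal(r$n_dropped_ambiguous, 1)  # s3 is A/T palindromic
  expect_equal(r$n_dropped_mismatch, 1)   # s5 A/G vs A/C unresolvable
  h <- hz$harmonized
  expect_equal(h$BETA[h$SNP == "s1"], 0.1)
  expect_equal(h$BETA[h$SNP == "s2"], 0.2)         # flip keeps alignment
  expect_equal(h$BETA[h$SNP == "s4"], -0.4)        # effect moved to a2
  expect_equal(h$EAF[h$SNP == "s4"], 0.7)
})

test_that("harmonization drops duplicated ids and its counts conserve", {
  base <- base_rec(c("d1", "d1", "s2"), c("A", "A", "C"),
                   c("G", "G", "T"))
  target <- target_rec(c("d1", "s2"), c("A", "C"), c("G", "T"))
  hz <- harmonize_variants(base, target)
  expect_equal(hz$report$n_dropped_duplicate, 1)
  expect_equal(hz$report$n_matched, 1)
  with(hz$report,
       expect_equal(n_matched + n_flipped + n_dropped_ambiguous +
                      n_dropped_duplicate + n_dropped_mismatch, n_shared))
  expect_error(harmonize_variants(base_rec("a", "A", "G"),
                                  target_rec("b", "A", "G")),
               "no shared")
})

test_that("strand flipping is involutive and the sign rule is exact", {
  set.seed(2)
  nt <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:30) {
    a1 <- sample(nt, 1); a2 <- sample(setdiff(nt, c(a1, comp[[a1]])), 1)
    beta <- rnorm(1)
    base <- base_rec("v", a1, a2, beta = beta)
    ## double complement returns the original classification
    t0 <- target_rec("v", a1, a2)
    t2 <- target_rec("v", comp[[comp[[a1]]]], comp[[comp[[a2]]]])
    expect_identical(harmonize_variants(base, t0)$harmonized$BETA,
                     harmonize_variants(base, t2)$harmonized$BETA)
    ## effect allele aligned to target a2 flips the sign, exactly once
    tswap <- target_rec("v", a2, a1)
    expect_equal(harmonize_variants(base, tswap)$harmonized$BETA, -beta)
  }
})

test_that("variant filters respect thresholds, boundaries, and idempotence", {
  set.seed(3)
  n <- 400
  dos <- sapply(rep(0.3, 8), function(p) rbinom(n, 2, p))
  colnames(dos) <- paste0("v", 1:8)
  v <- data.frame(snp_id = paste0("v", 1:8),
                  info = c(0.79, 0.80, rep(0.95, 6)),
                  stringsAsFactors = FALSE)
  ## plant failures: v3 low MAF, v4 high missingness
  dos[, 3] <- rbinom(n, 2, 0.004)
  dos[, 4][sample(n, 10)] <- NA
  fv <- filter_variants(dos, v, qc_thresholds())
  expect_false("v1" %in% fv$variants$snp_id)  # info 0.79 removed
  expect_true("v2" %in% fv$variants$snp_id)   # info 0.80 kept (boundary)
  expect_false("v3" %in% fv$variants$snp_id)  # maf < 0.01
  expect_false("v4" %in% fv$variants$snp_id)  # missingness 2.5%
  expect_equal(fv$report$n_input,
               fv$report$n_surviving + sum(unlist(fv$report$removed)))

  ## idempotence: re-filtering the survivors removes nothing
  fv2 <- filter_variants(fv$dosages, fv$variants, qc_thresholds())
  expect_equal(fv2$report$n_surviving, fv$report$n_surviving)
  expect_identical(fv2$variants$snp_id, fv$variants$snp_id)
})

test_that("sample QC computes the inbreeding coefficient and applies filters", {
  set.seed(4)
  n <- 2000; m <- 400
  p <- runif(m, 0.1, 0.5)
  dos <- sapply(p, function(pp) rbinom(n, 2, pp))
  rownames(dos) <- sprintf("S%04d", 1:n)
  ## fully homozygous sample
  dos[1, ] <- ifelse(runif(m) < p, 2, 0)
  ## sample with 2% missingness
  dos[2, sample(m, 8)] <- NA
  sq <- sample_qc(dos, qc_thresholds())
  expect_equal(sq$metrics$het_f[1], 1, tolerance = 1e-9)
  expect_true("S0002" %in%
                sq$removed$sample_id[sq$removed$reason == "missingness"])
  ## a Hardy-Weinberg cohort centres F at zero
  expect_lt(abs(mean(sq$metrics$het_f[-(1:2)])), 0.01)
  expect_error(sample_qc(dos[1, , drop = FALSE]), "at least 2")
})

test_that("kinship flags duplicates and parent-offspring pairs, spares unrelated", {
  set.seed(5)
  n <- 40; m <- 1500
  p <- runif(m, 0.1, 0.5)
  dos <- sapply(p, function(pp) rbinom(n, 2, pp))
  dos[2, ] <- dos[1, ]                       # duplicate pair (1,2)
  ## parent-offspring: one transmitted allele + one population allele
  transmitted <- rbinom(m, 1, dos[3, ] / 2)
  dos[4, ] <- transmitted + rbinom(m, 1, p)
  rownames(dos) <- sprintf("S%02d", 1:n)
  rel <- remove_related(dos, qc_thresholds())
  dup <- rel$kinship[(rel$kinship$id1 == "S01" & rel$kinship$id2 == "S02") |
                       (rel$kinship$id1 == "S02" & rel$kinship$id2 == "S01"), ]
  expect_equal(nrow(dup), 1)
  expect_equal(dup$kinship, 0.5, tolerance = 0.02)
  po <- rel$kinship[(rel$kinship$id1 == "S03" & rel$kinship$id2 == "S04") |
                      (rel$kinship$id1 == "S04" & rel$kinship$id2 == "S03"), ]
  expect_equal(nrow(po), 1)
  expect_gte(po$kinship, 0.17)
  expect_lte(po$kinship, 0.30)
  ## one member of each flagged pair is removed, and no flagged pair survives
  expect_equal(sum(c("S01", "S02") %in% rel$removed), 1)
  expect_equal(sum(c("S03", "S04") %in% rel$removed), 1)
  kept <- rownames(dos)[rel$keep]
  expect_false(any(rel$kinship$id1 %in% kept & rel$kinship$id2 %in% kept))
  expect_error(remove_related(dos[, 1:100]), "too few variants")
})

test_that("no unrelated pair is flagged at the second-degree cutoff", {
  set.seed(6)
  n <- 500; m <- 2000
  p <- runif(m, 0.1, 0.5)
  dos <- sapply(p, function(pp) rbinom(n, 2, pp))
  rownames(dos) <- sprintf("S%03d", 1:n)
  rel <- remove_related(dos, qc_thresholds())
  expect_equal(length(rel$removed), 0)
})

test_that("principal components are orthogonal, ordered, and separate structure", {
  cfg <- sim_config(n_samples = 600, n_variants = 400, n_blocks = 200,
                    n_instrument_snps = 10, n_subpops = 2, fst = 0.05,
                    missing_rate = 0.01, seed = 8)
  g <- simulate_genotypes(cfg)
  pc <- compute_pcs(g$dosages, 4)
  gram <- crossprod(pc$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-6 * max(diag(gram)))
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  ## sign threshold on PC1 recovers the subpopulation labels
  lab <- pc$scores[, 1] > 0
  acc <- max(mean(lab == (g$subpop == 1)), mean(lab == (g$subpop == 2)))
  expect_gte(acc, 0.95)
  expect_error(compute_pcs(g$dosages[1:5, ], 10), "rank")
})
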