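## Variant- and sample-level quality control and base/target harmonization.
## Filter order: marker missingness -> MAF -> HWE -> INFO -> sample
## missingness -> heterozygosity -> relatedness (marker metrics are needed
## before sample metrics; reported in the QC report).

#' Default QC thresholds
#'
#' @param maf_min minimum minor allele frequency (variants with MAF < 0.01
#'   removed).
#' @param marker_missing_max maximum per-marker missingness (> 0.01 removed).
#' @param sample_missing_max maximum per-sample missingness (> 0.01 removed).
#' @param hwe_p_min Hardy-Weinberg exact-test floor (p < 1e-6 removed).
#' @param info_min minimum imputation INFO score (< 0.8 removed).
#' @param het_sd heterozygosity-F outlier bound in SD units (default 3).
#' @param kinship_second_degree kinship cutoff above which a pair is a
#'   second-degree or closer relative (default 0.0884 = 2^-3.5).
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, marker_missing_max = 0.01,
                          sample_missing_max = 0.01, hwe_p_min = 1e-6,
                          info_min = 0.8, het_sd = 3,
                          kinship_second_degree = 0.0884) {
  th <- list(maf_min = maf_min, marker_missing_max = marker_missing_max,
             sample_missing_max = sample_missing_max, hwe_p_min = hwe_p_min,
             info_min = info_min, het_sd = het_sd,
             kinship_second_degree = kinship_second_degree)
  if (any(unlist(th) <= 0)) stop_config("all QC thresholds must be positive")
  for (nm in c("maf_min", "marker_missing_max", "sample_missing_max",
               "info_min"))
    if (th[[nm]] > 1) stop_config(nm, " must be in (0, 1]")
  structure(th, class = "qc_thresholds")
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Harmonize base GWAS records with target variants
#'
#' Shared variant ids are classified: duplicated ids (in either set) are
#' dropped entirely; palindromic (A/T, C/G) variants are dropped as
#' strand-ambiguous; exact allele matches are kept; matches after
#' complementing both target alleles are kept with the strand flip recorded;
#' anything else is dropped as a mismatch. When the base effect allele
#' aligns to the target's a2 allele, the effect is re-expressed on the
#' target a1 allele (beta sign flipped, EAF complemented).
#'
#' @param base data.frame of base GWAS records (columns SNP, A1, A2, EAF,
#'   BETA, SE, P, and optionally N, INFO, CHR, BP).
#' @param target data.frame of target variants (snp_id, a1, a2, and
#'   optionally chrom, pos).
#' @return list with `harmonized` (base records with BETA/EAF expressed on
#'   the target a1 allele, plus target chrom/pos) and `report` (counts:
#'   n_matched, n_flipped, n_dropped_ambiguous, n_dropped_duplicate,
#'   n_dropped_mismatch; they sum to the number of shared ids).
#' @export
harmonize_variants <- function(base, target) {
  shared <- intersect(base$SNP, target$snp_id)
  if (length(shared) == 0) stop_data("no shared variant ids to harmonize")
  dup_ids <- union(base$SNP[duplicated(base$SNP)],
                   target$snp_id[duplicated(target$snp_id)])
  dup_ids <- intersect(dup_ids, shared)
  keep_ids <- setdiff(shared, dup_ids)

  b <- base[match(keep_ids, base$SNP), , drop = FALSE]
  t <- target[match(keep_ids, target$snp_id), , drop = FALSE]
  b_a1 <- toupper(b$A1); b_a2 <- toupper(b$A2)
  t_a1 <- toupper(t$a1); t_a2 <- toupper(t$a2)

  ambig <- is_palindromic(b_a1, b_a2) | is_palindromic(t_a1, t_a2)
  exact <- !ambig & b_a1 == t_a1 & b_a2 == t_a2
  swap <- !ambig & b_a1 == t_a2 & b_a2 == t_a1
  flip <- !ambig & !exact & !swap &
    COMPLEMENT[t_a1] == b_a1 & COMPLEMENT[t_a2] == b_a2
  flip_swap <- !ambig & !exact & !swap & !flip &
    COMPLEMENT[t_a1] == b_a2 & COMPLEMENT[t_a2] == b_a1
  kept <- exact | swap | flip | flip_swap
  mism <- !ambig & !kept

  h <- b[kept, , drop = FALSE]
  tk <- t[kept, , drop = FALSE]
  sw <- (swap | flip_swap)[kept]
  h$BETA <- ifelse(sw, -h$BETA, h$BETA)
  if ("EAF" %in% names(h)) h$EAF <- ifelse(sw, 1 - h$EAF, h$EAF)
  h$A1 <- tk$a1; h$A2 <- tk$a2
  h$strand_flipped <- (flip | flip_swap)[kept]
  if ("chrom" %in% names(tk)) h$CHR <- tk$chrom
  if ("pos" %in% names(tk)) h$BP <- tk$pos
  o <- order(h$CHR %||% h$SNP, h$BP %||% seq_len(nrow(h)))
  h <- h[o, , drop = FALSE]
  rownames(h) <- NULL

  report <- list(n_matched = sum(exact | swap),
                 n_flipped = sum(flip | flip_swap),
                 n_dropped_ambiguous = sum(ambig),
                 n_dropped_duplicate = length(dup_ids),
                 n_dropped_mismatch = sum(mism),
                 n_shared = length(shared))
  stopifnot(report$n_matched + report$n_flipped + report$n_dropped_ambiguous +
              report$n_dropped_duplicate + report$n_dropped_mismatch ==
              report$n_shared)
  list(harmonized = h, report = report)
}

variant_metrics <- function(dosages) {
  n <- nrow(dosages)
  nm <- colSums(!is.na(dosages))
  af <- colMeans(dosages, na.rm = TRUE) / 2
  list(call_rate = nm / n, maf = pmin(af, 1 - af),
       n_hom1 = colSums(dosages == 2, na.rm = TRUE),
       n_het = colSums(dosages == 1, na.rm = TRUE),
       n_hom2 = colSums(dosages == 0, na.rm = TRUE))
}

#' Variant-level QC filters
#'
#' Applies, in order: marker missingness, minor allele frequency,
#' Hardy-Weinberg exact test, and imputation INFO. Metrics absent from
#' `variants` are computed from the dosages. Boundary values are retained
#' (e.g. INFO = 0.8 passes the "< 0.8 removed" rule).
#'
#' @param dosages samples x variants dosage matrix.
#' @param variants variant data.frame (snp_id; optional maf, call_rate,
#'   hwe_p, info).
#' @param th a [qc_thresholds()].
#' @return list with `variants` (retained rows), `dosages` (matching
#'   columns), and `report` (per-filter removal counts and survivors).
#' @export
filter_variants <- function(dosages, variants, th = qc_thresholds()) {
  stopifnot(inherits(th, "qc_thresholds"),
            ncol(dosages) == nrow(variants))
  met <- variant_metrics(dosages)
  call_rate <- variants$call_rate %||% met$call_rate
  maf <- variants$maf_observed %||% met$maf
  hwe_p <- variants$hwe_p
  if (is.null(hwe_p))
    hwe_p <- mapply(hwe_exact_test, met$n_hom1, met$n_het, met$n_hom2)
  info <- variants$info %||% rep(1, nrow(variants))

  keep <- rep(TRUE, nrow(variants))
  removed <- c(marker_missingness = 0L, maf = 0L, hwe = 0L, info = 0L)
  step <- function(cond, name) {
    drop <- keep & cond
    removed[name] <<- sum(drop)
    keep[drop] <<- FALSE
  }
  step(1 - call_rate > th$marker_missing_max, "marker_missingness")
  step(maf < th$maf_min, "maf")
  step(hwe_p < th$hwe_p_min, "hwe")
  step(info < th$info_min, "info")

  report <- list(n_input = nrow(variants), removed = as.list(removed),
                 n_surviving = sum(keep),
                 filter_order = names(removed))
  stopifnot(report$n_input == report$n_surviving + sum(removed))
  vk <- variants[keep, , drop = FALSE]
  vk$maf_observed <- maf[keep]
  vk$call_rate <- call_rate[keep]
  vk$hwe_p <- hwe_p[keep]
  rownames(vk) <- NULL
  list(variants = vk, dosages = dosages[, keep, drop = FALSE],
       report = report)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the sum of the probabilities of all heterozygote counts whose conditional
#' probability does not exceed the observed one. Probabilities are built by
#' the standard recurrence over heterozygote counts.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (hom a1 / het / hom a2).
#' @return exact-test p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  if (any(c(n_hom1, n_het, n_hom2) < 0)) stop_data("negative genotype count")
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) stop_data("all genotype counts are zero")
  n1 <- 2 * n_hom1 + n_het          # copies of allele 1
  rare <- min(n1, 2 * n - n1)
  if (rare == 0) return(1)
  ## admissible het counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  mid <- which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))
  probs[mid] <- 1
  ## upward recurrence: P(h+2)/P(h) = 4*hom1(h)*hom2(h) / ((h+2)*(h+1))
  if (mid < length(hets)) for (i in mid:(length(hets) - 1)) {
    h <- hets[i]
    hom_r <- (rare - h) / 2; hom_c <- n - h - hom_r
    probs[i + 1] <- probs[i] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
  }
  if (mid > 1) for (i in mid:2) {
    h <- hets[i]
    hom_r <- (rare - h) / 2; hom_c <- n - h - hom_r
    probs[i - 1] <- probs[i] * h * (h - 1) /
      (4 * (hom_r + 1) * (hom_c + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs)) stop_data("heterozygote count inconsistent with alleles")
  ## relative tolerance guards exact ties against floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Sample-level QC: missingness and heterozygosity F
#'
#' Computes per-sample call rate and the inbreeding coefficient
#' `F = (O_hom - E_hom) / (m - E_hom)` with `E_hom = sum_j (1 - 2 p_j q_j)`
#' over the sample's non-missing variants, then removes samples with
#' missingness above the threshold or |F - mean(F)| beyond `het_sd` SDs.
#'
#' @param dosages samples x variants dosage matrix.
#' @param th a [qc_thresholds()].
#' @return list with `metrics` (sample_id, call_rate, het_f), `removed`
#'   (ids with reasons), and `keep` (logical vector).
#' @export
sample_qc <- function(dosages, th = qc_thresholds()) {
  if (nrow(dosages) < 2) stop_data("sample QC needs at least 2 samples")
  m <- ncol(dosages)
  obs <- !is.na(dosages)
  usable <- rowSums(obs)
  if (any(usable == 0)) stop_data("sample with zero usable variants")
  af <- colMeans(dosages, na.rm = TRUE) / 2
  exp_hom_j <- 1 - 2 * af * (1 - af)     # per-variant expected hom share
  o_hom <- rowSums(dosages != 1 & obs, na.rm = TRUE)
  e_hom <- as.vector(obs %*% exp_hom_j)
  het_f <- (o_hom - e_hom) / (usable - e_hom)
  call_rate <- usable / m

  miss_fail <- 1 - call_rate > th$sample_missing_max
  mu <- mean(het_f); sdv <- stats::sd(het_f)
  het_fail <- if (sdv > 0) abs(het_f - mu) > th$het_sd * sdv else
    rep(FALSE, length(het_f))
  ids <- rownames(dosages) %||% as.character(seq_len(nrow(dosages)))
  metrics <- data.frame(sample_id = ids, call_rate = call_rate,
                        het_f = het_f, stringsAsFactors = FALSE)
  removed <- data.frame(
    sample_id = ids[miss_fail | het_fail],
    reason = ifelse(miss_fail[miss_fail | het_fail], "missingness",
                    "heterozygosity"),
    stringsAsFactors = FALSE)
  list(metrics = metrics, removed = removed, keep = !(miss_fail | het_fail))
}

#' Pairwise kinship and relatedness pruning
#'
#' Kinship is the robust identity-by-state moment estimator
#' `phi = (N_het,het - 2 N_opposite_hom) / (N_het,i + N_het,j)` over
#' variants observed in both samples (0.5 for duplicates, ~0.25 for
#' parent-offspring, ~0 for unrelated pairs). Pairs above the
#' second-degree cutoff are resolved greedily: remove the member with more
#' flagged pairs, ties broken by lower call rate then id.
#'
#' @param dosages samples x variants dosage matrix (>= 200 variants).
#' @param th a [qc_thresholds()].
#' @param max_variants kinship is computed on at most this many variants
#'   (evenly thinned) to bound cost on dense panels.
#' @return list with `kinship` (data.frame id1, id2, kinship for flagged
#'   pairs), `keep` (logical), `removed` (ids).
#' @export
remove_related <- function(dosages, th = qc_thresholds(),
                           max_variants = 5000L) {
  n <- nrow(dosages)
  if (n < 2) stop_data("relatedness pruning needs at least 2 samples")
  if (ncol(dosages) < 200)
    stop_data("too few variants (< 200) for stable kinship estimates")
  if (ncol(dosages) > max_variants) {
    keep_j <- round(seq(1, ncol(dosages), length.out = max_variants))
    dosages <- dosages[, keep_j, drop = FALSE]
  }
  obs <- !is.na(dosages)
  H <- (dosages == 1) & obs;  H[!obs] <- FALSE
  A0 <- (dosages == 0) & obs; A0[!obs] <- FALSE
  A2 <- (dosages == 2) & obs; A2[!obs] <- FALSE
  storage.mode(H) <- "double"; storage.mode(A0) <- "double"
  storage.mode(A2) <- "double"; storage.mode(obs) <- "double"
  N11 <- tcrossprod(H)
  N02 <- tcrossprod(A0, A2); N02 <- N02 + t(N02)
  Hi <- H %*% t(obs)                  # het count of i over sites seen in j
  denom <- Hi + t(Hi)
  phi <- (N11 - 2 * N02) / pmax(denom, 1)
  diag(phi) <- 0

  flagged <- which(phi > th$kinship_second_degree & upper.tri(phi),
                   arr.ind = TRUE)
  ids <- rownames(dosages) %||% as.character(seq_len(n))
  kin <- data.frame(id1 = ids[flagged[, 1]], id2 = ids[flagged[, 2]],
                    kinship = phi[flagged], stringsAsFactors = FALSE)
  keep <- rep(TRUE, n)
  if (nrow(flagged) > 0) {
    adj <- phi > th$kinship_second_degree
    call_rate <- rowMeans(obs)
    repeat {
      deg <- rowSums(adj & outer(keep, keep, "&"))
      deg[!keep] <- -1
      if (max(deg) <= 0) break
      cand <- which(deg == max(deg))
      cand <- cand[order(call_rate[cand], ids[cand])]  # low call rate first
      keep[cand[1]] <- FALSE
    }
  }
  list(kinship = kin, keep = keep, removed = ids[!keep])
}

#' Genetic principal components
#'
#' PCs of the column-standardized dosage matrix; missing dosages are
#' mean-imputed for this computation only. Components are ordered by
#' decreasing variance explained and the score vectors are orthogonal.
#'
#' @param dosages samples x variants dosage matrix.
#' @param k number of components (default 3).
#' @return list with `scores` (n x k matrix, columns PC1..PCk),
#'   `var_explained` (length-k fractions).
#' @export
compute_pcs <- function(dosages, k = 3L) {
  if (k < 1) stop_data("k must be >= 1")
  X <- dosages
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  sdv <- apply(X, 2, stats::sd)
  X <- X[, sdv > 0, drop = FALSE]
  X <- scale(X)
  if (k > min(dim(X)) - 1) stop_data("k exceeds the rank of the dosage matrix")
  ## eigen of the n x n cross-product is cheaper than svd for wide panels
  K <- tcrossprod(X) / (ncol(X) - 1)
  ev <- eigen(K, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  scores <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)] * (nrow(X) - 1)), k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(dosages)
  list(scores = scores, var_explained = vals[seq_len(k)] / sum(vals))
}
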