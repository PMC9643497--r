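## Instrument construction: clumping + thresholding (C+T). Greedy LD
## clumping against the target panel, weighted allele scoring, p-value
## threshold selection by incremental model fit over a covariate-only
## baseline, and a permutation-based empirical p-value for the selected fit.

#' Clumping parameters
#'
#' @param p_index_max p-value ceiling for index SNPs (default 1).
#' @param r2_max LD threshold above which neighbours are clumped away
#'   (default 0.1).
#' @param window_kb physical window around each index SNP (default 250).
#' @return object of class `clump_params`.
#' @export
clump_params <- function(p_index_max = 1, r2_max = 0.1, window_kb = 250) {
  if (r2_max < 0 || r2_max >= 1) stop_config("r2_max must be in [0, 1)")
  if (window_kb <= 0) stop_config("window_kb must be positive")
  structure(list(p_index_max = p_index_max, r2_max = r2_max,
                 window_kb = window_kb), class = "clump_params")
}

#' Squared LD correlation between two dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete entries.
#'
#' @param dosage_i,dosage_j equal-length dosage vectors.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(dosage_i, dosage_j) {
  stopifnot(length(dosage_i) == length(dosage_j))
  ok <- !is.na(dosage_i) & !is.na(dosage_j)
  if (sum(ok) < 2) stop_data("fewer than 2 non-missing shared entries")
  x <- dosage_i[ok]; y <- dosage_j[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_data("zero variance in a dosage vector")
  stats::cor(x, y)^2
}

#' Greedy LD clumping
#'
#' Processes variants by ascending p-value (ties: ascending position, then
#' id). Each index SNP removes all not-yet-processed SNPs on the same
#' chromosome within `window_kb` whose squared correlation with it exceeds
#' `r2_max` in the LD panel.
#'
#' @param stats harmonized summary statistics (columns SNP, CHR, BP, P).
#' @param dosages LD panel dosage matrix with columns covering `stats$SNP`.
#' @param params a [clump_params()].
#' @return the retained index-SNP rows of `stats`, sorted by chromosome and
#'   position.
#' @export
clump <- function(stats, dosages, params = clump_params()) {
  if (nrow(stats) == 0) stop_data("empty summary statistics")
  stats <- stats[stats$P <= params$p_index_max, , drop = FALSE]
  if (nrow(stats) == 0) stop_data("no variant passes p_index_max")
  missing <- setdiff(stats$SNP, colnames(dosages))
  if (length(missing)) stop_data("LD panel lacks variants: ",
                                 paste(utils::head(missing, 5), collapse = ", "))
  o <- order(stats$P, stats$BP, stats$SNP)
  st <- stats[o, , drop = FALSE]
  win <- params$window_kb * 1000
  alive <- rep(TRUE, nrow(st))    # not yet clumped away
  index <- logical(nrow(st))
  for (i in seq_len(nrow(st))) {
    if (!alive[i]) next
    index[i] <- TRUE
    cand <- which(alive & !index & st$CHR == st$CHR[i] &
                    abs(st$BP - st$BP[i]) <= win)
    if (length(cand)) {
      gi <- dosages[, st$SNP[i]]
      r2 <- suppressWarnings(
        stats::cor(gi, dosages[, st$SNP[cand], drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0
      alive[cand[r2 > params$r2_max]] <- FALSE
    }
  }
  out <- st[index, , drop = FALSE]
  out <- out[order(out$CHR, out$BP), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted allele score
#'
#' `score_i = sum_j beta_j * dose_ij` with each missing dosage replaced by
#' twice the effect-allele frequency among non-missing samples. Weights may
#' name either target allele as the effect allele; dosages (a1 counts) are
#' recoded to `2 - d` when the effect allele is a2.
#'
#' @param dosages samples x variants dosage matrix (a1-allele counts).
#' @param weights data.frame with snp_id (or SNP), effect_allele (or A1),
#'   beta (or BETA).
#' @param variants optional variant data.frame (snp_id, a1, a2) for allele
#'   alignment; if omitted the effect allele is assumed to be a1.
#' @return numeric per-sample score vector.
#' @export
prs_score <- function(dosages, weights, variants = NULL) {
  ids <- weights$snp_id %||% weights$SNP
  eff <- weights$effect_allele %||% weights$A1
  beta <- weights$beta %||% weights$BETA
  absent <- setdiff(ids, colnames(dosages))
  if (length(absent)) stop_data("weights reference variants absent from ",
                                "dosages: ",
                                paste(utils::head(absent, 5), collapse = ", "))
  D <- dosages[, ids, drop = FALSE]
  if (!is.null(variants)) {
    v <- variants[match(ids, variants$snp_id), , drop = FALSE]
    bad <- !(eff == v$a1 | eff == v$a2)
    if (any(bad)) stop_data("effect allele matches neither target allele ",
                            "for ", paste(ids[bad][1:min(5, sum(bad))],
                                          collapse = ", "))
    rec <- eff == v$a2
    if (any(rec)) D[, rec] <- 2 - D[, rec, drop = FALSE]
  }
  eafs <- colMeans(D, na.rm = TRUE) / 2
  for (j in which(colSums(is.na(D)) > 0))
    D[is.na(D[, j]), j] <- 2 * eafs[j]
  as.vector(D %*% beta)
}

## Residualize columns of Y on the covariate design [1, C] via a QR kept by
## the caller; returns residuals.
.resid_qr <- function(qrC, Y) Y - qr.fitted(qrC, Y)

## Incremental R^2 machinery shared by optimization and permutation: with
## covariate-residualized score s and exposure y, the R^2 gain of adding s
## equals cor(s, y_resid)^2 * var(y_resid) / var(y).
.threshold_scores <- function(stats, dosages, grid, variants = NULL) {
  scores <- sapply(grid, function(thr) {
    w <- stats[stats$P <= thr, , drop = FALSE]
    if (nrow(w) == 0) return(rep(NA_real_, nrow(dosages)))
    prs_score(dosages, w, variants)
  })
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = length(grid))
  colnames(scores) <- as.character(grid)
  scores
}

DEFAULT_GRID <- c(5e-8, 1e-6, 1e-5, 1e-4, 5e-4, 1e-3, 0.01, 0.05, 0.1,
                  0.5, 1)

#' Optimize the p-value threshold of a C+T score
#'
#' For each threshold in the grid, builds the score from the clumped SNPs
#' with p at or below the threshold, fits
#' `exposure ~ score + covariates`, and records the incremental R-squared
#' over the covariate-only fit. Returns the threshold with the best fit
#' (ties: the smaller threshold). Thresholds retaining no SNP are skipped.
#'
#' @param stats harmonized summary statistics restricted to clumped index
#'   SNPs (columns SNP, A1, BETA, P).
#' @param dosages target dosage matrix.
#' @param exposure numeric exposure vector (standardized log scale).
#' @param covariates data.frame or matrix of covariates (age, sex, PCs...);
#'   NULL for a crude fit.
#' @param grid numeric vector of candidate thresholds.
#' @param variants optional variant table for allele alignment in scoring.
#' @return object of class `prs_model`: threshold, weights (data.frame SNP,
#'   effect_allele, beta, p), n_snps, fit_r2 (incremental R-squared),
#'   score (per-sample), grid_fit (per-threshold table), empirical_p (NA
#'   until [empirical_pvalue()] is run).
#' @export
optimize_threshold <- function(stats, dosages, exposure, covariates = NULL,
                               grid = DEFAULT_GRID, variants = NULL) {
  if (length(grid) == 0) stop_data("empty threshold grid")
  grid <- sort(unique(grid))
  C <- if (is.null(covariates)) matrix(1, length(exposure), 1) else
    cbind(1, as.matrix(covariates))
  qrC <- qr(C)
  scores <- .threshold_scores(stats, dosages, grid, variants)
  usable <- colSums(!is.na(scores)) > 0 &
    apply(scores, 2, function(s) !all(is.na(s)) && stats::sd(s) > 0)
  if (!any(usable)) stop_data("no SNP survives any threshold in the grid")
  y_res <- .resid_qr(qrC, exposure)
  vy <- sum((exposure - mean(exposure))^2)
  fit_r2 <- rep(NA_real_, length(grid))
  for (j in which(usable)) {
    s_res <- .resid_qr(qrC, scores[, j])
    fit_r2[j] <- sum(s_res * y_res)^2 / sum(s_res^2) / vy
  }
  best <- which(fit_r2 == max(fit_r2, na.rm = TRUE))[1]
  thr <- grid[best]
  w <- stats[stats$P <= thr, , drop = FALSE]
  structure(list(
    threshold = thr,
    weights = data.frame(SNP = w$SNP, effect_allele = w$A1, beta = w$BETA,
                         p = w$P, stringsAsFactors = FALSE),
    n_snps = nrow(w), fit_r2 = fit_r2[best],
    score = scores[, best],
    grid_fit = data.frame(threshold = grid, fit_r2 = fit_r2,
                          n_snps = sapply(grid, function(t)
                            sum(stats$P <= t))),
    empirical_p = NA_real_), class = "prs_model")
}

#' Permutation-based empirical p-value for the optimized score
#'
#' Permutes the exposure across samples `n_perm` times, re-runs the full
#' grid optimization on each permutation (covariates and genotypes fixed),
#' and reports `(1 + #{permuted best fit >= observed best fit}) /
#' (n_perm + 1)`.
#'
#' @inheritParams optimize_threshold
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @return the input `prs_model` with `empirical_p` (and `n_perm`) filled in.
#' @export
empirical_pvalue <- function(stats, dosages, exposure, covariates = NULL,
                             grid = DEFAULT_GRID, variants = NULL,
                             n_perm = 10000L, seed = 1L) {
  if (n_perm < 1) stop_data("n_perm must be >= 1")
  grid <- sort(unique(grid))
  model <- optimize_threshold(stats, dosages, exposure, covariates, grid,
                              variants)
  C <- if (is.null(covariates)) matrix(1, length(exposure), 1) else
    cbind(1, as.matrix(covariates))
  qrC <- qr(C)
  scores <- .threshold_scores(stats, dosages, grid, variants)
  ok <- which(apply(scores, 2, function(s) !all(is.na(s)) && stats::sd(s) > 0))
  S_res <- .resid_qr(qrC, scores[, ok, drop = FALSE])
  ss <- colSums(S_res^2)
  set.seed(seed)
  n <- length(exposure)
  ## all permutations at once: best-over-grid fit per permuted exposure
  block <- 250L
  exceed <- 0L
  done <- 0L
  vy <- sum((exposure - mean(exposure))^2)
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    P <- matrix(0, n, nb)
    for (b in seq_len(nb)) P[, b] <- exposure[sample.int(n)]
    P_res <- .resid_qr(qrC, P)
    num <- crossprod(S_res, P_res)^2 / ss      # |grid| x nb
    best <- apply(num, 2, max) / vy
    exceed <- exceed + sum(best >= model$fit_r2 - 1e-15)
    done <- done + nb
  }
  model$empirical_p <- (1 + exceed) / (n_perm + 1)
  model$n_perm <- as.integer(n_perm)
  model
}

#' Count model SNPs within a flanked gene region
#'
#' @param model a `prs_model` (or any object with `weights$SNP`).
#' @param variants variant table with snp_id, chrom, pos.
#' @param chrom,start,end gene region (1-based inclusive).
#' @param flank flank in base pairs on each side (default 250000);
#'   boundaries are inclusive.
#' @return integer count.
#' @export
count_snps_near_gene <- function(model, variants, chrom, start, end,
                                 flank = 250000) {
  if (start > end) stop_data("region start exceeds end")
  ids <- model$weights$SNP
  v <- variants[match(ids, variants$snp_id), , drop = FALSE]
  if (any(is.na(v$pos))) stop_data("unknown positions for model variants")
  sum(v$chrom == chrom & v$pos >= start - flank & v$pos <= end + flank)
}
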