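## Causal estimation. All estimators take the outcome, the exposure
## (standardized log scale), the instrument (PRS), and an optional covariate
## matrix/data.frame, and return an `iv_estimate`: estimate, SE, 95% CI
## (estimate +/- 1.96 SE), two-sided normal p, n, method tag, and first-stage
## diagnostics. A weak-instrument flag is raised when the first-stage F
## (adjusted for the covariates in the model) falls below 10.

new_iv_estimate <- function(estimate, se, n, method,
                            adjustment = "partial", stratum = "all",
                            f_stat = NA_real_, converged = TRUE,
                            note = NULL) {
  structure(list(estimate = estimate, se = se, ci95 = ci95(estimate, se),
                 p = pval_norm(estimate, se), n = n, method = method,
                 adjustment = adjustment, stratum = stratum, f_stat = f_stat,
                 weak_instrument = is.finite(f_stat) && f_stat < 10,
                 converged = converged, note = note),
            class = "iv_estimate")
}

#' @export
print.iv_estimate <- function(x, ...) {
  eff <- if (x$method %in% c("two_stage_logistic", "gmm_logistic"))
    sprintf("OR %.3f (95%% CI %.3f-%.3f)", exp(x$estimate),
            exp(x$ci95[1]), exp(x$ci95[2]))
  else sprintf("beta %.3f (95%% CI %.3f-%.3f)", x$estimate,
               x$ci95[1], x$ci95[2])
  cat(sprintf("[%s|%s|%s] %s, p = %.3g, n = %d%s\n", x$method,
              x$adjustment, x$stratum, eff, x$p, x$n,
              if (isTRUE(x$weak_instrument)) " (weak instrument, F < 10)"
              else ""))
  invisible(x)
}

.design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  C <- as.matrix(covariates)
  keep <- apply(C, 2, function(v) stats::sd(v) > 0)
  cbind(1, C[, keep, drop = FALSE])
}

#' First-stage instrument-strength diagnostics
#'
#' F statistic of the instrument in `exposure ~ instrument + covariates`
#' (the squared t of the instrument coefficient) and the instrument's
#' incremental R-squared over the covariate-only model.
#'
#' @param exposure numeric exposure vector.
#' @param instrument numeric instrument (PRS) vector.
#' @param covariates optional covariates; NULL gives the crude F.
#' @return list: f_stat, r2_partial, coefficient, se.
#' @export
first_stage_f <- function(exposure, instrument, covariates = NULL) {
  n <- length(exposure)
  C <- .design(covariates, n)
  qrC <- qr(C)
  z_res <- instrument - qr.fitted(qrC, instrument)
  if (stats::sd(z_res) == 0)
    stop_data("instrument has zero variance after residualization")
  y_res <- exposure - qr.fitted(qrC, exposure)
  szz <- sum(z_res^2)
  coef <- sum(z_res * y_res) / szz
  resid <- y_res - coef * z_res
  df <- n - ncol(C) - 1
  se <- sqrt(sum(resid^2) / df / szz)
  f <- (coef / se)^2
  list(f_stat = f, r2_partial = sum(z_res * y_res)^2 / szz /
         sum((exposure - mean(exposure))^2),
       coefficient = coef, se = se)
}

.iv_design <- function(outcome, exposure, instrument, covariates) {
  n <- length(outcome)
  stopifnot(length(exposure) == n, length(instrument) == n)
  C <- .design(covariates, n)
  if (qr(C)$rank < ncol(C)) stop_data("collinear covariates")
  list(Zm = cbind(C, z = instrument), Xm = cbind(C, x = exposure),
       C = C, n = n)
}

#' Two-stage least squares
#'
#' Just-identified IV regression of the outcome on the exposure with the PRS
#' as the single excluded instrument. The point estimate equals the
#' coefficient on the first-stage fitted exposure; the SE uses the
#' structural residuals `y - beta*x - gamma'C` (not the second-stage
#' residuals). With one instrument the estimate equals the
#' covariate-residualized Wald ratio cov(z,y)/cov(z,x).
#'
#' @param outcome,exposure,instrument numeric vectors.
#' @param covariates optional covariate matrix/data.frame.
#' @param adjustment,stratum labels carried into the estimate.
#' @return an `iv_estimate` with `first_stage` diagnostics attached.
#' @export
tsls <- function(outcome, exposure, instrument, covariates = NULL,
                 adjustment = "partial", stratum = "all") {
  d <- .iv_design(outcome, exposure, instrument, covariates)
  ZtX <- crossprod(d$Zm, d$Xm)
  if (abs(det(ZtX)) < 1e-12 * nrow(d$Zm))
    stop_data("instrument has zero variance after residualization")
  beta <- solve(ZtX, crossprod(d$Zm, outcome))
  u <- outcome - d$Xm %*% beta                 # structural residuals
  sigma2 <- sum(u^2) / (d$n - ncol(d$Xm))
  A <- solve(ZtX)
  V <- sigma2 * A %*% crossprod(d$Zm) %*% t(A)
  k <- ncol(d$Xm)
  fs <- first_stage_f(exposure, instrument, covariates)
  est <- new_iv_estimate(beta[k], sqrt(V[k, k]), d$n, "tsls", adjustment,
                         stratum, f_stat = fs$f_stat)
  est$first_stage <- fs
  est
}

#' Two-step GMM for continuous outcomes
#'
#' Moment conditions `E[(y - beta x - gamma'C) (1, C', z)'] = 0` with a
#' heteroskedasticity-robust weight matrix. In this just-identified setting
#' the point estimate coincides with [tsls()]; the SE is the robust GMM
#' sandwich.
#'
#' @inheritParams tsls
#' @return an `iv_estimate` (method `gmm`).
#' @export
gmm_continuous <- function(outcome, exposure, instrument, covariates = NULL,
                           adjustment = "partial", stratum = "all") {
  d <- .iv_design(outcome, exposure, instrument, covariates)
  ZtX <- crossprod(d$Zm, d$Xm)
  if (abs(det(ZtX)) < 1e-12 * nrow(d$Zm))
    stop_data("instrument has zero variance after residualization")
  beta <- solve(ZtX, crossprod(d$Zm, outcome))
  u <- as.vector(outcome - d$Xm %*% beta)
  S <- crossprod(d$Zm * u)                      # robust meat
  A <- solve(ZtX)
  V <- A %*% S %*% t(A)
  k <- ncol(d$Xm)
  fs <- first_stage_f(exposure, instrument, covariates)
  est <- new_iv_estimate(beta[k], sqrt(V[k, k]), d$n, "gmm", adjustment,
                         stratum, f_stat = fs$f_stat)
  est$first_stage <- fs
  est
}

#' Two-stage estimator for binary outcomes
#'
#' Stage 1: linear regression of the exposure on the instrument and
#' covariates over the analysis sample. Stage 2: logistic regression of the
#' binary outcome on the stage-1 fitted exposure and covariates. Reported on
#' the log-odds scale (use `exp(estimate)` for the OR per 1 SD
#' log-exposure). The default SE is the second-stage model SE; an optional
#' nonparametric bootstrap (resampling individuals) is available because
#' two-stage SEs understate uncertainty.
#'
#' @inheritParams tsls
#' @param n_boot bootstrap resamples for the SE; 0 (default) uses the
#'   model-based SE.
#' @param seed seed for the bootstrap stream.
#' @return an `iv_estimate` (method `two_stage_logistic`); `note` records
#'   separation if the second stage did not converge cleanly.
#' @export
two_stage_binary <- function(outcome, exposure, instrument,
                             covariates = NULL, adjustment = "partial",
                             stratum = "all", n_boot = 0L, seed = 1L) {
  if (length(unique(outcome[!is.na(outcome)])) < 2)
    stop_data("binary outcome must have both classes present")
  n <- length(outcome)
  C <- .design(covariates, n)
  qrC <- qr(cbind(C, instrument))
  fitted_x <- qr.fitted(qrC, exposure)
  if (stats::sd(fitted_x) < 1e-12)
    stop_data("fitted exposure is constant (zero-weight instrument)")
  fit2 <- function(fx, y, Cm) {
    suppressWarnings(stats::glm.fit(cbind(Cm, x = fx), y,
                                    family = stats::binomial()))
  }
  g <- fit2(fitted_x, outcome, C)
  k <- ncol(C) + 1
  b <- g$coefficients[k]
  mu <- g$fitted.values
  sep <- !g$converged || any(mu < 1e-8 | mu > 1 - 1e-8)
  W <- mu * (1 - mu)
  XtWX <- crossprod(cbind(C, fitted_x) * sqrt(W))
  se <- sqrt(solve(XtWX)[k, k])
  if (n_boot > 0) {
    set.seed(seed)
    bb <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, replace = TRUE)
      Cb <- C[idx, , drop = FALSE]
      fxb <- qr.fitted(qr(cbind(Cb, instrument[idx])), exposure[idx])
      fit2(fxb, outcome[idx], Cb)$coefficients[ncol(Cb) + 1]
    }, numeric(1))
    se <- stats::sd(bb, na.rm = TRUE)
  }
  fs <- first_stage_f(exposure, instrument, covariates)
  est <- new_iv_estimate(unname(b), se, n, "two_stage_logistic", adjustment,
                         stratum, f_stat = fs$f_stat,
                         note = if (sep) "possible separation in stage 2")
  est$odds_ratio <- exp(est$estimate)
  est$first_stage <- fs
  est
}

#' GMM estimator for binary outcomes
#'
#' Solves the logistic-mean moment conditions
#' `E[(y - expit(alpha + beta x + gamma'C)) (1, C', z)'] = 0` by damped
#' Newton iteration (just-identified, so the two-step weighting leaves the
#' root unchanged); the SE is the GMM sandwich. Non-convergence is reported
#' as a diagnostic (`converged = FALSE`), never silently.
#'
#' @inheritParams tsls
#' @param max_iter iteration cap (default 100).
#' @param tol convergence tolerance on the scaled moment norm.
#' @return an `iv_estimate` (method `gmm_logistic`) with `converged` flag.
#' @export
gmm_binary <- function(outcome, exposure, instrument, covariates = NULL,
                       adjustment = "partial", stratum = "all",
                       max_iter = 100L, tol = 1e-9) {
  if (length(unique(outcome[!is.na(outcome)])) < 2)
    stop_data("binary outcome must have both classes present")
  d <- .iv_design(outcome, exposure, instrument, covariates)
  Zm <- d$Zm; Xm <- d$Xm; n <- d$n; k <- ncol(Xm)
  ## order: intercept + covariates + x (matches Xm columns)
  theta <- rep(0, k); theta[1] <- stats::qlogis(mean(outcome))
  converged <- FALSE; note <- NULL
  for (it in seq_len(max_iter)) {
    eta <- as.vector(Xm %*% theta)
    mu <- expit(eta)
    gmom <- crossprod(Zm, outcome - mu) / n
    if (max(abs(gmom)) < tol) { converged <- TRUE; break }
    W <- mu * (1 - mu)
    J <- crossprod(Zm, Xm * W) / n
    step <- tryCatch(solve(J, gmom), error = function(e) NULL)
    if (is.null(step)) { note <- "singular moment Jacobian"; break }
    ## damping keeps the logistic mean away from 0/1 blow-ups
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      if (max(abs(cand)) < 50) break
      lambda <- lambda / 2
      if (lambda < 1e-6) break
    }
    theta <- theta + lambda * as.vector(step)
    if (max(abs(theta)) >= 50) {
      note <- "estimates diverging (possible separation)"; break
    }
  }
  eta <- as.vector(Xm %*% theta)
  mu <- expit(eta)
  if (converged && (any(mu < 1e-10) || any(mu > 1 - 1e-10))) {
    converged <- FALSE
    note <- "fitted probabilities at machine bounds (possible separation)"
  }
  W <- mu * (1 - mu)
  J <- crossprod(Zm, Xm * W) / n
  Om <- crossprod(Zm * (outcome - mu)) / n
  V <- tryCatch({
    Ji <- solve(J)
    Ji %*% Om %*% t(Ji) / n
  }, error = function(e) matrix(NA_real_, k, k))
  fs <- first_stage_f(exposure, instrument, covariates)
  est <- new_iv_estimate(theta[k], sqrt(V[k, k]), n, "gmm_logistic",
                         adjustment, stratum, f_stat = fs$f_stat,
                         converged = converged, note = note)
  est$odds_ratio <- exp(est$estimate)
  est$intercept <- theta[1]
  est$first_stage <- fs
  est
}

STRATA <- c("all", "normal_weight", "overweight_obese", "men", "women")

stratum_rows <- function(data, stratum) {
  switch(stratum,
         all = rep(TRUE, nrow(data)),
         normal_weight = data$bmi < 25,
         overweight_obese = data$bmi >= 25,
         men = data$sex == 0,
         women = data$sex == 1,
         stop_config("unknown stratum: ", stratum))
}

#' Run an IV estimator across strata
#'
#' Strata: all samples, normal weight (BMI < 25), overweight/obese
#' (BMI >= 25), men, women. Sex strata drop sex from the covariates.
#' Exposure/outcome standardization is expected to have been computed on
#' the full analysis sample beforehand so stratum effects share a common
#' per-SD scale. Empty or failing strata are reported as unavailable.
#'
#' @param data data.frame with bmi and sex (1 = female) columns.
#' @param outcome,exposure,instrument numeric vectors aligned with `data`.
#' @param covariates covariate data.frame aligned with `data` (may include
#'   a `sex` column, dropped within sex strata).
#' @param estimator one of "tsls", "gmm", "two_stage_logistic",
#'   "gmm_logistic".
#' @param strata character vector of strata to run.
#' @param adjustment label carried into the estimates.
#' @return named list of `iv_estimate`s; unavailable strata hold a list
#'   with `available = FALSE` and a reason.
#' @export
run_stratified <- function(data, outcome, exposure, instrument,
                           covariates = NULL, estimator = "tsls",
                           strata = STRATA, adjustment = "partial") {
  fn <- switch(estimator, tsls = tsls, gmm = gmm_continuous,
               two_stage_logistic = two_stage_binary,
               gmm_logistic = gmm_binary,
               stop_config("unknown estimator: ", estimator))
  out <- list()
  for (s in strata) {
    rows <- stratum_rows(data, s) & !is.na(outcome)
    Cm <- covariates
    if (s %in% c("men", "women") && !is.null(Cm) && "sex" %in% colnames(Cm))
      Cm <- Cm[, setdiff(colnames(Cm), "sex"), drop = FALSE]
    out[[s]] <- if (sum(rows) < 10) {
      list(available = FALSE, stratum = s, reason = "empty or tiny stratum")
    } else tryCatch({
      e <- fn(outcome[rows], exposure[rows], instrument[rows],
              if (is.null(Cm)) NULL else Cm[rows, , drop = FALSE],
              adjustment = adjustment, stratum = s)
      e$available <- TRUE
      e
    }, error = function(err)
      list(available = FALSE, stratum = s, reason = conditionMessage(err)))
  }
  out
}

#' Instrument-confounder balance checks
#'
#' Regresses the PRS on each candidate confounder (age, sex, BMI, alcohol,
#' smoking) one at a time and reports coefficient and p-value, without
#' multiplicity adjustment. Constant covariates yield an NA row.
#'
#' @param prs numeric per-sample score.
#' @param data data.frame with age, sex, bmi, alcohol, smoking_current /
#'   smoking_former (combined into a smoking indicator).
#' @return data.frame: covariate, coefficient, se, p.
#' @export
confounder_balance <- function(prs, data) {
  covs <- list(age = data$age, sex = data$sex, bmi = data$bmi,
               alcohol = data$alcohol,
               smoking = as.integer(data$smoking_current == 1 |
                                      data$smoking_former == 1))
  rows <- lapply(names(covs), function(nm) {
    v <- covs[[nm]]
    if (is.null(v) || stats::sd(v, na.rm = TRUE) == 0)
      return(data.frame(covariate = nm, coefficient = NA_real_,
                        se = NA_real_, p = NA_real_))
    f <- stats::lm(prs ~ v)
    cf <- summary(f)$coefficients
    data.frame(covariate = nm, coefficient = cf[2, 1], se = cf[2, 2],
               p = cf[2, 4])
  })
  do.call(rbind, rows)
}

#' Per-SNP exposure/outcome association scatter (pleiotropy check)
#'
#' For each instrument SNP, fits PC-adjusted single-SNP linear regressions
#' of the (standardized) exposure and outcome on the dosage, then fits the
#' inverse-variance-weighted through-origin regression of the outcome betas
#' on the exposure betas. SNPs whose studentized residual from that fit
#' exceeds `outlier_z` in absolute value are flagged as potential
#' pleiotropic outliers.
#'
#' @param model a `prs_model` (or list with `weights$SNP`).
#' @param dosages dosage matrix covering the model SNPs.
#' @param exposure,outcome numeric standardized vectors.
#' @param pcs matrix of genetic PCs used as adjustment (NULL for crude).
#' @param outlier_z studentized-residual threshold (default 3).
#' @return data.frame: snp_id, beta_exposure, se_exposure, beta_outcome,
#'   se_outcome, outlier; attribute `slope` holds the IVW slope.
#' @export
pleiotropy_scatter <- function(model, dosages, exposure, outcome, pcs = NULL,
                               outlier_z = 3) {
  ids <- model$weights$SNP
  if (length(ids) == 0) stop_data("empty PRS model")
  n <- length(exposure)
  C <- .design(pcs, n)
  qrC <- qr(C)
  ex_res <- exposure - qr.fitted(qrC, exposure)
  out_res <- outcome - qr.fitted(qrC, outcome)
  df <- n - ncol(C) - 1
  res <- lapply(ids, function(id) {
    g <- dosages[, id]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    g_res <- g - qr.fitted(qrC, g)
    if (stats::sd(g_res) < 1e-12) return(NULL)  # monomorphic after adjust
    sgg <- sum(g_res^2)
    bx <- sum(g_res * ex_res) / sgg
    by <- sum(g_res * out_res) / sgg
    sex_ <- sqrt(sum((ex_res - bx * g_res)^2) / df / sgg)
    sey <- sqrt(sum((out_res - by * g_res)^2) / df / sgg)
    data.frame(snp_id = id, beta_exposure = bx, se_exposure = sex_,
               beta_outcome = by, se_outcome = sey,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0) warning(dropped, " monomorphic SNP(s) dropped from scatter")
  tab <- do.call(rbind, res)
  if (is.null(tab) || nrow(tab) == 0) stop_data("no usable scatter points")
  w <- 1 / tab$se_outcome^2
  slope <- sum(w * tab$beta_exposure * tab$beta_outcome) /
    sum(w * tab$beta_exposure^2)
  lev <- w * tab$beta_exposure^2 / sum(w * tab$beta_exposure^2)
  stud <- (tab$beta_outcome - slope * tab$beta_exposure) /
    (tab$se_outcome * sqrt(pmax(1 - lev, 1e-12)))
  tab$outlier <- abs(stud) > outlier_z
  attr(tab, "slope") <- slope
  tab
}
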