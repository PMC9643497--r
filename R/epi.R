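## Observational (non-genetic) association models and descriptive
## statistics. Conventions: natural log for all log transforms; skewed
## variables (adiponectin, HOMA-IR, triglycerides) summarized as median
## (25th-75th percentile) and log-transformed before modelling; all other
## continuous variables as mean (95% Wald CI); proportions as percent
## (95% Wald CI). Lipid-lowering-medication users are excluded from every
## model; T2D cases are excluded from HOMA-IR models; SBP/DBP models add
## blood-pressure-medication use to the covariates.

SKEWED_VARS <- c("adiponectin", "homa_ir", "triglycerides")
LOG_OUTCOMES <- c("homa_ir", "triglycerides")

#' Z-standardize a vector, optionally after a natural log transform
#'
#' @param values numeric vector (positive when `log_first`).
#' @param log_first take the natural log before standardizing.
#' @return numeric vector with mean 0 and SD 1 over non-missing entries.
#' @export
zstandardize <- function(values, log_first = FALSE) {
  v <- values
  if (log_first) {
    if (any(v <= 0, na.rm = TRUE))
      stop_data("non-positive values cannot be log-transformed")
    v <- log(v)
  }
  s <- stats::sd(v, na.rm = TRUE)
  if (is.na(s) || s == 0) stop_data("zero variance: cannot standardize")
  (v - mean(v, na.rm = TRUE)) / s
}

## Apply the analysis exclusions and return row filter + covariate matrix
## for a given outcome/adjustment; shared by epi and the pipeline.
analysis_frame <- function(data, outcome, adjustment = c("partial", "full"),
                           pcs = NULL) {
  adjustment <- match.arg(adjustment)
  if (!outcome %in% names(data)) stop_data("outcome absent: ", outcome)
  keep <- rep(TRUE, nrow(data))
  n_excl <- c(lipid_med = 0L, t2d_for_homa = 0L)
  if ("lipid_med" %in% names(data)) {
    drop <- keep & data$lipid_med == 1
    n_excl["lipid_med"] <- sum(drop); keep[drop] <- FALSE
  }
  if (outcome == "homa_ir" && "t2d" %in% names(data)) {
    drop <- keep & data$t2d == 1
    n_excl["t2d_for_homa"] <- sum(drop); keep[drop] <- FALSE
  }
  if (!any(keep)) stop_data("no samples left after exclusions")
  C <- data.frame(age = data$age, sex = data$sex)
  if (!is.null(pcs)) C <- cbind(C, as.data.frame(pcs))
  if (adjustment == "full")
    C <- cbind(C, bmi = data$bmi, alcohol = data$alcohol,
               smoking_current = data$smoking_current,
               smoking_former = data$smoking_former)
  if (outcome %in% c("sbp", "dbp") && "bp_med" %in% names(data))
    C <- cbind(C, bp_med = data$bp_med)
  list(keep = keep, covariates = C, exclusions = n_excl)
}

#' Observational association between the exposure and one outcome
#'
#' Linear regression for standardized continuous outcomes (HOMA-IR and
#' triglycerides log-transformed first), logistic regression for binary
#' outcomes; the effect is per 1 SD of standardized log exposure.
#' Partial adjustment: age, sex, genetic PCs; full adds BMI, alcohol and
#' smoking status; SBP/DBP models add BP medication.
#'
#' @param data cohort data.frame (see [simulate_cohort()] for columns).
#' @param outcome outcome column name.
#' @param exposure_col exposure column (default "adiponectin",
#'   log-standardized internally).
#' @param adjustment "partial" or "full".
#' @param pcs matrix/data.frame of genetic PCs aligned with `data`.
#' @return list of class `assoc_result`: outcome, effect (beta or odds
#'   ratio), estimate (always on the linear/log-odds scale), se, ci95, p,
#'   adjustment, n, n_excluded.
#' @export
observational_assoc <- function(data, outcome, exposure_col = "adiponectin",
                                adjustment = "partial", pcs = NULL) {
  fr <- analysis_frame(data, outcome, adjustment, pcs)
  d <- data[fr$keep, , drop = FALSE]
  C <- as.matrix(fr$covariates[fr$keep, , drop = FALSE])
  x <- zstandardize(d[[exposure_col]], log_first = TRUE)
  y <- d[[outcome]]
  binary <- outcome %in% BINARY_OUTCOMES ||
    length(unique(y[!is.na(y)])) == 2
  ok <- !is.na(y) & !is.na(x) & stats::complete.cases(C)
  n <- sum(ok)
  if (n == 0) stop_data("empty sample after exclusions")
  Cok <- C[ok, , drop = FALSE]
  Cok <- Cok[, apply(Cok, 2, function(v) stats::sd(v) > 0), drop = FALSE]
  if (binary) {
    f <- suppressWarnings(stats::glm.fit(cbind(1, Cok, x = x[ok]), y[ok],
                                         family = stats::binomial()))
    k <- ncol(Cok) + 2
    mu <- f$fitted.values
    V <- solve(crossprod(cbind(1, Cok, x[ok]) * sqrt(mu * (1 - mu))))
    est <- f$coefficients[k]; se <- sqrt(V[k, k])
    effect <- exp(est)
  } else {
    yz <- zstandardize(y[ok], log_first = outcome %in% LOG_OUTCOMES)
    Xd <- cbind(1, Cok, x = x[ok])
    fit <- stats::lm.fit(Xd, yz)
    k <- ncol(Xd)
    sigma2 <- sum(fit$residuals^2) / (n - k)
    V <- solve(crossprod(Xd)) * sigma2
    est <- fit$coefficients[k]; se <- sqrt(V[k, k])
    effect <- est
  }
  est <- unname(est); se <- unname(se)
  structure(list(outcome = outcome, effect = unname(effect),
                 estimate = est, se = se, ci95 = ci95(est, se),
                 p = pval_norm(est, se), adjustment = adjustment, n = n,
                 n_excluded = fr$exclusions,
                 binary = binary), class = "assoc_result")
}

wald_ci_mean <- function(v) {
  m <- mean(v); se <- stats::sd(v) / sqrt(length(v))
  c(m, m - Z95 * se, m + Z95 * se)
}

wald_ci_prop <- function(v) {
  p <- mean(v); se <- sqrt(p * (1 - p) / length(v))
  100 * c(p, p - Z95 * se, p + Z95 * se)
}

summarize_var <- function(v, kind) {
  v <- v[!is.na(v)]
  switch(kind,
         mean = { s <- wald_ci_mean(v)
           sprintf("%.1f (%.1f, %.1f)", s[1], s[2], s[3]) },
         median = { q <- stats::quantile(v, c(0.5, 0.25, 0.75))
           sprintf("%.2f (%.2f-%.2f)", q[1], q[2], q[3]) },
         percent = { s <- wald_ci_prop(v)
           sprintf("%.1f (%.1f, %.1f)", s[1], s[2], s[3]) })
}

#' Descriptive table with group comparisons
#'
#' Mirrors a population-characteristics table: normally distributed
#' variables as mean (95% Wald CI) compared by t-test; skewed variables
#' (adiponectin, HOMA-IR, triglycerides) as median (25th-75th percentile)
#' compared by Mann-Whitney U; categorical variables as percent (95% Wald
#' CI) compared by chi-square.
#'
#' @param data cohort data.frame.
#' @param variables columns to summarize (default: the standard set).
#' @param grouping NULL for total-sample summaries, or "weight_status" for
#'   normal weight (BMI < 25) vs overweight/obese (BMI >= 25).
#' @return data.frame: variable, kind, test, one summary column per group,
#'   and comparison p (NA without grouping).
#' @export
descriptive_table <- function(data,
                              variables = c("age", "sex", "alcohol",
                                            "smoking_current",
                                            "smoking_former", "adiponectin",
                                            "bmi", "homa_ir", "t2d", "hdl",
                                            "ldl", "total_cholesterol",
                                            "triglycerides", "sbp", "dbp",
                                            "hypertension"),
                              grouping = NULL) {
  groups <- if (is.null(grouping)) list(total = rep(TRUE, nrow(data)))
  else if (identical(grouping, "weight_status"))
    list(normal_weight = data$bmi < 25, overweight_obese = data$bmi >= 25)
  else stop_config("unknown grouping: ", grouping)
  if (any(vapply(groups, sum, numeric(1)) == 0)) stop_data("empty group")

  rows <- lapply(variables, function(nm) {
    v <- data[[nm]]
    if (is.null(v)) stop_data("variable absent: ", nm)
    is_bin <- all(v[!is.na(v)] %in% c(0, 1))
    kind <- if (is_bin) "percent" else if (nm %in% SKEWED_VARS) "median"
    else "mean"
    test <- switch(kind, percent = "chi-square", median = "Mann-Whitney U",
                   mean = "t-test")
    sums <- vapply(groups, function(g) summarize_var(v[g], kind),
                   character(1))
    p <- NA_real_
    if (length(groups) == 2) {
      v1 <- v[groups[[1]]]; v2 <- v[groups[[2]]]
      p <- tryCatch(switch(kind,
        mean = stats::t.test(v1, v2)$p.value,
        median = stats::wilcox.test(v1, v2, exact = FALSE)$p.value,
        percent = {
          tb <- rbind(table(factor(v1, c(0, 1))), table(factor(v2, c(0, 1))))
          if (identical(v1, v2) || stats::sd(v) == 0) 1
          else suppressWarnings(stats::chisq.test(tb)$p.value)
        }), error = function(e) NA_real_)
      if (is.na(p) && isTRUE(all.equal(sort(v1), sort(v2)))) p <- 1
    }
    out <- data.frame(variable = nm, kind = kind, test = test,
                      stringsAsFactors = FALSE)
    for (gn in names(groups)) out[[gn]] <- sums[[gn]]
    out$p <- p
    out
  })
  do.call(rbind, rows)
}
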