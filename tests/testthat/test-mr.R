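test_that("single-instrument 2SLS equals the residualized Wald ratio", {
  ## printed 6-point example: cov(z,y)/cov(z,x) = (2/3)/(2/3) = 1
  z <- c(0, 0, 1, 1, 2, 2); x <- c(0, 1, 1, 2, 2, 3); y <- c(0, 0, 1, 1, 2, 2)
  e <- tsls(y, x, z)
  expect_equal(e$estimate, 1.0, tolerance = 1e-12)

  set.seed(30)
  for (i in 1:25) {
    n <- 80
    C <- cbind(rnorm(n), rbinom(n, 1, 0.5))
    z <- rnorm(n); x <- 0.5 * z + 0.3 * C[, 1] + rnorm(n)
    y <- 0.7 * x + 0.2 * C[, 2] + rnorm(n)
    qrC <- qr(cbind(1, C))
    zt <- qr.resid(qrC, z); yt <- qr.resid(qrC, y); xt <- qr.resid(qrC, x)
    wald <- sum(zt * yt) / sum(zt * xt)
    expect_equal(tsls(y, x, z, C)$estimate, wald, tolerance = 1e-10)
  }
})

test_that("degenerate IV with instrument equal to exposure reduces to OLS", {
  set.seed(31)
  n <- 200
  x <- rnorm(n); y <- 0.4 * x + rnorm(n)
  expect_equal(tsls(y, x, x)$estimate, unname(coef(lm(y ~ x))[2]),
               tolerance = 1e-10)
})

test_that("2SLS confidence bounds and p follow the normal convention", {
  set.seed(32)
  n <- 500
  z <- rnorm(n); x <- 0.5 * z + rnorm(n); y <- 0.3 * x + rnorm(n)
  e <- tsls(y, x, z)
  expect_equal(e$ci95, c(e$estimate - 1.96 * e$se, e$estimate + 1.96 * e$se),
               tolerance = 1e-9)
  expect_equal(e$p, 2 * pnorm(-abs(e$estimate / e$se)), tolerance = 1e-12)
})

test_that("first-stage F is scale-invariant and matches the closed form", {
  set.seed(33)
  n <- 20
  z <- rnorm(n); x <- 0.8 * z + rnorm(n)
  f1 <- first_stage_f(x, z)
  f2 <- first_stage_f(x, z * 17.3)
  expect_equal(f1$f_stat, f2$f_stat, tolerance = 1e-9)
  r2 <- cor(x, z)^2
  expect_equal(f1$f_stat, (n - 2) * r2 / (1 - r2), tolerance = 1e-9)
})

test_that("null-instrument F follows its reference distribution", {
  set.seed(34)
  n <- 60
  hits <- replicate(1000, {
    z <- rnorm(n); x <- rnorm(n)
    first_stage_f(x, z)$f_stat > qf(0.95, 1, n - 2)
  })
  expect_gte(mean(hits), 0.05 - 0.016)
  expect_lte(mean(hits), 0.05 + 0.016)
})

test_that("GMM continuous reproduces 2SLS points with comparable SEs", {
  set.seed(35)
  ratio <- replicate(50, {
    n <- 1000
    z <- rnorm(n); x <- 0.4 * z + rnorm(n); y <- 0.3 * x + rnorm(n)
    a <- tsls(y, x, z); b <- gmm_continuous(y, x, z)
    expect_equal(a$estimate, b$estimate, tolerance = 1e-8)
    b$se / a$se
  })
  expect_lt(abs(mean(ratio) - 1), 0.1)   # homoskedastic: robust SE agrees
})

test_that("robust GMM intervals cover under heteroskedasticity", {
  set.seed(36)
  cover <- replicate(200, {
    n <- 800
    z <- rnorm(n); u <- rnorm(n)
    x <- 0.5 * z + 0.4 * u + rnorm(n)
    y <- 0.5 * x + 0.4 * u + rnorm(n, 0, abs(x))   # error sd ~ |x|
    ci <- gmm_continuous(y, x, z)$ci95
    ci[1] <= 0.5 && 0.5 <= ci[2]
  })
  expect_gte(mean(cover), 0.91)
  expect_lte(mean(cover), 0.98)
})

test_that("binary estimators reject degenerate inputs and flag separation", {
  set.seed(37)
  n <- 100
  y <- rbinom(n, 1, 0.4); x <- rnorm(n)
  expect_error(two_stage_binary(y, x, instrument = rep(0, n)),
               "constant")
  expect_error(two_stage_binary(rep(1, n), x, rnorm(n)), "both classes")
  ## perfectly separated outcome: diagnostic, not a crash
  z <- rnorm(n)
  xs <- z + rnorm(n, 0, 0.01)
  ysep <- as.integer(xs > 0)
  g <- gmm_binary(ysep, xs, z)
  expect_false(g$converged)
  expect_true(!is.null(g$note))
})

test_that("stratified runs honor strata definitions and report empty strata", {
  set.seed(38)
  cfg <- quick_config(n = 600, seed = 39)
  st <- make_study(cfg, "ldl")
  res <- run_stratified(st$cohort, st$y, st$x, st$z, st$covs,
                        estimator = "tsls")
  expect_setequal(names(res), c("all", "normal_weight", "overweight_obese",
                                "men", "women"))
  expect_true(all(vapply(res, function(e) isTRUE(e$available), logical(1))))
  nw <- sum(st$cohort$bmi < 25)
  expect_equal(res$normal_weight$n, nw)
  expect_equal(res$all$n, nrow(st$cohort))

  ## force an empty stratum
  co2 <- st$cohort; co2$bmi <- 20
  res2 <- run_stratified(co2, st$y, st$x, st$z, st$covs, estimator = "tsls")
  expect_false(isTRUE(res2$overweight_obese$available))
  expect_true(isTRUE(res2$normal_weight$available))

  ## sex strata drop the sex covariate (constant within stratum)
  covs_sex <- cbind(st$covs, sex = st$cohort$sex)
  res3 <- run_stratified(st$cohort, st$y, st$x, st$z, covs_sex,
                         estimator = "tsls")
  expect_true(isTRUE(res3$men$available))
})

test_that("a planted stratum-specific effect is recovered where it exists", {
  set.seed(40)
  estA <- estB <- numeric(60)
  for (i in 1:60) {
    n <- 1500
    z <- rnorm(n); u <- rnorm(n)
    x <- 0.3 * z + 0.5 * u + rnorm(n)
    grp <- rbinom(n, 1, 0.5)   # 1 = stratum with the causal effect
    y <- 0.6 * x * grp + 0.5 * u + rnorm(n)
    estA[i] <- tsls(y[grp == 1], x[grp == 1], z[grp == 1])$estimate
    estB[i] <- tsls(y[grp == 0], x[grp == 0], z[grp == 0])$estimate
  }
  expect_lt(abs(mean(estA) - 0.6), 0.1)
  expect_lt(abs(mean(estB)), 0.1)
})

test_that("confounder balance is calibrated and robust to constants", {
  set.seed(41)
  ## independent PRS: per-covariate type-I error near nominal
  pvals <- replicate(200, {
    n <- 300
    d <- data.frame(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5),
                    bmi = rnorm(n, 27, 4), alcohol = rbinom(n, 1, 0.3),
                    smoking_current = rbinom(n, 1, 0.05),
                    smoking_former = rbinom(n, 1, 0.1))
    confounder_balance(rnorm(n), d)$p
  })
  rate <- rowMeans(pvals < 0.05)
  expect_true(all(rate > 0.005 & rate < 0.12))

  ## PRS loading on BMI is detected
  n <- 3000
  d <- data.frame(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5),
                  bmi = rnorm(n, 27, 4), alcohol = rbinom(n, 1, 0.3),
                  smoking_current = rbinom(n, 1, 0.05),
                  smoking_former = rbinom(n, 1, 0.1))
  prs <- 0.1 * scale(d$bmi) + rnorm(n)
  b <- confounder_balance(prs, d)
  expect_lt(b$p[b$covariate == "bmi"], 0.05)

  d$alcohol <- 0
  b2 <- confounder_balance(rnorm(n), d)
  expect_true(is.na(b2$p[b2$covariate == "alcohol"]))
  expect_equal(nrow(b2), 5)
})

test_that("pleiotropy scatter flags a planted direct effect and not nulls", {
  set.seed(42)
  flag_null <- flag_planted <- logical(20)
  for (i in 1:20) {
    n <- 800; m <- 60
    dos <- sapply(runif(m, 0.2, 0.5), function(p) rbinom(n, 2, p))
    colnames(dos) <- paste0("v", 1:m)
    beta <- rnorm(m, 0, 0.08)
    beta[1] <- 0.15            # the SNP that later gets the direct effect
    expo <- as.vector(scale(dos %*% beta + rnorm(n)))
    y_null <- as.vector(scale(0.4 * expo + rnorm(n)))
    model <- list(weights = data.frame(SNP = colnames(dos)))
    s0 <- pleiotropy_scatter(model, dos, expo, y_null)
    flag_null[i] <- any(s0$outlier)
    ## one SNP with a direct effect 10x its mediated path
    direct <- 10 * 0.4 * beta[1]
    y_pl <- as.vector(scale(0.4 * expo + direct * dos[, 1] + rnorm(n)))
    s1 <- pleiotropy_scatter(model, dos, expo, y_pl)
    flag_planted[i] <- s1$outlier[s1$snp_id == "v1"]
  }
  expect_lte(mean(flag_null), 0.3)
  expect_gte(mean(flag_planted), 0.8)
  expect_error(pleiotropy_scatter(list(weights = data.frame(SNP = character(0))),
                                  matrix(0, 2, 2), 1:2, 1:2), "empty")
})
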