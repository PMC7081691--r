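test_that("the balanced paired-eye fixture matches the independent reference", {
  fit <- fit_gee(fixture_balanced, "fd", covariates = "dr_stage",
                 tol = 1e-12, maxit = 500)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), ref_balanced$beta, tolerance = 1e-6)
  expect_equal(unname(fit$robust_se), ref_balanced$robust_se, tolerance = 1e-6)
  expect_equal(unname(fit$model_se), ref_balanced$model_se, tolerance = 1e-6)
  expect_equal(fit$alpha, ref_balanced$alpha, tolerance = 1e-6)
  expect_equal(fit$dispersion, ref_balanced$phi, tolerance = 1e-6)
  expect_equal(fit$qic, ref_balanced$qic, tolerance = 1e-6)
})

test_that("the unbalanced mixed-cluster fixture matches the independent reference", {
  fit <- fit_gee(fixture_unbalanced, "fd", tol = 1e-12, maxit = 500)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), ref_unbalanced$beta, tolerance = 1e-6)
  expect_equal(unname(fit$robust_se), ref_unbalanced$robust_se,
               tolerance = 1e-6)
  expect_equal(unname(fit$model_se), ref_unbalanced$model_se,
               tolerance = 1e-6)
  expect_equal(fit$alpha, ref_unbalanced$alpha, tolerance = 1e-6)
  expect_equal(fit$dispersion, ref_unbalanced$phi, tolerance = 1e-6)
  expect_equal(fit$qic, ref_unbalanced$qic, tolerance = 1e-6)
})

test_that("with singleton clusters only, GEE reduces to ordinary least squares", {
  dat <- fixture_unbalanced[!duplicated(fixture_unbalanced$patient_id), ]
  fit <- fit_gee(dat, "fd")
  ols <- lm(fd ~ age_years + dr_stage, dat)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$alpha, 0)
  expect_true(fit$no_pairs)
})

test_that("an independence working correlation reproduces OLS coefficients", {
  dat <- generate_cohort(cohort_config(seed = 31))
  fit <- fit_gee(dat, "fd_outer", corstr = "independence")
  ols <- lm(fd_outer ~ age_years + dr_stage, dat)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$alpha, 0)
})

test_that("a singular design is rejected", {
  dat <- generate_cohort(cohort_config(seed = 32))
  dat$age_copy <- dat$age_years
  expect_error(fit_gee(dat, "fd_inner", covariates = c("age_years", "age_copy")),
               class = "ccfd_singular_design")
})

test_that("the estimating equations are solved at convergence", {
  dat <- generate_cohort(cohort_config(seed = 33))
  dat$age_years <- scale(dat$age_years)[, 1]   # standardized data
  dat$dr_stage <- scale(dat$dr_stage)[, 1]
  dat$fd_inner <- scale(dat$fd_inner)[, 1]
  fit <- fit_gee(dat, "fd_inner")
  expect_lt(fit$ee_norm, 1e-6)
})

test_that("the fit is invariant to row order and cluster relabeling", {
  dat <- generate_cohort(cohort_config(seed = 34))
  fit1 <- fit_gee(dat, "fd_middle")
  set.seed(1)
  dat2 <- dat[sample(nrow(dat)), ]
  lev <- unique(dat2$patient_id)
  relabel <- stats::setNames(paste0("zz", sample(length(lev))), lev)
  dat2$patient_id <- relabel[dat2$patient_id]
  fit2 <- fit_gee(dat2, "fd_middle")
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-10)
  expect_equal(fit1$robust_se, fit2$robust_se, tolerance = 1e-10)
  expect_equal(fit1$alpha, fit2$alpha, tolerance = 1e-10)
})

test_that("alpha moment estimator tracks limiting and simulated correlations", {
  # perfectly correlated pairs -> clipped at the upper boundary
  r <- rep(rnorm(50), each = 2)
  expect_warning(a1 <- estimate_alpha(r, rep(1:50, each = 2), p = 1),
                 "clipped")
  expect_equal(a1, 1 - 1e-6)
  # perfectly anti-correlated pairs -> negative
  r2 <- rep(rnorm(50), each = 2) * c(1, -1)
  expect_lt(suppressWarnings(estimate_alpha(r2, rep(1:50, each = 2), p = 1)), 0)
  # singletons only -> undefined, distinct signal
  expect_error(estimate_alpha(rnorm(10), 1:10, p = 1),
               class = "ccfd_no_pairs")
  # Monte-Carlo recovery of an intra-class correlation of 0.3
  set.seed(91)
  n <- 5000
  b <- rnorm(n, 0, sqrt(0.3))
  resid <- rep(b, each = 2) + rnorm(2 * n, 0, sqrt(0.7))
  expect_lt(abs(estimate_alpha(resid, rep(1:n, each = 2), p = 0) - 0.3), 0.02)
})

test_that("Wald p-values follow the two-sided normal rule", {
  fake <- structure(list(coefficients = c(a = 0, b = 1.959964, c = 3),
                         robust_se = c(a = 1, b = 1, c = 0)),
                    class = "gee_fit")
  expect_warning(p <- wald_pvalues(fake), "zero robust standard error")
  expect_equal(p[["a"]], 1)
  expect_equal(p[["b"]], 0.05, tolerance = 1e-5)
  expect_true(is.na(p[["c"]]))
})

test_that("QIC approaches the quasi-AIC penalty for independent data", {
  set.seed(92)
  n <- 3000
  dat <- data.frame(patient_id = seq_len(n), age_years = rnorm(n),
                    dr_stage = sample(0:4, n, TRUE))
  dat$fd <- 1 + 0.5 * dat$age_years + rnorm(n)
  fit <- fit_gee(dat, "fd", corstr = "independence")
  p <- 3
  trace_term <- (fit$qic - fit$rss / fit$dispersion) / 2
  expect_lt(abs(trace_term - p) / p, 0.15)
})

test_that("QIC prefers the exchangeable structure under strong correlation", {
  # large-cohort regime: with cluster-constant covariates QIC separates the
  # working correlations only slowly, so the check runs at 1000 patients
  eff <- default_region_effects()[1, ]
  eff$alpha <- 0.6
  cfg <- cohort_config(n_patients = 1000,
                       stage_counts = c(367, 189, 89, 111, 244),
                       effects = eff)
  set.seed(93)
  wins <- 0L
  for (i in 1:200) {
    d <- generate_cohort(cfg, seed = NULL)
    fe <- fit_gee(d, "fd_inner", corstr = "exchangeable")
    fi <- fit_gee(d, "fd_inner", corstr = "independence")
    wins <- wins + (fe$qic < fi$qic)
  }
  expect_gte(wins / 200, 0.9)
})

test_that("coefficient RMSE shrinks like 1/sqrt(n_patients)", {
  eff <- default_region_effects()[1, ]
  rmse_for <- function(np, reps, seed) {
    sc <- round(np * c(33, 17, 8, 10, 22) / 90)
    sc[1] <- np - sum(sc[-1])
    cfg <- cohort_config(n_patients = np, stage_counts = sc, effects = eff)
    set.seed(seed)
    est <- replicate(reps, {
      d <- generate_cohort(cfg, seed = NULL)
      coef(fit_gee(d, "fd_inner"))[["age_years"]]
    })
    sqrt(mean((est - eff$beta_age)^2))
  }
  ratio <- rmse_for(90, 300, 94) / rmse_for(360, 300, 95)
  expect_gt(ratio, 1.6)   # ideal ratio 2
  expect_lt(ratio, 2.5)
})

test_that("robust standard errors are calibrated at study size", {
  cfg <- cohort_config()
  set.seed(96)
  res <- replicate(1000, {
    d <- generate_cohort(cfg, seed = NULL)
    f <- fit_gee(d, "fd_inner")
    c(f$coefficients[["age_years"]], f$robust_se[["age_years"]])
  })
  expect_lt(abs(sd(res[1, ]) - mean(res[2, ])) / mean(res[2, ]), 0.15)
})

test_that("too few clusters are rejected up front", {
  dat <- fixture_balanced[1:4, ]
  expect_error(fit_gee(dat, "fd", covariates = "dr_stage"),
               class = "ccfd_too_few_clusters")
})
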