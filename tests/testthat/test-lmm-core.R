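# The likelihood itself is checked against a dense multivariate-normal
# oracle in test-acceptance.R; here we pin down estimation, inference and
# effect-size behaviour.

test_that("log-likelihood handles degenerate and reduction cases exactly", {
  # one group, one observation, unit residual variance, zero residual
  d1 <- data.frame(patient_id = "g1", month_index = 1, y = 0)
  ll <- loglik_lmm(lmm_spec("y", character(0)), d1,
                   list(sigma2_resid = 1, sigma2_intercept = 0), beta = 0)
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-12)

  # AR(1) with rho = 0 collapses to the independent-residual model
  d <- make_tiny_dataset(5, n_groups = 4, n_per = 5)
  vp <- list(sigma2_resid = 1.3, sigma2_intercept = 0.7)
  ll_ri <- loglik_lmm(lmm_spec("y", "x", "RI"), d, vp, beta = c(1, 0.5))
  vp$rho <- 0
  ll_ar <- loglik_lmm(lmm_spec("y", "x", "RI_AR1"), d, vp, beta = c(1, 0.5))
  expect_equal(ll_ri, ll_ar, tolerance = 1e-8)

  # non-positive-definite covariance is reported, not swallowed
  vp_bad <- list(sigma2_resid = 1, sigma2_intercept = 4, sigma2_slope = 1,
                 cov_intercept_slope = 3)  # |cov| > sqrt(g0 g1)
  expect_error(loglik_lmm(lmm_spec("y", "x", "RI_RS", slope = "x"), d,
                          vp_bad, beta = c(1, 0.5)),
               "positive definite")
})

test_that("noise-free data are interpolated exactly", {
  d <- expand.grid(month_index = 1:6, patient_id = sprintf("g%d", 1:4))
  d$x <- seq_len(nrow(d)) / 7
  d$y <- 2 + 3 * d$x
  fit <- fit_lmm(lmm_spec("y", "x", "RI"), d)
  expect_lt(max(abs(fit$beta - c(2, 3))), 1e-6)
})

test_that("balanced random-intercept ML matches the closed-form estimators", {
  d <- make_balanced_ri(31, k = 12, m = 6)
  oracle <- balanced_ri_ml(d)
  fit <- fit_lmm(lmm_spec("y", character(0), "RI"), d)
  expect_equal(unname(fit$beta[[1]]), oracle$mu, tolerance = 1e-6)
  expect_equal(fit$var_params$sigma2_resid, oracle$s2e, tolerance = 1e-4)
  expect_equal(fit$var_params$sigma2_intercept, oracle$s2b, tolerance = 1e-3)
})

test_that("random-intercept fits agree with an established library's ML fits", {
  skip_if_not_installed("lme4")
  for (seed in c(3, 17)) {
    d <- make_tiny_dataset(seed, n_groups = 12, n_per = 6)
    fit <- fit_lmm(lmm_spec("y", "x", "RI"), d)
    ref <- lme4::lmer(y ~ x + (1 | patient_id), d, REML = FALSE)
    expect_equal(unname(fit$beta), unname(lme4::fixef(ref)),
                 tolerance = 1e-3)
    expect_equal(fit$minus2_loglik, -2 * as.numeric(stats::logLik(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(fit$se),
                 unname(sqrt(diag(as.matrix(stats::vcov(ref))))),
                 tolerance = 1e-3)
  }
})

test_that("richer random structures never fit worse than their nested model", {
  for (seed in c(2, 9, 23)) {
    d <- make_tiny_dataset(seed, n_groups = 8, n_per = 6)
    f_ri <- fit_lmm(lmm_spec("y", "x", "RI"), d)
    f_ar <- fit_lmm(lmm_spec("y", "x", "RI_AR1"), d)
    f_rs <- fit_lmm(lmm_spec("y", "x", "RI_RS"), d)
    expect_gte(f_ri$minus2_loglik, f_ar$minus2_loglik - 1e-4)
    expect_gte(f_ri$minus2_loglik, f_rs$minus2_loglik - 1e-4)
  }
})

test_that("Satterthwaite df hits the balanced-case and degenerate limits", {
  # balanced one-way: intercept df tracks the between-groups df
  d <- make_balanced_ri(8, k = 30, m = 5)
  fit <- fit_lmm(lmm_spec("y", character(0), "RI"), d)
  expect_equal(fit$satterthwaite_df[[1]], 29, tolerance = 0.05)

  # no group structure in the data: df approaches the regression limit n - p
  set.seed(12)
  d2 <- make_tiny_dataset(12, n_groups = 10, n_per = 8)
  d2$y <- 1 + 0.5 * d2$x + rnorm(nrow(d2))  # zero between-group variance
  f2 <- fit_lmm(lmm_spec("y", "x", "RI"), d2)
  expect_gt(f2$satterthwaite_df[["x"]], 0.9 * (nrow(d2) - 2))

  # clamping contract on fuzzed fits
  for (seed in c(4, 44)) {
    d3 <- make_tiny_dataset(seed, n_groups = 6, n_per = 5)
    f3 <- fit_lmm(lmm_spec("y", "x", "RI_AR1"), d3)
    dfs <- f3$satterthwaite_df
    expect_true(all(dfs >= 1 & dfs <= f3$n_obs - 2))
  }
})

test_that("Wald t-tests reproduce printed clinical-table inference", {
  wt <- wald_t_test(0.548, 0.172, 469.7)
  expect_equal(round(wt$t, 1), 3.2)
  expect_equal(round(wald_t_test(-2.4 * 0.1, 0.1, 20)$p, 2), 0.03)
  expect_equal(wald_t_test(0, 1, 50)$p, 1)
  expect_error(wald_t_test(1, 0, 10), "positive")
  expect_error(wald_t_test(1, -1, 10), "positive")
})

test_that("marginal pseudo-R2 and Cohen f2 behave per definition", {
  d <- make_balanced_ri(15, k = 10, m = 4)
  fit0 <- fit_lmm(lmm_spec("y", character(0), "RI"), d)
  expect_equal(fit0$Rm, 0)  # intercept-only: no fixed-effect variance
  expect_equal(fit0$f2, 0)
  expect_equal(0.5 / (1 - 0.5), 1)  # the f2 = Rm/(1-Rm) identity at Rm = .5
  d$x <- rnorm(nrow(d))
  far <- fit_lmm(lmm_spec("y", "x", "RI_AR1"), d)
  expect_error(marginal_r2_f2(far), "matrix, not a scalar")
})

test_that("estimated marginal R2 recovers a planted fixed-variance share", {
  # x ~ N(0,1) with slope 1 -> var_f = 1; s2b + s2e = 4 -> share = 0.2
  reps <- 150
  rms <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    k <- 30; m <- 8
    d <- data.frame(patient_id = rep(seq_len(k), each = m),
                    month_index = rep(seq_len(m), k),
                    x = rnorm(k * m))
    d$y <- d$x + rep(rnorm(k, 0, sqrt(2)), each = m) +
      rnorm(k * m, 0, sqrt(2))
    rms[[r]] <- fit_lmm(lmm_spec("y", "x", "RI"), d)$Rm
  }
  expect_lt(abs(mean(rms) - 0.2), 0.02)
})

test_that("likelihood-ratio tests use the stated null distributions", {
  r1 <- lrt(fake_fit(100), fake_fit(100.4), "chi2_1")
  expect_equal(round(r1$p_value, 2), 0.53)
  r2 <- lrt(fake_fit(100), fake_fit(103.7), "mix_half_chi2_1_chi2_2")
  expect_equal(round(r2$p_value, 2), 0.11)
  expect_equal(lrt(fake_fit(50), fake_fit(50), "chi2_1")$p_value, 1)
  expect_equal(lrt(fake_fit(50), fake_fit(50),
                   "mix_half_chi2_1_chi2_2")$p_value, 1)
  # p decreases in the statistic
  lams <- seq(0, 10, by = 0.5)
  ps <- vapply(lams, function(l)
    lrt(fake_fit(0), fake_fit(l), "mix_half_chi2_1_chi2_2")$p_value,
    numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(lrt(fake_fit(101), fake_fit(100), "chi2_1"), "restarts")
  expect_error(lrt(fake_fit(1, n = 5), fake_fit(2, n = 6), "chi2_1"),
               "different numbers of rows")
})

test_that("data contracts are enforced before fitting", {
  d <- make_tiny_dataset(1, n_groups = 2, n_per = 2)
  expect_error(fit_lmm(lmm_spec("y", c("x", "I(x^2)", "month_index")),
                       d[1:3, ]), "fewer observations")
  expect_error(fit_lmm(lmm_spec("y", "x"), transform(d, patient_id = "g1")),
               "2 groups")
  expect_error(lmm_spec("y", character(0), "RI_RS"), "slope")
})
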