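test_that("REML fit matches the brute-force grid-search oracle", {
  for (seed in c(101, 202)) {
    d <- make_grouped_data(n_groups = 3, n_per = 4, seed = seed)
    fit <- nrt_lmm(y ~ x, d, "g")
    X <- stats::model.matrix(~x, d)
    orc <- oracle_reml_fit(d$y, X, d$g)
    expect_equal(unname(coef(fit)), unname(orc$beta), tolerance = 1e-4)
    expect_equal(fit$sigma2_e, orc$sigma2_e, tolerance = 1e-3)
    expect_equal(fit$sigma2_b, orc$sigma2_b, tolerance = 1e-3)
    expect_equal(fit$loglik, orc$loglik, tolerance = 1e-6)
  }
  # a larger fixture with two covariates, still below 50 rows
  d <- make_grouped_data(n_groups = 6, n_per = 8, seed = 42)
  d$x2 <- stats::runif(nrow(d))
  fit <- nrt_lmm(y ~ x + x2, d, "g")
  orc <- oracle_reml_fit(d$y, stats::model.matrix(~ x + x2, d), d$g)
  expect_equal(unname(coef(fit)), unname(orc$beta), tolerance = 1e-4)
  expect_equal(fit$sigma2_b, orc$sigma2_b, tolerance = 1e-3)
})

test_that("REML fit agrees with an independent mixed-model implementation", {
  library(lme4)
  d <- make_grouped_data(n_groups = 8, n_per = 6, seed = 9)
  fit <- nrt_lmm(y ~ x, d, "g")
  m <- lmer(y ~ x + (1 | g), d, REML = TRUE)
  expect_equal(unname(coef(fit)), unname(fixef(m)), tolerance = 1e-6)
  vc <- as.data.frame(VarCorr(m))
  expect_equal(fit$sigma2_b, vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$sigma2_e, vc$vcov[2], tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(m)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(vcov(m))))),
               tolerance = 1e-5)
  expect_equal(unname(blup_random_intercepts(fit)),
               ranef(m)$g[, 1], tolerance = 1e-5)
})

test_that("degenerate grouping reduces to OLS with a warning", {
  d <- make_grouped_data(n_groups = 12, n_per = 1, seed = 3)
  expect_warning(fit <- nrt_lmm(y ~ x, d, "g"), "one observation per group")
  ols <- stats::lm(y ~ x, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-12)
  expect_identical(fit$sigma2_b, 0)
})

test_that("boundary sigma_b^2 = 0 reproduces ordinary least squares", {
  # group means made exactly equal: no between-group variance to absorb
  set.seed(21)
  d <- data.frame(g = rep(1:5, each = 6), x = stats::rnorm(30))
  d$y <- 1 + 0.5 * d$x + stats::rnorm(30, 0, 2)
  d$y <- d$y - stats::ave(d$y, d$g) + stats::ave(1 + 0.5 * d$x, d$g)
  fit <- nrt_lmm(y ~ x, d, "g")
  expect_identical(fit$sigma2_b, 0)
  ols <- stats::lm(y ~ x, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$residuals_marginal), unname(resid(ols)),
               tolerance = 1e-10)
  expect_equal(unname(blup_random_intercepts(fit)), rep(0, 5))
})

test_that("parameter recovery at large n is within sampling error", {
  set.seed(55)
  G <- 150
  ni <- 10
  d <- data.frame(g = rep(seq_len(G), each = ni),
                  x = stats::rnorm(G * ni))
  beta_true <- c(3, -1.4)
  d$y <- beta_true[1] + beta_true[2] * d$x +
    rep(stats::rnorm(G, 0, 2), each = ni) + stats::rnorm(G * ni, 0, 1)
  fit <- nrt_lmm(y ~ x, d, "g")
  expect_lt(abs(coef(fit)[1] - beta_true[1]), 2 * fit$se[1])
  expect_lt(abs(coef(fit)[2] - beta_true[2]), 2 * fit$se[2])
  expect_equal(fit$sigma2_b, 4, tolerance = 0.3)
  expect_equal(fit$sigma2_e, 1, tolerance = 0.15)
})

test_that("Wald test computes the normal-reference z and p", {
  fake <- structure(list(coefficients = c(scalarST = -8.50),
                         se = c(scalarST = 1.97)), class = "nrt_lmm")
  w <- wald_test(fake, "scalarST")
  expect_equal(w$z, -4.3147, tolerance = 1e-4)
  expect_lt(w$p, 0.01)
  fake$coefficients[] <- 0
  expect_equal(wald_test(fake, "scalarST")$p, 1)
  fake$coefficients[] <- 1.96 * 1.97
  expect_equal(wald_test(fake, "scalarST")$p, 0.05, tolerance = 1e-3)
  expect_error(wald_test(fake, "nope"), "unknown coefficient")
})

test_that("Wald p-values are invariant to covariate rescaling", {
  d <- make_grouped_data(n_groups = 6, n_per = 8, seed = 13)
  d$x_scaled <- d$x * 1000
  f1 <- nrt_lmm(y ~ x, d, "g")
  f2 <- nrt_lmm(y ~ x_scaled, d, "g")
  expect_equal(coef(f2)[["x_scaled"]] * 1000, coef(f1)[["x"]],
               tolerance = 1e-8)
  expect_equal(wald_test(f2, "x_scaled")$p, wald_test(f1, "x")$p,
               tolerance = 1e-8)
})

test_that("BIC follows -2 logLik + k log(N) and penalizes pure noise", {
  d <- make_grouped_data(n_groups = 6, n_per = 8, seed = 31)
  fit <- nrt_lmm(y ~ x, d, "g")
  k <- length(coef(fit)) + 2
  expect_equal(model_bic(fit), -2 * fit$loglik + k * log(nobs(fit)),
               tolerance = 1e-10)
  expect_equal(model_bic(fit), BIC(logLik(fit)), tolerance = 1e-10)
  expect_identical(model_bic(fit), model_bic(fit))
  # adding pure-noise covariates raises ML-based BIC in most replicates
  set.seed(99)
  worse <- 0
  for (i in 1:10) {
    d$junk <- stats::rnorm(nrow(d))
    b0 <- nrt_lmm(y ~ x, d, "g", method = "ML")$bic
    b1 <- nrt_lmm(y ~ x + junk, d, "g", method = "ML")$bic
    worse <- worse + (b1 > b0)
  }
  expect_gte(worse, 8)
})

test_that("rank deficiency is reported with the aliased columns", {
  d <- make_grouped_data(n_groups = 4, n_per = 6, seed = 8)
  d$x_dup <- 2 * d$x
  expect_error(nrt_lmm(y ~ x + x_dup, d, "g"), "aliased.*x_dup")
})

test_that("prediction bands are centered and widen under extrapolation", {
  d <- make_grouped_data(n_groups = 6, n_per = 8, seed = 77)
  fit <- nrt_lmm(y ~ x, d, "g")
  nd <- data.frame(x = d$x[1:5])
  pr <- predict(fit, nd, interval = "confidence")
  expect_true(all(pr$lwr < pr$fit & pr$fit < pr$upr))
  expect_equal(pr$fit, unname(drop(cbind(1, nd$x) %*% coef(fit))),
               tolerance = 1e-10)
  # no-intercept model at x = 0: mean 0, zero-width band
  f0 <- nrt_lmm(y ~ x - 1, d, "g")
  p0 <- predict(f0, data.frame(x = 0), interval = "confidence")
  expect_equal(unname(unlist(p0)), c(0, 0, 0))
  # extrapolation widens the band
  w_in <- with(predict(fit, data.frame(x = 0), interval = "confidence"),
               upr - lwr)
  w_out <- with(predict(fit, data.frame(x = 10), interval = "confidence"),
                upr - lwr)
  expect_gt(w_out, w_in)
  expect_error(predict(fit, data.frame(z = 1)), "object 'x' not found")
})

test_that("BLUPs shrink subject mean residuals by the variance ratio", {
  d <- make_grouped_data(n_groups = 8, n_per = 6, seed = 15)
  fit <- nrt_lmm(y ~ x, d, "g")
  ni <- fit$group_sizes
  shrink <- fit$sigma2_b * ni / (fit$sigma2_e + ni * fit$sigma2_b)
  rbar <- as.numeric(tapply(fit$residuals_marginal, fit$group_index,
                            mean))
  expect_equal(unname(blup_random_intercepts(fit)), shrink * rbar,
               tolerance = 1e-10)
  # with n_i = 2 and sigma_b^2 = sigma_e^2 the shrinkage factor is 2/3
  expect_equal(1 * 2 / (1 + 2 * 1), 2 / 3)
  expect_true(all(abs(unname(blup_random_intercepts(fit))) <=
                    abs(rbar) + 1e-12))
})

test_that("fitted, residuals and simulate are mutually consistent", {
  d <- make_grouped_data(n_groups = 6, n_per = 8, seed = 19)
  fit <- nrt_lmm(y ~ x, d, "g")
  expect_equal(fitted(fit) + residuals(fit, "marginal"), d$y,
               tolerance = 1e-12)
  expect_equal(fitted(fit, "conditional") + residuals(fit, "conditional"),
               d$y, tolerance = 1e-12)
  s1 <- simulate(fit, nsim = 2, seed = 5)
  s2 <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(s1, s2)
  expect_identical(dim(s1), c(nobs(fit), 2L))
})

test_that("functional form selection is self-consistent", {
  # straight-line truth
  set.seed(2)
  G <- 60
  ni <- 10
  g <- rep(seq_len(G), each = ni)
  f <- stats::runif(G * ni, 500, 16000)
  y <- 100 + 0.002 * f + rep(stats::rnorm(G, 0, 5), each = ni) +
    stats::rnorm(G * ni, 0, 3)
  sel <- select_functional_form(y, f, g)
  expect_identical(sel$chosen, "linear")
  # double-bump truth from the default generator
  tab <- generate_cohort(generator_config(n_subjects = 100, seed = 11))
  sel2 <- select_functional_form(tab$nrt_threshold_cl, tab$cnf_hz,
                                 tab$subject_id)
  expect_identical(sel2$chosen, "spline")
  # a single candidate is returned unconditionally
  sel3 <- select_functional_form(y, f, g, forms = "cubic")
  expect_identical(sel3$chosen, "cubic")
  expect_named(sel3$bic, "cubic")
})
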