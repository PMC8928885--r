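test_that("standardize centers, scales, and is idempotent", {
  z <- standardize(c(590, 600, 610))
  expect_equal(z, c(-1, 0, 1))
  withr::with_seed(2, x <- rnorm(50, 100, 9))
  z <- standardize(x)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(standardize(z), z)
  expect_error(standardize(rep(3, 5)), class = "partmigr_validation_error")
})

test_that("logistic IRLS reproduces closed forms and the glm oracle", {
  # intercept-only: logit of the observed proportion (53 of 73)
  y <- c(rep(1, 53), rep(0, 20))
  f <- fit_binomial(y)
  expect_equal(unname(f$coefficients), qlogis(53 / 73), tolerance = 1e-10)
  # one binary predictor: slope equals the 2x2 log odds ratio
  y2 <- c(rep(1, 30), rep(0, 10), rep(1, 12), rep(0, 28))
  x2 <- rep(c(0, 1), c(40, 40))
  f2 <- fit_binomial(y2, cbind(1, x2))
  lor <- log((12 / 28) / (30 / 10))
  expect_equal(unname(f2$coefficients[2]), lor, tolerance = 1e-10)
  # random instances against stats::glm (full ML, identical likelihood)
  withr::with_seed(33, {
    for (rep in 1:5) {
      n <- 50
      X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
      yy <- rbinom(n, 1, plogis(drop(X %*% c(-0.3, 0.8, -0.5))))
      fm <- fit_binomial(yy, X)
      gm <- glm(yy ~ X[, 2] + X[, 3], family = binomial)
      expect_equal(unname(fm$coefficients), unname(coef(gm)), tolerance = 1e-6)
      expect_equal(fm$loglik, as.numeric(logLik(gm)), tolerance = 1e-8)
    }
  })
  expect_error(fit_binomial(rep(1, 10)), class = "partmigr_validation_error")
})

test_that("complete separation triggers a named warning and flag", {
  y <- rep(c(0, 1), each = 10)
  x <- c(rnorm(10, -5), rnorm(10, 5))
  expect_warning(f <- fit_binomial(y, cbind(1, x)), class = "partmigr_separation")
  expect_true(f$separation)
})

test_that("gaussian fit is OLS with a full-ML likelihood", {
  withr::with_seed(4, {
    X <- cbind(1, rnorm(40))
    y <- drop(X %*% c(2, -1)) + rnorm(40)
  })
  f <- fit_gaussian(y, X)
  # normal-equations oracle
  expect_equal(unname(f$coefficients), drop(solve(crossprod(X), crossprod(X, y))),
    tolerance = 1e-10
  )
  expect_equal(f$loglik, as.numeric(logLik(lm(y ~ X[, 2]))), tolerance = 1e-8)
  expect_equal(f$k, 3) # slope, intercept, residual variance
  fi <- fit_gaussian(y)
  expect_equal(unname(fi$coefficients), mean(y))
  # exact fit: degenerate flag
  fd <- fit_gaussian(drop(X %*% c(1, 2)), X)
  expect_true(fd$degenerate)
  expect_error(
    fit_gaussian(y, cbind(X, X[, 2])),
    class = "partmigr_singular_design"
  )
})

test_that("AICc follows the small-sample formula and ranks models", {
  expect_equal(aicc(-10, 2, 20), 24 + 12 / 17)
  expect_error(aicc(-10, 9, 10), class = "partmigr_validation_error")
  mk <- function(ll, k) {
    structure(list(loglik = ll, k = k, n = 40, family = "gaussian-identity"), class = "glm_fit")
  }
  # equal AICc -> equal weights
  tab <- rank_models(list(a = mk(-10, 2), b = mk(-10, 2)))
  expect_equal(tab$weight, c(0.5, 0.5))
  tab <- rank_models(list(m1 = mk(-12, 3), m2 = mk(-10, 2), m3 = mk(-15, 1)))
  expect_equal(tab$delta_AICc[1], 0)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(tab$cum_weight) >= 0))
  expect_equal(tab$cum_weight[3], 1, tolerance = 1e-12)
  expect_true(all(diff(tab$AICc) >= 0))
  expect_error(
    rank_models(list(a = mk(-10, 2), b = structure(
      list(loglik = -1, k = 2, n = 30, family = "x"),
      class = "glm_fit"
    ))),
    class = "partmigr_validation_error"
  )
})

test_that("CMP distribution reduces to Poisson at nu = 1", {
  expect_equal(cmp_log_normalizer(2, 1), 2, tolerance = 1e-12)
  expect_equal(cmp_log_normalizer(c(0.5, 7), 1), c(0.5, 7), tolerance = 1e-10)
  expect_equal(cmp_pmf(0:30, 5, 1), dpois(0:30, 5), tolerance = 1e-10)
})

test_that("CMP pmf is a proper distribution with the advertised dispersion", {
  for (mu in c(1, 5, 20)) {
    for (nu in c(0.3, 1, 2, 5)) {
      jmax <- ceiling(10 * mu + 30 / nu + 50)
      p <- cmp_pmf(0:jmax, mu, nu)
      expect_equal(sum(p), 1, tolerance = 1e-8)
      m <- sum((0:jmax) * p)
      v <- sum((0:jmax)^2 * p) - m^2
      expect_equal(m, mu, tolerance = 1e-6) # mean parameterization holds
      if (nu > 1) expect_lt(v, mu) # underdispersed
      if (nu < 1) expect_gt(v, mu) # overdispersed
    }
  }
  # nu = 2, mu = 9: variance by direct summation is below the mean
  p <- cmp_pmf(0:60, 9, 2)
  v <- sum((0:60)^2 * p) - sum((0:60) * p)^2
  expect_lt(v, 9)
})

test_that("CMP regression matches Poisson at fixed nu = 1 and recovers truth", {
  withr::with_seed(8, {
    x <- rnorm(150)
    yy <- rpois(150, exp(1.5 + 0.3 * x))
  })
  fm <- fit_cmp_regression(yy, cbind(1, x), fix_nu = 1)
  gm <- glm(yy ~ x, family = poisson)
  expect_equal(unname(fm$coefficients), unname(coef(gm)), tolerance = 1e-6)
  expect_equal(fm$loglik, as.numeric(logLik(gm)), tolerance = 1e-6)
  # underdispersed truth: nu estimated above 1; overdispersed: below 1
  withr::with_seed(9, yu <- rcmp(400, 10, 2))
  fu <- fit_cmp_regression(yu)
  expect_gt(fu$nu, 1)
  expect_equal(unname(exp(fu$coefficients[1])), 10, tolerance = 0.05)
  withr::with_seed(10, yo <- rcmp(400, 5, 0.4))
  fo <- fit_cmp_regression(yo)
  expect_lt(fo$nu, 1)
})

test_that("CMP regression agrees with the glmmTMB COM-Poisson oracle", {
  skip_if_not_installed("glmmTMB")
  withr::with_seed(11, {
    x <- rnorm(70)
    yy <- rcmp(70, exp(2.2 + 0.1 * x), 2)
  })
  fm <- fit_cmp_regression(yy, cbind(1, x))
  dat <- data.frame(yy = yy, x = x)
  tm <- glmmTMB::glmmTMB(yy ~ x, family = glmmTMB::compois, data = dat)
  expect_equal(unname(fm$coefficients), unname(glmmTMB::fixef(tm)$cond), tolerance = 1e-4)
  expect_equal(fm$loglik, as.numeric(stats::logLik(tm)), tolerance = 1e-4)
})

test_that("candidate sets have the standard sizes and covariate checks", {
  sim <- simulate_population(sim_config(n_birds = 60, n_years = 2, seed = 88))
  tr <- truth_transitions(sim)
  suppressWarnings(cs <- run_candidate_sets(tr, sim$birds, sim$nests))
  expect_equal(nrow(cs$migration$table), 5)
  expect_equal(nrow(cs$distance$table), 5)
  expect_equal(nrow(cs$clutch_size$table), 8)
  expect_equal(nrow(cs$nest_fate$table), 8)
  for (tab in list(
    cs$migration$table, cs$distance$table,
    cs$clutch_size$table, cs$nest_fate$table
  )) {
    expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
    expect_equal(tab$delta_AICc[1], 0)
  }
  bad_birds <- dplyr::select(sim$birds, -weight_g)
  expect_error(
    run_candidate_sets(tr, bad_birds, sim$nests),
    class = "partmigr_validation_error", regexp = "weight_g"
  )
})

test_that("a generated juvenile-only weight effect selects the interaction model", {
  # replicate experiment: with a strong weight-by-age interaction in the
  # generator, the interaction model should win the AICc ranking in most
  # replicates
  wins <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(
      n_birds = 150, n_years = 1,
      beta0 = 1, beta_w = -2.5, beta_ad = 0.2, beta_w_ad = 2.5,
      p_nest = 0, n_gps_birds = 0, fixes_per_season = c(1, 2),
      seed = 7000 + r
    )
    sim <- simulate_population(cfg)
    tr <- truth_transitions(sim)
    tab <- suppressWarnings(run_candidate_sets(tr, sim$birds, nests = NULL)$migration$table)
    if (tab$model[1] == "Weight + Age + Weight x Age") wins <- wins + 1
  }
  expect_gt(wins / n_rep, 0.5)
})
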