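test_that("least squares interpolates zero-noise data and matches a numeric optimizer", {
  # exact recovery on noiseless multiplicative data
  betas <- c(1.2, -0.5, 0.3, 0.8)
  d0 <- random_design(50, betas, sigma = 0, seed = 1)
  f0 <- fit_unit_cost_model(d0, "ols")
  expect_equal(unname(coef(f0)), betas, tolerance = 1e-10)
  expect_equal(f0$r_squared, 1, tolerance = 1e-10)

  # small noisy instance against a brute-force minimizer of the RSS
  d <- random_design(12, c(0.5, 1, -2), sigma = 0.4, seed = 2)
  f <- fit_unit_cost_model(d, "ols")
  rss <- function(b) sum((d$response - b[1] - as.matrix(d$frame) %*% b[-1])^2)
  opt <- optim(c(0, 0, 0), rss, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(coef(f)), opt$par, tolerance = 1e-6)

  # constant response: intercept c, zero slopes, R-squared 0 by convention
  dc <- uc_design(rep(exp(2.5), 10), data.frame(x = rnorm(10)))
  fc <- fit_unit_cost_model(dc, "ols")
  expect_equal(unname(coef(fc)), c(2.5, 0), tolerance = 1e-10)
  expect_equal(fc$r_squared, 0)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  x <- rnorm(20)
  d <- uc_design(exp(rnorm(20)), data.frame(x = x, x_dup = x))
  expect_error(fit_unit_cost_model(d, "ols"), "x_dup")
})

test_that("the gamma log-link GLM agrees with known closed forms and with OLS at zero noise", {
  # intercept-only gamma GLM fits the log of the sample mean
  f1 <- fit_unit_cost_model(uc_design(c(1, 2, 4)), "glm")
  expect_equal(unname(coef(f1)), log(7 / 3), tolerance = 1e-9)

  # zero-noise agreement across several random designs
  for (seed in 1:5) {
    d0 <- random_design(40, c(2, -0.4, 0.9), sigma = 0, seed = seed)
    expect_equal(coef(fit_unit_cost_model(d0, "glm")),
                 coef(fit_unit_cost_model(d0, "ols")), tolerance = 1e-6)
  }

  # the IRLS fixed point does not depend on the starting point
  d <- random_design(80, c(1, 0.5, -0.7), sigma = 0.5, seed = 7)
  from_ols <- fit_unit_cost_model(d, "glm")
  dat <- d$frame
  dat$.y <- d$uc
  from_zero <- glm(.y ~ x1 + x2, data = dat, family = Gamma(link = "log"),
                   start = c(0, 0, 0),
                   control = glm.control(epsilon = 1e-10, maxit = 200))
  expect_equal(unname(coef(from_ols)), unname(coef(from_zero)),
               tolerance = 1e-6)
  d_neg <- d
  d_neg$uc[1] <- -1
  expect_error(fit_unit_cost_model(d_neg, "glm"), "positive")
})

test_that("information criteria follow the penalized-likelihood formulas", {
  expect_equal(unname(information_criteria(-10, p = 3, n = 20)),
               c(26, 20 + 3 * log(20)))
  expect_equal(unname(information_criteria(-10, p = 0, n = 20)), c(20, 20))

  # nested models: the larger model never fits worse in likelihood
  d <- random_design(60, c(1, 0.5, -0.7), sigma = 0.5, seed = 3)
  full <- fit_unit_cost_model(d, "ols")
  red <- fit_unit_cost_model(uc_design(d$uc, d$frame["x1"]), "ols")
  expect_gte(full$log_likelihood, red$log_likelihood)
  expect_equal(unname(information_criteria(full)),
               unname(c(AIC(full$fit), BIC(full$fit))))
})

test_that("the nested F-test matches hand-computed algebra and is well calibrated", {
  d <- random_design(25, c(1, 0.6, -0.2), sigma = 0.7, seed = 4)
  full <- fit_unit_cost_model(d, "ols")
  red <- fit_unit_cost_model(uc_design(d$uc, d$frame["x1"]), "ols")

  expect_equal(unname(uc_f_test(full, full)[c("statistic", "p_value")]),
               c(0, 1))
  expect_error(uc_f_test(red, full), "nested")

  rss_f <- sum(residuals(full)^2)
  rss_r <- sum(residuals(red)^2)
  by_hand <- ((rss_r - rss_f) / 1) / (rss_f / (25 - 3))
  ft <- uc_f_test(full, red)
  expect_equal(unname(ft["statistic"]), by_hand, tolerance = 1e-9)
  expect_equal(unname(ft["p_value"]), pf(by_hand, 1, 22, lower.tail = FALSE),
               tolerance = 1e-9)

  # adding a pure-noise column yields uniform p-values under the null
  n <- 30
  withr::with_seed(11, {
    X <- data.frame(x1 = rnorm(n), junk = rnorm(n))
    pvals <- replicate(1500, {
      y <- exp(1 + 0.5 * X$x1 + rnorm(n, 0, 0.6))
      f <- fit_unit_cost_model(uc_design(y, X), "ols")
      r <- fit_unit_cost_model(uc_design(y, X["x1"]), "ols")
      unname(uc_f_test(f, r)["p_value"])
    })
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("variance inflation factors match their defining auxiliary regressions", {
  # orthogonal columns: all VIF equal 1
  X <- data.frame(a = rep(c(-1, 1), 10), b = rep(c(-1, -1, 1, 1), 5))
  expect_equal(unname(uc_vif(X)), c(1, 1), tolerance = 1e-12)

  # duplicated column: infinite, flagged
  Xd <- data.frame(a = rnorm(20))
  Xd$b <- Xd$a
  expect_warning(v <- uc_vif(Xd), "collinear")
  expect_true(all(is.infinite(v)))

  # correlated 3-column instance against car's implementation
  withr::with_seed(5, {
    Z <- data.frame(x = rnorm(50))
    Z$y <- 0.8 * Z$x + rnorm(50, 0, 0.5)
    Z$z <- rnorm(50)
  })
  mine <- uc_vif(Z)
  resp <- rnorm(50)
  oracle <- car::vif(lm(resp ~ x + y + z, data = Z))
  expect_equal(unname(mine), unname(oracle), tolerance = 1e-9)
})

test_that("the Breusch-Pagan test scores n times the auxiliary R-squared", {
  d <- random_design(100, c(1, 0.5, -0.3), sigma = 0.6, seed = 6)
  f <- fit_unit_cost_model(d, "ols")
  e2 <- residuals(f)^2
  aux <- summary(lm(e2 ~ x1 + x2, data = d$frame))$r.squared
  expect_equal(unname(f$bp_test["statistic"]), 100 * aux, tolerance = 1e-9)
  expect_equal(unname(f$bp_test["p_value"]),
               pchisq(100 * aux, 2, lower.tail = FALSE), tolerance = 1e-9)

  # noiseless fit: constant (zero) residuals carry no signal
  d0 <- random_design(30, c(1, 0.5, -0.3), sigma = 0, seed = 6)
  f0 <- fit_unit_cost_model(d0, "ols")
  expect_equal(unname(f0$bp_test[c("statistic", "p_value")]), c(0, 1))

  # power: residual spread tied to a covariate is detected at n = 500
  rej <- withr::with_seed(12, mean(replicate(200, {
    x <- runif(500, 0.2, 2)
    y <- exp(1 + 0.3 * x + rnorm(500, 0, 0.4 * x))
    ff <- fit_unit_cost_model(uc_design(y, data.frame(x = x, w = rnorm(500))),
                              "ols")
    ff$bp_test["p_value"] < 0.05
  })))
  expect_gt(rej, 0.8)
})

test_that("the smearing factor is the mean exponentiated residual", {
  expect_equal(smearing_factor(rep(0, 5)), 1)
  expect_equal(smearing_factor(c(log(2), -log(2))), 1.25)
  r <- withr::with_seed(13, rnorm(1e6, 0, 0.5))
  expect_lt(abs(smearing_factor(r) / exp(0.5^2 / 2) - 1), 0.005)
})

test_that("least-squares invariants hold: zero-sum residuals and coefficient equivariance", {
  d <- random_design(80, c(1, 0.5, -0.7), sigma = 0.5, seed = 8)
  f <- fit_unit_cost_model(d, "ols")
  expect_lt(abs(sum(residuals(f))), 1e-9 * d$n)

  scaled <- d$frame
  scaled$x1 <- scaled$x1 * 10
  fs <- fit_unit_cost_model(uc_design(d$uc, scaled), "ols")
  expect_equal(coef(fs)[["x1"]], coef(f)[["x1"]] / 10, tolerance = 1e-12)
  expect_equal(coef(fs)[["x2"]], coef(f)[["x2"]], tolerance = 1e-12)
})

test_that("fits recover the generating facility-level coefficients at large n", {
  cfg <- sim_config(n_facilities = 5000)
  st <- quick_study(seed = 21, config = cfg)
  fit <- fit_cost_curve(st$facilities, st$contexts)
  truth <- cfg$true_coefficients_eq1
  # the generator recentres the covariate contribution, shifting only the
  # recoverable intercept
  truth[["alpha"]] <- truth[["alpha"]] - attr(st$facilities, "calibration")
  est <- coef(fit)[names(truth)]
  expect_true(all(abs(est - truth) <= 3 * fit$se[names(truth)]))
})

test_that("robust standard errors are reported alongside classical ones", {
  d <- random_design(60, c(1, 0.5, -0.7), sigma = 0.5, seed = 9)
  f <- fit_unit_cost_model(d, "ols")
  expect_true(all(f$robust_se > 0))
  expect_equal(names(f$robust_se), names(f$se))
  expect_equal(unname(f$robust_se),
               unname(sqrt(diag(sandwich::vcovHC(f$fit, type = "HC1")))),
               tolerance = 1e-12)
  s <- summary(f, robust = TRUE)
  expect_equal(s$table$se, unname(f$robust_se))
})
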