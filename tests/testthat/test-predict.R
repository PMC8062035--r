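test_that("cost curves are monotone without the squared term and parallel across platforms", {
  st <- quick_study(seed = 31, n_facilities = 400)
  fit <- fit_cost_curve(st$facilities, st$contexts)

  # force a pure log-linear scale effect to check monotonicity
  fit_mono <- fit
  fit_mono$coefficients[["scale_log"]] <- -0.2
  fit_mono$coefficients[["scale_log_sq"]] <- 0
  grid <- c(50, 100, 500, 1000, 5000)
  pts <- curve_points(fit_mono, c(gdp_log = log(2000)), grid)
  expect_true(all(diff(pts$predicted_uc) < 0))

  # hospital vs clinic curves: constant log-scale gap equal to the
  # hospital coefficient
  base <- c(gdp_log = log(2000), year_offset = -3)
  hosp <- c(base, hospital = 1)
  p_clin <- curve_points(fit, base, grid)
  p_hosp <- curve_points(fit, hosp, grid)
  gap <- log(p_hosp$predicted_uc) - log(p_clin$predicted_uc)
  expect_lt(max(abs(gap - coef(fit)[["hospital"]])), 1e-12)

  expect_error(curve_points(fit, c(bogus = 1), grid), "bogus")
  expect_error(curve_points(fit, base, c(-5, 10)))
})

test_that("an intercept-only truth yields a flat curve at the exponentiated constant", {
  cfg <- sim_config()
  beta0 <- cfg$true_coefficients_eq1
  beta0[] <- 0
  beta0[["alpha"]] <- 4.13
  ctx <- generate_contexts(cfg, seed = 1)
  fac <- generate_facilities(cfg, ctx, seed = 2)
  costed <- simulate_costs(fac, ctx, cfg, coefficients = beta0,
                           dispersion = 0, seed = 3, denominate = "usd2016")
  fit <- fit_cost_curve(compute_unit_cost(costed), ctx)
  pts <- curve_points(fit, c(), c(10, 100, 1000))
  expect_equal(pts$predicted_uc, rep(exp(4.13), 3), tolerance = 1e-8)
  expect_equal(pts$lo95, pts$hi95, tolerance = 1e-8)
})

test_that("predictions respond to covariates exactly as the log-linear form dictates", {
  g <- generate_sdp_dataset(sim_config(), n = 80, n_countries = 10, seed = 41)
  fit <- fit_extrapolation(g$sdp, g$contexts)
  frame <- fit$design$frame[1, , drop = FALSE]
  doubled <- frame
  doubled$gdp_log <- frame$gdp_log + log(2)
  p1 <- predict(fit, frame)
  p2 <- predict(fit, doubled)
  expect_equal(p2$point_usd / p1$point_usd, 2^coef(fit)[["gdp_log"]],
               tolerance = 1e-12)
})

test_that("interval kinds are ordered and degenerate training collapses them", {
  g <- generate_sdp_dataset(sim_config(), n = 60, n_countries = 10, seed = 42)
  fit <- fit_extrapolation(g$sdp, g$contexts)
  nd <- fit$design$frame[1:5, ]
  ci <- predict(fit, nd, interval = "confidence")
  pi <- predict(fit, nd, interval = "prediction")
  expect_true(all(ci$lo_usd <= ci$point_usd & ci$point_usd <= ci$hi_usd))
  expect_true(all(pi$lo_usd <= ci$lo_usd & pi$hi_usd >= ci$hi_usd))

  # zero-noise training: lo = point = hi
  g0 <- generate_sdp_dataset(sim_config(), n = 60, n_countries = 10,
                             seed = 42, dispersion = 0)
  fit0 <- fit_extrapolation(g0$sdp, g0$contexts)
  p0 <- predict(fit0, fit0$design$frame[1:3, ], interval = "prediction")
  expect_equal(p0$lo_usd, p0$point_usd, tolerance = 1e-6)
  expect_equal(p0$hi_usd, p0$point_usd, tolerance = 1e-6)

  # intercept-only fit on constant costs predicts that constant
  fitc <- fit_unit_cost_model(uc_design(rep(42, 10)), "ols")
  pc <- predict(fitc, data.frame(row.names = 1))
  expect_equal(pc$point_usd, 42, tolerance = 1e-9)
})

test_that("extrapolation covers the full platform grid for any country list", {
  cfg <- sim_config()
  g <- generate_sdp_dataset(cfg, n = 60, n_countries = 10, seed = 43)
  fit <- fit_extrapolation(g$sdp, g$contexts)

  ctx14 <- generate_contexts(cfg, seed = 44, n_countries = 14, gdp_spread = 4)
  tab <- suppressWarnings(
    extrapolate_all(fit, ctx14$countries$country, ctx14))
  expect_equal(nrow(tab), 112)
  expect_true(all(tab$lo95_usd <= tab$point_usd &
                    tab$point_usd <= tab$hi95_usd))
  expect_equal(tab$country, rep(ctx14$countries$country, each = 8))

  tab8 <- suppressWarnings(
    extrapolate_all(fit, ctx14$countries$country[1:8], ctx14))
  expect_equal(nrow(tab8), 64)
  tab1 <- suppressWarnings(
    extrapolate_all(fit, ctx14$countries$country[1], ctx14))
  expect_equal(nrow(tab1), 8)

  expect_error(extrapolate_all(fit, c("SC001", "NOPE"), ctx14), "NOPE")
})

test_that("out-of-range target covariates trigger an extrapolation warning", {
  cfg <- sim_config()
  g <- generate_sdp_dataset(cfg, n = 60, n_countries = 10, seed = 45)
  fit <- fit_extrapolation(g$sdp, g$contexts)
  rich <- data.frame(country = "RICH", currency = "USD",
                     gdp_per_capita_2016 = 1e6,
                     salary_index = 0.5, vmmc_coverage = 0.5)
  expect_warning(extrapolate_all(fit, "RICH", rich), "gdp_log")
})

test_that("single-platform prediction accepts string keys", {
  g <- generate_sdp_dataset(sim_config(), n = 60, n_countries = 10, seed = 46)
  fit <- fit_extrapolation(g$sdp, g$contexts)
  key <- paste(g$contexts$countries$country[1], "clinic", "public", "urban",
               sep = "/")
  p <- predict_sdp(fit, key, g$contexts)
  expect_equal(nrow(p), 1)
  expect_true(p$lo95_usd <= p$point_usd && p$point_usd <= p$hi95_usd)
  expect_error(predict_sdp(fit, "too/few", g$contexts), "key")
})

test_that("smearing retransformation scales points and bounds together", {
  st <- quick_study(seed = 32, n_facilities = 300)
  fit <- fit_cost_curve(st$facilities, st$contexts)
  expect_gte(fit$smearing_factor, 1)
  nd <- fit$design$frame[1:4, ]
  sm <- predict(fit, nd, interval = "confidence")
  nv <- predict(fit, nd, interval = "confidence", retransform = "naive")
  expect_equal(sm$point_usd / nv$point_usd,
               rep(fit$smearing_factor, 4), tolerance = 1e-12)
  expect_equal(sm$lo_usd / nv$lo_usd, rep(fit$smearing_factor, 4),
               tolerance = 1e-12)
})
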