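test_that("default configuration encodes the study conditions", {
  cfg <- sim_config()
  expect_equal(cfg$n_countries, 8L)
  expect_equal(cfg$n_facilities, 220L)
  expect_equal(cfg$covariate_mix[["private"]], 0.36)
  expect_equal(cfg$covariate_mix[["rural"]], 0.50)
  expect_equal(cfg$covariate_mix[["hospital"]], 0.47)
  expect_equal(cfg$covariate_mix[["outreach"]], 0.13)
  expect_equal(cfg$true_coefficients_eq1[["hospital"]], 0.61)
  expect_equal(cfg$true_coefficients_eq1[["scale_log"]], -0.13)
  expect_equal(cfg$true_coefficients_eq2[["gdp_log"]], 0.47)
  expect_equal(cfg$target_r2, 0.56)

  # method-of-moments lognormal: sdlog^2 = log(1 + (sd/mean)^2)
  s2 <- log(1 + (1796 / 1097)^2)
  expect_equal(cfg$scale_sdlog, sqrt(s2))
  expect_equal(cfg$scale_meanlog, log(1097) - s2 / 2)
  draws <- withr::with_seed(4, rlnorm(1e6, cfg$scale_meanlog, cfg$scale_sdlog))
  expect_lt(abs(mean(draws) / 1097 - 1), 0.01)
  expect_lt(abs(sd(draws) / 1796 - 1), 0.01)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(sim_config(n_countries = 0))
  expect_error(sim_config(covariate_mix = c(rural = 1.5, private = 0.3,
                                            hospital = 0.4, outreach = 0.1)))
  expect_error(sim_config(dispersion = -1))
  expect_error(sim_config(cost_shares = c(capital = 0.5, recurrent = 0.5,
                                          personnel = 0.5)))
})

test_that("context generation is sized, deterministic and mean-calibrated", {
  cfg <- sim_config()
  ctx <- generate_contexts(cfg, seed = 1)
  expect_equal(nrow(ctx$countries), 8)
  expect_false(anyDuplicated(ctx$countries$country) > 0)
  expect_identical(ctx, generate_contexts(cfg, seed = 1))
  expect_true(all(ctx$fx$rate > 0))
  expect_true(all(ctx$deflator$index > 0))
  expect_equal(ctx$deflator$index[ctx$deflator$year == 2016], 1)
  expect_true(all(ctx$countries$salary_index > 0 &
                    ctx$countries$salary_index < 1))
  expect_true(all(ctx$countries$vmmc_coverage >= 0 &
                    ctx$countries$vmmc_coverage <= 1))

  big <- generate_contexts(cfg, seed = 2, n_countries = 1e4)
  expect_lt(abs(mean(big$countries$gdp_per_capita_2016) / cfg$gdp_center - 1),
            0.1)
})

test_that("facility generation matches the configured mix and counts", {
  cfg <- sim_config()
  ctx <- generate_contexts(cfg, seed = 1)
  fac <- generate_facilities(cfg, ctx, seed = 2)
  expect_equal(nrow(fac), 220)
  expect_identical(fac, generate_facilities(cfg, ctx, seed = 2))
  expect_true(all(fac$annual_vmmc >= 1))
  expect_true(all(fac$year %in% 2008:2013))

  big_cfg <- sim_config(n_facilities = 1e5)
  big <- generate_facilities(big_cfg, generate_contexts(big_cfg, seed = 1),
                             seed = 3)
  expect_lt(abs(mean(big$urbanicity == "rural") - 0.50), 0.01)
  expect_lt(abs(mean(big$ownership == "private") - 0.36), 0.01)
  expect_lt(abs(mean(big$facility_type == "hospital") - 0.47), 0.01)
  expect_lt(abs(mean(big$delivery_model == "outreach") - 0.13), 0.01)
})

test_that("noise calibration follows the closed form and drives empirical R2", {
  expect_equal(calibrate_noise_r2(1, 0.5), 1)
  expect_equal(calibrate_noise_r2(2, 0.8), sqrt(0.5))
  v <- 3.7
  expect_equal(calibrate_noise_r2(v, 0.56), sqrt(v * 0.44 / 0.56))
  expect_error(calibrate_noise_r2(1, 0))
  expect_error(calibrate_noise_r2(1, 1))
  expect_error(calibrate_noise_r2(-1, 0.5))

  # empirical check: R2 of a univariate fit converges to the target
  withr::with_seed(9, {
    x <- rnorm(2e4)
    y <- 2 * x + rnorm(2e4, 0, calibrate_noise_r2(4, 0.7))
  })
  expect_lt(abs(summary(lm(y ~ x))$r.squared - 0.7), 0.02)
})

test_that("simulated costs follow the generating model exactly at zero noise", {
  cfg <- sim_config(dispersion = 0)
  ctx <- generate_contexts(cfg, seed = 1)
  fac <- generate_facilities(cfg, ctx, seed = 2)
  costed <- simulate_costs(fac, ctx, cfg, seed = 3, denominate = "usd2016")
  uc <- compute_unit_cost(costed)$unit_cost_2016usd
  expect_equal(log(uc), attr(costed, "lp"), tolerance = 1e-12)

  # all slopes zero: every unit cost equals exp(intercept)
  beta0 <- cfg$true_coefficients_eq1
  beta0[] <- 0
  beta0[["alpha"]] <- 4.13
  costed0 <- simulate_costs(fac, ctx, cfg, coefficients = beta0,
                            dispersion = 0, seed = 3, denominate = "usd2016")
  uc0 <- compute_unit_cost(costed0)$unit_cost_2016usd
  expect_equal(uc0, rep(exp(4.13), nrow(fac)), tolerance = 1e-12)
})

test_that("cost simulation errors on facilities without a country context", {
  cfg <- sim_config()
  ctx <- generate_contexts(cfg, seed = 1)
  fac <- generate_facilities(cfg, ctx, seed = 2)
  fac$country[1] <- "ZZZ"
  expect_error(simulate_costs(fac, ctx, cfg, seed = 3), "ZZZ")
})

test_that("the calibrated generator reproduces the study's cost level", {
  means <- vapply(1:10, function(s) {
    st <- quick_study(seed = s)
    mean(st$facilities$unit_cost_2016usd)
  }, numeric(1))
  expect_lt(abs(mean(means) / 66 - 1), 0.15)
})

test_that("gamma noise produces positive costs with the requested log-scale spread", {
  cfg <- sim_config(noise_model = "gamma", dispersion = 0.4)
  ctx <- generate_contexts(cfg, seed = 1)
  fac <- generate_facilities(cfg, ctx, seed = 2)
  costed <- simulate_costs(fac, ctx, cfg, seed = 3, denominate = "usd2016")
  uc <- compute_unit_cost(costed)$unit_cost_2016usd
  expect_true(all(uc > 0))
  resid <- log(uc) - attr(costed, "lp")
  expect_lt(abs(sd(resid) - 0.4), 0.08)
})

test_that("SDP dataset generation matches its generating model", {
  cfg <- sim_config()
  g <- generate_sdp_dataset(cfg, n = 60, n_countries = 10, seed = 11)
  expect_equal(nrow(g$sdp), 60)
  expect_true(all(g$sdp$unit_cost_2016usd > 0))
  expect_identical(g, generate_sdp_dataset(cfg, n = 60, n_countries = 10,
                                           seed = 11))

  # zero noise: the SDP-level regression interpolates exactly
  g0 <- generate_sdp_dataset(cfg, n = 60, n_countries = 10, seed = 11,
                             dispersion = 0)
  fit <- fit_extrapolation(g0$sdp, g0$contexts)
  truth <- cfg$true_coefficients_eq2
  expect_equal(coef(fit)[names(truth)], truth, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
})

test_that("the SDP linear predictor reproduces a hand-computed reference cell", {
  # clinic/public/urban cell, GDP = e, salary 0, coverage 0:
  # log unit cost = alpha + gdp coefficient = -0.51 + 0.47
  cfg <- sim_config()
  ctx <- structure(list(
    countries = data.frame(country = sprintf("SC%03d", 1:2),
                           currency = "USD",
                           gdp_per_capita_2016 = exp(1),
                           salary_index = 0, vmmc_coverage = 0),
    fx = fixture_fx(), deflator = fixture_deflator()),
    class = "vmmc_contexts")
  g <- generate_sdp_dataset(cfg, n = 40, n_countries = 2, seed = 3,
                            dispersion = 0, contexts = ctx)
  cell <- g$sdp$facility_type == "clinic" & g$sdp$ownership == "public" &
    g$sdp$urbanicity == "urban"
  expect_true(any(cell))
  expect_equal(unique(log(g$sdp$unit_cost_2016usd[cell])), -0.51 + 0.47,
               tolerance = 1e-12)
})
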