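# Small in-code fixtures shared across test files.

fixture_fx <- function() {
  data.frame(currency = rep(c("XYZ", "ABC"), each = 9),
             year = rep(2008:2016, 2),
             rate = c(rep(9, 9), rep(120, 9)))
}

fixture_deflator <- function() {
  data.frame(year = 2008:2016, index = 1.018^((2008:2016) - 2016))
}

fixture_contexts <- function() {
  data.frame(country = c("AAA", "BBB", "CCC"),
             currency = c("XYZ", "ABC", "XYZ"),
             gdp_per_capita_2016 = c(1000, 3000, 2000),
             salary_index = c(0.2, 0.4, 0.3),
             vmmc_coverage = c(0.3, 0.6, 0.45),
             stringsAsFactors = FALSE)
}

fixture_facilities <- function(n = 6) {
  data.frame(
    facility_id = sprintf("F%02d", seq_len(n)),
    country = rep(c("AAA", "BBB"), length.out = n),
    year = rep(c(2012, 2013), length.out = n),
    facility_type = rep(c("hospital", "clinic"), length.out = n),
    ownership = rep(c("private", "public"), length.out = n),
    urbanicity = rep(c("rural", "urban"), length.out = n),
    delivery_model = rep(c("fixed", "fixed", "outreach"), length.out = n),
    annual_vmmc = seq(100, by = 150, length.out = n),
    cost_capital = seq(1000, by = 500, length.out = n),
    cost_recurrent = seq(3000, by = 400, length.out = n),
    cost_personnel = seq(4000, by = 300, length.out = n),
    cost_other = rep(0, n),
    currency = "USD",
    stringsAsFactors = FALSE
  )
}

# A generated, standardized study in 2016 USD (no currency round trip),
# small enough for fast tests.
quick_study <- function(seed = 1, n_facilities = 220, config = NULL, ...) {
  cfg <- if (is.null(config)) sim_config(n_facilities = n_facilities, ...)
  else config
  st <- simulate_study(cfg, seed = seed, denominate = "usd2016")
  st$facilities <- compute_unit_cost(st$facilities)
  st
}

# Random regression design for generic estimator tests.
random_design <- function(n, betas, sigma = 0, seed = 1) {
  withr::with_seed(seed, {
    p <- length(betas) - 1
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    lp <- betas[1] + as.vector(X %*% betas[-1])
    uc <- exp(lp + rnorm(n, 0, sigma))
    uc_design(uc, as.data.frame(X))
  })
}
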