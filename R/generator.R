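#' Configuration for the synthetic costing-study generator
#'
#' Builds the configuration object used by [generate_contexts()],
#' [generate_facilities()], [simulate_costs()] and [generate_sdp_dataset()].
#' The defaults emulate the pooled multi-country VMMC costing dataset the
#' package's models are designed for: 220 facilities across 8 countries,
#' half rural, 36% privately owned, 47% hospitals, 13% outreach, annual
#' circumcision volumes lognormal with mean 1,097 and standard deviation
#' 1,796, data-collection years 2008--2013, GDP per capita centred on
#' 2,252 USD, and log-scale noise calibrated so the facility-level model has
#' a population R-squared of 0.56.  The generating coefficients default to
#' the reference estimates in [reference_coefficients()].
#'
#' @param n_countries Number of synthetic countries.
#' @param n_facilities Total number of facilities across all countries.
#' @param covariate_mix Named proportions for `rural`, `private`, `hospital`
#'   and `outreach` facility attributes, each in `[0, 1]`.
#' @param scale_mean,scale_sd Mean and standard deviation of the annual
#'   number of circumcisions per facility; converted internally to lognormal
#'   `meanlog`/`sdlog` by method of moments.
#' @param years Calendar years of data collection to sample from (uniformly).
#' @param gdp_center Centre (arithmetic mean) of the GDP per capita
#'   distribution, 2016 USD.
#' @param gdp_spread Multiplicative half-range of the log-uniform GDP draw;
#'   the range is calibrated so the arithmetic mean equals `gdp_center`.
#' @param salary_range Range of the health-personnel salary index (uniform).
#' @param coverage_range Range of national VMMC coverage, as proportions.
#' @param noise_model `"lognormal"` (normal disturbance on the log scale,
#'   the default, matching the log-linear model) or `"gamma"`
#'   (multiplicative gamma disturbance, for GLM stress tests).
#' @param dispersion Noise dispersion: the log-scale standard deviation for
#'   `"lognormal"`, the gamma dispersion (1/shape) for `"gamma"`.  When
#'   `NULL`, the dispersion is calibrated at generation time from the
#'   realized signal variance via [calibrate_noise_r2()] and `target_r2`.
#' @param target_r2 Population R-squared of the facility-level log model used
#'   to calibrate noise when `dispersion` is `NULL`.
#' @param target_r2_sdp Same, for the SDP-level extrapolation model.
#' @param cost_shares Named shares splitting each facility's total cost into
#'   `capital`, `recurrent` and `personnel` components (must sum to 1; the
#'   split does not affect any estimator).
#' @param true_coefficients_eq1 Named generating coefficients for the
#'   facility-level model (see [reference_coefficients()]).
#' @param true_coefficients_eq2 Named generating coefficients for the
#'   SDP-level model.
#' @param seed Default integer seed used by the generator functions when no
#'   seed is passed explicitly; `NULL` leaves the RNG state alone.
#' @return An object of class `"vmmc_sim_config"`.
#' @examples
#' cfg <- sim_config()
#' cfg$covariate_mix[["private"]]  # 0.36
#' @export
sim_config <- function(n_countries = 8,
                       n_facilities = 220,
                       covariate_mix = c(rural = 0.50, private = 0.36,
                                         hospital = 0.47, outreach = 0.13),
                       scale_mean = 1097,
                       scale_sd = 1796,
                       years = 2008:2013,
                       gdp_center = 2252,
                       gdp_spread = 2,
                       salary_range = c(0.12, 0.52),
                       coverage_range = c(0.10, 0.88),
                       noise_model = c("lognormal", "gamma"),
                       dispersion = NULL,
                       target_r2 = 0.56,
                       target_r2_sdp = 0.68,
                       cost_shares = c(capital = 0.15, recurrent = 0.45,
                                       personnel = 0.40),
                       true_coefficients_eq1 = reference_coefficients("facility", "ols"),
                       true_coefficients_eq2 = reference_coefficients("sdp", "ols"),
                       seed = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(
    n_countries >= 1, n_facilities >= 1,
    all(c("rural", "private", "hospital", "outreach") %in% names(covariate_mix)),
    all(covariate_mix >= 0 & covariate_mix <= 1),
    scale_mean > 0, scale_sd > 0,
    gdp_center > 0, gdp_spread > 1,
    length(salary_range) == 2, length(coverage_range) == 2,
    all(coverage_range >= 0 & coverage_range <= 1),
    is.null(dispersion) || dispersion >= 0,
    is.null(target_r2) || (target_r2 > 0 && target_r2 < 1),
    abs(sum(cost_shares) - 1) < 1e-8,
    all(c("alpha", eq1_terms()) %in% names(true_coefficients_eq1)),
    all(c("alpha", eq2_terms()) %in% names(true_coefficients_eq2))
  )
  ln <- lognormal_params(scale_mean, scale_sd)
  structure(
    list(n_countries = as.integer(n_countries),
         n_facilities = as.integer(n_facilities),
         covariate_mix = covariate_mix,
         scale_mean = scale_mean, scale_sd = scale_sd,
         scale_meanlog = ln[["meanlog"]], scale_sdlog = ln[["sdlog"]],
         years = as.integer(years),
         gdp_center = gdp_center, gdp_spread = gdp_spread,
         salary_range = salary_range, coverage_range = coverage_range,
         noise_model = noise_model, dispersion = dispersion,
         target_r2 = target_r2, target_r2_sdp = target_r2_sdp,
         cost_shares = cost_shares,
         true_coefficients_eq1 = true_coefficients_eq1,
         true_coefficients_eq2 = true_coefficients_eq2,
         seed = seed),
    class = "vmmc_sim_config")
}

#' @export
print.vmmc_sim_config <- function(x, ...) {
  cat("Synthetic VMMC costing-study configuration\n")
  cat(sprintf("  %d facilities in %d countries; years %d-%d\n",
              x$n_facilities, x$n_countries, min(x$years), max(x$years)))
  cat(sprintf("  covariate mix: rural %.2f, private %.2f, hospital %.2f, outreach %.2f\n",
              x$covariate_mix[["rural"]], x$covariate_mix[["private"]],
              x$covariate_mix[["hospital"]], x$covariate_mix[["outreach"]]))
  cat(sprintf("  annual volumes ~ lognormal(mean %s, sd %s); GDP centre %s USD\n",
              format(x$scale_mean), format(x$scale_sd), format(x$gdp_center)))
  cat(sprintf("  noise: %s, %s\n", x$noise_model,
              if (is.null(x$dispersion))
                sprintf("calibrated to R-squared %.2f", x$target_r2)
              else sprintf("dispersion %.3f", x$dispersion)))
  invisible(x)
}

# Method-of-moments lognormal parameters: sdlog^2 = log(1 + (sd/mean)^2),
# meanlog = log(mean) - sdlog^2 / 2.
lognormal_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Generate synthetic country contexts
#'
#' Draws one context per synthetic country: GDP per capita (log-uniform with
#' the range calibrated so the arithmetic mean equals the configured centre),
#' health-personnel salary index, national VMMC coverage, HIV prevalence
#' (carried but unused by the final models), a local currency with exchange
#' rates per year, and a shared GDP deflator series with base year 2016.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed (defaults to `config$seed`).
#' @param n_countries Optional override of `config$n_countries`.
#' @param gdp_spread Optional override of `config$gdp_spread`.
#' @return An object of class `"vmmc_contexts"`: a list with components
#'   `countries` (data frame: `country`, `currency`, `gdp_per_capita_2016`,
#'   `salary_index`, `vmmc_coverage`, `hiv_prevalence`), `fx` (data frame:
#'   `currency`, `year`, `rate` in local units per USD) and `deflator`
#'   (data frame: `year`, `index`, with `index == 1` in 2016).
#' @export
generate_contexts <- function(config = sim_config(), seed = config$seed,
                              n_countries = config$n_countries,
                              gdp_spread = config$gdp_spread) {
  stopifnot(n_countries >= 1)
  with_seed_opt(seed, {
    country <- sprintf("SC%03d", seq_len(n_countries))
    currency <- sprintf("CU%03d", seq_len(n_countries))
    s <- gdp_spread
    # geometric centre g chosen so that E[gdp] = gdp_center for a
    # log-uniform draw on [g/s, g*s]: E = g * (s - 1/s) / (2 log s)
    g <- config$gdp_center * 2 * log(s) / (s - 1 / s)
    gdp <- exp(runif(n_countries, log(g) - log(s), log(g) + log(s)))
    salary <- runif(n_countries, config$salary_range[1], config$salary_range[2])
    coverage <- runif(n_countries, config$coverage_range[1], config$coverage_range[2])
    hiv <- runif(n_countries, 0.02, 0.28)
    fx_years <- seq(min(config$years), 2016L)
    base_rate <- exp(runif(n_countries, log(0.8), log(1500)))
    drift <- runif(n_countries, -0.02, 0.06)
    fx <- data.frame(
      currency = rep(currency, each = length(fx_years)),
      year = rep(fx_years, times = n_countries),
      rate = as.vector(t(outer(seq_len(n_countries), fx_years,
                               function(i, y) base_rate[i] * (1 + drift[i])^(y - min(fx_years)))))
    )
    # US-style deflator, 1.8% annual inflation, base 2016 = 1
    deflator <- data.frame(year = fx_years, index = 1.018^(fx_years - 2016))
    structure(
      list(countries = data.frame(country = country, currency = currency,
                                  gdp_per_capita_2016 = gdp,
                                  salary_index = salary,
                                  vmmc_coverage = coverage,
                                  hiv_prevalence = hiv,
                                  stringsAsFactors = FALSE),
           fx = fx, deflator = deflator),
      class = "vmmc_contexts")
  })
}

# Accept either a vmmc_contexts bundle or a bare countries data frame.
context_table <- function(contexts) {
  if (inherits(contexts, "vmmc_contexts")) return(contexts$countries)
  if (is.data.frame(contexts)) return(contexts)
  stop("`contexts` must be a vmmc_contexts object or a countries data frame")
}

#' Generate synthetic facility records (covariates only)
#'
#' Draws facility covariates: country assignment (as even as possible across
#' countries), binary attributes at the configured proportions, annual
#' circumcision volume from the configured lognormal rounded to a positive
#' integer, and a data-collection year sampled uniformly from
#' `config$years`.  Costs are left unset; see [simulate_costs()].
#'
#' @inheritParams generate_contexts
#' @param contexts Output of [generate_contexts()].
#' @return A data frame of facility records with columns `facility_id`,
#'   `country`, `year`, `facility_type`, `ownership`, `urbanicity`,
#'   `delivery_model`, `annual_vmmc`, `currency`.
#' @export
generate_facilities <- function(config = sim_config(),
                                contexts = generate_contexts(config),
                                seed = config$seed) {
  ctab <- context_table(contexts)
  stopifnot(nrow(ctab) >= 1)
  n <- config$n_facilities
  k <- nrow(ctab)
  counts <- diff(floor(seq(0, n, length.out = k + 1)))
  with_seed_opt(seed, {
    mix <- config$covariate_mix
    country <- rep(ctab$country, times = counts)
    vol <- rlnorm(n, config$scale_meanlog, config$scale_sdlog)
    data.frame(
      facility_id = sprintf("F%04d", seq_len(n)),
      country = country,
      year = sample(config$years, n, replace = TRUE),
      facility_type = ifelse(runif(n) < mix[["hospital"]], "hospital", "clinic"),
      ownership = ifelse(runif(n) < mix[["private"]], "private", "public"),
      urbanicity = ifelse(runif(n) < mix[["rural"]], "rural", "urban"),
      delivery_model = ifelse(runif(n) < mix[["outreach"]], "outreach", "fixed"),
      annual_vmmc = pmax(1L, as.integer(round(vol))),
      currency = ctab$currency[match(country, ctab$country)],
      stringsAsFactors = FALSE
    )
  })
}

#' Closed-form noise calibration for a target R-squared
#'
#' Returns the disturbance standard deviation `sigma` satisfying
#' `sigma^2 = signal_variance * (1 - target_r2) / target_r2`, so that a
#' linear model whose systematic part has variance `signal_variance` attains
#' population R-squared `target_r2`.
#'
#' @param signal_variance Variance of the linear predictor (must be > 0).
#' @param target_r2 Target population R-squared, in (0, 1).
#' @return The noise standard deviation.
#' @examples
#' calibrate_noise_r2(1, 0.5)   # 1
#' calibrate_noise_r2(2, 0.8)   # sqrt(0.5)
#' @export
calibrate_noise_r2 <- function(signal_variance, target_r2) {
  if (!is.numeric(signal_variance) || signal_variance <= 0)
    stop("`signal_variance` must be positive")
  if (!is.numeric(target_r2) || target_r2 <= 0 || target_r2 >= 1)
    stop("`target_r2` must lie strictly between 0 and 1")
  sqrt(signal_variance * (1 - target_r2) / target_r2)
}

# Linear predictor of the facility-level model for generation.  The
# covariate contribution is recentred by its log-mean-exp so that the
# sample mean of exp(lp) equals exp(alpha): the intercept then sets the
# average dollar-scale unit cost directly, keeping the simulated cost level
# at the calibrated study mean regardless of covariate scaling.  Slopes are
# untouched, so model fits recover the generating non-intercept
# coefficients; the recoverable intercept is alpha - calibration.
eq1_linear_predictor <- function(facilities, contexts, coefficients) {
  X <- eq1_frame(facilities, contexts)
  beta <- coefficients[colnames(X)]
  if (anyNA(beta))
    stop("generating coefficients missing terms: ",
         paste(setdiff(colnames(X), names(coefficients)), collapse = ", "))
  dev <- as.vector(as.matrix(X) %*% beta)
  calib <- if (all(dev == 0)) 0 else log(mean(exp(dev)))
  list(lp = coefficients[["alpha"]] + dev - calib, calibration = calib)
}

#' Simulate facility costs from the unit-cost model
#'
#' Fills cost components into facility records generated by
#' [generate_facilities()].  The log unit cost is the facility-level linear
#' predictor (coefficients `coefficients`, covariate coding as in
#' [facility_design()], covariate contribution recentred so the intercept
#' pins the average dollar-scale unit cost) plus a mean-zero log-scale
#' disturbance.  Total cost is unit cost times annual volume, split into
#' capital/recurrent/personnel at `config$cost_shares`, and by default
#' denominated in the facility's local currency at its data-collection year
#' (so that [standardize_facilities()] recovers the 2016-USD values).
#'
#' @inheritParams generate_facilities
#' @param facilities Facility records from [generate_facilities()].
#' @param coefficients Named generating coefficient vector.
#' @param noise_model,dispersion Override the configured noise model; a
#'   `dispersion` of 0 gives noiseless costs.  `NULL` dispersion calibrates
#'   the log-scale noise SD from the realized signal variance and
#'   `config$target_r2`.
#' @param denominate `"local"` (default) writes costs in local currency at
#'   the collection year; `"usd2016"` writes them directly in 2016 USD.
#' @return The facility data frame with columns `cost_capital`,
#'   `cost_recurrent`, `cost_personnel`, `cost_other` and `currency` filled.
#'   Attributes `lp` (generating log unit costs before noise), `noise_sd`
#'   and `calibration` record the generating process for testing.
#' @export
simulate_costs <- function(facilities, contexts, config = sim_config(),
                           coefficients = config$true_coefficients_eq1,
                           noise_model = config$noise_model,
                           dispersion = config$dispersion,
                           seed = config$seed,
                           denominate = c("local", "usd2016")) {
  denominate <- match.arg(denominate)
  ctab <- context_table(contexts)
  missing_ctx <- setdiff(unique(facilities$country), ctab$country)
  if (length(missing_ctx))
    stop("no country context for: ", paste(missing_ctx, collapse = ", "))
  pred <- eq1_linear_predictor(facilities, contexts, coefficients)
  lp <- pred$lp
  n <- length(lp)
  sigma <- dispersion
  if (is.null(sigma))
    sigma <- if (var(lp) == 0) 0 else calibrate_noise_r2(var(lp), config$target_r2)
  uc <- with_seed_opt(seed, {
    if (sigma == 0) {
      exp(lp)
    } else if (noise_model == "lognormal") {
      exp(lp + rnorm(n, 0, sigma))
    } else {
      # gamma multiplicative noise with mean 1; shape chosen so the
      # log-scale variance matches sigma^2 (trigamma(shape) = sigma^2)
      shape <- uniroot(function(k) trigamma(k) - sigma^2,
                       interval = c(1e-3, 1e6), tol = 1e-10)$root
      exp(lp) * rgamma(n, shape = shape, rate = shape)
    }
  })
  total_2016 <- uc * facilities$annual_vmmc
  sh <- config$cost_shares
  out <- facilities
  out$cost_capital <- total_2016 * sh[["capital"]]
  out$cost_recurrent <- total_2016 * sh[["recurrent"]]
  out$cost_personnel <- total_2016 * sh[["personnel"]]
  out$cost_other <- 0
  if (denominate == "local" && inherits(contexts, "vmmc_contexts")) {
    defl <- contexts$deflator
    idx <- defl$index[match(out$year, defl$year)] /
      defl$index[match(2016, defl$year)]
    fxr <- contexts$fx
    rate <- fxr$rate[match(paste(out$currency, out$year),
                           paste(fxr$currency, fxr$year))]
    adj <- idx * rate
    for (col in c("cost_capital", "cost_recurrent", "cost_personnel", "cost_other"))
      out[[col]] <- out[[col]] * adj
  } else {
    out$currency <- "USD"
    out$year_of_dollars <- 2016L
  }
  attr(out, "lp") <- lp
  attr(out, "noise_sd") <- sigma
  attr(out, "calibration") <- pred$calibration
  out
}

#' Generate a synthetic SDP-level dataset from the extrapolation model
#'
#' Draws SDP records directly at the service-delivery-platform level: each
#' record is a (country, facility type, ownership, urbanicity) cell sampled
#' uniformly from the country-by-platform grid, with log unit cost equal to
#' the SDP-level linear predictor (coding as in [sdp_design()]) plus
#' mean-zero lognormal noise calibrated to `config$target_r2_sdp` unless a
#' dispersion is given.
#'
#' @inheritParams simulate_costs
#' @param n Number of SDP records.
#' @param n_countries Number of synthetic countries to spread cells over.
#' @param gdp_spread GDP spread for the drawn contexts; the default is wider
#'   than the facility-level default because extrapolation target countries
#'   span a wider income range.
#' @param contexts Optional pre-drawn contexts (e.g. for controlled tests);
#'   drawn internally when `NULL`.
#' @return A list with components `sdp` (data frame: platform key fields,
#'   `unit_cost_2016usd`, `n_facilities`, `mean_scale`, `source`) and
#'   `contexts`.  Attributes `lp` and `noise_sd` on `sdp` record the truth.
#' @export
generate_sdp_dataset <- function(config = sim_config(), n = 47,
                                 n_countries = 10, seed = config$seed,
                                 coefficients = config$true_coefficients_eq2,
                                 dispersion = config$dispersion,
                                 gdp_spread = 4, contexts = NULL) {
  stopifnot(n >= length(coefficients) + 2)
  seeds <- if (is.null(seed)) list(NULL, NULL) else list(seed, seed + 1L)
  if (is.null(contexts))
    contexts <- generate_contexts(config, seed = seeds[[1]],
                                  n_countries = n_countries,
                                  gdp_spread = gdp_spread)
  ctab <- context_table(contexts)
  with_seed_opt(seeds[[2]], {
    country <- ctab$country[rep_len(seq_len(nrow(ctab)), n)]
    cells <- expand.grid(facility_type = c("clinic", "hospital"),
                         ownership = c("public", "private"),
                         urbanicity = c("urban", "rural"),
                         stringsAsFactors = FALSE)
    pick <- sample(8L, n, replace = TRUE)
    sdp <- data.frame(country = country, cells[pick, , drop = FALSE],
                      row.names = NULL, stringsAsFactors = FALSE)
    X <- eq2_frame(sdp, contexts)
    beta <- coefficients[colnames(X)]
    lp <- coefficients[["alpha"]] + as.vector(as.matrix(X) %*% beta)
    sigma <- dispersion
    if (is.null(sigma))
      sigma <- if (var(lp) == 0) 0 else
        calibrate_noise_r2(var(lp), config$target_r2_sdp)
    uc <- exp(lp + if (sigma == 0) 0 else rnorm(n, 0, sigma))
    sdp$unit_cost_2016usd <- uc
    sdp$n_facilities <- sample(1:12, n, replace = TRUE)
    sdp$mean_scale <- round(rlnorm(n, config$scale_meanlog, config$scale_sdlog))
    sdp$source <- "synthetic"
    attr(sdp, "lp") <- lp
    attr(sdp, "noise_sd") <- sigma
    list(sdp = sdp, contexts = contexts)
  })
}

#' Generate a complete synthetic costing study
#'
#' Convenience wrapper drawing contexts, facility covariates and costs in
#' one call with sub-seeds derived from `seed`.
#'
#' @inheritParams generate_contexts
#' @param denominate Passed to [simulate_costs()].
#' @return A list with components `facilities` (costed records) and
#'   `contexts`.
#' @export
simulate_study <- function(config = sim_config(), seed = config$seed,
                           denominate = "local") {
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL)
  else list(seed, seed + 1L, seed + 2L)
  contexts <- generate_contexts(config, seed = seeds[[1]])
  facilities <- generate_facilities(config, contexts, seed = seeds[[2]])
  facilities <- simulate_costs(facilities, contexts, config,
                               seed = seeds[[3]], denominate = denominate)
  list(facilities = facilities, contexts = contexts)
}
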