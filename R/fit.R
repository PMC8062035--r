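# Estimation machinery shared by the cost-curve and extrapolation stages.
# Two estimators are supported on the same design: least squares on the log
# unit cost ("ols") and a gamma GLM with log link on the raw unit cost
# ("glm").  Both imply multiplicative covariate effects; they coincide
# exactly when log cost is affine in the covariates (the zero-noise limit).

#' Fit a unit-cost regression model
#'
#' Low-level fitting function shared by [fit_cost_curve()] and
#' [fit_extrapolation()].  For `estimator = "ols"` the response is the log
#' unit cost and the fit minimises the residual sum of squares; the Duan
#' smearing factor (mean of exponentiated residuals) is recorded for
#' dollar-scale retransformation.  For `estimator = "glm"` the raw unit cost
#' is fitted by a gamma GLM with log link via iteratively reweighted least
#' squares (convergence tolerance 1e-8, at most 100 iterations, started from
#' the log-response least-squares solution); the Pearson dispersion is
#' recorded.  Heteroskedasticity-robust (HC1) standard errors, variance
#' inflation factors and -- for the log-linear fit -- the Breusch-Pagan test
#' are attached as diagnostics.
#'
#' @param design A `"uc_design"` object from [facility_design()] or
#'   [sdp_design()].
#' @param estimator `"ols"` or `"glm"`.
#' @return An object of class `"unit_cost_fit"`; see Details for components.
#'   Methods: `print`, `summary`, `coef`, `vcov`, `residuals`, `fitted`,
#'   `logLik`, `nobs`, `predict`, `simulate`, `plot`.
#' @details The returned object contains `coefficients` (named, intercept
#'   `alpha`), `vcov`, `se`, `robust_se`, `r_squared` and `smearing_factor`
#'   (log-linear fit only), `dispersion` (GLM only), `sigma` (residual SD of
#'   the log-linear fit), `log_likelihood`, `aic`, `bic`, `vif`, `bp_test`,
#'   `residuals` (log-scale), `n`, `p`, the `design`, and the underlying
#'   `stats` fit object as `fit`.
#' @export
fit_unit_cost_model <- function(design, estimator = c("ols", "glm")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(design, "uc_design"))
  # degenerate (noise-free) designs fit exactly; the stock warnings about
  # perfect fits and the NaN gamma AIC at zero dispersion are expected there
  quiet_degenerate(fit_unit_cost_model_impl(design, estimator))
}

quiet_degenerate <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit|NaNs produced", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

fit_unit_cost_model_impl <- function(design, estimator) {
  dat <- design$frame
  form <- if (length(design$terms)) reformulate(design$terms, response = ".y")
  else .y ~ 1
  if (estimator == "ols") {
    dat$.y <- design$response
    fit <- lm(form, data = dat)
    check_full_rank(fit, design)
    res <- residuals(fit)
    sm <- summary(fit)
    tss <- sum((design$response - mean(design$response))^2)
    r2 <- if (tss < 1e-300) 0 else sm$r.squared
    sigma <- sm$sigma
    dispersion <- NULL
    smear <- mean(exp(res))
    ll <- logLik(fit)
  } else {
    if (any(design$uc <= 0))
      stop("gamma GLM requires strictly positive unit costs", call. = FALSE)
    dat$.y <- design$uc
    # start at the log-response least-squares solution
    sdat <- dat
    sdat$.y <- design$response
    start <- coef(lm(form, data = sdat))
    fit <- glm(form, data = dat, family = Gamma(link = "log"),
               start = start,
               control = glm.control(epsilon = 1e-8, maxit = 100))
    check_full_rank(fit, design)
    if (!fit$converged)
      stop(sprintf("gamma GLM did not converge in %d IRLS iterations (deviance %.6g)",
                   fit$iter, fit$deviance), call. = FALSE)
    res <- log(design$uc) - fit$linear.predictors
    r2 <- NULL
    sigma <- NULL
    dispersion <- sum(residuals(fit, type = "pearson")^2) / fit$df.residual
    smear <- NULL
    ll <- logLik(fit)
  }
  beta <- coef(fit)
  names(beta)[names(beta) == "(Intercept)"] <- "alpha"
  V <- vcov(fit)
  dimnames(V) <- list(names(beta), names(beta))
  Vr <- sandwich::vcovHC(fit, type = "HC1")
  dimnames(Vr) <- dimnames(V)
  structure(
    list(estimator = estimator, model = design$model,
         coefficients = beta, vcov = V,
         se = sqrt(diag(V)), robust_se = sqrt(diag(Vr)),
         r_squared = r2, sigma = sigma, dispersion = dispersion,
         smearing_factor = smear,
         log_likelihood = as.numeric(ll),
         aic = AIC(fit), bic = BIC(fit),
         residuals = res, linear_predictors = as.vector(
           if (estimator == "ols") fitted(fit) else fit$linear.predictors),
         vif = if (length(design$terms) >= 2)
           suppressWarnings(uc_vif(design$frame)) else NULL,
         bp_test = if (estimator == "ols" && length(design$terms))
           bp_test_lm(fit) else NULL,
         n = design$n, p = design$p,
         df_residual = fit$df.residual,
         design = design, fit = fit),
    class = "unit_cost_fit")
}

check_full_rank <- function(fit, design) {
  if (fit$rank < design$p) {
    aliased <- design$terms[is.na(coef(fit))[-1]]
    stop("design is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  invisible(fit)
}

#' Fit the facility-level unit-cost curve
#'
#' Builds the facility-level design ([facility_design()]) and fits the
#' unit-cost curve: log unit cost on log annual volume and its square,
#' facility attributes, log GDP per capita, year of data collection and the
#' hospital-by-private interaction.  A non-significant squared-scale term
#' (|t| < 1.96) is flagged in the returned object.
#'
#' @param records Standardized facility records.
#' @param contexts Country contexts.
#' @param estimator `"ols"` (log-linear least squares, default) or `"glm"`
#'   (gamma log link).
#' @return A `"unit_cost_fit"` object (model `"facility"`).
#' @export
fit_cost_curve <- function(records, contexts, estimator = c("ols", "glm")) {
  estimator <- match.arg(estimator)
  fit <- fit_unit_cost_model(facility_design(records, contexts), estimator)
  tval <- fit$coefficients[["scale_log_sq"]] / fit$se[["scale_log_sq"]]
  fit$scale_sq_nonsignificant <- abs(tval) < 1.96
  fit
}

#' Fit the SDP-level extrapolation model
#'
#' Builds the SDP-level design ([sdp_design()]) and fits the extrapolation
#' model: log unit cost on log GDP per capita, platform attributes, the
#' health-personnel salary index and national VMMC coverage.
#'
#' @param sdp_records Pooled SDP records.
#' @inheritParams fit_cost_curve
#' @return A `"unit_cost_fit"` object (model `"sdp"`).
#' @export
fit_extrapolation <- function(sdp_records, contexts,
                              estimator = c("ols", "glm")) {
  estimator <- match.arg(estimator)
  if (nrow(sdp_records) < length(eq2_terms()) + 3)
    stop("too few SDP records to fit the extrapolation model", call. = FALSE)
  fit_unit_cost_model(sdp_design(sdp_records, contexts), estimator)
}

#' @export
print.unit_cost_fit <- function(x, ...) {
  cat(sprintf("Unit-cost model (%s level), estimator: %s\n", x$model,
              if (x$estimator == "ols") "log-linear least squares"
              else "gamma GLM, log link"))
  cat(sprintf("  n = %d, parameters = %d\n", x$n, x$p))
  print(round(x$coefficients, 4))
  if (!is.null(x$r_squared))
    cat(sprintf("  R-squared %.3f, smearing factor %.3f\n",
                x$r_squared, x$smearing_factor))
  if (!is.null(x$dispersion))
    cat(sprintf("  Pearson dispersion %.4f\n", x$dispersion))
  cat(sprintf("  AIC %.1f, BIC %.1f\n", x$aic, x$bic))
  invisible(x)
}

#' @export
coef.unit_cost_fit <- function(object, ...) object$coefficients

#' @export
vcov.unit_cost_fit <- function(object, robust = FALSE, ...) {
  if (robust) {
    V <- sandwich::vcovHC(object$fit, type = "HC1")
    dimnames(V) <- dimnames(object$vcov)
    V
  } else object$vcov
}

#' @export
residuals.unit_cost_fit <- function(object, ...) object$residuals

#' @export
fitted.unit_cost_fit <- function(object, ...) object$linear_predictors

#' @export
logLik.unit_cost_fit <- function(object, ...) logLik(object$fit)

#' @export
nobs.unit_cost_fit <- function(object, ...) object$n

#' Summarize a unit-cost model fit
#'
#' @param object A `"unit_cost_fit"`.
#' @param robust Report heteroskedasticity-robust (HC1) standard errors in
#'   place of classical ones.
#' @param ... Unused.
#' @return A `"summary.unit_cost_fit"` object whose print method shows the
#'   coefficient table with standard errors in parentheses and significance
#'   stars at the 0.01 / 0.05 / 0.1 levels, plus fit statistics and
#'   diagnostics.
#' @export
summary.unit_cost_fit <- function(object, robust = FALSE, ...) {
  se <- if (robust) object$robust_se else object$se
  tval <- object$coefficients / se
  pval <- if (object$estimator == "ols")
    2 * pt(abs(tval), object$df_residual, lower.tail = FALSE)
  else 2 * pnorm(abs(tval), lower.tail = FALSE)
  stars <- cut(pval, breaks = c(-Inf, 0.01, 0.05, 0.1, Inf),
               labels = c("***", "**", "*", ""))
  tab <- data.frame(estimate = object$coefficients, se = se,
                    statistic = tval, p_value = pval,
                    stars = as.character(stars),
                    stringsAsFactors = FALSE)
  structure(list(fit = object, table = tab, robust = robust),
            class = "summary.unit_cost_fit")
}

#' @export
print.summary.unit_cost_fit <- function(x, ...) {
  f <- x$fit
  cat(sprintf("Unit-cost model (%s level), estimator: %s\n", f$model,
              toupper(f$estimator)))
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("  %-20s %8.3f%-3s\n", rownames(x$table)[i],
                x$table$estimate[i], x$table$stars[i]))
    cat(sprintf("  %-20s (%5.3f)\n", "", x$table$se[i]))
  }
  cat(sprintf("  Observations: %d\n", f$n))
  if (!is.null(f$r_squared)) cat(sprintf("  R-squared: %.2f\n", f$r_squared))
  cat(sprintf("  AIC %.1f, BIC %.1f%s\n", f$aic, f$bic,
              if (x$robust) "  (robust HC1 SEs)" else ""))
  if (!is.null(f$bp_test))
    cat(sprintf("  Breusch-Pagan: %.2f (p = %.3f)\n",
                f$bp_test[["statistic"]], f$bp_test[["p_value"]]))
  if (any(is.finite(f$vif) & f$vif > 10))
    cat("  note: VIF > 10 for ",
        paste(names(f$vif)[is.finite(f$vif) & f$vif > 10], collapse = ", "), "\n")
  cat("  Significance: *** p<0.01, ** p<0.05, * p<0.1; SEs in parentheses\n")
  invisible(x)
}

#' Simulate responses from a fitted unit-cost model
#'
#' Draws new dollar-scale unit costs at the training covariates: lognormal
#' around the fitted log-scale mean for the log-linear fit, gamma with the
#' fitted Pearson dispersion for the GLM.
#'
#' @param object A `"unit_cost_fit"`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated unit costs.
#' @export
simulate.unit_cost_fit <- function(object, nsim = 1, seed = NULL, ...) {
  lp <- object$linear_predictors
  draw <- function() {
    if (object$estimator == "ols") exp(lp + rnorm(length(lp), 0, object$sigma))
    else {
      shape <- 1 / object$dispersion
      rgamma(length(lp), shape = shape, rate = shape / exp(lp))
    }
  }
  sims <- with_seed_opt(seed, replicate(nsim, draw()))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.unit_cost_fit <- function(x, ...) {
  obs <- exp(x$design$response)
  pred <- exp(x$linear_predictors) *
    (if (!is.null(x$smearing_factor)) x$smearing_factor else 1)
  plot(pred, obs, log = "xy",
       xlab = "Predicted unit cost (2016 USD)",
       ylab = "Observed unit cost (2016 USD)",
       main = sprintf("Unit-cost model (%s level)", x$model), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}
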