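# Regression diagnostics: variance inflation factors, Breusch-Pagan
# heteroskedasticity test, nested F-test, information criteria and the Duan
# smearing retransformation factor.

#' Variance inflation factors
#'
#' Computes `VIF_j = 1 / (1 - R2_j)` for each covariate, where `R2_j` is the
#' R-squared from regressing column `j` on all other covariates (with
#' intercept).  Perfectly collinear columns are reported as `Inf`.  A
#' warning is issued when any VIF exceeds 10.
#'
#' @param x A `"uc_design"`, `"unit_cost_fit"`, data frame or numeric matrix
#'   of covariate columns (intercept excluded).
#' @return Named numeric vector of VIFs.
#' @export
uc_vif <- function(x) {
  if (inherits(x, "unit_cost_fit")) x <- x$design
  if (inherits(x, "uc_design")) x <- x$frame
  X <- as.matrix(x)
  if (ncol(X) < 2) stop("VIF needs at least two covariate columns", call. = FALSE)
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)  # constant column: perfectly collinear with intercept
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  if (any(is.infinite(out)))
    warning("perfectly collinear column(s): ",
            paste(names(out)[is.infinite(out)], collapse = ", "), call. = FALSE)
  else if (any(out > 10))
    warning("VIF > 10 for: ", paste(names(out)[out > 10], collapse = ", "),
            call. = FALSE)
  out
}

# Breusch-Pagan (Koenker studentized form, statistic n * R2 of the
# squared-residual auxiliary regression) on an lm fit.
bp_test_lm <- function(fit) {
  e2 <- residuals(fit)^2
  if (var(e2) <= 1e-20 * (1 + mean(e2))^2) {
    # constant squared residuals carry no heteroskedasticity signal
    df <- length(coef(fit)) - 1
    return(c(statistic = 0, df = df, p_value = 1))
  }
  bp <- lmtest::bptest(fit)
  c(statistic = unname(bp$statistic), df = unname(bp$parameter),
    p_value = unname(bp$p.value))
}

#' Breusch-Pagan heteroskedasticity test
#'
#' Regresses squared residuals of the log-linear fit on the covariates and
#' refers `n * R2` of that auxiliary regression to a chi-squared
#' distribution with `p - 1` degrees of freedom.
#'
#' @param fit A `"unit_cost_fit"` with `estimator = "ols"`.
#' @return Named vector `c(statistic, df, p_value)`.
#' @export
bp_test <- function(fit) {
  stopifnot(inherits(fit, "unit_cost_fit"))
  if (fit$estimator != "ols")
    stop("the Breusch-Pagan test applies to the log-linear least-squares fit",
         call. = FALSE)
  fit$bp_test
}

#' Nested F-test between two unit-cost model fits
#'
#' Tests the joint significance of the terms dropped from the full model:
#' `F = ((RSS_r - RSS_f) / dp) / (RSS_f / (n - p_f))` with the p-value from
#' the F distribution.  Both fits must be log-linear least squares on the
#' same observations, with the reduced model's terms a subset of the full
#' model's.
#'
#' @param full,reduced `"unit_cost_fit"` objects, `estimator = "ols"`.
#' @return Named vector `c(statistic, df1, df2, p_value)`.
#' @export
uc_f_test <- function(full, reduced) {
  stopifnot(inherits(full, "unit_cost_fit"), inherits(reduced, "unit_cost_fit"))
  if (full$estimator != "ols" || reduced$estimator != "ols")
    stop("the F-test compares log-linear least-squares fits", call. = FALSE)
  if (full$n != reduced$n)
    stop("models must be fitted to the same observations", call. = FALSE)
  if (!all(reduced$design$terms %in% full$design$terms))
    stop("models are not nested: reduced terms must be a subset of full terms",
         call. = FALSE)
  if (setequal(reduced$design$terms, full$design$terms))
    return(c(statistic = 0, df1 = 0, df2 = full$df_residual, p_value = 1))
  rss_f <- sum(residuals(full)^2)
  rss_r <- sum(residuals(reduced)^2)
  dp <- full$p - reduced$p
  stat <- ((rss_r - rss_f) / dp) / (rss_f / full$df_residual)
  c(statistic = stat, df1 = dp, df2 = full$df_residual,
    p_value = pf(stat, dp, full$df_residual, lower.tail = FALSE))
}

#' Akaike and Bayesian information criteria
#'
#' For a fitted model, returns the stored AIC/BIC (computed from the full
#' likelihood, with the residual scale or dispersion counted as an estimated
#' parameter).  Alternatively computes `aic = -2*ll + 2*p` and
#' `bic = -2*ll + p*log(n)` from an explicit log-likelihood.
#'
#' @param object A `"unit_cost_fit"`, or a numeric log-likelihood.
#' @param p,n Parameter count and sample size (required when `object` is a
#'   log-likelihood).
#' @return Named vector `c(aic, bic)`.
#' @examples
#' information_criteria(-10, p = 3, n = 20)  # aic 26, bic 28.99
#' @export
information_criteria <- function(object, p = NULL, n = NULL) {
  if (inherits(object, "unit_cost_fit"))
    return(c(aic = object$aic, bic = object$bic))
  stopifnot(is.numeric(object), length(object) == 1, !is.null(p), !is.null(n))
  c(aic = -2 * object + 2 * p, bic = -2 * object + p * log(n))
}

#' Duan smearing retransformation factor
#'
#' The mean of the exponentiated log-scale residuals,
#' `mean(exp(residuals))`.  Multiplying exponentiated log-scale predictions
#' by this factor corrects the retransformation bias of the log-linear
#' model; for mean-zero residuals it is always at least 1 (Jensen).
#'
#' @param residuals Residuals from a log-linear fit, or a
#'   `"unit_cost_fit"`.
#' @return The smearing factor (scalar).
#' @examples
#' smearing_factor(c(log(2), -log(2)))  # 1.25
#' @export
smearing_factor <- function(residuals) {
  if (inherits(residuals, "unit_cost_fit")) {
    if (residuals$estimator != "ols")
      stop("smearing applies to the log-linear fit", call. = FALSE)
    residuals <- residuals$residuals
  }
  mean(exp(residuals))
}
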