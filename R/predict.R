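# Dollar-scale prediction from fitted unit-cost models: point predictions
# with Duan smearing retransformation (log-linear fit), confidence intervals
# for the conditional mean and prediction intervals for new observations,
# both formed on the log scale and exponentiated (hence asymmetric in
# dollars).

build_frame <- function(object, newdata, contexts) {
  if (inherits(newdata, "uc_design")) return(newdata$frame[, object$design$terms])
  stopifnot(is.data.frame(newdata))
  if (all(object$design$terms %in% names(newdata)))
    return(newdata[, object$design$terms, drop = FALSE])
  if (is.null(contexts))
    stop("`contexts` is required to build the design from raw records",
         call. = FALSE)
  builder <- if (object$model == "facility") eq1_frame else eq2_frame
  builder(newdata, contexts)[, object$design$terms, drop = FALSE]
}

#' Predict dollar-scale unit costs from a fitted model
#'
#' Computes the linear predictor at new covariates, its standard error, and
#' dollar-scale predictions.  For the log-linear fit the point prediction is
#' `exp(x'beta)` times the Duan smearing factor (`retransform = "naive"`
#' drops the factor); intervals use t quantiles on the log scale with
#' `se(x'beta)` (confidence) or `sqrt(se^2 + sigma^2)` (prediction) and are
#' retransformed with the same factor, so `lo <= point <= hi` always holds.
#' For the gamma GLM the point is `exp(x'beta)` with normal quantiles, and
#' the prediction interval widens the log-scale standard error by the
#' log-scale noise variance implied by the fitted dispersion.
#'
#' @param object A `"unit_cost_fit"`.
#' @param newdata New observations: a `"uc_design"`, a data frame already
#'   containing the design columns, or raw records (then `contexts` is
#'   required).
#' @param contexts Country contexts used to build the design from raw
#'   records.
#' @param interval `"none"`, `"confidence"` (conditional mean) or
#'   `"prediction"` (new observation).
#' @param level Interval coverage level.
#' @param retransform `"smearing"` (default) or `"naive"` exponentiation
#'   (log-linear fit only; the GLM needs no retransformation).
#' @param ... Unused.
#' @return A data frame with columns `point_usd`, `log_se` and -- unless
#'   `interval = "none"` -- `lo_usd`, `hi_usd` and `interval_kind`.
#' @export
predict.unit_cost_fit <- function(object, newdata = NULL, contexts = NULL,
                                  interval = c("none", "confidence", "prediction"),
                                  level = 0.95,
                                  retransform = c("smearing", "naive"), ...) {
  interval <- match.arg(interval)
  retransform <- match.arg(retransform)
  frame <- if (is.null(newdata)) object$design$frame
  else build_frame(object, newdata, contexts)
  X <- cbind(alpha = 1, as.matrix(frame))
  beta <- object$coefficients[colnames(X)]
  lp <- as.vector(X %*% beta)
  se_lp <- sqrt(rowSums((X %*% object$vcov) * X))
  factor <- if (object$estimator == "ols" && retransform == "smearing")
    object$smearing_factor else 1
  out <- data.frame(point_usd = exp(lp) * factor, log_se = se_lp)
  if (interval != "none") {
    noise_var <- if (object$estimator == "ols") object$sigma^2
    else trigamma(1 / object$dispersion)
    se_int <- if (interval == "confidence") se_lp
    else sqrt(se_lp^2 + noise_var)
    q <- if (object$estimator == "ols") qt((1 + level) / 2, object$df_residual)
    else qnorm((1 + level) / 2)
    out$lo_usd <- exp(lp - q * se_int) * factor
    out$hi_usd <- exp(lp + q * se_int) * factor
    out$interval_kind <- interval
    if (interval == "prediction") out$log_se <- se_int
  }
  rownames(out) <- NULL
  out
}

#' Cost-curve points across a scale grid
#'
#' Evaluates the fitted facility-level model over a grid of annual volumes
#' for one service delivery platform, returning dollar-scale predictions
#' with confidence bounds.  Because the model has no scale-by-attribute
#' interactions, curves for different platforms are parallel on the log
#' scale.
#'
#' @param fit A facility-level `"unit_cost_fit"`.
#' @param sdp_covariates Named values for the non-scale covariates
#'   (`hospital`, `private`, `rural`, `outreach` as 0/1, `gdp_log`,
#'   `year_offset`); omitted entries default to the reference coding (0:
#'   an urban public clinic with fixed delivery, GDP of 1 USD, year 2016).
#'   The `hospital_x_private` interaction is filled in automatically.
#' @param scale_grid Positive annual volumes at which to evaluate the curve.
#' @param retransform Passed to [predict.unit_cost_fit()].
#' @param level Confidence level for the bounds.
#' @return Data frame with columns `scale`, `predicted_uc`, `lo95`, `hi95`.
#' @export
curve_points <- function(fit, sdp_covariates = c(), scale_grid,
                         retransform = c("smearing", "naive"), level = 0.95) {
  stopifnot(inherits(fit, "unit_cost_fit"), fit$model == "facility",
            all(scale_grid > 0))
  retransform <- match.arg(retransform)
  cov <- setNames(rep(0, length(eq1_terms())), eq1_terms())
  known <- intersect(names(sdp_covariates), names(cov))
  cov[known] <- unlist(sdp_covariates)[known]
  extra <- setdiff(names(sdp_covariates),
                   c(names(cov), "scale_log", "scale_log_sq"))
  if (length(extra))
    stop("unknown covariate(s): ", paste(extra, collapse = ", "), call. = FALSE)
  cov[["hospital_x_private"]] <- cov[["hospital"]] * cov[["private"]]
  frame <- as.data.frame(as.list(cov))[rep(1, length(scale_grid)), , drop = FALSE]
  frame$scale_log <- log(scale_grid)
  frame$scale_log_sq <- log(scale_grid)^2
  pred <- predict(fit, frame, interval = "confidence", level = level,
                  retransform = retransform)
  data.frame(scale = scale_grid, predicted_uc = pred$point_usd,
             lo95 = pred$lo_usd, hi95 = pred$hi_usd)
}

#' Extrapolate unit costs for every platform in a set of countries
#'
#' Predicts the unit cost, with uncertainty, for all eight service delivery
#' platforms in each listed country -- including countries absent from the
#' training data, which are predicted from their country covariates alone.
#' A warning (not an error) is issued when target-country covariates fall
#' outside the range observed in training.
#'
#' @param fit An SDP-level `"unit_cost_fit"` from [fit_extrapolation()].
#' @param countries Character vector of target country codes.
#' @param contexts Country contexts covering every listed country (checked
#'   before any prediction is made).
#' @param interval `"confidence"` (default) or `"prediction"`.
#' @param level Interval coverage level.
#' @param retransform Passed to [predict.unit_cost_fit()].
#' @return Data frame with one row per platform (8 per country, in grid
#'   order): key fields, `point_usd`, `lo95_usd`, `hi95_usd`,
#'   `interval_kind`, `estimator`.
#' @export
extrapolate_all <- function(fit, countries, contexts,
                            interval = c("confidence", "prediction"),
                            level = 0.95,
                            retransform = c("smearing", "naive")) {
  stopifnot(inherits(fit, "unit_cost_fit"), fit$model == "sdp")
  interval <- match.arg(interval)
  retransform <- match.arg(retransform)
  ctab <- context_table(contexts)
  missing_ctx <- setdiff(unique(countries), ctab$country)
  if (length(missing_ctx))
    stop("no country context for: ", paste(missing_ctx, collapse = ", "),
         call. = FALSE)
  grid <- enumerate_sdp_grid(countries)
  frame <- eq2_frame(grid, contexts)
  train <- fit$design$frame
  outside <- vapply(c("gdp_log", "salary_index", "coverage"), function(col)
    any(frame[[col]] < min(train[[col]]) | frame[[col]] > max(train[[col]])),
    logical(1))
  if (any(outside))
    warning("extrapolating beyond the training range of: ",
            paste(names(outside)[outside], collapse = ", "), call. = FALSE)
  pred <- predict(fit, frame, interval = interval, level = level,
                  retransform = retransform)
  data.frame(grid,
             point_usd = pred$point_usd, lo95_usd = pred$lo_usd,
             hi95_usd = pred$hi_usd, interval_kind = interval,
             estimator = fit$estimator, stringsAsFactors = FALSE)
}

#' Predict the unit cost of a single service delivery platform
#'
#' Convenience wrapper around [predict.unit_cost_fit()] for one platform
#' key.
#'
#' @inheritParams extrapolate_all
#' @param key Platform key: either a one-row data frame with the key fields
#'   or a string `"country/facility_type/ownership/urbanicity"`.
#' @param interval `"confidence"` or `"prediction"`.
#' @return One-row data frame with the key fields and prediction columns.
#' @export
predict_sdp <- function(fit, key, contexts,
                        interval = c("confidence", "prediction"),
                        level = 0.95) {
  interval <- match.arg(interval)
  if (is.character(key)) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    if (length(parts) != 4)
      stop("key must be 'country/facility_type/ownership/urbanicity'",
           call. = FALSE)
    key <- data.frame(country = parts[1], facility_type = parts[2],
                      ownership = parts[3], urbanicity = parts[4],
                      stringsAsFactors = FALSE)
  }
  pred <- predict(fit, key, contexts = contexts, interval = interval,
                  level = level)
  cbind(key, point_usd = pred$point_usd, lo95_usd = pred$lo_usd,
        hi95_usd = pred$hi_usd, interval_kind = interval)
}
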