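# Leave-one-country-out (LOCO) validation of the extrapolation model: each
# country's SDP records are withheld in turn, the model is refitted on the
# remainder, the withheld platforms are predicted, and prediction accuracy
# is summarised.

#' Split pooled SDP records by withholding one country
#'
#' @param pooled Pooled SDP records with a `country` column (at least two
#'   countries).
#' @param country The country to withhold.
#' @return A list with components `train` (all other countries) and `test`
#'   (the withheld country); the two partition the input exactly.
#' @export
loco_split <- function(pooled, country) {
  require_columns(pooled, "country", "pooled records")
  if (length(unique(pooled$country)) < 2)
    stop("leave-one-country-out needs at least two countries", call. = FALSE)
  if (!country %in% pooled$country)
    stop(sprintf("country '%s' not present in the pooled records", country),
         call. = FALSE)
  is_test <- pooled$country == country
  list(train = pooled[!is_test, , drop = FALSE],
       test = pooled[is_test, , drop = FALSE])
}

#' Accuracy metrics for observed/predicted unit-cost pairs
#'
#' @param pairs Data frame with columns `observed` and `predicted` (2016
#'   USD), and optionally `lo` and `hi` (95% prediction bounds).
#' @return Named vector: `median_abs_error` (USD), `median_pct_error`
#'   (percent of the observed value) and `coverage_rate` (share of observed
#'   values inside their interval; `NA` without bounds).
#' @examples
#' prediction_metrics(data.frame(observed = c(10, 20), predicted = c(10, 25)))
#' @export
prediction_metrics <- function(pairs) {
  require_columns(pairs, c("observed", "predicted"), "pairs")
  if (nrow(pairs) == 0) stop("no pairs to score", call. = FALSE)
  abs_err <- abs(pairs$observed - pairs$predicted)
  pct_err <- 100 * abs_err / pairs$observed
  coverage <- if (all(c("lo", "hi") %in% names(pairs)))
    mean(pairs$observed >= pairs$lo & pairs$observed <= pairs$hi)
  else NA_real_
  c(median_abs_error = median(abs_err),
    median_pct_error = median(pct_err),
    coverage_rate = coverage)
}

#' Leave-one-country-out validation of the extrapolation model
#'
#' For each country in the pooled SDP data: refit the extrapolation model
#' without that country, predict its withheld platforms, and compare with
#' the observed unit costs.  "Not statistically different from observed" is
#' operationalized as the observed value lying inside the 95% prediction
#' interval; a standardized log-scale error is also reported so alternative
#' definitions can be applied downstream.
#'
#' @param pooled Pooled SDP records ([pool_sdp()] output or equivalent).
#' @param contexts Country contexts covering every country in `pooled`.
#' @param estimator `"ols"` or `"glm"`.
#' @param level Prediction-interval level.
#' @return An object of class `"uc_validation"`: a list with `records` (one
#'   row per pooled record: key fields, `observed_usd`, `predicted_usd`,
#'   `lo_usd`, `hi_usd`, `abs_error_usd`, `pct_error`, `std_log_error`,
#'   `covered`), the aggregate `median_abs_error_usd`, `median_pct_error`
#'   and `coverage_rate`, and the `estimator`.  Methods: `print`, `plot`
#'   (observed vs predicted with the 45-degree line).
#' @export
loco_validate <- function(pooled, contexts, estimator = c("ols", "glm"),
                          level = 0.95) {
  estimator <- match.arg(estimator)
  countries <- unique(pooled$country)
  if (length(countries) < 2)
    stop("leave-one-country-out needs at least two countries", call. = FALSE)
  p <- length(eq2_terms()) + 1L
  rows <- lapply(countries, function(ct) {
    split <- loco_split(pooled, ct)
    if (nrow(split$train) < p + 2)
      stop(sprintf("training set too small after removing '%s' (%d records, need %d)",
                   ct, nrow(split$train), p + 2), call. = FALSE)
    fit <- fit_extrapolation(split$train, contexts, estimator)
    pred <- predict(fit, split$test, contexts = contexts,
                    interval = "prediction", level = level)
    obs <- split$test$unit_cost_2016usd
    keep_cols <- intersect(c("country", "facility_type", "ownership",
                             "urbanicity", "source"), names(split$test))
    data.frame(split$test[keep_cols],
               observed_usd = obs,
               predicted_usd = pred$point_usd,
               lo_usd = pred$lo_usd, hi_usd = pred$hi_usd,
               abs_error_usd = abs(obs - pred$point_usd),
               pct_error = 100 * abs(obs - pred$point_usd) / obs,
               std_log_error = (log(obs) - log(pred$point_usd)) / pred$log_se,
               covered = obs >= pred$lo_usd & obs <= pred$hi_usd,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  records <- do.call(rbind, rows)
  records <- records[order(sdp_key(records)), , drop = FALSE]
  rownames(records) <- NULL
  metrics <- prediction_metrics(data.frame(observed = records$observed_usd,
                                           predicted = records$predicted_usd,
                                           lo = records$lo_usd,
                                           hi = records$hi_usd))
  structure(list(records = records,
                 median_abs_error_usd = unname(metrics["median_abs_error"]),
                 median_pct_error = unname(metrics["median_pct_error"]),
                 coverage_rate = unname(metrics["coverage_rate"]),
                 estimator = estimator, level = level),
            class = "uc_validation")
}

#' @export
print.uc_validation <- function(x, ...) {
  cat("Leave-one-country-out validation of the extrapolation model\n")
  cat(sprintf("  %d records, %d countries, estimator %s\n",
              nrow(x$records), length(unique(x$records$country)),
              toupper(x$estimator)))
  cat(sprintf("  median absolute error: %.2f USD\n", x$median_abs_error_usd))
  cat(sprintf("  median percent error:  %.1f%%\n", x$median_pct_error))
  cat(sprintf("  observed within %d%% prediction interval: %.1f%%\n",
              round(100 * x$level), 100 * x$coverage_rate))
  invisible(x)
}

#' @export
plot.uc_validation <- function(x, ...) {
  r <- x$records
  lim <- range(c(r$observed_usd, r$predicted_usd))
  plot(r$predicted_usd, r$observed_usd, xlim = lim, ylim = lim,
       xlab = "Predicted unit cost (2016 USD)",
       ylab = "Observed unit cost (2016 USD)",
       main = "Leave-one-country-out validation", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}
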