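# Design-matrix construction for the two unit-cost regressions.
#
# Coding conventions (reference categories carry the zero code):
#   hospital = 1 / clinic = 0;  private = 1 / public = 0;
#   rural = 1 / urban = 0;      outreach = 1 / fixed = 0;
#   scale enters as the natural log of annual volume plus its uncentred
#   square; GDP per capita enters in logs; year is coded year - 2016
#   (non-positive for historical data), so a positive coefficient means
#   costs rising toward 2016.

require_columns <- function(df, cols, what = "records") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

binary_code <- function(x, one, zero, field) {
  bad <- !(x %in% c(one, zero)) | is.na(x)
  if (any(bad))
    stop(sprintf("field '%s' has missing or unrecognised values (expected '%s'/'%s'): %s",
                 field, one, zero,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  as.numeric(x == one)
}

# Covariate frame for the facility-level model (no response column).
eq1_frame <- function(records, contexts) {
  ctab <- context_table(contexts)
  require_columns(records, c("country", "year", "facility_type", "ownership",
                             "urbanicity", "delivery_model", "annual_vmmc"))
  miss <- setdiff(unique(records$country), ctab$country)
  if (length(miss))
    stop("no country context for: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(is.na(records$annual_vmmc)) || any(records$annual_vmmc < 1))
    stop("annual_vmmc must be >= 1 for every record (log scale undefined otherwise)",
         call. = FALSE)
  gdp <- ctab$gdp_per_capita_2016[match(records$country, ctab$country)]
  if (any(is.na(gdp) | gdp <= 0))
    stop("gdp_per_capita_2016 must be positive for every country", call. = FALSE)
  hosp <- binary_code(records$facility_type, "hospital", "clinic", "facility_type")
  priv <- binary_code(records$ownership, "private", "public", "ownership")
  sl <- log(records$annual_vmmc)
  data.frame(
    scale_log = sl,
    scale_log_sq = sl^2,
    gdp_log = log(gdp),
    rural = binary_code(records$urbanicity, "rural", "urban", "urbanicity"),
    private = priv,
    hospital = hosp,
    outreach = binary_code(records$delivery_model, "outreach", "fixed",
                           "delivery_model"),
    year_offset = records$year - 2016,
    hospital_x_private = hosp * priv
  )
}

# Covariate frame for the SDP-level extrapolation model.
eq2_frame <- function(records, contexts) {
  ctab <- context_table(contexts)
  require_columns(records, c("country", "facility_type", "ownership",
                             "urbanicity"), "SDP records")
  require_columns(ctab, c("country", "gdp_per_capita_2016", "salary_index",
                          "vmmc_coverage"), "country contexts")
  miss <- setdiff(unique(records$country), ctab$country)
  if (length(miss))
    stop("no country context for: ", paste(miss, collapse = ", "), call. = FALSE)
  i <- match(records$country, ctab$country)
  gdp <- ctab$gdp_per_capita_2016[i]
  salary <- ctab$salary_index[i]
  coverage <- ctab$vmmc_coverage[i]
  for (v in c("gdp_per_capita_2016", "salary_index", "vmmc_coverage")) {
    val <- ctab[[v]][i]
    if (anyNA(val))
      stop(sprintf("country context missing %s for: %s", v,
                   paste(unique(records$country[is.na(val)]), collapse = ", ")),
           call. = FALSE)
  }
  if (any(gdp <= 0))
    stop("gdp_per_capita_2016 must be positive for every country", call. = FALSE)
  # coverage is stored as a proportion; values > 1 are read as percents
  if (any(coverage > 1)) coverage[coverage > 1] <- coverage[coverage > 1] / 100
  data.frame(
    gdp_log = log(gdp),
    rural = binary_code(records$urbanicity, "rural", "urban", "urbanicity"),
    private = binary_code(records$ownership, "private", "public", "ownership"),
    hospital = binary_code(records$facility_type, "hospital", "clinic",
                           "facility_type"),
    salary_index = salary,
    coverage = coverage
  )
}

new_uc_design <- function(response, uc, frame, model) {
  stopifnot(!anyNA(frame), !anyNA(response), nrow(frame) == length(response))
  if (nrow(frame) <= ncol(frame) + 1)
    stop("need more observations than parameters (n > p)", call. = FALSE)
  if (anyDuplicated(colnames(frame)))
    stop("design column names must be unique", call. = FALSE)
  structure(list(response = response, uc = uc, frame = frame,
                 model = model, terms = colnames(frame),
                 n = nrow(frame), p = ncol(frame) + 1L),
            class = "uc_design")
}

#' Construct a unit-cost design from raw unit costs and covariates
#'
#' General-purpose constructor for the estimation machinery in
#' [fit_unit_cost_model()]: the response is `log(uc)` for the log-linear
#' estimator and `uc` itself for the gamma GLM.  The purpose-built designs
#' [facility_design()] and [sdp_design()] should be preferred for the two
#' canonical models; this constructor supports custom specifications (e.g.
#' reduced models for nested tests).
#'
#' @param uc Positive unit costs.
#' @param frame Data frame (or matrix) of covariate columns; may have zero
#'   columns for an intercept-only model.
#' @param model Label carried on the design (`"custom"` by default).
#' @return A `"uc_design"` object.
#' @export
uc_design <- function(uc, frame = NULL, model = "custom") {
  stopifnot(is.numeric(uc), all(uc > 0))
  frame <- if (is.null(frame)) data.frame(row.names = seq_along(uc))
  else as.data.frame(frame)
  new_uc_design(log(uc), uc, frame, model)
}

#' Design matrix for the facility-level unit-cost curve
#'
#' Builds the regression design for the facility-level model: response
#' `log(unit_cost_2016usd)`; covariates log annual volume and its
#' (uncentred) square, log GDP per capita, rural/private/hospital/outreach
#' dummies, year of data collection coded `year - 2016`, and the
#' hospital-by-private interaction.
#'
#' @param records Standardized facility records (see
#'   [standardize_facilities()]) with positive `unit_cost_2016usd`.
#' @param contexts Country contexts ([generate_contexts()] output or a
#'   countries data frame).
#' @return A `"uc_design"` object.
#' @export
facility_design <- function(records, contexts) {
  require_columns(records, "unit_cost_2016usd")
  if (any(is.na(records$unit_cost_2016usd) | records$unit_cost_2016usd <= 0))
    stop("unit_cost_2016usd must be positive for every record", call. = FALSE)
  frame <- eq1_frame(records, contexts)[, eq1_terms()]
  new_uc_design(log(records$unit_cost_2016usd), records$unit_cost_2016usd,
                frame, "facility")
}

#' Design matrix for the SDP-level extrapolation model
#'
#' Builds the regression design for the SDP-level model: response
#' `log(unit_cost_2016usd)`; covariates log GDP per capita,
#' rural/private/hospital dummies, the health-personnel salary index and
#' national VMMC coverage (as a proportion).
#'
#' @param sdp_records SDP records ([collapse_to_sdp()] / [pool_sdp()] output)
#'   with positive `unit_cost_2016usd`.
#' @inheritParams facility_design
#' @return A `"uc_design"` object.
#' @export
sdp_design <- function(sdp_records, contexts) {
  require_columns(sdp_records, "unit_cost_2016usd", "SDP records")
  if (any(is.na(sdp_records$unit_cost_2016usd) | sdp_records$unit_cost_2016usd <= 0))
    stop("unit_cost_2016usd must be positive for every record", call. = FALSE)
  frame <- eq2_frame(sdp_records, contexts)[, eq2_terms()]
  new_uc_design(log(sdp_records$unit_cost_2016usd),
                sdp_records$unit_cost_2016usd, frame, "sdp")
}

#' @export
print.uc_design <- function(x, ...) {
  cat(sprintf("Unit-cost design (%s model): %d observations, %d parameters\n",
              x$model, x$n, x$p))
  cat("  terms:", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}
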