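# Plain-text interchange: all tables are CSV with documented headers.
# Money columns are 2016 USD after standardization; predictions are written
# with two decimals in a fixed, deterministic column and row order.

facility_schema <- function() {
  list(required = c("facility_id", "country", "year", "facility_type",
                    "ownership", "urbanicity", "delivery_model",
                    "annual_vmmc", "cost_capital", "cost_recurrent",
                    "cost_personnel", "cost_other", "currency"),
       numeric = c("year", "annual_vmmc", "cost_capital", "cost_recurrent",
                   "cost_personnel", "cost_other"))
}

read_table_checked <- function(path, required, numeric_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s %s is missing required column(s): %s", what, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & trimws(as.character(raw)) != "" & is.na(num))
    if (length(bad))
      stop(sprintf("%s %s: non-numeric '%s' in column '%s' at data row(s) %s",
                   what, path, raw[bad[1]], col,
                   paste(head(bad, 5), collapse = ", ")), call. = FALSE)
    df[[col]] <- num
  }
  df
}

#' Read facility records from CSV
#'
#' Expects the columns `facility_id`, `country`, `year`, `facility_type`,
#' `ownership`, `urbanicity`, `delivery_model`, `annual_vmmc`,
#' `cost_capital`, `cost_recurrent`, `cost_personnel`, `cost_other`,
#' `currency`.  Missing columns and non-numeric cost entries are reported
#' with column names and data row numbers.
#'
#' @param path CSV file path.
#' @return Data frame of facility records.
#' @export
read_facilities <- function(path) {
  sch <- facility_schema()
  read_table_checked(path, sch$required, sch$numeric, "facility file")
}

#' Read country contexts from CSV
#'
#' Expects `country`, `gdp_per_capita_2016`, `salary_index`,
#' `vmmc_coverage`; further columns (e.g. `currency`, `hiv_prevalence`) are
#' kept.
#'
#' @param path CSV file path.
#' @return Data frame of country contexts.
#' @export
read_contexts <- function(path) {
  read_table_checked(path,
                     c("country", "gdp_per_capita_2016", "salary_index",
                       "vmmc_coverage"),
                     c("gdp_per_capita_2016", "salary_index", "vmmc_coverage"),
                     "context file")
}

#' Read an exchange-rate table from CSV
#'
#' Expects `currency`, `year`, `rate` (local currency units per USD).
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_fx <- function(path) {
  read_table_checked(path, c("currency", "year", "rate"), c("year", "rate"),
                     "fx file")
}

#' Read a GDP-deflator series from CSV
#'
#' Expects `year`, `index` with the base year 2016 present.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_deflator <- function(path) {
  read_table_checked(path, c("year", "index"), c("year", "index"),
                     "deflator file")
}

#' Read SDP records from CSV
#'
#' Expects the platform key fields and `unit_cost_2016usd`.
#'
#' @param path CSV file path.
#' @return Data frame of SDP records.
#' @export
read_sdp <- function(path) {
  read_table_checked(path,
                     c("country", "facility_type", "ownership", "urbanicity",
                       "unit_cost_2016usd"),
                     c("unit_cost_2016usd"), "SDP file")
}

#' Write a table to CSV
#'
#' Thin wrapper with the package's conventions: no row names, no quoting of
#' numerics, deterministic output for identical input.
#'
#' @param df Data frame.
#' @param path Output path (directories are created).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write extrapolated unit-cost predictions to CSV
#'
#' Fixed column order (`country`, `facility_type`, `ownership`,
#' `urbanicity`, `point_usd`, `lo95_usd`, `hi95_usd`, `interval_kind`,
#' `estimator`), USD values rounded to 2 decimals, rows in the deterministic
#' grid order produced by [extrapolate_all()].
#'
#' @param predictions Output of [extrapolate_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  cols <- c("country", "facility_type", "ownership", "urbanicity",
            "point_usd", "lo95_usd", "hi95_usd", "interval_kind", "estimator")
  require_columns(predictions, setdiff(cols, "estimator"), "predictions")
  if (!"estimator" %in% names(predictions)) predictions$estimator <- NA
  out <- predictions[cols]
  for (col in c("point_usd", "lo95_usd", "hi95_usd"))
    out[[col]] <- round(out[[col]], 2)
  write_table(out, path)
}

#' Write a plain-text report for a fitted unit-cost model
#'
#' Serializes the coefficient table (standard errors in parentheses,
#' significance stars at 0.01/0.05/0.1), fit statistics and diagnostics.
#'
#' @param fit A `"unit_cost_fit"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  txt <- utils::capture.output(print(summary(fit)))
  writeLines(txt, path)
  invisible(path)
}

#' Write a generated study to CSV files
#'
#' Writes `facilities.csv`, `countries.csv`, `fx.csv` and `deflator.csv`
#' under `dir`.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(study$facilities, file.path(dir, "facilities.csv"))
  write_table(study$contexts$countries, file.path(dir, "countries.csv"))
  write_table(study$contexts$fx, file.path(dir, "fx.csv"))
  write_table(study$contexts$deflator, file.path(dir, "deflator.csv"))
  invisible(dir)
}
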