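# Standardization of raw facility cost records into comparable 2016-USD
# unit costs: currency conversion at the data-collection year, inflation to
# 2016 with a GDP implicit price deflator, input-category harmonization,
# unit-cost computation and exclusion rules.

#' Convert an amount from local currency to USD
#'
#' Divides by the exchange rate (local currency units per USD) for the given
#' year.  USD amounts pass through unchanged.  Vectorized over
#' `amount`/`currency`/`year`.
#'
#' @param amount Numeric amounts in `currency`.
#' @param currency Currency code(s); `"USD"` is the identity.
#' @param year Calendar year(s) whose exchange rate applies.
#' @param fx Exchange-rate table: data frame with columns `currency`, `year`,
#'   `rate` (local units per USD, positive).
#' @return Amounts in USD of the same year.
#' @export
convert_to_usd <- function(amount, currency, year, fx) {
  n <- length(amount)
  currency <- rep_len(currency, n)
  year <- rep_len(year, n)
  out <- amount
  need <- currency != "USD" & !is.na(amount)
  if (any(need)) {
    require_columns(fx, c("currency", "year", "rate"), "fx table")
    i <- match(paste(currency[need], year[need]), paste(fx$currency, fx$year))
    if (anyNA(i)) {
      bad <- unique(paste0(currency[need][is.na(i)], "/", year[need][is.na(i)]))
      stop("no exchange rate for: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    rate <- fx$rate[i]
    if (any(rate <= 0)) stop("exchange rates must be positive", call. = FALSE)
    out[need] <- amount[need] / rate
  }
  out
}

#' Inflate a USD amount to 2016 dollars
#'
#' Multiplies by `deflator(2016) / deflator(year)` using a GDP implicit
#' price deflator series.  Vectorized over `amount`/`year`.
#'
#' @param amount USD amounts expressed in `year` dollars.
#' @param year Calendar year(s) of the amounts.
#' @param deflator Data frame with columns `year`, `index` (positive); must
#'   include 2016.
#' @return Amounts in 2016 USD.
#' @export
inflate_to_2016 <- function(amount, year, deflator) {
  require_columns(deflator, c("year", "index"), "deflator table")
  if (any(deflator$index <= 0)) stop("deflator indices must be positive", call. = FALSE)
  base <- deflator$index[match(2016, deflator$year)]
  if (is.na(base)) stop("deflator series must include the base year 2016", call. = FALSE)
  idx <- deflator$index[match(year, deflator$year)]
  if (anyNA(idx) && any(!is.na(amount) & is.na(rep_len(idx, length(amount)))))
    stop("deflator missing for year(s): ",
         paste(unique(year[is.na(idx)]), collapse = ", "), call. = FALSE)
  amount * base / idx
}

#' Default input-category harmonization map
#'
#' Maps common cost line-item labels to the three broad input categories
#' used for VMMC unit costs: capital (non-consumables lasting over a year,
#' e.g. equipment and vehicles), recurrent (consumables such as HIV test and
#' disposable circumcision kits, maintenance, utilities, training) and
#' personnel (salaries of direct medical and non-medical staff).  Matching
#' in [harmonize_inputs()] is case-insensitive.
#'
#' @return A named character vector: line-item label -> category.
#' @export
default_category_map <- function() {
  c("vehicles" = "capital", "equipment" = "capital", "building" = "capital",
    "buildings" = "capital", "furniture" = "capital",
    "hiv test kits" = "recurrent", "circumcision kits" = "recurrent",
    "disposable circumcision kits" = "recurrent", "supplies" = "recurrent",
    "consumables" = "recurrent", "medicines" = "recurrent",
    "maintenance" = "recurrent", "utilities" = "recurrent",
    "training" = "recurrent", "transport" = "recurrent",
    "nurse salary" = "personnel", "physician salary" = "personnel",
    "salaries" = "personnel", "staff" = "personnel", "personnel" = "personnel",
    "managers" = "personnel", "supervisors" = "personnel",
    "ancillary staff" = "personnel")
}

#' Harmonize cost line items into input categories
#'
#' Sums named line items into the capital/recurrent/personnel/other
#' categories.  Items not covered by the map are assigned to `other` and
#' reported via the `"unmapped"` attribute (or rejected in strict mode);
#' nothing is silently dropped, so the category sums always conserve the
#' input total.
#'
#' @param items Named numeric vector of line-item amounts.
#' @param category_map Named character vector mapping lowercase labels to
#'   `"capital"`, `"recurrent"`, `"personnel"` or `"other"`.
#' @param strict If `TRUE`, unmapped labels are an error.
#' @return Named numeric vector `c(capital, recurrent, personnel, other)`
#'   with attribute `"unmapped"` listing unmapped labels.
#' @examples
#' harmonize_inputs(c("vehicles" = 10, "HIV test kits" = 5, "nurse salary" = 20))
#' @export
harmonize_inputs <- function(items, category_map = default_category_map(),
                             strict = FALSE) {
  out <- c(capital = 0, recurrent = 0, personnel = 0, other = 0)
  if (length(items) == 0) return(structure(out, unmapped = character()))
  if (is.null(names(items)) || any(!nzchar(names(items))))
    stop("every line item must be named", call. = FALSE)
  cat_of <- unname(category_map[tolower(names(items))])
  unmapped <- names(items)[is.na(cat_of)]
  if (length(unmapped) && strict)
    stop("unmapped line item(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  cat_of[is.na(cat_of)] <- "other"
  sums <- tapply(items, factor(cat_of, levels = names(out)), sum)
  out[names(sums)[!is.na(sums)]] <- sums[!is.na(sums)]
  structure(out, unmapped = unmapped)
}

#' Compute the unit cost of records already in 2016 USD
#'
#' The unit cost is the total annual cost (sum of capital, recurrent,
#' personnel and other components) divided by the annual number of
#' circumcisions performed.
#'
#' @param records Facility records with 2016-USD cost columns and
#'   `annual_vmmc`.
#' @return `records` with `unit_cost_2016usd` filled.
#' @export
compute_unit_cost <- function(records) {
  cost_cols <- c("cost_capital", "cost_recurrent", "cost_personnel", "cost_other")
  require_columns(records, c(cost_cols, "annual_vmmc"))
  if (any(is.na(records$annual_vmmc) | records$annual_vmmc < 1))
    stop("annual_vmmc must be >= 1; zero-output records are exclusions, not NaNs",
         call. = FALSE)
  costs <- as.matrix(records[cost_cols])
  if (any(costs < 0, na.rm = TRUE))
    stop("negative cost components are not allowed", call. = FALSE)
  records$unit_cost_2016usd <- rowSums(costs) / records$annual_vmmc
  records
}

#' Apply exclusion rules to facility or SDP records
#'
#' Partitions records into kept and excluded sets, attaching a
#' machine-readable reason to each exclusion:
#' `"missing_critical_input"` (personnel cost absent -- studies that failed
#' to measure staff costs underestimate the unit cost), `"missing_output"`
#' (annual volume missing or below one), `"nonpositive_total_cost"`, and
#' `"heterogeneous_sdp"` (records whose platform attributes are not a single
#' clean category, e.g. averages over a mixed sample).
#'
#' @param records Records to screen.
#' @param require_personnel Exclude records with missing personnel costs.
#' @return A list with components `kept` and `excluded`; `excluded` carries
#'   an `exclusion_reason` column.  `kept` and `excluded` partition the
#'   input.
#' @export
apply_exclusions <- function(records, require_personnel = TRUE) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  has <- function(col) col %in% names(records)
  if (has("facility_type") || has("ownership") || has("urbanicity")) {
    ok <- rep(TRUE, n)
    if (has("facility_type"))
      ok <- ok & records$facility_type %in% c("hospital", "clinic")
    if (has("ownership"))
      ok <- ok & records$ownership %in% c("private", "public")
    if (has("urbanicity"))
      ok <- ok & records$urbanicity %in% c("rural", "urban")
    reason[!ok] <- "heterogeneous_sdp"
  }
  if (has("annual_vmmc")) {
    bad <- is.na(records$annual_vmmc) | records$annual_vmmc < 1
    reason[is.na(reason) & bad] <- "missing_output"
  }
  if (require_personnel && has("cost_personnel")) {
    bad <- is.na(records$cost_personnel)
    reason[is.na(reason) & bad] <- "missing_critical_input"
  }
  cost_cols <- intersect(c("cost_capital", "cost_recurrent", "cost_personnel",
                           "cost_other"), names(records))
  if (length(cost_cols)) {
    total <- rowSums(as.matrix(records[cost_cols]), na.rm = TRUE)
    reason[is.na(reason) & total <= 0] <- "nonpositive_total_cost"
  }
  excluded <- records[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) excluded$exclusion_reason <- reason[!is.na(reason)]
  else excluded$exclusion_reason <- character(0)
  list(kept = records[is.na(reason), , drop = FALSE], excluded = excluded)
}

#' Standardize facility records to 2016-USD unit costs
#'
#' Full standardization: screens records with [apply_exclusions()], converts
#' each cost component from local currency to USD at the data-collection
#' year's exchange rate, inflates to 2016 dollars with the deflator series,
#' and computes the unit cost.  Records already in 2016 USD pass through
#' unchanged (idempotence).
#'
#' @param records Raw facility records (see [read_facilities()] for the
#'   schema).
#' @param fx Exchange-rate table (`currency`, `year`, `rate`); a
#'   `"vmmc_contexts"` object may be passed instead to supply both tables.
#' @param deflator Deflator table (`year`, `index`), base year 2016.
#' @param exclusions Apply exclusion screening first.
#' @return A list with components `kept` (standardized records with
#'   `unit_cost_2016usd`, costs in 2016 USD and currency set to `"USD"`) and
#'   `excluded` (screened-out records with reasons).
#' @export
standardize_facilities <- function(records, fx, deflator = NULL,
                                   exclusions = TRUE) {
  if (inherits(fx, "vmmc_contexts")) {
    deflator <- fx$deflator
    fx <- fx$fx
  }
  if (is.null(deflator))
    stop("a deflator table is required", call. = FALSE)
  cost_cols <- c("cost_capital", "cost_recurrent", "cost_personnel", "cost_other")
  require_columns(records, c(cost_cols, "annual_vmmc", "currency", "year"))
  if (any(as.matrix(records[cost_cols]) < 0, na.rm = TRUE))
    stop("negative cost components are not allowed", call. = FALSE)
  if (exclusions) {
    split <- apply_exclusions(records)
  } else {
    split <- list(kept = records,
                  excluded = cbind(records[0, , drop = FALSE],
                                   exclusion_reason = character(0)))
  }
  kept <- split$kept
  if (nrow(kept)) {
    # money_year tracks the dollars the costs are expressed in; after
    # standardization it is 2016, making the operation idempotent
    money_year <- if ("year_of_dollars" %in% names(kept)) kept$year_of_dollars
    else kept$year
    for (col in cost_cols) {
      usd <- convert_to_usd(kept[[col]], kept$currency, money_year, fx)
      kept[[col]] <- inflate_to_2016(usd, money_year, deflator)
    }
    kept$currency <- "USD"
    kept$year_of_dollars <- 2016L
    kept <- compute_unit_cost(kept)
  }
  list(kept = kept, excluded = split$excluded)
}
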