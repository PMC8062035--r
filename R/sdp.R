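# Service delivery platforms: a platform is the combination of facility
# type (hospital/clinic), ownership (public/private) and urbanicity
# (urban/rural) within a country -- 2 x 2 x 2 = 8 platforms per country.
# The outreach/fixed delivery model is a facility attribute, not part of
# the platform key.

#' Service-delivery-platform key of facility or SDP records
#'
#' Builds the deterministic platform key `country/facility_type/ownership/`
#' `urbanicity` for each record.  The outreach attribute is deliberately not
#' part of the key.
#'
#' @param records Data frame with `country`, `facility_type`, `ownership`,
#'   `urbanicity` columns (no missing values).
#' @return Character vector of keys.
#' @examples
#' sdp_key(data.frame(country = "KEN", facility_type = "clinic",
#'                    ownership = "public", urbanicity = "rural"))
#' @export
sdp_key <- function(records) {
  fields <- c("country", "facility_type", "ownership", "urbanicity")
  require_columns(records, fields)
  for (f in fields)
    if (anyNA(records[[f]]) || any(!nzchar(records[[f]])))
      stop(sprintf("field '%s' is missing for some records", f), call. = FALSE)
  paste(records$country, records$facility_type, records$ownership,
        records$urbanicity, sep = "/")
}

#' Collapse facility records to SDP-level unit costs
#'
#' Aggregates standardized facility records to one record per occupied
#' platform.  By default the platform unit cost is output-weighted: total
#' cost over all member facilities divided by total circumcisions, which
#' equals the platform-level average cost per circumcision.  An unweighted
#' mean of facility unit costs is available for sensitivity analysis.
#'
#' @param records Standardized facility records with `unit_cost_2016usd` and
#'   `annual_vmmc`.
#' @param weighted Output-weighted collapse (default) or unweighted mean.
#' @return Data frame with one row per occupied platform: key fields,
#'   `unit_cost_2016usd`, `n_facilities`, `total_vmmc`, `mean_scale`,
#'   `source = "primary_collapsed"`, sorted by key.
#' @export
collapse_to_sdp <- function(records, weighted = TRUE) {
  require_columns(records, c("unit_cost_2016usd", "annual_vmmc"))
  key <- sdp_key(records)
  total_cost <- records$unit_cost_2016usd * records$annual_vmmc
  agg <- function(x, f) as.vector(tapply(x, key, f))  # sorted key order
  keys <- sort(unique(key))
  parts <- do.call(rbind, strsplit(keys, "/", fixed = TRUE))
  uc <- if (weighted) agg(total_cost, sum) / agg(records$annual_vmmc, sum)
  else agg(records$unit_cost_2016usd, mean)
  out <- data.frame(
    country = parts[, 1], facility_type = parts[, 2],
    ownership = parts[, 3], urbanicity = parts[, 4],
    unit_cost_2016usd = uc,
    n_facilities = agg(records$annual_vmmc, length),
    total_vmmc = agg(records$annual_vmmc, sum),
    mean_scale = agg(records$annual_vmmc, mean),
    source = "primary_collapsed",
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Pool collapsed primary and secondary SDP records
#'
#' Concatenates SDP-level records from collapsed primary data and published
#' secondary data, preserving source labels.  The same platform key may
#' occur in both sources, but duplicated keys within the primary set are an
#' error (collapsing should have merged them).
#'
#' @param primary Collapsed primary SDP records ([collapse_to_sdp()]).
#' @param secondary Published SDP records (may have zero rows); must carry
#'   the key fields and `unit_cost_2016usd`.
#' @return The pooled data frame, sorted by key within source.
#' @export
pool_sdp <- function(primary, secondary = NULL) {
  key_p <- sdp_key(primary)
  if (anyDuplicated(key_p))
    stop("duplicate platform key(s) in primary records: ",
         paste(unique(key_p[duplicated(key_p)]), collapse = ", "),
         call. = FALSE)
  if (!"source" %in% names(primary)) primary$source <- "primary_collapsed"
  if (is.null(secondary) || nrow(secondary) == 0)
    return(primary[order(key_p), , drop = FALSE])
  require_columns(secondary, c("country", "facility_type", "ownership",
                               "urbanicity", "unit_cost_2016usd"),
                  "secondary records")
  if (!"source" %in% names(secondary)) secondary$source <- "secondary_published"
  cols <- union(names(primary), names(secondary))
  add_missing <- function(df) {
    for (col in setdiff(cols, names(df))) df[[col]] <- NA
    df[cols]
  }
  out <- rbind(add_missing(primary[order(key_p), , drop = FALSE]),
               add_missing(secondary[order(sdp_key(secondary)), , drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Enumerate the full SDP grid for a set of countries
#'
#' All eight platforms (2 facility types x 2 ownerships x 2 urbanicities)
#' for each country, deduplicated and in deterministic order (country as
#' given, then facility type, ownership, urbanicity with reference
#' categories first).
#'
#' @param countries Character vector of country codes (nonempty).
#' @return Data frame of platform keys, `8 * length(unique(countries))` rows.
#' @examples
#' nrow(enumerate_sdp_grid(c("A", "B")))  # 16
#' @export
enumerate_sdp_grid <- function(countries) {
  countries <- unique(as.character(countries))
  if (length(countries) == 0 || anyNA(countries))
    stop("`countries` must be a nonempty vector of country codes", call. = FALSE)
  grid <- expand.grid(
    urbanicity = c("urban", "rural"),
    ownership = c("public", "private"),
    facility_type = c("clinic", "hospital"),
    country = countries,
    stringsAsFactors = FALSE
  )[, c("country", "facility_type", "ownership", "urbanicity")]
  rownames(grid) <- NULL
  grid
}
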