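#' Reference coefficient sets for the unit-cost models
#'
#' Named coefficient vectors for the two unit-cost regressions implemented by
#' the package: the facility-level cost-curve model (log unit cost on log
#' scale, its square, facility attributes, log GDP per capita and year of
#' data collection) and the SDP-level extrapolation model (log unit cost on
#' log GDP per capita, platform attributes, national VMMC coverage and the
#' health-personnel salary index).  The values are reference estimates from
#' the multi-country VMMC costing literature.  They serve two purposes: they
#' are the default generating truth of the synthetic-data module
#' ([sim_config()]), and they are convenient inputs for the effect
#' interpretation helpers ([elasticity_effect()], [level_effect()]).
#'
#' Coefficient naming follows the design-matrix columns built by the package
#' (see [facility_design()] and [sdp_design()]); `alpha` is the intercept.
#'
#' @param model `"facility"` for the facility-level cost-curve model,
#'   `"sdp"` for the SDP-level extrapolation model.
#' @param estimator `"ols"` for the log-linear least-squares column,
#'   `"glm"` for the gamma log-link column.
#' @return A named numeric vector of coefficients.
#' @examples
#' reference_coefficients("facility", "ols")["scale_log"]   # -0.13
#' reference_coefficients("sdp", "ols")["gdp_log"]          # 0.47
#' @export
reference_coefficients <- function(model = c("facility", "sdp"),
                                   estimator = c("ols", "glm")) {
  model <- match.arg(model)
  estimator <- match.arg(estimator)
  tabs <- list(
    facility = list(
      ols = c(alpha = 4.13, scale_log = -0.13, scale_log_sq = -0.007,
              gdp_log = 0.56, rural = 0.01, private = 0.27, hospital = 0.61,
              outreach = 0.27, year_offset = 0.14, hospital_x_private = -0.52),
      glm = c(alpha = 4.49, scale_log = -0.15, scale_log_sq = -0.008,
              gdp_log = 0.49, rural = 0.004, private = 0.16, hospital = 0.62,
              outreach = 0.29, year_offset = 0.18, hospital_x_private = -0.53)
    ),
    sdp = list(
      ols = c(alpha = -0.51, gdp_log = 0.47, rural = 0.10, private = 0.14,
              hospital = 0.14, salary_index = 2.55, coverage = 0.10),
      glm = c(alpha = -0.23, gdp_log = 0.44, rural = 0.10, private = 0.09,
              hospital = 0.10, salary_index = 2.84, coverage = 0.06)
    )
  )
  tabs[[model]][[estimator]]
}

# Column order used for display, matching the conventional table layout.
eq1_terms <- function() {
  c("scale_log", "scale_log_sq", "gdp_log", "rural", "private", "hospital",
    "outreach", "year_offset", "hospital_x_private")
}

eq2_terms <- function() {
  c("gdp_log", "rural", "private", "hospital", "salary_index", "coverage")
}
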