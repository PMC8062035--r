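# Coefficient interpretation helpers.  In a log-log model the coefficient
# is an elasticity: the percent change in unit cost per 1% change in the
# covariate.  Dummy and per-unit coefficients are level shifts of log cost,
# with exact percent effect (exp(beta) - 1) * 100.

#' First-order elasticity interpretation of a log-log coefficient
#'
#' Percent change in unit cost associated with a `pct_change` percent change
#' in the covariate, `beta * pct_change`.  Appropriate for coefficients of
#' log-transformed covariates (log annual volume, log GDP per capita); a
#' scale coefficient of -0.15 means a 10% increase in annual volume lowers
#' the unit cost by 1.5% on average.
#'
#' @param beta Coefficient(s) of a log-transformed covariate.
#' @param pct_change Percent change in the covariate (default 10).
#' @return Percent change(s) in unit cost.
#' @examples
#' elasticity_effect(-0.15, 10)  # -1.5
#' @export
elasticity_effect <- function(beta, pct_change = 10) {
  stopifnot(is.numeric(beta), is.numeric(pct_change))
  beta * pct_change
}

#' Exact percent effect of a dummy or per-unit coefficient
#'
#' Percent change in unit cost when the covariate switches from 0 to 1 (or
#' increases by one unit), `(exp(beta) - 1) * 100`.  A year coefficient of
#' 0.14 corresponds to a 15% average increase per year.
#'
#' @param beta Coefficient(s) of a dummy or per-unit covariate.
#' @return Percent change(s) in unit cost.
#' @examples
#' level_effect(0.14)  # 15.03
#' @export
level_effect <- function(beta) {
  stopifnot(is.numeric(beta))
  (exp(beta) - 1) * 100
}
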