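#' Specification of interpretation units for MR estimates
#'
#' Describes how raw MR coefficients map to reporting units. For a binary
#' exposure analysed on the log-odds scale and a continuous outcome in SD
#' units, a unit increase in the exposure coefficient corresponds to an
#' e-fold (2.72x) multiplicative increase in the odds of the exposure; for
#' rare conditions this approximates the prevalence, so multiplying by
#' ln(2) expresses the effect per doubling of liability, and multiplying by
#' the outcome SD (for years of education, SD = 4.2) converts SD units to
#' years, months (x12) or days (x365).
#'
#' @param exposure_type `"binary_liability"` or `"continuous_sd"`.
#' @param outcome_type `"binary_liability"` or `"continuous_sd"`.
#' @param outcome_sd_years outcome SD in years; required when converting an
#'   SD-scale outcome to time units (education: 4.2).
#' @param time_unit `"years"`, `"months"` or `"days"`.
#' @return a `scale_spec` object.
#' @export
scale_spec <- function(exposure_type = c("binary_liability", "continuous_sd"),
                       outcome_type = c("continuous_sd", "binary_liability"),
                       outcome_sd_years = NULL,
                       time_unit = c("months", "days", "years")) {
  exposure_type <- match.arg(exposure_type)
  outcome_type <- match.arg(outcome_type)
  time_unit <- match.arg(time_unit)
  if (!is.null(outcome_sd_years) &&
      (!is.numeric(outcome_sd_years) || outcome_sd_years <= 0)) {
    err_config("outcome_sd_years must be a positive number")
  }
  structure(list(exposure_type = exposure_type, outcome_type = outcome_type,
                 outcome_sd_years = outcome_sd_years, time_unit = time_unit),
            class = "scale_spec")
}

unit_factor <- function(time_unit) {
  switch(time_unit, years = 1, months = 12, days = 365)
}

#' Effect per doubling of genetic liability, in time units
#'
#' For a log-odds-scale binary exposure and an SD-scale continuous outcome:
#' `beta * ln(2) * outcome_sd_years * unit factor` (12 for months, 365 for
#' days). With `round_output = TRUE` the presentation rounding used in
#' reports is applied: one decimal for months and years, nearest integer
#' for days.
#'
#' @param beta raw MR coefficient (outcome SD per unit log-odds exposure).
#' @param spec a `scale_spec` with `exposure_type = "binary_liability"`,
#'   continuous outcome and a known outcome SD.
#' @param round_output apply presentation rounding; default FALSE (full
#'   precision).
#' @return the converted effect (vectorised over `beta`).
#' @export
doubling_effect <- function(beta, spec, round_output = FALSE) {
  if (!inherits(spec, "scale_spec")) err_config("spec must be a scale_spec")
  if (spec$exposure_type != "binary_liability" ||
      spec$outcome_type != "continuous_sd") {
    err_config("doubling_effect needs a binary-liability exposure and a continuous outcome")
  }
  if (is.null(spec$outcome_sd_years)) {
    err_config("outcome_sd_years is required to convert SD units to time")
  }
  out <- beta * log(2) * spec$outcome_sd_years * unit_factor(spec$time_unit)
  if (round_output) {
    digits <- switch(spec$time_unit, days = 0L, 1L)
    out <- round(out, digits)
  }
  out
}

#' Invert a doubling-of-liability time effect back to the raw coefficient
#' @param value converted effect in `spec$time_unit`.
#' @param spec the `scale_spec` used for the forward conversion.
#' @return the raw coefficient.
#' @export
doubling_effect_inverse <- function(value, spec) {
  if (is.null(spec$outcome_sd_years)) err_config("outcome_sd_years is required")
  value / (log(2) * spec$outcome_sd_years * unit_factor(spec$time_unit))
}

#' Confidence interval for an odds ratio from its log-scale SE
#'
#' `exp(ln(OR) +/- z * se_log)` with the two-sided normal quantile for the
#' requested level (1.959964 at 95%).
#'
#' @param or_point odds ratio point estimate (> 0).
#' @param se_log standard error on the log-odds scale (> 0).
#' @param level confidence level in (0, 1); default 0.95.
#' @param round_output round to two decimals as in report tables.
#' @return named numeric vector `c(low, high)`.
#' @export
or_ci_from_log_scale <- function(or_point, se_log, level = 0.95,
                                 round_output = FALSE) {
  if (!is.numeric(or_point) || any(or_point <= 0)) err_config("or_point must be positive")
  if (!is.numeric(se_log) || any(se_log <= 0)) err_config("se_log must be positive")
  if (level <= 0 || level >= 1) err_config("level must lie in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- c(low = exp(log(or_point) - z * se_log),
           high = exp(log(or_point) + z * se_log))
  if (round_output) out <- round(out, 2L)
  out
}

#' Multiplicative odds increase for a unit log-odds coefficient
#'
#' `exp(beta)`: a unit increase on the log-odds scale is a 2.72-fold
#' multiplicative increase in the odds; `ln(2)` corresponds to a doubling.
#'
#' @param beta_logodds coefficient on the log-odds scale.
#' @return fold change in the odds.
#' @export
unit_logodds_fold <- function(beta_logodds) exp(beta_logodds)
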