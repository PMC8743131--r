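# Internal helpers: classed error conditions so the pipeline (and tests) can
# distinguish configuration, data and numerical failures.

err_config <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("mrlink_config_error", "mrlink_error", "error")))
}

err_data <- function(msg) {
  stop(errorCondition(msg, class = c("mrlink_data_error", "mrlink_error", "error")))
}

err_numeric <- function(msg) {
  stop(errorCondition(msg, class = c("mrlink_numeric_error", "mrlink_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sign() that never returns 0: zero exposure effects keep their row orientation
sign1 <- function(x) ifelse(x < 0, -1, 1)

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))
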