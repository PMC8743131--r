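#' @title Multivariable Mendelian randomization
#' @description Joint modelling of two (or more) exposures: direct effects,
#'   the exposure-uncertainty-adjusted heterogeneity statistic Q_a,
#'   conditional instrument strength, and weak-instrument-robust estimation
#'   by Q minimization.
#' @name mvmr
NULL

check_mvmr <- function(h, min_extra = 1L) {
  if (!inherits(h, "harmonized_set")) err_config("expected a harmonized_set")
  K <- ncol(h$bx)
  if (n_snps(h) < K + min_extra) {
    err_data("not enough instruments for the number of exposures")
  }
  K
}

check_collinear <- function(X) {
  d <- svd(scale(X, center = FALSE, scale = sqrt(colSums(X^2))))$d
  if (!all(is.finite(d)) || min(d) / max(d) < 1e-8) {
    err_numeric("exposure effect columns are collinear; inspect the conditional F statistics")
  }
}

mvmr_result <- function(exposure_ids, betas, ses, pvalues, n_snps, het,
                        conditional_F = NULL, robust = NULL, ci_level = 0.95) {
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(list(exposure_ids = exposure_ids,
                 direct_betas = betas, ses = ses,
                 ci = cbind(low = betas - z * ses, high = betas + z * ses),
                 pvalues = pvalues, n_snps = n_snps, het = het,
                 conditional_F = conditional_F, robust = robust),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable MR (%d SNPs, %d exposures)\n",
              x$n_snps, length(x$exposure_ids)))
  for (k in seq_along(x$exposure_ids)) {
    cat(sprintf("  %s: direct beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g",
                x$exposure_ids[k], x$direct_betas[k], x$ses[k],
                x$ci[k, 1L], x$ci[k, 2L], x$pvalues[k]))
    if (!is.null(x$conditional_F)) {
      cat(sprintf(", conditional F = %.1f", x$conditional_F[k]))
    }
    cat("\n")
  }
  if (!is.null(x$het)) {
    cat(sprintf("  Q_a = %.3g on %d df (p = %.3g)\n",
                x$het$Q, x$het$df, x$het$pvalue))
  }
  if (!is.null(x$robust)) {
    cat("  Q-minimization (robust) estimates:\n")
    for (k in seq_along(x$exposure_ids)) {
      cat(sprintf("    %s: %.4g [%.4g, %.4g]\n", x$exposure_ids[k],
                  x$robust$betas[k], x$robust$ci[k, 1L], x$robust$ci[k, 2L]))
    }
  }
  invisible(x)
}

#' Multivariable IVW regression
#'
#' Weighted least squares of the outcome coefficients on all exposure
#' coefficient columns with no intercept and weights `1/sy^2`. The
#' coefficient vector estimates the direct effect of each exposure
#' conditional on the others. SEs carry the same multiplicative variance
#' inflation as univariable IVW (`sqrt(max(1, RSS_w/(n-K)))`); the attached
#' heterogeneity statistic is the exposure-uncertainty-adjusted Q_a from
#' [mvmr_q()] evaluated at the fitted coefficients. With a single exposure
#' this reduces exactly to univariable IVW.
#'
#' @param h `harmonized_set` (typically with >= 2 exposures).
#' @param conditional_F also compute per-exposure conditional F statistics
#'   (only when K >= 2); default TRUE.
#' @return an `mvmr_result`.
#' @export
mvmr_ivw <- function(h, conditional_F = TRUE) {
  K <- check_mvmr(h)
  X <- h$bx
  w <- 1 / h$sy^2
  if (K >= 2L) check_collinear(X)
  fit <- stats::lm.wfit(X, h$by, w)
  betas <- unname(fit$coefficients)
  n <- n_snps(h)
  XtWX <- crossprod(X * sqrt(w))
  se_fixed <- sqrt(diag(solve(XtWX)))
  rss <- sum(w * fit$residuals^2)
  infl <- if (n > K) sqrt(max(1, rss / (n - K))) else 1
  ses <- unname(se_fixed * infl)
  het <- mvmr_q(h, betas)
  cf <- NULL
  if (conditional_F && K >= 2L) {
    cf <- vapply(seq_len(K), function(k) conditional_f(h, k), 0)
    names(cf) <- h$exposure_ids
  }
  mvmr_result(h$exposure_ids, betas, ses, two_sided_p(betas / ses),
              n, het, conditional_F = cf)
}

#' Exposure-uncertainty-adjusted heterogeneity statistic Q_a
#'
#' `Q_a = sum_j w_j(theta) (by_j - sum_k theta_k bx_kj)^2` with weights
#' `w_j(theta) = 1 / (sy_j^2 + sum_k theta_k^2 sx_kj^2)` (zero covariance
#' between exposure estimates assumed), on `n - K` degrees of freedom with
#' an upper-tail chi-square p-value. Large values signal pleiotropy or
#' model misfit.
#'
#' @param h `harmonized_set`.
#' @param betas coefficient vector, one per exposure.
#' @return list `Q`, `df`, `pvalue`.
#' @export
mvmr_q <- function(h, betas) {
  K <- ncol(h$bx)
  if (length(betas) != K) err_config("betas must have one entry per exposure")
  w <- 1 / (h$sy^2 + as.vector(h$sx^2 %*% betas^2))
  Q <- sum(w * (h$by - as.vector(h$bx %*% betas))^2)
  het_stats(Q, n_snps(h) - K)
}

#' Conditional instrument strength for one exposure
#'
#' Measures how strongly the instruments predict the target exposure over
#' and above their association with the other exposures: the target's
#' coefficients are regressed on the other exposures' coefficients by
#' minimizing the uncertainty-weighted statistic
#' `Q_x = sum_j (bx_kj - sum_l delta_l bx_lj)^2 / (sx_kj^2 + sum_l delta_l^2 sx_lj^2)`
#' (cross-exposure estimate covariance assumed zero), and the conditional F
#' statistic is `Q_x / (n - K + 1)`. Values near the univariable mean F
#' indicate instruments specific to the target; values near zero indicate
#' no conditional strength.
#'
#' @param h `harmonized_set` with >= 2 exposures.
#' @param exposure_index which exposure to assess.
#' @return a single conditional F value.
#' @export
conditional_f <- function(h, exposure_index) {
  K <- ncol(h$bx)
  if (K < 2L) err_config("conditional_f requires at least 2 exposures")
  if (exposure_index < 1L || exposure_index > K) err_config("exposure_index out of range")
  x <- h$bx[, exposure_index]
  sxk <- h$sx[, exposure_index]
  Z <- h$bx[, -exposure_index, drop = FALSE]
  sz <- h$sx[, -exposure_index, drop = FALSE]
  n <- n_snps(h)
  qx <- function(delta) {
    # zero SEs make the statistic diverge; floor the denominator so the
    # "strength grows without bound as noise shrinks" limit stays finite
    denom <- pmax(sxk^2 + as.vector(sz^2 %*% delta^2), 1e-300)
    sum((x - as.vector(Z %*% delta))^2 / denom)
  }
  w_init <- 1 / sxk^2
  if (!all(is.finite(w_init))) w_init <- rep(1, n)
  init <- stats::lm.wfit(Z, x, w_init)$coefficients
  init[!is.finite(init)] <- 0
  if (length(init) == 1L) {
    span <- max(abs(init), 1) * 20
    opt <- stats::optimize(function(d) qx(d), c(init - span, init + span),
                           tol = 1e-10)
    qmin <- opt$objective
  } else {
    opt <- stats::optim(init, qx, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 5000L))
    qmin <- opt$value
  }
  qmin / (n - K + 1)
}

q_minimize <- function(h, init, reltol = 1e-10) {
  obj <- function(theta) mvmr_q(h, theta)$Q
  run1 <- function(par) {
    if (length(par) == 1L) {
      span <- max(abs(par), 1) * 20
      o <- stats::optimize(function(t) obj(t), c(par - span, par + span),
                           tol = 1e-12)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      stats::optim(par, obj, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = 10000L))
    }
  }
  starts <- list(init, init * 1.2 + 1e-6, init * 0.8 - 1e-6)
  fits <- lapply(starts, run1)
  conv <- vapply(fits, function(f) f$convergence == 0L, TRUE)
  if (!any(conv)) err_numeric("Q minimization did not converge from any start")
  best <- fits[conv][[which.min(vapply(fits[conv], `[[`, 0, "value"))]]
  best$par
}

#' Weak-instrument-robust multivariable MR by Q minimization
#'
#' Direct effects are the minimizer of the exposure-uncertainty-adjusted
#' Q_a statistic (derivative-free simplex initialized at the IVW solution
#' with restarts at +/-20% perturbations). Confidence intervals come from a
#' non-parametric bootstrap resampling SNPs with replacement and
#' re-minimizing (percentile 2.5/97.5 intervals). The result records
#' whether each robust CI overlaps the corresponding IVW CI (concordance
#' between the two supports the findings).
#'
#' @param h `harmonized_set`.
#' @param boot_reps bootstrap iterations (>= 100, default 1000; 0 skips the
#'   bootstrap).
#' @param seed integer seed, required when `boot_reps > 0`.
#' @return an `mvmr_result` whose `robust` field holds the Q-minimizing
#'   betas, percentile CIs and per-exposure `concordant` flags.
#' @export
mvmr_robust <- function(h, boot_reps = 1000L, seed = NULL) {
  K <- check_mvmr(h)
  if (boot_reps != 0L && boot_reps < 100L) {
    err_config("boot_reps must be 0 (skip) or at least 100")
  }
  ivw <- mvmr_ivw(h, conditional_F = (K >= 2L))
  betas <- q_minimize(h, ivw$direct_betas)
  ci <- matrix(NA_real_, K, 2L, dimnames = list(NULL, c("low", "high")))
  concordant <- rep(NA, K)
  if (boot_reps > 0L) {
    if (is.null(seed)) err_config("seed is required when boot_reps > 0")
    set.seed(as.integer(seed))
    n <- n_snps(h)
    boots <- matrix(NA_real_, boot_reps, K)
    for (b in seq_len(boot_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      boots[b, ] <- q_minimize(h_subset(h, idx), betas)
    }
    for (k in seq_len(K)) {
      ci[k, ] <- stats::quantile(boots[, k], c(0.025, 0.975), names = FALSE)
      concordant[k] <- ci[k, 1L] <= ivw$ci[k, 2L] && ivw$ci[k, 1L] <= ci[k, 2L]
    }
  }
  out <- ivw
  out$robust <- list(betas = betas, ci = ci, concordant = concordant,
                     Q_at_min = mvmr_q(h, betas)$Q)
  out
}
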