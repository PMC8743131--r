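#' @title Univariable two-sample MR estimators
#' @description Point estimators, diagnostics and sensitivity analyses for a
#'   harmonized set with a single exposure. All causal estimates are in
#'   outcome units per unit exposure (log-odds units for binary exposures).
#' @name uvmr
NULL

mr_estimate <- function(method, beta, se, pvalue, n_snps, ci_level = 0.95,
                        ci = NULL, intercept = NULL, het = NULL) {
  if (is.null(ci)) {
    z <- stats::qnorm(1 - (1 - ci_level) / 2)
    ci <- c(beta - z * se, beta + z * se)
  }
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci[1L], ci_high = ci[2L], pvalue = pvalue,
                 n_snps = n_snps, intercept = intercept, het = het),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%d SNPs): beta = %.4g, se = %.4g, 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$method, x$n_snps, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4g (se %.4g, p = %.3g)\n",
                x$intercept$value, x$intercept$se, x$intercept$pvalue))
  }
  if (!is.null(x$het) && is.finite(x$het$Q)) {
    cat(sprintf("  heterogeneity: Q = %.3g on %d df (p = %.3g)\n",
                x$het$Q, x$het$df, x$het$pvalue))
  }
  invisible(x)
}

het_stats <- function(Q, df) {
  p <- if (df >= 1) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  list(Q = Q, df = df, pvalue = p)
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of the SNP-outcome coefficients on the SNP-exposure
#' coefficients with the intercept constrained to zero and weights
#' `1/sy^2`: `beta = sum(w bx by) / sum(w bx^2)`. Under the fixed-effect
#' model `se = sqrt(1 / sum(w bx^2))`; under the default multiplicative
#' random-effects model the SE is inflated by `sqrt(max(1, Q/(n-1)))`, where
#' `Q` is Cochran's heterogeneity statistic.
#'
#' @param h univariable `harmonized_set`.
#' @param variance_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return an `mr_estimate` with heterogeneity statistics attached.
#' @export
mr_ivw <- function(h, variance_model = c("multiplicative_random", "fixed")) {
  check_univariable(h)
  variance_model <- match.arg(variance_model)
  n <- n_snps(h)
  if (n == 0L) err_data("no instruments available for IVW")
  bx <- h$bx[, 1L]; by <- h$by; sy <- h$sy
  w <- 1 / sy^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  Q <- sum(w * (by - beta * bx)^2)
  df <- n - 1L
  se <- if (variance_model == "multiplicative_random" && df >= 1L) {
    se_fixed * sqrt(max(1, Q / df))
  } else se_fixed
  mr_estimate(method = if (variance_model == "fixed") "IVW (fixed)" else "IVW",
              beta = beta, se = se, pvalue = two_sided_p(beta / se),
              n_snps = n, het = het_stats(Q, df))
}

# reorient rows so all exposure effects are non-negative (Egger identifiability)
egger_orient <- function(h) {
  s <- sign1(h$bx[, 1L])
  list(bx = abs(h$bx[, 1L]), by = h$by * s, sy = h$sy)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome coefficients on the exposure
#' coefficients with a free intercept (weights `1/sy^2`), after reorienting
#' every row so the exposure effect is non-negative. The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates the average
#' directional pleiotropic effect and its p-value is the directional
#' pleiotropy test. Inference uses the t distribution with n - 2 df; the SE
#' keeps the multiplicative residual inflation when residual dispersion
#' exceeds 1.
#'
#' @param h univariable `harmonized_set` with at least 3 variants.
#' @return an `mr_estimate` with `intercept` and heterogeneity fields.
#' @export
mr_egger <- function(h) {
  check_univariable(h)
  n <- n_snps(h)
  if (n < 3L) err_data("MR-Egger requires at least 3 instruments")
  o <- egger_orient(h)
  w <- 1 / o$sy^2
  fit <- stats::lm(o$by ~ o$bx, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  # do not let under-dispersion shrink the SEs below the fixed-effect level
  infl <- 1 / min(1, sm$sigma)
  slope <- co[2L, 1L]; slope_se <- co[2L, 2L] * infl
  int <- co[1L, 1L]; int_se <- co[1L, 2L] * infl
  tq <- stats::qt(0.975, df = n - 2L)
  Q <- sum(w * stats::residuals(fit)^2)
  mr_estimate(
    method = "MR-Egger", beta = slope, se = slope_se,
    pvalue = 2 * stats::pt(-abs(slope / slope_se), df = n - 2L),
    n_snps = n,
    ci = c(slope - tq * slope_se, slope + tq * slope_se),
    intercept = list(value = int, se = int_se,
                     pvalue = 2 * stats::pt(-abs(int / int_se), df = n - 2L)),
    het = het_stats(Q, n - 2L)
  )
}

# closed-form weighted least squares slope/intercept (internal fast path)
egger_fit_raw <- function(bx, by, w) {
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  slope <- (sw * sum(w * bx * by) - swx * swy) /
    (sw * sum(w * bx^2) - swx^2)
  c(intercept = (swy - slope * swx) / sw, slope = slope)
}

#' SIMEX measurement-error correction for MR-Egger
#'
#' Simulation-extrapolation for regression dilution of the Egger slope: for
#' each inflation factor lambda in the grid, noise with variance
#' `lambda * sx^2` is added to the exposure coefficients over `reps`
#' replicates and the mean Egger slope recorded; a quadratic in lambda is
#' then extrapolated back to lambda = -1 (the error-free limit). The SE is a
#' jackknife over replicates. With `sx = 0` the procedure returns the naive
#' Egger slope.
#'
#' @param h univariable `harmonized_set` with at least 3 variants.
#' @param lambdas non-negative grid (at least 3 distinct values, 0 included
#'   recommended); default `c(0, 0.5, 1, 1.5, 2)`.
#' @param reps simulation replicates per lambda (>= 100).
#' @param seed integer seed (mandatory for reproducibility).
#' @return an `mr_estimate` with SIMEX-extrapolated slope and intercept.
#' @export
mr_egger_simex <- function(h, lambdas = c(0, 0.5, 1, 1.5, 2), reps = 200L,
                           seed) {
  check_univariable(h)
  n <- n_snps(h)
  if (n < 3L) err_data("SIMEX MR-Egger requires at least 3 instruments")
  if (length(unique(lambdas)) < 3L || any(lambdas < 0)) {
    err_config("lambdas must contain at least 3 distinct non-negative values")
  }
  if (reps < 100L) err_config("reps must be at least 100")
  if (missing(seed)) err_config("seed is required")
  set.seed(as.integer(seed))
  o <- egger_orient(h)
  sx <- h$sx[, 1L]
  w <- 1 / o$sy^2
  lambdas <- sort(unique(lambdas))
  L <- length(lambdas)
  slopes <- matrix(NA_real_, reps, L)
  ints <- matrix(NA_real_, reps, L)
  for (l in seq_len(L)) {
    lam <- lambdas[l]
    if (lam == 0) {
      cf <- egger_fit_raw(o$bx, o$by, w)
      slopes[, l] <- cf[2L]; ints[, l] <- cf[1L]
    } else {
      for (r in seq_len(reps)) {
        bxr <- o$bx + stats::rnorm(n, 0, sqrt(lam) * sx)
        cf <- egger_fit_raw(bxr, o$by, w)
        slopes[r, l] <- cf[2L]; ints[r, l] <- cf[1L]
      }
    }
  }
  X <- cbind(1, lambdas, lambdas^2)
  XtXi <- solve(crossprod(X))
  extrapolate <- function(means) {
    # quadratic in lambda evaluated at lambda = -1
    sum(c(1, -1, 1) * (XtXi %*% crossprod(X, means)))
  }
  slope_hat <- extrapolate(colMeans(slopes))
  int_hat <- extrapolate(colMeans(ints))
  # jackknife over replicates
  jack <- vapply(seq_len(reps), function(r) {
    extrapolate(colMeans(slopes[-r, , drop = FALSE]))
  }, 0)
  se <- sqrt((reps - 1) / reps * sum((jack - mean(jack))^2))
  if (se == 0) { # degenerate (e.g. sx = 0): fall back to naive Egger SE
    se <- mr_egger(h)$se
  }
  tq <- stats::qt(0.975, df = n - 2L)
  mr_estimate(
    method = "MR-Egger (SIMEX)", beta = slope_hat, se = se,
    pvalue = 2 * stats::pt(-abs(slope_hat / se), df = n - 2L),
    n_snps = n, ci = c(slope_hat - tq * se, slope_hat + tq * se),
    intercept = list(value = int_hat, se = NA_real_, pvalue = NA_real_)
  )
}

# weighted median of ratio estimates: cumulative standardized weights with
# linear interpolation between the bracketing order statistics
weighted_median_point <- function(bx, by, sy) {
  r <- by / bx
  w <- (bx^2 / sy^2)
  w <- w / sum(w)
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  s <- cumsum(w) - 0.5 * w
  k <- sum(s < 0.5)
  if (k == 0L) return(r[1L])
  if (k == length(r)) return(r[length(r)])
  r[k] + (r[k + 1L] - r[k]) * (0.5 - s[k]) / (s[k + 1L] - s[k])
}

#' Weighted median estimator
#'
#' The inverse-variance weighted median of per-SNP Wald ratios
#' `by/bx`: consistent when instruments carrying at least half of the
#' weight are valid. The SE comes from a parametric bootstrap resampling
#' `bx` and `by` from normal distributions centred on the observed values.
#'
#' @param h univariable `harmonized_set` with at least 3 variants and no
#'   zero exposure effects.
#' @param boot_reps bootstrap resamples (0 skips the bootstrap and returns
#'   `NA` SE; default 1000).
#' @param seed integer seed, required when `boot_reps > 0`.
#' @return an `mr_estimate`.
#' @export
mr_weighted_median <- function(h, boot_reps = 1000L, seed = NULL) {
  check_univariable(h)
  n <- n_snps(h)
  if (n < 3L) err_data("weighted median requires at least 3 instruments")
  bx <- h$bx[, 1L]
  if (any(bx == 0)) {
    err_data(paste0("zero exposure effect for variant(s): ",
                    paste(h$variant_id[bx == 0], collapse = ", ")))
  }
  est <- weighted_median_point(bx, h$by, h$sy)
  se <- NA_real_
  if (boot_reps > 0L) {
    if (is.null(seed)) err_config("seed is required when boot_reps > 0")
    set.seed(as.integer(seed))
    sx <- h$sx[, 1L]
    boots <- vapply(seq_len(boot_reps), function(b) {
      weighted_median_point(stats::rnorm(n, bx, sx),
                            stats::rnorm(n, h$by, h$sy), h$sy)
    }, 0)
    se <- stats::sd(boots)
  }
  mr_estimate(method = "Weighted median", beta = est, se = se,
              pvalue = two_sided_p(est / se), n_snps = n)
}

# weighted kernel-density mode of the ratio estimates
weighted_mode_point <- function(bx, by, sy, bandwidth_factor) {
  r <- by / bx
  if (diff(range(r)) < 1e-14) return(r[1L])  # degenerate consensus
  w <- bx^2 / sy^2
  w <- w / sum(w)
  n <- length(r)
  # modified Silverman spread: mad-guarded so a majority of identical
  # ratios does not collapse (or explode) the bandwidth
  spread <- min(stats::sd(r), stats::mad(r))
  if (!is.finite(spread) || spread <= 0) {
    spread <- min(stats::sd(r), stats::IQR(r) / 1.349)
  }
  if (!is.finite(spread) || spread <= 0) spread <- stats::sd(r)
  s <- 0.9 * spread * n^(-1 / 5)
  if (!is.finite(s) || s <= 0) s <- 1e-12
  d <- stats::density(r, weights = w, bw = bandwidth_factor * s, n = 2048L)
  d$x[which.max(d$y)]
}

#' Weighted mode estimator
#'
#' The mode of the weighted kernel-smoothed density of per-SNP Wald ratios
#' (normal kernel; bandwidth is `bandwidth_factor` times the modified
#' Silverman rule `0.9 min(sd, mad) n^{-1/5}`): consistent when the largest
#' cluster of instruments is valid. SE by parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor multiplier on the automatic bandwidth; default 1.
#' @return an `mr_estimate`.
#' @export
mr_weighted_mode <- function(h, bandwidth_factor = 1, boot_reps = 1000L,
                             seed = NULL) {
  check_univariable(h)
  n <- n_snps(h)
  if (n < 3L) err_data("weighted mode requires at least 3 instruments")
  bx <- h$bx[, 1L]
  if (any(bx == 0)) {
    err_data(paste0("zero exposure effect for variant(s): ",
                    paste(h$variant_id[bx == 0], collapse = ", ")))
  }
  if (bandwidth_factor <= 0) err_config("bandwidth_factor must be positive")
  est <- weighted_mode_point(bx, h$by, h$sy, bandwidth_factor)
  se <- NA_real_
  if (boot_reps > 0L) {
    if (is.null(seed)) err_config("seed is required when boot_reps > 0")
    set.seed(as.integer(seed))
    sx <- h$sx[, 1L]
    boots <- vapply(seq_len(boot_reps), function(b) {
      weighted_mode_point(stats::rnorm(n, bx, sx),
                          stats::rnorm(n, h$by, h$sy), h$sy, bandwidth_factor)
    }, 0)
    se <- stats::sd(boots)
  }
  mr_estimate(method = "Weighted mode", beta = est, se = se,
              pvalue = two_sided_p(est / se), n_snps = n)
}

# Huber influence function with tuning constant c
psi_huber <- function(t, c = 1.345) pmin(pmax(t, -c), c)

#' Robust adjusted profile score (RAPS) estimator
#'
#' Solves the profile-score estimating equation
#' `sum psi(t_j(theta)) * d t_j / d theta = 0` with standardized residuals
#' `t_j = (by_j - theta bx_j) / sqrt(sy_j^2 + theta^2 sx_j^2 + tau^2)`,
#' which accounts for sampling error in the exposure coefficients and is
#' therefore robust to weak instrument bias. `psi` is the identity (`l2`) or
#' the Huber influence function with tuning constant 1.345 (`huber`,
#' default). The optional multiplicative overdispersion parameter `tau^2`
#' absorbs systematic (balanced) pleiotropy and is profiled jointly via the
#' second moment equation `sum (psi(t) t - delta) / sigma^2 = 0` with
#' `delta = E[psi(Z) Z]` for standard normal Z. SEs use a sandwich formula.
#' Root finding is bracketed around the IVW estimate.
#'
#' @param h univariable `harmonized_set` with at least 3 variants.
#' @param loss `"huber"` (default) or `"l2"`.
#' @param overdispersion profile an overdispersion parameter (default TRUE).
#' @param max_expand bracket expansion attempts before declaring
#'   non-convergence.
#' @return an `mr_estimate`.
#' @export
mr_raps <- function(h, loss = c("huber", "l2"), overdispersion = TRUE,
                    max_expand = 60L) {
  check_univariable(h)
  loss <- match.arg(loss)
  n <- n_snps(h)
  if (n < 3L) err_data("MR-RAPS requires at least 3 instruments")
  bx <- h$bx[, 1L]; sx <- h$sx[, 1L]; by <- h$by; sy <- h$sy
  cc <- 1.345
  psi <- if (loss == "l2") function(t) t else function(t) psi_huber(t, cc)
  delta <- if (loss == "l2") 1 else 2 * stats::pnorm(cc) - 1

  rho <- if (loss == "l2") {
    function(t) t^2 / 2
  } else {
    function(t) ifelse(abs(t) <= cc, t^2 / 2, cc * abs(t) - cc^2 / 2)
  }
  score <- function(theta, tau2) {
    sig2 <- sy^2 + theta^2 * sx^2 + tau2
    sig <- sqrt(sig2)
    resid <- by - theta * bx
    t_j <- resid / sig
    dt <- -(bx * sig2 + resid * theta * sx^2) / (sig2 * sig)
    sum(psi(t_j) * dt)
  }
  # the score is the gradient of the integrated objective; minimizing the
  # objective is far more robust than sign-change bracketing because the
  # score decays to zero in both tails
  objective <- function(theta, tau2) {
    sig <- sqrt(sy^2 + theta^2 * sx^2 + tau2)
    sum(rho((by - theta * bx) / sig))
  }
  solve_theta <- function(tau2) {
    start <- mr_ivw(h, "fixed")$beta
    span <- max(abs(start), 0.5)
    k <- 0L
    repeat {
      opt <- stats::optimize(objective, c(start - span, start + span),
                             tau2 = tau2, tol = 1e-12)
      edge <- 0.01 * span
      if (opt$minimum > start - span + edge &&
          opt$minimum < start + span - edge) {
        return(opt$minimum)
      }
      span <- span * 3
      k <- k + 1L
      if (k > max_expand) err_numeric("MR-RAPS: profile-score minimization did not converge")
    }
  }
  moment <- function(tau2) {
    theta <- solve_theta(tau2)
    sig2 <- sy^2 + theta^2 * sx^2 + tau2
    t_j <- (by - theta * bx) / sqrt(sig2)
    sum((psi(t_j) * t_j - delta) / sig2)
  }
  tau2 <- 0
  if (overdispersion) {
    if (moment(0) > 0) {
      upper <- stats::var(by) + max(sy^2)
      k <- 0L
      while (moment(upper) > 0) {
        upper <- upper * 4
        k <- k + 1L
        if (k > 30L) err_numeric("MR-RAPS: overdispersion estimate did not converge")
      }
      tau2 <- stats::uniroot(moment, c(0, upper), tol = 1e-12)$root
    }
  }
  theta <- solve_theta(tau2)
  # sandwich SE: V = sum psi^2 (dt)^2, I = -d score/d theta (numeric)
  sig2 <- sy^2 + theta^2 * sx^2 + tau2
  sig <- sqrt(sig2)
  resid <- by - theta * bx
  dt <- -(bx * sig2 + resid * theta * sx^2) / (sig2 * sig)
  V <- sum(psi(resid / sig)^2 * dt^2)
  eps <- max(1e-6, abs(theta) * 1e-6)
  I <- abs(score(theta + eps, tau2) - score(theta - eps, tau2)) / (2 * eps)
  if (!is.finite(I) || I == 0) err_numeric("MR-RAPS: singular information at the solution")
  se <- sqrt(V) / I
  mr_estimate(method = "MR-RAPS", beta = theta, se = se,
              pvalue = two_sided_p(theta / se), n_snps = n)
}

#' Per-SNP instrument strength (F statistics)
#'
#' Under the standard approximation the per-variant F statistic equals the
#' squared exposure z-score, `F_j = (bx_j / sx_j)^2`. As a rule of thumb,
#' instruments with F > 10 are unlikely to induce appreciable weak
#' instrument bias in IVW.
#'
#' @param h univariable `harmonized_set`.
#' @return an `instrument_strength` object: named `per_snp_F` plus
#'   `min_F`, `mean_F`, `max_F`.
#' @export
per_snp_f <- function(h) {
  check_univariable(h)
  sx <- h$sx[, 1L]
  if (any(sx == 0)) {
    err_data(paste0("zero exposure SE for variant(s): ",
                    paste(h$variant_id[sx == 0], collapse = ", ")))
  }
  f <- (h$bx[, 1L] / sx)^2
  names(f) <- h$variant_id
  structure(list(per_snp_F = f, min_F = min(f), mean_F = mean(f),
                 max_F = max(f)),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("Instrument strength: %d SNP(s); F min %.1f, mean %.1f, max %.1f; %d with F < 10\n",
              length(x$per_snp_F), x$min_F, x$mean_F, x$max_F,
              sum(x$per_snp_F < 10)))
  invisible(x)
}

# variance explained by one variant in one trait
steiger_r2 <- function(beta, se, n, binary, method, eaf = NULL) {
  z <- beta / se
  if (!binary) {
    t2 <- z^2
    t2 / (t2 + n - 2)
  } else if (method == "z_sqrt_n") {
    z^2 / n
  } else { # log-odds-based observed-scale approximation; needs eaf
    if (is.null(eaf) || anyNA(eaf)) {
      err_config("binary_method = 'logodds' requires effect allele frequencies")
    }
    v <- beta^2 * 2 * eaf * (1 - eaf)
    v / (v + pi^2 / 3)
  }
}

#' Steiger directionality filtering
#'
#' Per variant, estimates the variance explained in the exposure and in the
#' outcome and retains only variants explaining more variance in the
#' exposure (consistent with the assumed causal direction). Continuous
#' traits use `r2 = t^2 / (t^2 + n - 2)`; binary traits use the
#' observed-scale approximation `r ~ z / sqrt(n)` by default, or a
#' log-odds-based approximation requiring allele frequencies
#' (`binary_method = "logodds"`). The report includes the Steiger z-test
#' p-value comparing the two correlations (Fisher z transform).
#'
#' @param h univariable `harmonized_set`.
#' @param n_exposure,n_outcome GWAS sample sizes (required).
#' @param exposure_binary,outcome_binary trait types.
#' @param binary_method `"z_sqrt_n"` (default) or `"logodds"`.
#' @return list with `filtered` (retained subset, a `harmonized_set`) and
#'   `report` (per-variant r2 values, retention flag, Steiger p).
#' @export
steiger_filter <- function(h, n_exposure, n_outcome,
                           exposure_binary = FALSE, outcome_binary = FALSE,
                           binary_method = c("z_sqrt_n", "logodds")) {
  check_univariable(h)
  binary_method <- match.arg(binary_method)
  if (missing(n_exposure) || missing(n_outcome) ||
      is.null(n_exposure) || is.null(n_outcome) ||
      !is.finite(n_exposure) || !is.finite(n_outcome) ||
      n_exposure <= 0 || n_outcome <= 0) {
    err_config("steiger_filter requires positive sample sizes for both traits")
  }
  r2x <- steiger_r2(h$bx[, 1L], h$sx[, 1L], n_exposure, exposure_binary,
                    binary_method)
  r2y <- steiger_r2(h$by, h$sy, n_outcome, outcome_binary, binary_method)
  rx <- sqrt(pmin(r2x, 1 - 1e-12))
  ry <- sqrt(pmin(r2y, 1 - 1e-12))
  zstat <- (atanh(rx) - atanh(ry)) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  retained <- r2x > r2y
  report <- data.frame(variant_id = h$variant_id,
                       r2_exposure = r2x, r2_outcome = r2y,
                       retained = retained,
                       steiger_p = two_sided_p(zstat),
                       stringsAsFactors = FALSE)
  list(filtered = h_subset(h, retained), report = report)
}

#' Run a set of univariable estimators and collect a results table
#'
#' @param h univariable `harmonized_set`.
#' @param methods subset of `c("ivw", "egger", "wmedian", "wmode", "raps")`.
#' @param boot_reps bootstrap resamples for median/mode SEs.
#' @param seed integer seed for the bootstraps.
#' @return data frame with one row per method (see [mr_results_table()]).
#' @export
run_uvmr <- function(h, methods = c("ivw", "egger", "wmedian", "wmode", "raps"),
                     boot_reps = 1000L, seed = 1L) {
  known <- c("ivw", "egger", "wmedian", "wmode", "raps")
  bad <- setdiff(methods, known)
  if (length(bad)) err_config(paste0("unknown method(s): ", paste(bad, collapse = ", ")))
  ests <- list()
  for (m in methods) {
    est <- tryCatch(switch(m,
      ivw = mr_ivw(h),
      egger = mr_egger(h),
      wmedian = mr_weighted_median(h, boot_reps = boot_reps, seed = seed),
      wmode = mr_weighted_mode(h, boot_reps = boot_reps, seed = seed),
      raps = mr_raps(h)
    ), mrlink_data_error = function(e) e)
    ests[[m]] <- est
  }
  mr_results_table(ests)
}

#' Assemble a common results table from a list of estimates
#'
#' @param ests list of `mr_estimate` objects (entries that are error
#'   conditions are reported as not-estimable rows).
#' @return data frame with columns method, n_snps, beta, se, ci_low,
#'   ci_high, pvalue, intercept, intercept_se, intercept_pvalue, Q, Q_df,
#'   Q_pvalue, note.
#' @export
mr_results_table <- function(ests) {
  rows <- lapply(ests, function(e) {
    if (inherits(e, "condition")) {
      return(data.frame(method = NA_character_, n_snps = NA_integer_,
                        beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, pvalue = NA_real_,
                        intercept = NA_real_, intercept_se = NA_real_,
                        intercept_pvalue = NA_real_, Q = NA_real_,
                        Q_df = NA_integer_, Q_pvalue = NA_real_,
                        note = conditionMessage(e), stringsAsFactors = FALSE))
    }
    data.frame(method = e$method, n_snps = e$n_snps, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
               intercept = e$intercept$value %||% NA_real_,
               intercept_se = e$intercept$se %||% NA_real_,
               intercept_pvalue = e$intercept$pvalue %||% NA_real_,
               Q = e$het$Q %||% NA_real_,
               Q_df = e$het$df %||% NA_integer_,
               Q_pvalue = e$het$pvalue %||% NA_real_,
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bad <- is.na(out$method)
  out$method[bad] <- paste0("not estimable (", names(ests)[bad], ")")
  rownames(out) <- NULL
  out
}
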