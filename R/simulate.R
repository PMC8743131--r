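#' Configuration for a synthetic two-sample MR dataset
#'
#' Describes the generative model for a pair (or trio) of GWAS
#' summary-statistic sets with known causal structure. Per variant j the
#' exposure effect `bx_j` is drawn from a normal distribution (truncated
#' away from zero when genome-wide-significant instruments are requested),
#' the outcome effect is `by_j = theta * bx_j + alpha_j + noise`, standard
#' errors scale as `1/sqrt(2 n f (1-f))` with reference allele frequency
#' `f` (drawn uniform(0.05, 0.5) when frequencies are requested, constant
#' 0.25 otherwise; doubled for log-odds-scale binary traits), and
#' `alpha_j` follows the chosen pleiotropy regime.
#'
#' @param n_snps number of variants (>= 1).
#' @param theta true causal effect: scalar, or length 2 for two exposures.
#' @param bx_sd SD of the true exposure effect distribution (default 0.02;
#'   recycled over exposures). A value of 0 makes that exposure's effects
#'   exactly zero.
#' @param ensure_significant truncate true effects so every instrument's
#'   expected z-score is genome-wide significant (|z| >= 6.5); default TRUE.
#' @param positive_effects force all true exposure effects positive
#'   (coding every variant by its exposure-increasing allele); under
#'   directional pleiotropy this is the orientation in which the Egger
#'   intercept estimates the mean pleiotropic effect.
#' @param pleiotropy `"none"`, `"balanced"` (mean-zero direct effects),
#'   `"directional"` (mean `pleiotropy_mag`), or `"inside_violating"`
#'   (direct effects correlated with the instrument strength, violating the
#'   InSIDE assumption).
#' @param pleiotropy_mag magnitude parameter of the regime (SD for
#'   balanced, mean for directional, slope scale for inside_violating).
#' @param pleiotropy_frac fraction of variants receiving a pleiotropic
#'   effect (default 1; set below 0.5 to emulate a majority-valid set).
#' @param n_exp,n_out GWAS sample sizes driving the SE scales (recycled
#'   over exposures for `n_exp`).
#' @param exposure_binary,outcome_binary log-odds-scale traits (doubles the
#'   SE scale).
#' @param with_eaf draw and emit effect allele frequencies.
#' @param ld_blocks optional `list(n_blocks =, r2_range = c(lo, hi))`:
#'   variants are grouped into exchangeable LD blocks with within-block r2
#'   drawn from the range and zero across blocks.
#' @param palindromic_fraction fraction of variants assigned A/T or C/G
#'   allele pairs.
#' @param exposure_cor correlation between the two exposures' true effects
#'   (two-exposure configurations only).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_snps, theta, bx_sd = 0.02, ensure_significant = TRUE,
                       positive_effects = FALSE,
                       pleiotropy = c("none", "balanced", "directional",
                                      "inside_violating"),
                       pleiotropy_mag = 0, pleiotropy_frac = 1,
                       n_exp = 5e4, n_out = 5e4,
                       exposure_binary = FALSE, outcome_binary = FALSE,
                       with_eaf = FALSE, ld_blocks = NULL,
                       palindromic_fraction = 0, exposure_cor = 0, seed) {
  pleiotropy <- match.arg(pleiotropy)
  if (missing(seed)) err_config("seed is required")
  if (!is.numeric(n_snps) || n_snps < 1) err_config("n_snps must be >= 1")
  if (!length(theta) %in% 1:2) err_config("theta must have length 1 or 2")
  if (pleiotropy_mag < 0) err_config("pleiotropy_mag must be non-negative")
  if (pleiotropy_frac < 0 || pleiotropy_frac > 1) {
    err_config("pleiotropy_frac must lie in [0, 1]")
  }
  if (palindromic_fraction < 0 || palindromic_fraction > 1) {
    err_config("palindromic_fraction must lie in [0, 1]")
  }
  if (!is.null(ld_blocks)) {
    if (!is.list(ld_blocks) || is.null(ld_blocks$n_blocks) ||
        is.null(ld_blocks$r2_range)) {
      err_config("ld_blocks must be list(n_blocks =, r2_range = c(lo, hi))")
    }
  }
  if (abs(exposure_cor) > 1) err_config("exposure_cor must lie in [-1, 1]")
  K <- length(theta)
  structure(list(
    n_snps = as.integer(n_snps), theta = theta,
    bx_sd = rep_len(bx_sd, K), ensure_significant = ensure_significant,
    positive_effects = positive_effects,
    pleiotropy = pleiotropy, pleiotropy_mag = pleiotropy_mag,
    pleiotropy_frac = pleiotropy_frac,
    n_exp = rep_len(n_exp, K), n_out = n_out,
    exposure_binary = rep_len(exposure_binary, K),
    outcome_binary = outcome_binary,
    with_eaf = with_eaf, ld_blocks = ld_blocks,
    palindromic_fraction = palindromic_fraction,
    exposure_cor = exposure_cor, seed = as.integer(seed)
  ), class = "sim_config")
}

base_se <- function(n, f, binary) {
  (if (binary) 2 else 1) / sqrt(2 * n * f * (1 - f))
}

# chromosomes/positions/LD pairs for n variants in optional blocks
assign_loci <- function(n, ld_blocks) {
  if (is.null(ld_blocks)) {
    locus <- seq_len(n)
    block <- seq_len(n)
  } else {
    block <- rep(seq_len(ld_blocks$n_blocks), length.out = n)
    block <- sort(block)
    locus <- block
  }
  chromosome <- as.character(((locus - 1L) %% 22L) + 1L)
  base <- (((locus - 1L) %/% 22L) + 1L) * 5e7
  offset <- stats::ave(seq_len(n), block, FUN = seq_along) - 1L
  position <- as.integer(base + offset * 1000L)
  pairs <- NULL
  if (!is.null(ld_blocks)) {
    lo <- ld_blocks$r2_range[1L]; hi <- ld_blocks$r2_range[2L]
    plist <- list()
    for (b in unique(block)) {
      idx <- which(block == b)
      if (length(idx) >= 2L) {
        cmb <- utils::combn(idx, 2L)
        plist[[length(plist) + 1L]] <- data.frame(
          ia = cmb[1L, ], ib = cmb[2L, ],
          r2 = stats::runif(ncol(cmb), lo, hi))
      }
    }
    if (length(plist)) pairs <- do.call(rbind, plist)
  }
  list(chromosome = chromosome, position = position, block = block,
       pairs = pairs)
}

draw_alleles <- function(n, palindromic_fraction) {
  nonpal <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                     "G", "A", "C", "A", "G", "T", "C", "T"),
                   ncol = 2L, byrow = TRUE)
  pal <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                ncol = 2L, byrow = TRUE)
  n_pal <- round(palindromic_fraction * n)
  is_pal <- rep(FALSE, n)
  if (n_pal > 0L) is_pal[sample.int(n, n_pal)] <- TRUE
  ea <- oa <- character(n)
  pick_np <- sample.int(nrow(nonpal), n, replace = TRUE)
  pick_p <- sample.int(nrow(pal), n, replace = TRUE)
  ea <- ifelse(is_pal, pal[pick_p, 1L], nonpal[pick_np, 1L])
  oa <- ifelse(is_pal, pal[pick_p, 2L], nonpal[pick_np, 2L])
  list(ea = ea, oa = oa, is_pal = is_pal)
}

draw_pleiotropy <- function(cfg, n, bx_true_std) {
  alpha <- rep(0, n)
  if (cfg$pleiotropy == "none" || cfg$pleiotropy_mag == 0) return(alpha)
  n_pl <- round(cfg$pleiotropy_frac * n)
  if (n_pl == 0L) return(alpha)
  idx <- sample.int(n, n_pl)
  m <- cfg$pleiotropy_mag
  alpha[idx] <- switch(cfg$pleiotropy,
    balanced = stats::rnorm(n_pl, 0, m),
    directional = stats::rnorm(n_pl, m, m / 2),
    inside_violating = m * bx_true_std[idx] + stats::rnorm(n_pl, 0, m / 2)
  )
  alpha
}

sim_build_sumstats <- function(id, variant_id, loci, alleles, eaf, beta, se) {
  # extreme z-scores underflow the normal p to 0; floor at the smallest
  # normalized double (published GWAS files truncate such p-values too)
  p <- pmax(two_sided_p(beta / se), .Machine$double.xmin)
  sumstats(data.frame(
    variant_id = variant_id, chromosome = loci$chromosome,
    position = loci$position, effect_allele = alleles$ea,
    other_allele = alleles$oa, eaf = eaf, beta = beta, se = se,
    pvalue = p, n = NA_real_,
    stringsAsFactors = FALSE), trait_id = id)
}

#' Simulate a two-sample MR dataset with known causal structure
#'
#' @param cfg a `sim_config` with scalar `theta`.
#' @param exposure_id,outcome_id trait labels for the emitted tables.
#' @return list with `exposure` and `outcome` ([sumstats()] objects), `ld`
#'   (an [ld_table()]) and `truth` (true effect, per-variant pleiotropic
#'   effects, validity labels, true exposure effects).
#' @export
simulate_pair <- function(cfg, exposure_id = "exposure",
                          outcome_id = "outcome") {
  if (!inherits(cfg, "sim_config")) err_config("cfg must be a sim_config")
  if (length(cfg$theta) != 1L) err_config("simulate_pair needs a scalar theta")
  set.seed(cfg$seed)
  n <- cfg$n_snps
  f <- if (cfg$with_eaf) stats::runif(n, 0.05, 0.5) else rep(0.25, n)
  se_x <- base_se(cfg$n_exp[1L], f, cfg$exposure_binary[1L])
  se_y <- base_se(cfg$n_out, f, cfg$outcome_binary)
  bx_true <- stats::rnorm(n, 0, cfg$bx_sd[1L])
  if (cfg$ensure_significant && cfg$bx_sd[1L] > 0) {
    bx_true <- sign1(bx_true) * pmax(abs(bx_true), 6.5 * se_x)
  }
  if (cfg$positive_effects) bx_true <- abs(bx_true)
  alpha <- draw_pleiotropy(cfg, n, bx_true / max(cfg$bx_sd[1L], 1e-12))
  bx_obs <- bx_true + stats::rnorm(n, 0, se_x)
  by_obs <- cfg$theta * bx_true + alpha + stats::rnorm(n, 0, se_y)
  loci <- assign_loci(n, cfg$ld_blocks)
  alleles <- draw_alleles(n, cfg$palindromic_fraction)
  ids <- sprintf("rs%d", seq_len(n))
  eaf <- if (cfg$with_eaf) f else NA_real_
  exposure <- sim_build_sumstats(exposure_id, ids, loci, alleles, eaf,
                                 bx_obs, se_x)
  outcome <- sim_build_sumstats(outcome_id, ids, loci, alleles, eaf,
                                by_obs, se_y)
  ld <- if (is.null(loci$pairs)) ld_table(NULL) else {
    ld_table(data.frame(id_a = ids[loci$pairs$ia], id_b = ids[loci$pairs$ib],
                        r2 = loci$pairs$r2))
  }
  list(exposure = exposure, outcome = outcome, ld = ld,
       truth = list(theta = cfg$theta, alpha = alpha, valid = alpha == 0,
                    bx_true = bx_true, palindromic = ids[alleles$is_pal]))
}

#' Simulate a three-table dataset for multivariable MR
#'
#' Two exposures with true effect correlation `exposure_cor`; the outcome
#' is `by = theta[1] bx1 + theta[2] bx2 + alpha + noise`.
#'
#' @param cfg a `sim_config` with length-2 `theta`.
#' @param exposure_ids,outcome_id trait labels.
#' @return list with `exposure1`, `exposure2`, `outcome`, `ld`, `truth`.
#' @export
simulate_mvmr <- function(cfg, exposure_ids = c("exposure1", "exposure2"),
                          outcome_id = "outcome") {
  if (!inherits(cfg, "sim_config")) err_config("cfg must be a sim_config")
  if (length(cfg$theta) != 2L) err_config("simulate_mvmr needs a length-2 theta")
  set.seed(cfg$seed)
  n <- cfg$n_snps
  f <- if (cfg$with_eaf) stats::runif(n, 0.05, 0.5) else rep(0.25, n)
  se_x1 <- base_se(cfg$n_exp[1L], f, cfg$exposure_binary[1L])
  se_x2 <- base_se(cfg$n_exp[2L], f, cfg$exposure_binary[2L])
  se_y <- base_se(cfg$n_out, f, cfg$outcome_binary)
  z1 <- stats::rnorm(n)
  z2 <- cfg$exposure_cor * z1 + sqrt(1 - cfg$exposure_cor^2) * stats::rnorm(n)
  bx1_true <- cfg$bx_sd[1L] * z1
  bx2_true <- cfg$bx_sd[2L] * z2
  if (cfg$ensure_significant) {
    if (cfg$bx_sd[1L] > 0) {
      bx1_true <- sign1(bx1_true) * pmax(abs(bx1_true), 6.5 * se_x1)
    }
    if (cfg$bx_sd[2L] > 0) {
      bx2_true <- sign1(bx2_true) * pmax(abs(bx2_true), 6.5 * se_x2)
    }
  }
  alpha <- draw_pleiotropy(cfg, n, z1)
  bx1_obs <- bx1_true + stats::rnorm(n, 0, se_x1)
  bx2_obs <- bx2_true + stats::rnorm(n, 0, se_x2)
  by_obs <- cfg$theta[1L] * bx1_true + cfg$theta[2L] * bx2_true + alpha +
    stats::rnorm(n, 0, se_y)
  loci <- assign_loci(n, cfg$ld_blocks)
  alleles <- draw_alleles(n, cfg$palindromic_fraction)
  ids <- sprintf("rs%d", seq_len(n))
  eaf <- if (cfg$with_eaf) f else NA_real_
  ld <- if (is.null(loci$pairs)) ld_table(NULL) else {
    ld_table(data.frame(id_a = ids[loci$pairs$ia], id_b = ids[loci$pairs$ib],
                        r2 = loci$pairs$r2))
  }
  list(
    exposure1 = sim_build_sumstats(exposure_ids[1L], ids, loci, alleles, eaf,
                                   bx1_obs, se_x1),
    exposure2 = sim_build_sumstats(exposure_ids[2L], ids, loci, alleles, eaf,
                                   bx2_obs, se_x2),
    outcome = sim_build_sumstats(outcome_id, ids, loci, alleles, eaf,
                                 by_obs, se_y),
    ld = ld,
    truth = list(theta = cfg$theta, alpha = alpha, valid = alpha == 0,
                 bx1_true = bx1_true, bx2_true = bx2_true,
                 palindromic = ids[alleles$is_pal])
  )
}
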