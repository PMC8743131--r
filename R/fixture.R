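#' Synthetic analysis bundles shaped like the published GWAS analyses
#'
#' Emits fully synthetic two-sample MR bundles sized like the four
#' trait-pair analyses of the motivating study of ADHD, autism (ASD),
#' educational attainment (EA) and cognitive ability: 11 ADHD instruments
#' (per-SNP F in 30-51), 10 ASD instruments at the relaxed 5e-7 threshold
#' (F in 26-36), 481 EA instruments (F in 30-240), and in every bundle a
#' 212-instrument cognitive-ability second exposure for multivariable MR.
#' Each instrument comes with an LD satellite (r2 = 0.95, weaker p-value)
#' so clumping and proxy lookup have real work to do; one instrument is
#' absent from the outcome table so the proxy path is exercised; outcome
#' records use randomly swapped or strand-complemented allele
#' representations so harmonization must act; null filler variants (some
#' palindromic) pad the tables. The EA-exposure bundles embed a fixed
#' number of reverse-direction contaminants (81 for the ADHD outcome, 62
#' for ASD) that explain more variance in the outcome than in the exposure,
#' so Steiger filtering removes exactly that many; all other instruments
#' are constructed to survive the filter.
#'
#' @param name one of `"adhd_to_ea"`, `"asd_to_ea"`, `"ea_to_adhd"`,
#'   `"ea_to_asd"`.
#' @param seed integer seed; each bundle has a fixed default so repeated
#'   calls are byte-identical.
#' @return an `mr_fixture` list: `exposure`, `outcome`, `second_exposure`
#'   (cognitive ability), `ld`, `p_threshold`, sample sizes/trait types,
#'   and a `truth` record (true direct effects, instrument and contaminant
#'   ids, per-instrument F values, satellite map).
#' @export
fixture_bundle <- function(name, seed = NULL) {
  specs <- list(
    adhd_to_ea = list(exposure_id = "adhd", outcome_id = "ea",
                      n_exposure = 55374, n_outcome = 766345,
                      exposure_binary = TRUE, outcome_binary = FALSE,
                      n_inst = 11L, f_range = c(30, 51), p_threshold = 5e-8,
                      theta1 = -0.049, theta2 = 0.3, n_rev = 0L, seed = 101L),
    asd_to_ea = list(exposure_id = "asd", outcome_id = "ea",
                     n_exposure = 46350, n_outcome = 766345,
                     exposure_binary = TRUE, outcome_binary = FALSE,
                     n_inst = 10L, f_range = c(26, 36), p_threshold = 5e-7,
                     theta1 = 0.028, theta2 = 0.3, n_rev = 0L, seed = 102L),
    ea_to_adhd = list(exposure_id = "ea", outcome_id = "adhd",
                      n_exposure = 766345, n_outcome = 55374,
                      exposure_binary = FALSE, outcome_binary = TRUE,
                      n_inst = 481L, f_range = c(30, 240), p_threshold = 5e-8,
                      theta1 = log(0.33), theta2 = -0.5, n_rev = 81L,
                      seed = 103L),
    ea_to_asd = list(exposure_id = "ea", outcome_id = "asd",
                     n_exposure = 766345, n_outcome = 46350,
                     exposure_binary = FALSE, outcome_binary = TRUE,
                     n_inst = 481L, f_range = c(30, 240), p_threshold = 5e-8,
                     theta1 = log(1.24), theta2 = 0.3, n_rev = 62L,
                     seed = 104L)
  )
  if (length(name) != 1L || !name %in% names(specs)) {
    err_config(paste0("unknown fixture name: ", paste(name, collapse = ", "),
                      " (expected one of ", paste(names(specs), collapse = ", "), ")"))
  }
  sp <- specs[[name]]
  n_cog <- 212L
  cog_f_range <- c(30, 120)
  n_cog_gwas <- 269867
  n_fill <- 60L
  set.seed(if (is.null(seed)) sp$seed else as.integer(seed))

  f_ref <- 0.25
  sx1 <- base_se(sp$n_exposure, f_ref, sp$exposure_binary)   # primary exposure
  sx2 <- base_se(n_cog_gwas, f_ref, FALSE)                    # cognitive ability
  sy <- base_se(sp$n_outcome, f_ref, sp$outcome_binary)

  # --- variant bookkeeping -------------------------------------------------
  n_inst <- sp$n_inst
  roles <- c(rep("inst", n_inst), rep("sat", n_inst),
             rep("cog", n_cog), rep("cog_sat", n_cog),
             rep("fill", n_fill))
  n_all <- length(roles)
  ids <- sprintf("rs%d", seq_len(n_all))
  inst_idx <- which(roles == "inst")
  sat_idx <- which(roles == "sat")
  cog_idx <- which(roles == "cog")
  cog_sat_idx <- which(roles == "cog_sat")
  fill_idx <- which(roles == "fill")

  # each instrument shares a locus with its satellite; everything else is
  # an isolated locus
  locus <- integer(n_all)
  locus[inst_idx] <- seq_len(n_inst)
  locus[sat_idx] <- seq_len(n_inst)
  locus[cog_idx] <- n_inst + seq_len(n_cog)
  locus[cog_sat_idx] <- n_inst + seq_len(n_cog)
  locus[fill_idx] <- n_inst + n_cog + seq_len(n_fill)
  chromosome <- as.character(((locus - 1L) %% 22L) + 1L)
  base_pos <- (((locus - 1L) %/% 22L) + 1L) * 5e7
  position <- as.integer(base_pos + ifelse(roles %in% c("sat", "cog_sat"),
                                           1000L, 0L))

  # alleles: instruments non-palindromic; ~15% of fillers palindromic
  alleles <- list(ea = character(n_all), oa = character(n_all))
  nonpal <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                   ncol = 2L, byrow = TRUE)
  pick <- sample.int(nrow(nonpal), n_all, replace = TRUE)
  alleles$ea <- nonpal[pick, 1L]
  alleles$oa <- nonpal[pick, 2L]
  pal_fill <- fill_idx[seq_len(round(0.15 * n_fill))]
  alleles$ea[pal_fill] <- "A"; alleles$oa[pal_fill] <- "T"

  # --- exposure effects ----------------------------------------------------
  # primary instruments: observed F drawn from the reported range
  F1 <- stats::runif(n_inst, sp$f_range[1L], sp$f_range[2L])
  sgn1 <- sample(c(-1, 1), n_inst, replace = TRUE)
  # satellites: same sign, F between the range floor and the partner's F,
  # so the instrument always wins the greedy clump
  F1s <- stats::runif(n_inst, sp$f_range[1L], F1)
  bx1 <- numeric(n_all)
  bx1[inst_idx] <- sgn1 * sqrt(F1) * sx1
  bx1[sat_idx] <- sgn1 * sqrt(F1s) * sx1
  # cognitive instruments and their satellites
  F2 <- stats::runif(n_cog, cog_f_range[1L], cog_f_range[2L])
  sgn2 <- sample(c(-1, 1), n_cog, replace = TRUE)
  F2s <- stats::runif(n_cog, cog_f_range[1L], F2)
  bx2 <- numeric(n_all)
  bx2[cog_idx] <- sgn2 * sqrt(F2) * sx2
  bx2[cog_sat_idx] <- sgn2 * sqrt(F2s) * sx2
  # weak cross-trait effects: z-scores clamped below significance so no
  # stray variant crosses the instrument threshold
  rnorm_clamped <- function(n, sd) {
    z <- stats::rnorm(n, 0, sd)
    pmin(pmax(z, -4.5), 4.5)
  }
  bx2[c(inst_idx, sat_idx)] <- rnorm_clamped(2L * n_inst, 1.5) * sx2
  bx1[c(cog_idx, cog_sat_idx)] <- rnorm_clamped(2L * n_cog, 1.5) * sx1
  z_fill <- stats::qnorm(stats::runif(n_fill, 0.2, 1) / 2) *
    sample(c(-1, 1), n_fill, replace = TRUE)
  bx1[fill_idx] <- z_fill * sx1
  bx2[fill_idx] <- rnorm_clamped(n_fill, 0.5) * sx2

  # --- outcome effects -----------------------------------------------------
  by <- sp$theta1 * bx1 + sp$theta2 * bx2 + stats::rnorm(n_all, 0, sy)

  # variance explained in the exposure per primary instrument/satellite
  r2_exp <- function(Fv) {
    if (sp$exposure_binary) Fv / sp$n_exposure
    else Fv / (Fv + sp$n_exposure - 2)
  }
  # outcome z bound below which a variant explains less outcome variance
  z_keep_limit <- function(r2x) {
    if (sp$outcome_binary) sqrt(r2x * sp$n_outcome)
    else sqrt(r2x * (sp$n_outcome - 2) / (1 - r2x))
  }
  # guarantee the causal direction is detectable as correct for every
  # non-contaminant instrument (and satellite, which can become a proxy)
  guard <- c(inst_idx, sat_idx)
  r2x_guard <- r2_exp(c(F1, F1s))
  lim <- 0.9 * z_keep_limit(r2x_guard)
  zg <- by[guard] / sy
  by[guard] <- sign1(zg) * pmin(abs(zg), lim) * sy
  # reverse-direction contaminants: overwrite so the outcome r2 is 3x the
  # exposure r2 (removed by Steiger filtering, by construction)
  rev_idx <- integer(0)
  if (sp$n_rev > 0L) {
    # never contaminate the instrument that is absent from the outcome:
    # its proxy satellite is direction-guarded, so the contaminant count
    # after proxy substitution would fall short
    rev_idx <- sort(sample(inst_idx[-n_inst], sp$n_rev))
    r2x_rev <- r2_exp(F1[match(rev_idx, inst_idx)])
    z_rev <- if (sp$outcome_binary) {
      sqrt(3 * r2x_rev * sp$n_outcome)
    } else {
      sqrt(3 * r2x_rev * (sp$n_outcome - 2) / (1 - 3 * r2x_rev))
    }
    by[rev_idx] <- sign(sp$theta1) * z_rev * sy
  }

  # --- emit tables ---------------------------------------------------------
  loci <- list(chromosome = chromosome, position = position)
  mk <- function(trait, beta, se) {
    sim_build_sumstats(trait, ids, loci, alleles, NA_real_, beta,
                       rep(se, n_all))
  }
  exposure <- mk(sp$exposure_id, bx1, sx1)
  second <- mk("cognitive", bx2, sx2)

  # outcome: vary the allele representation; drop one instrument so the
  # proxy path is exercised
  rep_kind <- sample(c("same", "swap", "strand", "strand_swap"), n_all,
                     replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
  rep_kind[pal_fill] <- "same"
  out_ea <- alleles$ea; out_oa <- alleles$oa; out_beta <- by
  sw <- rep_kind %in% c("swap", "strand_swap")
  st <- rep_kind %in% c("strand", "strand_swap")
  tmp <- out_ea[sw]; out_ea[sw] <- out_oa[sw]; out_oa[sw] <- tmp
  out_beta[sw] <- -out_beta[sw]
  out_ea[st] <- unname(COMPLEMENT[out_ea[st]])
  out_oa[st] <- unname(COMPLEMENT[out_oa[st]])
  dropped_instrument <- ids[inst_idx[n_inst]]
  keep_out <- ids != dropped_instrument
  outcome <- sumstats(data.frame(
    variant_id = ids[keep_out], chromosome = chromosome[keep_out],
    position = position[keep_out], effect_allele = out_ea[keep_out],
    other_allele = out_oa[keep_out], eaf = NA_real_,
    beta = out_beta[keep_out], se = sy,
    pvalue = pmax(two_sided_p(out_beta[keep_out] / sy), .Machine$double.xmin),
    n = NA_real_,
    stringsAsFactors = FALSE), trait_id = sp$outcome_id)

  ld <- ld_table(data.frame(
    id_a = ids[c(inst_idx, cog_idx)],
    id_b = ids[c(sat_idx, cog_sat_idx)],
    r2 = 0.95))

  structure(list(
    name = name,
    exposure = exposure, outcome = outcome, second_exposure = second,
    ld = ld,
    p_threshold = sp$p_threshold,
    n_exposure = sp$n_exposure, n_outcome = sp$n_outcome,
    n_second_exposure = n_cog_gwas,
    exposure_binary = sp$exposure_binary,
    outcome_binary = sp$outcome_binary,
    truth = list(theta_direct = sp$theta1, theta_second = sp$theta2,
                 instruments = ids[inst_idx], satellites = ids[sat_idx],
                 satellite_of = stats::setNames(ids[sat_idx], ids[inst_idx]),
                 cognitive_instruments = ids[cog_idx],
                 contaminants = ids[rev_idx],
                 dropped_from_outcome = dropped_instrument,
                 F_instruments = stats::setNames(F1, ids[inst_idx]),
                 F_cognitive = stats::setNames(F2, ids[cog_idx]))
  ), class = "mr_fixture")
}

#' @export
print.mr_fixture <- function(x, ...) {
  cat(sprintf("Synthetic MR fixture '%s': %s (%d variants) -> %s; %d primary instruments, 212 cognitive instruments\n",
              x$name, trait_id(x$exposure), nrow(x$exposure),
              trait_id(x$outcome), length(x$truth$instruments)))
  invisible(x)
}
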