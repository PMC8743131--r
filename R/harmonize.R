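#' Is a variant palindromic?
#'
#' Palindromic (ambiguous-strand) variants carry the allele pair A/T or C/G,
#' which is identical to its own reverse complement, so strand cannot be
#' resolved from the alleles alone.
#'
#' @param effect_allele,other_allele single-letter allele vectors.
#' @return logical vector.
#' @export
classify_palindromic <- function(effect_allele, other_allele) {
  a <- toupper(effect_allele)
  b <- toupper(other_allele)
  pair <- paste(pmin(a, b), pmax(a, b), sep = "")
  pair %in% c("AT", "CG")
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

# Align one trait's record onto the reference effect/other allele.
# Returns list(status, beta, eaf, action); status "ok" or an exclusion reason.
align_alleles <- function(ref_ea, ref_oa, ea, oa, beta, eaf,
                          ref_eaf, use_eaf, eaf_window) {
  if (classify_palindromic(ref_ea, ref_oa)) {
    same_pair <- setequal(c(ea, oa), c(ref_ea, ref_oa))
    if (!same_pair) {
      return(list(status = "allele_mismatch", beta = NA_real_, eaf = NA_real_,
                  action = "allele_mismatch"))
    }
    if (!isTRUE(use_eaf) || is.na(eaf) || is.na(ref_eaf) ||
        abs(eaf - 0.5) < eaf_window || abs(ref_eaf - 0.5) < eaf_window) {
      return(list(status = "palindromic", beta = NA_real_, eaf = NA_real_,
                  action = "palindromic"))
    }
    # orient by allele labels first, then check whether the minor allele
    # agrees with the reference; disagreement implies the other strand
    if (ea == ref_ea) {
      b1 <- beta; f1 <- eaf; act <- "copy"
    } else {
      b1 <- -beta; f1 <- 1 - eaf; act <- "flip"
    }
    if ((f1 < 0.5) != (ref_eaf < 0.5)) {
      b1 <- -b1; f1 <- 1 - f1; act <- "palindromic_freq_flip"
    }
    return(list(status = "ok", beta = b1, eaf = f1, action = act))
  }
  if (ea == ref_ea && oa == ref_oa) {
    return(list(status = "ok", beta = beta, eaf = eaf, action = "copy"))
  }
  if (ea == ref_oa && oa == ref_ea) {
    return(list(status = "ok", beta = -beta,
                eaf = if (is.na(eaf)) NA_real_ else 1 - eaf, action = "flip"))
  }
  cea <- unname(COMPLEMENT[ea]); coa <- unname(COMPLEMENT[oa])
  if (cea == ref_ea && coa == ref_oa) {
    return(list(status = "ok", beta = beta, eaf = eaf, action = "strand"))
  }
  if (cea == ref_oa && coa == ref_ea) {
    return(list(status = "ok", beta = -beta,
                eaf = if (is.na(eaf)) NA_real_ else 1 - eaf, action = "strand_flip"))
  }
  list(status = "allele_mismatch", beta = NA_real_, eaf = NA_real_,
       action = "allele_mismatch")
}

#' Harmonize exposure and outcome effects onto a shared effect allele
#'
#' Aligns every variant shared by all exposures and the outcome to the first
#' exposure's effect allele. Swapped allele orders negate the mismatched
#' trait's beta (and complement the allele frequency); alternate-strand
#' representations are mapped through the base complement first. Palindromic
#' variants cannot be resolved from alleles alone: by default they are
#' excluded with reason `"palindromic"`; when `use_eaf = TRUE` and both sides
#' carry informative allele frequencies (outside `0.5 +/- eaf_window`) they
#' are oriented by matching the minor allele. Irreconcilable allele pairs
#' are excluded with reason `"allele_mismatch"`.
#'
#' @param exposures a `sumstats` object or list of them (already
#'   instrument-selected); the first exposure fixes the reference allele.
#' @param outcome a `sumstats` object.
#' @param use_eaf attempt frequency-based rescue of palindromic variants.
#' @param eaf_window half-width of the ambiguity zone around 0.5 within
#'   which palindromic frequencies are considered uninformative; default
#'   0.08 (frequencies in 0.42-0.58 always ambiguous).
#' @return a `harmonized_set`: list with `exposure_ids`, `outcome_id`,
#'   `variant_id`, `effect_allele`, `other_allele`, `bx`/`sx` (n x K
#'   matrices), `by`/`sy`, `exposure_pvalues`, `exclusions` (variant, reason)
#'   and a per-variant `report` of actions taken.
#' @export
harmonize <- function(exposures, outcome, use_eaf = FALSE, eaf_window = 0.08) {
  if (inherits(exposures, "sumstats")) exposures <- list(exposures)
  if (!length(exposures) || !all(vapply(exposures, inherits, TRUE, "sumstats"))) {
    err_config("exposures must be a sumstats object or a list of them")
  }
  if (!inherits(outcome, "sumstats")) err_config("outcome must be a sumstats object")
  if (!is.numeric(eaf_window) || eaf_window < 0 || eaf_window >= 0.5) {
    err_config("eaf_window must lie in [0, 0.5)")
  }
  K <- length(exposures)
  exposure_ids <- vapply(exposures, trait_id, "")
  shared <- Reduce(intersect, c(lapply(exposures, function(s) s$variant_id),
                                list(outcome$variant_id)))
  if (!length(shared)) err_data("no shared variants between exposures and outcome")
  # preserve exposure-1 ordering
  shared <- exposures[[1L]]$variant_id[exposures[[1L]]$variant_id %in% shared]

  ref <- as.data.frame(exposures[[1L]])
  ref <- ref[match(shared, ref$variant_id), , drop = FALSE]
  n <- length(shared)
  bx <- matrix(NA_real_, n, K, dimnames = list(NULL, exposure_ids))
  sx <- bx
  px <- bx
  bx[, 1L] <- ref$beta; sx[, 1L] <- ref$se; px[, 1L] <- ref$pvalue
  by <- rep(NA_real_, n); sy <- rep(NA_real_, n)
  status <- rep("ok", n)
  report <- list()

  other_traits <- c(if (K > 1L) exposures[-1L], list(outcome))
  other_names <- c(if (K > 1L) exposure_ids[-1L], trait_id(outcome))
  aligned <- vector("list", length(other_traits))
  for (t in seq_along(other_traits)) {
    tt <- as.data.frame(other_traits[[t]])
    tt <- tt[match(shared, tt$variant_id), , drop = FALSE]
    res_beta <- rep(NA_real_, n)
    actions <- character(n)
    for (i in seq_len(n)) {
      if (status[i] != "ok") { actions[i] <- "skipped"; next }
      al <- align_alleles(ref$effect_allele[i], ref$other_allele[i],
                          tt$effect_allele[i], tt$other_allele[i],
                          tt$beta[i], tt$eaf[i], ref$eaf[i],
                          use_eaf, eaf_window)
      actions[i] <- al$action
      if (al$status != "ok") {
        status[i] <- al$status
      } else {
        res_beta[i] <- al$beta
      }
    }
    report[[t]] <- data.frame(variant_id = shared, trait = other_names[t],
                              action = actions, stringsAsFactors = FALSE)
    aligned[[t]] <- list(beta = res_beta, se = tt$se, pvalue = tt$pvalue)
  }

  keep <- status == "ok"
  if (K > 1L) {
    for (k in 2:K) {
      bx[, k] <- aligned[[k - 1L]]$beta
      sx[, k] <- aligned[[k - 1L]]$se
      px[, k] <- aligned[[k - 1L]]$pvalue
    }
  }
  by <- aligned[[length(aligned)]]$beta
  sy <- aligned[[length(aligned)]]$se

  exclusions <- data.frame(variant_id = shared[!keep], reason = status[!keep],
                           stringsAsFactors = FALSE)
  h <- structure(list(
    exposure_ids = exposure_ids,
    outcome_id = trait_id(outcome),
    variant_id = shared[keep],
    effect_allele = ref$effect_allele[keep],
    other_allele = ref$other_allele[keep],
    bx = bx[keep, , drop = FALSE],
    sx = sx[keep, , drop = FALSE],
    exposure_pvalues = px[keep, , drop = FALSE],
    by = by[keep],
    sy = sy[keep],
    exclusions = exclusions,
    report = do.call(rbind, report)
  ), class = "harmonized_set")
  h
}

#' Construct a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor for simulation and testing: all inputs are
#' assumed already expressed per the same effect allele.
#'
#' @param bx,sx exposure effects and SEs: vectors (univariable) or n x K
#'   matrices.
#' @param by,sy outcome effects and SEs.
#' @param variant_id optional ids (defaults `snp1..snpN`).
#' @param exposure_ids,outcome_id trait labels.
#' @return a `harmonized_set`.
#' @export
harmonized_set <- function(bx, sx, by, sy, variant_id = NULL,
                           exposure_ids = NULL, outcome_id = "outcome") {
  bx <- as.matrix(bx); sx <- as.matrix(sx)
  n <- nrow(bx); K <- ncol(bx)
  if (is.null(exposure_ids)) exposure_ids <- paste0("exposure", seq_len(K))
  if (is.null(variant_id)) variant_id <- paste0("snp", seq_len(n))
  stopifnot(nrow(sx) == n, ncol(sx) == K, length(by) == n, length(sy) == n)
  if (any(sx <= 0) || any(sy <= 0)) err_data("all standard errors must be positive")
  colnames(bx) <- colnames(sx) <- exposure_ids
  structure(list(
    exposure_ids = exposure_ids, outcome_id = outcome_id,
    variant_id = as.character(variant_id),
    effect_allele = rep("A", n), other_allele = rep("G", n),
    bx = bx, sx = sx,
    exposure_pvalues = matrix(two_sided_p(bx / sx), n, K,
                              dimnames = list(NULL, exposure_ids)),
    by = as.numeric(by), sy = as.numeric(sy),
    exclusions = data.frame(variant_id = character(), reason = character(),
                            stringsAsFactors = FALSE),
    report = NULL
  ), class = "harmonized_set")
}

#' Number of variants in a harmonized set
#' @param h a `harmonized_set`.
#' @return integer.
#' @export
n_snps <- function(h) length(h$by)

# subset rows of a harmonized set
h_subset <- function(h, idx) {
  h$variant_id <- h$variant_id[idx]
  h$effect_allele <- h$effect_allele[idx]
  h$other_allele <- h$other_allele[idx]
  h$bx <- h$bx[idx, , drop = FALSE]
  h$sx <- h$sx[idx, , drop = FALSE]
  h$exposure_pvalues <- h$exposure_pvalues[idx, , drop = FALSE]
  h$by <- h$by[idx]
  h$sy <- h$sy[idx]
  h
}

check_univariable <- function(h) {
  if (!inherits(h, "harmonized_set")) err_config("expected a harmonized_set")
  if (ncol(h$bx) != 1L) err_config("this estimator requires a single exposure")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s; %d variant(s), %d excluded\n",
              paste(x$exposure_ids, collapse = " + "), x$outcome_id,
              n_snps(x), nrow(x$exclusions)))
  invisible(x)
}
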