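#' GWAS summary statistics for a single trait
#'
#' A `sumstats` object is a validated data frame of per-variant association
#' results with canonical columns `variant_id`, `chromosome`, `position`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' Betas are on the trait's reported scale: log odds for binary traits,
#' standard-deviation units for continuous traits. Restricted to biallelic
#' SNPs (single-nucleotide alleles in A/C/G/T).
#'
#' @param df data frame with at least the mandatory canonical columns
#'   (`eaf` and `n` may be absent; they are filled with `NA`).
#' @param trait_id character scalar identifying the trait.
#' @param validate_pvalues if `TRUE`, check that each reported p-value is
#'   consistent with the two-sided normal p implied by `beta/se` to within
#'   `p_log10_tol` on the log10 scale. Off by default because published GWAS
#'   files often truncate extreme p-values.
#' @param p_log10_tol tolerance for the p-value consistency check.
#' @return a `sumstats` object.
#' @export
sumstats <- function(df, trait_id, validate_pvalues = FALSE, p_log10_tol = 0.5) {
  if (!is.character(trait_id) || length(trait_id) != 1L || !nzchar(trait_id)) {
    err_config("trait_id must be a non-empty character scalar")
  }
  mandatory <- c("variant_id", "chromosome", "position", "effect_allele",
                 "other_allele", "beta", "se", "pvalue")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    err_config(paste0("missing mandatory column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_real_
  df <- df[c("variant_id", "chromosome", "position", "effect_allele",
             "other_allele", "eaf", "beta", "se", "pvalue", "n")]
  df$variant_id <- as.character(df$variant_id)
  df$chromosome <- as.character(df$chromosome)
  df$position <- as.integer(df$position)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n")) df[[col]] <- as.numeric(df[[col]])

  dup <- df$variant_id[duplicated(df$variant_id)]
  if (length(dup)) {
    err_data(paste0("duplicated variant_id: ", paste(unique(dup), collapse = ", ")))
  }
  bad_allele <- !(df$effect_allele %in% c("A", "C", "G", "T")) |
    !(df$other_allele %in% c("A", "C", "G", "T")) |
    df$effect_allele == df$other_allele
  if (any(bad_allele)) {
    err_data(paste0("invalid allele pair for variant(s): ",
                    paste(df$variant_id[bad_allele], collapse = ", ")))
  }
  if (any(!is.finite(df$position) | df$position <= 0L)) {
    err_data("position must be a positive integer for every variant")
  }
  if (any(!is.finite(df$se) | df$se <= 0)) {
    err_data(paste0("se must be positive; offending variant(s): ",
                    paste(df$variant_id[!is.finite(df$se) | df$se <= 0], collapse = ", ")))
  }
  if (any(!is.finite(df$beta))) err_data("beta must be finite for every variant")
  if (any(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1)) {
    err_data("pvalue must lie in (0, 1] for every variant")
  }
  if (any(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1))) {
    err_data("eaf, when present, must lie strictly in (0, 1)")
  }
  if (validate_pvalues) {
    implied <- two_sided_p(df$beta / df$se)
    off <- abs(log10(implied) - log10(df$pvalue)) > p_log10_tol
    if (any(off)) {
      err_data(paste0("reported p-value inconsistent with beta/se for: ",
                      paste(df$variant_id[off], collapse = ", ")))
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("sumstats", "data.frame"), trait_id = trait_id)
}

#' Trait identifier of a summary-statistics object
#' @param ss a `sumstats` object.
#' @return character scalar.
#' @export
trait_id <- function(ss) attr(ss, "trait_id", exact = TRUE)

# re-wrap a row subset without rerunning full validation
ss_subset <- function(ss, idx) {
  out <- as.data.frame(ss)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("sumstats", "data.frame"), trait_id = trait_id(ss))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: trait '%s', %d variant(s)\n",
              trait_id(x), nrow(x)))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more row(s)\n", nrow(x) - 10L))
  invisible(x)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-delimited file with a header row (gzip files are
#' handled transparently), renames columns to the canonical scheme via
#' `column_map`, drops rows with missing effect sizes, standard errors or
#' non-SNP alleles (counted in a message), and validates the result.
#'
#' @param path file path.
#' @param trait_id trait identifier; defaults to the file name without
#'   extensions.
#' @param column_map named character vector mapping canonical field names to
#'   file headers. Defaults: `SNP, CHR, BP, A1, A2, EAF, BETA, SE, P, N`
#'   (effect allele `A1`). Only override entries you need to change.
#' @param validate_pvalues,p_log10_tol see [sumstats()].
#' @return a `sumstats` object with attribute `n_dropped` recording the
#'   number of unusable rows removed.
#' @export
read_sumstats <- function(path, trait_id = NULL, column_map = NULL,
                          validate_pvalues = FALSE, p_log10_tol = 0.5) {
  if (!file.exists(path)) err_config(paste0("file not found: ", path))
  default_map <- c(variant_id = "SNP", chromosome = "CHR", position = "BP",
                   effect_allele = "A1", other_allele = "A2", eaf = "EAF",
                   beta = "BETA", se = "SE", pvalue = "P", n = "N")
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(default_map))
    if (length(unknown)) {
      err_config(paste0("unknown canonical field(s) in column_map: ",
                        paste(unknown, collapse = ", ")))
    }
    default_map[names(column_map)] <- column_map
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  mandatory <- c("variant_id", "chromosome", "position", "effect_allele",
                 "other_allele", "beta", "se", "pvalue")
  have <- default_map[default_map %in% names(raw)]
  missing_mand <- setdiff(mandatory, names(have))
  if (length(missing_mand)) {
    err_config(paste0("input file lacks mandatory column(s): ",
                      paste(default_map[missing_mand], collapse = ", ")))
  }
  df <- raw[unname(have)]
  names(df) <- names(have)

  usable <- !is.na(df$beta) & !is.na(df$se) &
    !is.na(df$effect_allele) & !is.na(df$other_allele) &
    toupper(df$effect_allele) %in% c("A", "C", "G", "T") &
    toupper(df$other_allele) %in% c("A", "C", "G", "T")
  n_dropped <- sum(!usable)
  if (n_dropped > 0L) {
    message(sprintf("read_sumstats: dropped %d row(s) with missing beta/se or non-SNP alleles", n_dropped))
  }
  df <- df[usable, , drop = FALSE]
  trait_id <- trait_id %||% sub("\\.(txt|tsv|csv)(\\.gz)?$", "", basename(path))
  out <- sumstats(df, trait_id = trait_id,
                  validate_pvalues = validate_pvalues, p_log10_tol = p_log10_tol)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write summary statistics in the canonical tab-delimited layout
#' @param ss a `sumstats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  out <- as.data.frame(ss)
  names(out) <- c("SNP", "CHR", "BP", "A1", "A2", "EAF", "BETA", "SE", "P", "N")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select genetic instruments by p-value threshold
#'
#' Keeps variants whose association p-value is at or below `p_threshold`
#' (the conventional genome-wide threshold is 5e-8; a relaxed threshold such
#' as 5e-7 can be used for underpowered traits at the cost of potential weak
#' instrument bias). Input order is preserved.
#'
#' @param ss a `sumstats` object.
#' @param p_threshold significance threshold, strictly inside (0, 1).
#' @return a `sumstats` object with the qualifying subset (possibly empty).
#' @export
select_instruments <- function(ss, p_threshold) {
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      !is.finite(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    err_config("p_threshold must be a single number strictly between 0 and 1")
  }
  ss_subset(ss, ss$pvalue <= p_threshold)
}
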