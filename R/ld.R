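#' Pairwise linkage-disequilibrium table
#'
#' A sparse symmetric map of squared correlations between variants. Absent
#' pairs are treated as unlinked (r2 = 0); the diagonal is implicitly 1.
#'
#' @param pairs data frame with columns `id_a`, `id_b`, `r2`.
#' @return an `ld_table` object.
#' @export
ld_table <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    pairs <- data.frame(id_a = character(), id_b = character(), r2 = numeric())
  }
  need <- c("id_a", "id_b", "r2")
  if (!all(need %in% names(pairs))) {
    err_config("LD table needs columns id_a, id_b, r2")
  }
  pairs <- pairs[need]
  pairs$id_a <- as.character(pairs$id_a)
  pairs$id_b <- as.character(pairs$id_b)
  pairs$r2 <- as.numeric(pairs$r2)
  if (any(!is.finite(pairs$r2) | pairs$r2 < 0 | pairs$r2 > 1)) {
    err_data("LD r2 values must lie in [0, 1]")
  }
  idx <- pairs$r2
  names(idx) <- paste(pmin(pairs$id_a, pairs$id_b),
                      pmax(pairs$id_a, pairs$id_b), sep = "\r")
  idx <- idx[!duplicated(names(idx))]
  structure(list(pairs = pairs, index = idx), class = "ld_table")
}

#' Read a three-column tab-delimited LD table (id_a, id_b, r2)
#' @param path file path.
#' @return an `ld_table` object.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) err_config(paste0("file not found: ", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ld_table(df)
}

#' Write an LD table in the three-column tab-delimited layout
#' @param ld an `ld_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_table <- function(ld, path) {
  utils::write.table(ld$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up pairwise r2 values (vectorised; absent pairs give 0, self gives 1)
#' @param ld an `ld_table`.
#' @param a,b variant id vectors (recycled to common length).
#' @return numeric vector of r2 values.
#' @export
ld_r2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  out <- unname(ld$index[key])
  out[is.na(out)] <- 0
  out[a == b] <- 1
  out
}

#' @export
print.ld_table <- function(x, ...) {
  cat(sprintf("LD table: %d stored pair(s)\n", nrow(x$pairs)))
  invisible(x)
}

#' Greedy LD clumping of instruments
#'
#' Sorts variants by ascending p-value (ties broken by variant id) and keeps
#' each variant only if its r2 with every already-kept variant on the same
#' chromosome within the window is below `r2_threshold`. Pairs within the
#' window but absent from the LD table are treated as unlinked (and noted
#' once in a message), matching common clumping-tool behaviour.
#'
#' @param ss a `sumstats` object.
#' @param ld an `ld_table`.
#' @param r2_threshold exclusion threshold in (0, 1); default 0.01.
#' @param window_kb window size in kilobases; default 10000. The window test
#'   is `|pos_a - pos_b| <= window_kb * 1000` on the same chromosome
#'   (1-based coordinates).
#' @return the accepted variants as a `sumstats` object sorted by p-value.
#' @export
clump <- function(ss, ld, r2_threshold = 0.01, window_kb = 10000) {
  if (!is.numeric(r2_threshold) || length(r2_threshold) != 1L ||
      r2_threshold <= 0 || r2_threshold >= 1) {
    err_config("r2_threshold must lie strictly in (0, 1)")
  }
  if (!is.numeric(window_kb) || length(window_kb) != 1L || window_kb <= 0) {
    err_config("window_kb must be a positive number")
  }
  if (nrow(ss) == 0L) return(ss)
  ord <- order(ss$pvalue, ss$variant_id)
  df <- as.data.frame(ss)[ord, , drop = FALSE]
  window_bp <- window_kb * 1000
  keep <- logical(nrow(df))
  missing_pair <- FALSE
  for (i in seq_len(nrow(df))) {
    acc <- which(keep)
    if (length(acc)) {
      same <- acc[df$chromosome[acc] == df$chromosome[i] &
                    abs(df$position[acc] - df$position[i]) <= window_bp]
      if (length(same)) {
        key <- paste(pmin(df$variant_id[same], df$variant_id[i]),
                     pmax(df$variant_id[same], df$variant_id[i]), sep = "\r")
        r2 <- unname(ld$index[key])
        if (anyNA(r2)) missing_pair <- TRUE
        r2[is.na(r2)] <- 0
        if (any(r2 >= r2_threshold)) next
      }
    }
    keep[i] <- TRUE
  }
  if (missing_pair) {
    message("clump: some variant pairs within the window were absent from the LD table; treated as unlinked (r2 = 0)")
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("sumstats", "data.frame"), trait_id = trait_id(ss))
}

#' Find an LD proxy for a variant missing from another dataset
#'
#' Among `candidates`, returns the variant with the highest r2 to `target`
#' strictly above `r2_min` (ties broken by variant id). Returns
#' `NA_character_` when no candidate qualifies. If `target` itself is among
#' the candidates it is returned unchanged.
#'
#' @param target variant id to be proxied.
#' @param candidates a `sumstats` object of available variants.
#' @param ld an `ld_table`.
#' @param r2_min minimum r2 for a usable proxy, in (0, 1); default 0.9.
#' @return a variant id or `NA_character_`.
#' @export
find_proxy <- function(target, candidates, ld, r2_min = 0.9) {
  if (!is.numeric(r2_min) || length(r2_min) != 1L || r2_min <= 0 || r2_min >= 1) {
    err_config("r2_min must lie strictly in (0, 1)")
  }
  ids <- candidates$variant_id
  if (target %in% ids) return(target)
  if (!length(ids)) return(NA_character_)
  r2 <- ld_r2(ld, rep(target, length(ids)), ids)
  ok <- which(r2 > r2_min)
  if (!length(ok)) return(NA_character_)
  best <- ok[order(-r2[ok], ids[ok])][1L]
  message(sprintf("find_proxy: substituting %s for %s (r2 = %.3f)",
                  ids[best], target, r2[best]))
  ids[best]
}
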