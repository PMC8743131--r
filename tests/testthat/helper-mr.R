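# shared builders for the test suite; everything is generated in code

make_ss <- function(ids, p, beta = NULL, se = NULL, chr = NULL, pos = NULL,
                    ea = NULL, oa = NULL, eaf = NA_real_, trait = "trait",
                    n = NA_real_) {
  k <- length(ids)
  if (is.null(se)) se <- rep(0.01, k)
  if (is.null(beta)) beta <- stats::qnorm(p / 2, lower.tail = FALSE) * se
  sumstats(data.frame(
    variant_id = ids,
    chromosome = chr %||% rep("1", k),
    position = pos %||% seq(1e6, by = 1e4, length.out = k),
    effect_allele = ea %||% rep("A", k),
    other_allele = oa %||% rep("G", k),
    eaf = eaf, beta = beta, se = se, pvalue = p, n = n,
    stringsAsFactors = FALSE), trait_id = trait)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

h_from_pair <- function(sim) {
  harmonized_set(sim$exposure$beta, sim$exposure$se,
                 sim$outcome$beta, sim$outcome$se,
                 variant_id = sim$exposure$variant_id)
}

h_from_mvmr <- function(sm) {
  harmonized_set(cbind(sm$exposure1$beta, sm$exposure2$beta),
                 cbind(sm$exposure1$se, sm$exposure2$se),
                 sm$outcome$beta, sm$outcome$se,
                 variant_id = sm$exposure1$variant_id)
}

# independent clumping oracle: enumerate all pairwise-compatible subsets and
# pick the one preferred lexicographically in p-value order (ties by id)
brute_force_clump <- function(ss, ld, r2_threshold, window_kb) {
  df <- as.data.frame(ss)
  ord <- order(df$pvalue, df$variant_id)
  df <- df[ord, ]
  n <- nrow(df)
  compatible <- function(i, j) {
    if (df$chromosome[i] != df$chromosome[j]) return(TRUE)
    if (abs(df$position[i] - df$position[j]) > window_kb * 1000) return(TRUE)
    ld_r2(ld, df$variant_id[i], df$variant_id[j]) < r2_threshold
  }
  best <- NULL; best_score <- -1
  for (mask in 0:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    ok <- TRUE
    if (length(members) >= 2) {
      for (a in seq_along(members)[-1]) {
        for (b in seq_len(a - 1)) {
          if (!compatible(members[a], members[b])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (!ok) next
    score <- sum(2^(n - members))
    if (score > best_score) { best_score <- score; best <- members }
  }
  df$variant_id[best]
}
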