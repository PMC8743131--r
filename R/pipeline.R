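#' Declarative analysis plan for a full MR run
#'
#' Captures every parameter of an end-to-end analysis: instrument
#' selection, clumping, proxy lookup, the univariable estimators, optional
#' Steiger filtering with refit, optional multivariable MR with a second
#' exposure, effect-scale conversion, and the seed. Trait inputs may be
#' `sumstats` objects or file paths readable by [read_sumstats()]; the LD
#' input may be an `ld_table` or a file path for [read_ld_table()].
#'
#' @param exposure,outcome trait inputs.
#' @param second_exposure optional second trait input (enables MVMR).
#' @param ld LD input (required for clumping/proxy work; an empty table is
#'   allowed).
#' @param p_threshold instrument significance threshold (default 5e-8).
#' @param second_p_threshold threshold for the second exposure's
#'   instruments (default 5e-8).
#' @param clump_r2,clump_kb clumping parameters (defaults 0.01, 10000).
#' @param proxy_r2 minimum r2 for proxy substitution (default 0.9).
#' @param methods univariable estimators to run.
#' @param steiger run Steiger directionality filtering and refit.
#' @param n_exposure,n_outcome,n_second_exposure GWAS sample sizes (needed
#'   for Steiger; taken from the tables' `n` column when absent there).
#' @param exposure_binary,outcome_binary trait types (drive Steiger r2
#'   approximations and effect scaling).
#' @param scale optional [scale_spec()] for interpretation units.
#' @param robust_mvmr also run Q-minimization MVMR with bootstrap CIs.
#' @param boot_reps bootstrap replicates for median/mode/robust CIs.
#' @param seed integer seed (mandatory).
#' @return an `analysis_plan`.
#' @export
analysis_plan <- function(exposure, outcome, second_exposure = NULL,
                          ld = NULL, p_threshold = 5e-8,
                          second_p_threshold = 5e-8,
                          clump_r2 = 0.01, clump_kb = 10000, proxy_r2 = 0.9,
                          methods = c("ivw", "egger", "wmedian", "wmode", "raps"),
                          steiger = FALSE, n_exposure = NULL, n_outcome = NULL,
                          n_second_exposure = NULL,
                          exposure_binary = FALSE, outcome_binary = FALSE,
                          scale = NULL, robust_mvmr = FALSE,
                          boot_reps = 1000L, seed) {
  if (missing(seed)) err_config("an analysis plan requires a seed")
  for (p in list(p_threshold, second_p_threshold)) {
    if (p <= 0 || p >= 1) err_config("p-value thresholds must lie in (0, 1)")
  }
  if (clump_r2 <= 0 || clump_r2 >= 1) err_config("clump_r2 must lie in (0, 1)")
  if (clump_kb <= 0) err_config("clump_kb must be positive")
  if (proxy_r2 <= 0 || proxy_r2 >= 1) err_config("proxy_r2 must lie in (0, 1)")
  if (!is.null(scale) && !inherits(scale, "scale_spec")) {
    err_config("scale must be a scale_spec")
  }
  structure(list(exposure = exposure, outcome = outcome,
                 second_exposure = second_exposure, ld = ld,
                 p_threshold = p_threshold,
                 second_p_threshold = second_p_threshold,
                 clump_r2 = clump_r2, clump_kb = clump_kb,
                 proxy_r2 = proxy_r2, methods = methods, steiger = steiger,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 n_second_exposure = n_second_exposure,
                 exposure_binary = exposure_binary,
                 outcome_binary = outcome_binary, scale = scale,
                 robust_mvmr = robust_mvmr, boot_reps = boot_reps,
                 seed = as.integer(seed)),
            class = "analysis_plan")
}

#' Read an analysis plan from a YAML configuration file
#'
#' The file mirrors [analysis_plan()] field for field; trait and LD fields
#' are file paths, and `scale` is a mapping with the [scale_spec()] fields.
#'
#' @param path YAML file.
#' @return an `analysis_plan`.
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) err_config(paste0("file not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$scale)) cfg$scale <- do.call(scale_spec, cfg$scale)
  do.call(analysis_plan, cfg)
}

#' Serialize an analysis plan to YAML (file-path inputs only)
#' @param plan an `analysis_plan` whose trait/LD inputs are file paths.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  p <- unclass(plan)
  for (fld in c("exposure", "outcome", "second_exposure", "ld")) {
    if (!is.null(p[[fld]]) && !is.character(p[[fld]])) {
      err_config("write_plan requires file-path trait and LD inputs")
    }
  }
  if (!is.null(p$scale)) p$scale <- unclass(p$scale)
  yaml::write_yaml(p[!vapply(p, is.null, TRUE)], path)
  invisible(path)
}

resolve_trait <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "sumstats")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_sumstats(x))
  err_config(paste0(what, " must be a sumstats object or a file path"))
}

resolve_ld <- function(x) {
  if (is.null(x)) return(ld_table(NULL))
  if (inherits(x, "ld_table")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_ld_table(x))
  err_config("ld must be an ld_table or a file path")
}

sample_size_of <- function(explicit, ss, what) {
  if (!is.null(explicit)) return(explicit)
  n <- stats::median(ss$n, na.rm = TRUE)
  if (!is.finite(n)) {
    err_config(paste0("sample size for ", what,
                      " is needed (set it in the plan or provide an n column)"))
  }
  n
}

# instrument selection + clumping + proxy substitution for one exposure
stage_instruments <- function(expo, outcome, ld, p_threshold, clump_r2,
                              clump_kb, proxy_r2, log) {
  sel <- select_instruments(expo, p_threshold)
  log$add(sel$variant_id, "select", "kept",
          sprintf("p <= %g", p_threshold))
  cl <- clump(sel, ld, r2_threshold = clump_r2, window_kb = clump_kb)
  clumped_away <- setdiff(sel$variant_id, cl$variant_id)
  log$add(clumped_away, "clump", "removed", "in LD with a stronger instrument")
  log$add(cl$variant_id, "clump", "kept", "")
  missing <- setdiff(cl$variant_id, outcome$variant_id)
  keep <- cl$variant_id
  for (m in missing) {
    candidates <- ss_subset(expo, expo$variant_id %in% outcome$variant_id)
    proxy <- suppressMessages(find_proxy(m, candidates, ld, r2_min = proxy_r2))
    if (is.na(proxy)) {
      keep <- setdiff(keep, m)
      log$add(m, "proxy", "dropped", "absent from outcome, no proxy found")
    } else {
      keep <- c(setdiff(keep, m), proxy)
      log$add(m, "proxy", "substituted",
              sprintf("replaced by %s (r2 = %.3f)", proxy,
                      ld_r2(ld, m, proxy)))
    }
  }
  ss_subset(expo, expo$variant_id %in% keep)
}

make_log <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$add <- function(variant_id, stage, action, detail) {
    if (!length(variant_id)) return(invisible(NULL))
    env$rows[[length(env$rows) + 1L]] <- data.frame(
      variant_id = variant_id, stage = stage, action = action,
      detail = detail, stringsAsFactors = FALSE)
    invisible(NULL)
  }
  env$table <- function() {
    if (!length(env$rows)) {
      return(data.frame(variant_id = character(), stage = character(),
                        action = character(), detail = character(),
                        stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, env$rows)
    rownames(out) <- NULL
    out
  }
  env
}

#' Refit estimators on the full and Steiger-filtered instrument sets
#'
#' Runs the configured estimators on the complete harmonized set and on
#' the subset surviving Steiger directionality filtering, and summarises
#' the attenuation (difference and ratio of the causal estimates). Methods
#' whose instrument minimum is not met on the filtered set are reported as
#' not estimable rather than aborting.
#'
#' @param h univariable `harmonized_set`.
#' @param n_exposure,n_outcome,exposure_binary,outcome_binary passed to
#'   [steiger_filter()].
#' @param methods,boot_reps,seed passed to [run_uvmr()].
#' @return list with `full`, `filtered` (results tables), `attenuation`
#'   (per-method beta difference and ratio) and the Steiger `report`.
#' @export
steiger_refit <- function(h, n_exposure, n_outcome, exposure_binary = FALSE,
                          outcome_binary = FALSE,
                          methods = c("ivw", "egger", "wmedian", "wmode", "raps"),
                          boot_reps = 1000L, seed = 1L) {
  st <- steiger_filter(h, n_exposure, n_outcome, exposure_binary,
                       outcome_binary)
  full <- run_uvmr(h, methods, boot_reps = boot_reps, seed = seed)
  filtered <- run_uvmr(st$filtered, methods, boot_reps = boot_reps,
                       seed = seed)
  att <- data.frame(method = full$method,
                    beta_full = full$beta, beta_filtered = filtered$beta,
                    difference = filtered$beta - full$beta,
                    ratio = filtered$beta / full$beta,
                    stringsAsFactors = FALSE)
  list(full = full, filtered = filtered, attenuation = att,
       report = st$report)
}

#' Run a complete MR analysis plan
#'
#' Executes instrument selection, clumping, proxy substitution,
#' harmonization, the univariable estimators with instrument-strength
#' diagnostics, optional Steiger filtering with refit, optional
#' multivariable MR (IVW plus, if requested, Q-minimization with bootstrap
#' CIs) with conditional F statistics, and effect-scale conversion. All
#' randomness is governed by the plan's seed, so identical plans yield
#' identical reports.
#'
#' @param plan an `analysis_plan`.
#' @return an `mr_report` list: `results` (all estimator rows),
#'   `instrument_log`, `harmonization` (actions and exclusions),
#'   `strength`, `steiger`, `mvmr`, `scaled`, and a `manifest` of every
#'   parameter.
#' @export
run_plan <- function(plan) {
  if (!inherits(plan, "analysis_plan")) err_config("plan must be an analysis_plan")
  set.seed(plan$seed)
  log <- make_log()
  expo <- resolve_trait(plan$exposure, "exposure")
  outc <- resolve_trait(plan$outcome, "outcome")
  second <- resolve_trait(plan$second_exposure, "second_exposure")
  ld <- resolve_ld(plan$ld)

  inst <- stage_instruments(expo, outc, ld, plan$p_threshold, plan$clump_r2,
                            plan$clump_kb, plan$proxy_r2, log)
  if (nrow(inst) == 0L) err_data("no instruments survive selection")

  h <- harmonize(inst, outc)
  if (nrow(h$exclusions)) {
    log$add(h$exclusions$variant_id, "harmonize", "excluded",
            h$exclusions$reason)
  }
  strength <- per_snp_f(h)
  uv <- run_uvmr(h, plan$methods, boot_reps = plan$boot_reps,
                 seed = plan$seed)
  uv$analysis <- "univariable"
  results <- uv

  steiger_out <- NULL
  if (isTRUE(plan$steiger)) {
    nx <- sample_size_of(plan$n_exposure, expo, "exposure")
    ny <- sample_size_of(plan$n_outcome, outc, "outcome")
    steiger_out <- steiger_refit(h, nx, ny, plan$exposure_binary,
                                 plan$outcome_binary, plan$methods,
                                 boot_reps = plan$boot_reps, seed = plan$seed)
    removed <- steiger_out$report$variant_id[!steiger_out$report$retained]
    log$add(removed, "steiger", "removed",
            "explains more variance in the outcome")
    filt <- steiger_out$filtered
    filt$analysis <- "univariable_steiger"
    results <- rbind(results, filt)
  }

  mvmr_out <- NULL
  if (!is.null(second)) {
    inst2 <- stage_instruments(second, outc, ld, plan$second_p_threshold,
                               plan$clump_r2, plan$clump_kb, plan$proxy_r2,
                               log)
    # pool both exposures' instruments, jointly clump, then harmonize
    pooled_ids <- union(inst$variant_id, inst2$variant_id)
    pool_from <- function(ss) {
      d <- as.data.frame(ss)[ss$variant_id %in% pooled_ids, , drop = FALSE]
      d
    }
    p1 <- pool_from(expo); p2 <- pool_from(second)
    p2 <- p2[!p2$variant_id %in% p1$variant_id, , drop = FALSE]
    pooled <- sumstats(rbind(p1, p2), trait_id = "pooled")
    pooled <- clump(pooled, ld, r2_threshold = plan$clump_r2,
                    window_kb = plan$clump_kb)
    keep_ids <- intersect(pooled$variant_id,
                          intersect(expo$variant_id,
                                    intersect(second$variant_id,
                                              outc$variant_id)))
    log$add(setdiff(pooled_ids, keep_ids), "mvmr_pool", "removed",
            "joint clump or missing from a trait table")
    h2 <- harmonize(list(ss_subset(expo, expo$variant_id %in% keep_ids),
                         ss_subset(second, second$variant_id %in% keep_ids)),
                    outc)
    if (nrow(h2$exclusions)) {
      log$add(h2$exclusions$variant_id, "mvmr_harmonize", "excluded",
              h2$exclusions$reason)
    }
    mvmr_out <- if (isTRUE(plan$robust_mvmr)) {
      mvmr_robust(h2, boot_reps = plan$boot_reps, seed = plan$seed)
    } else {
      mvmr_ivw(h2)
    }
    if (isTRUE(plan$steiger)) {
      # refit MVMR without variants the univariable Steiger filter flags
      nx <- sample_size_of(plan$n_exposure, expo, "exposure")
      ny <- sample_size_of(plan$n_outcome, outc, "outcome")
      h2_uni <- h_subset(h2, rep(TRUE, n_snps(h2)))
      h2_uni$bx <- h2$bx[, 1L, drop = FALSE]
      h2_uni$sx <- h2$sx[, 1L, drop = FALSE]
      h2_uni$exposure_pvalues <- h2$exposure_pvalues[, 1L, drop = FALSE]
      h2_uni$exposure_ids <- h2$exposure_ids[1L]
      st2 <- steiger_filter(h2_uni, nx, ny, plan$exposure_binary,
                            plan$outcome_binary)
      mvmr_out$steiger_refit <- mvmr_ivw(h_subset(h2, st2$report$retained))
    }
    mv_rows <- data.frame(
      method = paste0(if (isTRUE(plan$robust_mvmr)) "MVMR-IVW" else "MVMR-IVW"),
      n_snps = mvmr_out$n_snps, beta = mvmr_out$direct_betas,
      se = mvmr_out$ses, ci_low = mvmr_out$ci[, 1L],
      ci_high = mvmr_out$ci[, 2L], pvalue = mvmr_out$pvalues,
      intercept = NA_real_, intercept_se = NA_real_,
      intercept_pvalue = NA_real_, Q = mvmr_out$het$Q,
      Q_df = mvmr_out$het$df, Q_pvalue = mvmr_out$het$pvalue,
      note = paste0("exposure = ", mvmr_out$exposure_ids,
                    if (!is.null(mvmr_out$conditional_F)) {
                      sprintf("; conditional F = %.1f", mvmr_out$conditional_F)
                    } else ""),
      analysis = "mvmr", stringsAsFactors = FALSE)
    results <- rbind(results, mv_rows)
  }

  scaled <- NULL
  if (!is.null(plan$scale)) {
    sc <- plan$scale
    ivw_rows <- results[grepl("IVW", results$method), , drop = FALSE]
    if (sc$exposure_type == "binary_liability" &&
        sc$outcome_type == "continuous_sd" &&
        !is.null(sc$outcome_sd_years)) {
      scaled <- data.frame(
        analysis = ivw_rows$analysis, method = ivw_rows$method,
        unit = paste0(sc$time_unit, " per doubling of liability"),
        effect = doubling_effect(ivw_rows$beta, sc),
        ci_low = doubling_effect(ivw_rows$ci_low, sc),
        ci_high = doubling_effect(ivw_rows$ci_high, sc),
        stringsAsFactors = FALSE)
    } else if (sc$outcome_type == "binary_liability") {
      or_ci <- t(mapply(function(b, s) {
        or_ci_from_log_scale(exp(b), s)
      }, ivw_rows$beta, ivw_rows$se))
      scaled <- data.frame(
        analysis = ivw_rows$analysis, method = ivw_rows$method,
        unit = "odds ratio per unit exposure",
        effect = exp(ivw_rows$beta),
        ci_low = or_ci[, 1L], ci_high = or_ci[, 2L],
        stringsAsFactors = FALSE)
    }
  }

  manifest <- list(
    exposure_id = trait_id(expo), outcome_id = trait_id(outc),
    second_exposure_id = if (!is.null(second)) trait_id(second) else NULL,
    p_threshold = plan$p_threshold,
    second_p_threshold = plan$second_p_threshold,
    clump_r2 = plan$clump_r2, clump_kb = plan$clump_kb,
    proxy_r2 = plan$proxy_r2, methods = plan$methods,
    steiger = plan$steiger, robust_mvmr = plan$robust_mvmr,
    boot_reps = plan$boot_reps, seed = plan$seed,
    package_version = as.character(utils::packageVersion("mrlink")))

  structure(list(results = results, instrument_log = log$table(),
                 harmonization = list(report = h$report,
                                      exclusions = h$exclusions),
                 strength = strength, steiger = steiger_out,
                 mvmr = mvmr_out, scaled = scaled, manifest = manifest),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("MR report: %s -> %s\n", x$manifest$exposure_id,
              x$manifest$outcome_id))
  print(x$results[c("analysis", "method", "n_snps", "beta", "se", "pvalue")])
  invisible(x)
}

#' Write a report bundle as diffable tab-delimited tables plus a manifest
#'
#' @param report an `mr_report` from [run_plan()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(report$results, "results.tsv")
  wt(report$instrument_log, "instrument_log.tsv")
  if (!is.null(report$harmonization$report)) {
    wt(report$harmonization$report, "harmonization.tsv")
  }
  wt(report$harmonization$exclusions, "harmonization_exclusions.tsv")
  if (!is.null(report$steiger)) wt(report$steiger$report, "steiger.tsv")
  if (!is.null(report$scaled)) wt(report$scaled, "scaled_effects.tsv")
  f <- report$strength$per_snp_F
  wt(data.frame(variant_id = names(f), F = unname(f)), "instrument_strength.tsv")
  yaml::write_yaml(report$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
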