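# Study orchestration: forward MR across many exposures, reverse MR,
# multivariable prioritization, mediation and enrichment, with per-stage
# instrument accounting. Mirrors the bidirectional two-sample + two-step
# design: screen instruments, clump, proxy, harmonize, filter (F, Steiger),
# estimate with the full panel, and flag results at the suggestive (0.05)
# and Bonferroni-corrected thresholds.

#' Study configuration
#'
#' @param exposures Named list of exposure GWAS tables (canonical columns),
#'   or file paths readable by [read_gwas_table()].
#' @param outcome Outcome GWAS table or path.
#' @param mediators Optional named list of mediator GWAS tables or paths.
#' @param ld An [ld_reference()] (or path to a 3-column LD table).
#' @param p_exposure Instrument p-value threshold for the exposures
#'   (1e-5, the microbiome-GWAS convention; use 5e-8 for metabolites).
#' @param p_reverse Instrument threshold when the outcome acts as exposure
#'   in reverse MR (genome-wide significance).
#' @param eaf_min Allele-frequency filter (both alleles), default 0.01.
#' @param clump_r2,clump_window_kb LD-clumping parameters (0.001, 10000).
#' @param proxy_r2 Minimum r-squared for proxy substitution (0.8).
#' @param f_min Weak-instrument F cut-off (10).
#' @param alpha_suggestive Suggestive significance level (0.05).
#' @param bonferroni_family Number of tests in the Bonferroni family
#'   (e.g. 207 taxa or 1400 metabolites + ratios).
#' @param methods Estimator panel for [mr_fit()].
#' @param presso_nsim MR-PRESSO simulation count.
#' @param seed Master seed.
#' @return A `study_config` list.
#' @export
mr_study_config <- function(exposures, outcome, mediators = NULL, ld = NULL,
                            p_exposure = 1e-5, p_reverse = 5e-8,
                            eaf_min = 0.01, clump_r2 = 0.001,
                            clump_window_kb = 10000, proxy_r2 = 0.8,
                            f_min = 10, alpha_suggestive = 0.05,
                            bonferroni_family = length(exposures),
                            methods = c("ivw", "egger", "weighted_median",
                                        "raps", "cml_ma"),
                            presso_nsim = 1000, seed = 1) {
  load_table <- function(x) if (is.character(x)) read_gwas_table(x) else x
  if (is.data.frame(exposures)) exposures <- list(exposure = exposures)
  exposures <- lapply(exposures, load_table)
  if (is.null(names(exposures)) || any(!nzchar(names(exposures)))) {
    names(exposures) <- sprintf("exposure_%d", seq_along(exposures))
  }
  outcome <- load_table(outcome)
  if (!is.null(mediators)) {
    if (is.data.frame(mediators)) mediators <- list(mediator = mediators)
    mediators <- lapply(mediators, load_table)
    if (is.null(names(mediators)) || any(!nzchar(names(mediators)))) {
      names(mediators) <- sprintf("mediator_%d", seq_along(mediators))
    }
  }
  if (is.character(ld)) ld <- read_ld_table(ld)
  for (nm in c("p_exposure", "p_reverse")) {
    v <- get(nm)
    if (v <= 0 || v >= 1) stop_field(nm, "must be in (0, 1)")
  }
  if (bonferroni_family < 1) stop_field("bonferroni_family", "must be >= 1")
  structure(
    list(exposures = exposures, outcome = outcome, mediators = mediators,
         ld = ld, p_exposure = p_exposure, p_reverse = p_reverse,
         eaf_min = eaf_min, clump_r2 = clump_r2,
         clump_window_kb = clump_window_kb, proxy_r2 = proxy_r2,
         f_min = f_min, alpha_suggestive = alpha_suggestive,
         bonferroni_family = bonferroni_family, methods = methods,
         presso_nsim = presso_nsim, seed = seed),
    class = "study_config"
  )
}

# One exposure-outcome pass: select -> clump -> proxy -> harmonize ->
# F filter -> Steiger. Returns the harmonized set plus a per-stage log.
prepare_instruments <- function(exposure, outcome, config,
                                p_threshold = config$p_exposure) {
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[stage]] <<- data.frame(stage = stage, n_in = n_in, n_out = n_out,
                                dropped = n_in - n_out,
                                stringsAsFactors = FALSE)
  }
  sel <- select_instruments(exposure, p_threshold, config$eaf_min)
  note("select", nrow(exposure), nrow(sel))
  if (nrow(sel) > 0 && !is.null(config$ld)) {
    clumped <- ld_clump(sel, config$ld, config$clump_r2,
                        config$clump_window_kb)
  } else {
    clumped <- sel
  }
  note("clump", nrow(sel), nrow(clumped))
  # proxy substitution for instruments missing from the outcome table:
  # the instrument is replaced wholesale by its best proxy (exposure and
  # outcome rows of the proxy SNP), requiring the proxy in both tables
  missing <- setdiff(clumped$snp_id, outcome$snp_id)
  n_proxied <- 0L
  if (length(missing) > 0 && !is.null(config$ld)) {
    candidates <- outcome[outcome$snp_id %in% exposure$snp_id, , drop = FALSE]
    for (snp in missing) {
      proxy <- find_proxy(snp, candidates, config$ld, config$proxy_r2)
      if (!is.null(proxy) && !(proxy$snp_id %in% clumped$snp_id)) {
        repl <- exposure[exposure$snp_id == proxy$snp_id, , drop = FALSE]
        clumped <- rbind(clumped[clumped$snp_id != snp, , drop = FALSE], repl)
        n_proxied <- n_proxied + 1L
      }
    }
  }
  hset <- harmonize(clumped, outcome)
  note("harmonize", nrow(clumped), nrow(hset))
  strong <- filter_weak(hset, config$f_min)
  note("f_filter", nrow(hset), nrow(strong))
  directed <- if (nrow(strong) > 0) steiger_filter(strong) else strong
  note("steiger", nrow(strong), nrow(directed))
  list(set = directed, log = do.call(rbind, log), n_proxied = n_proxied)
}

# Operationalized "consistent with sensitivity analyses": IVW suggestive,
# point estimates of all fitted estimators agree in sign, no Egger-intercept
# evidence of directional pleiotropy, and PRESSO either finds no global
# pleiotropy or the outlier-corrected estimate keeps the sign.
sensitivity_consistent <- function(fit, presso, alpha = 0.05) {
  res <- summary(fit)
  ivw <- res[grepl("^IVW", res$method), , drop = FALSE]
  if (nrow(ivw) == 0 || ivw$pvalue[1] >= alpha) return(FALSE)
  if (length(unique(sign(res$beta))) > 1) return(FALSE)
  eg <- res$egger_intercept_p[!is.na(res$egger_intercept_p)]
  if (length(eg) > 0 && any(eg < alpha)) return(FALSE)
  if (!is.null(presso) && !inherits(presso, "error") &&
      presso$global_pvalue < alpha) {
    if (is.null(presso$corrected)) return(FALSE)
    if (sign(presso$corrected$beta) != sign(ivw$beta[1])) return(FALSE)
  }
  TRUE
}

run_mr_pass <- function(exposures, outcome, config, p_threshold, direction) {
  results <- list()
  for (nm in names(exposures)) {
    prep <- prepare_instruments(exposures[[nm]], outcome, config, p_threshold)
    set <- prep$set
    if (nrow(set) == 0) {
      results[[nm]] <- list(exposure = nm, direction = direction,
                            status = "no instruments",
                            stage_log = prep$log)
      next
    }
    fit <- mr_fit(set, methods = config$methods,
                  seed = derive_seed(config$seed, 11))
    presso <- if (nrow(set) >= 4) {
      tryCatch(mr_presso(set, n_sim = config$presso_nsim,
                         seed = derive_seed(config$seed, 12)),
               error = function(e) e)
    } else {
      NULL
    }
    res <- summary(fit)
    ivw_p <- res$pvalue[grepl("^IVW", res$method)][1]
    bonf <- bonferroni_threshold(config$alpha_suggestive,
                                 config$bonferroni_family)
    results[[nm]] <- list(
      exposure = nm, direction = direction, status = "ok",
      n_snp = nrow(set), set = set, fit = fit, presso = presso,
      stage_log = prep$log, n_proxied = prep$n_proxied,
      suggestive = is.finite(ivw_p) && ivw_p < config$alpha_suggestive,
      significant = is.finite(ivw_p) && ivw_p < bonf,
      consistent = sensitivity_consistent(fit, presso,
                                          config$alpha_suggestive)
    )
  }
  results
}

#' Forward MR across all configured exposures
#'
#' Executes the full instrument pipeline (select, clump, proxy, harmonize,
#' F-filter, Steiger) and the configured estimator panel for every
#' exposure-outcome pair, flagging IVW results as suggestive (p below
#' `alpha_suggestive`) and significant (p below the Bonferroni threshold
#' for the configured family size). Exposures yielding zero instruments are
#' recorded and skipped, and the pipeline continues.
#'
#' @param config An [mr_study_config()].
#' @return A `mr_pass` list: per-exposure results with stage logs.
#' @export
run_forward_mr <- function(config) {
  structure(run_mr_pass(config$exposures, config$outcome, config,
                        config$p_exposure, "forward"),
            class = "mr_pass")
}

#' Reverse MR: outcome as exposure
#'
#' Same contract as [run_forward_mr()] with the roles swapped: instruments
#' are selected from the outcome GWAS at the (genome-wide) `p_reverse`
#' threshold; when no variant passes, the pair is skipped with a reason.
#'
#' @param config An [mr_study_config()].
#' @return A `mr_pass` list, one entry per original exposure (now the
#'   outcome of the reverse analysis).
#' @export
run_reverse_mr <- function(config) {
  results <- list()
  for (nm in names(config$exposures)) {
    res <- run_mr_pass(stats::setNames(list(config$outcome), nm),
                       config$exposures[[nm]], config,
                       config$p_reverse, "reverse")
    results[[nm]] <- res[[1]]
  }
  structure(results, class = "mr_pass")
}

#' Tidy one-row-per-method table from an MR pass
#'
#' @param pass A `mr_pass` from [run_forward_mr()] or [run_reverse_mr()].
#' @return Data frame: exposure, direction, method, estimates, diagnostics
#'   and flags; pairs without instruments appear with `status`.
#' @export
mr_pass_table <- function(pass) {
  rows <- lapply(pass, function(r) {
    if (r$status != "ok") {
      return(data.frame(exposure = r$exposure, direction = r$direction,
                        status = r$status, method = NA_character_,
                        n_snp = NA_integer_, beta = NA_real_, se = NA_real_,
                        pvalue = NA_real_, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, suggestive = NA, significant = NA,
                        consistent = NA, stringsAsFactors = FALSE))
    }
    res <- summary(r$fit)
    data.frame(exposure = r$exposure, direction = r$direction, status = "ok",
               method = res$method, n_snp = res$n_snp, beta = res$beta,
               se = res$se, pvalue = res$pvalue, or = res$or,
               ci_low = res$ci_low, ci_high = res$ci_high,
               suggestive = r$suggestive, significant = r$significant,
               consistent = r$consistent, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mr_pass <- function(x, ...) {
  tab <- mr_pass_table(x)
  ivw <- tab[is.na(tab$method) | grepl("^IVW", tab$method), , drop = FALSE]
  cat(sprintf("MR pass (%s): %d pair(s)\n", ivw$direction[1], length(x)))
  print(ivw[, c("exposure", "status", "n_snp", "beta", "se", "pvalue",
                "suggestive", "significant", "consistent")],
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' Run the full study: forward and reverse MR, prioritization, mediation
#'
#' Stages execute in design order: forward MR for every exposure; reverse
#' MR; MR-BMA over the exposures whose forward IVW reached the suggestive
#' threshold (on their pooled instrument set); two-step mediation for every
#' exposure-mediator pair where both the exposure-to-mediator and
#' mediator-to-outcome legs pass the suggestive threshold; optional
#' metabolite-set enrichment when a GMT and hit list are supplied. Stage
#' errors are recorded and downstream dependents skipped; a bundle is
#' always produced and is deterministic under a fixed seed and config.
#'
#' @param config An [mr_study_config()].
#' @param gmt Optional list of pathway sets ([read_gmt()]) for enrichment.
#' @param enrichment_hits,enrichment_background Optional hit list and
#'   background for [enrich()].
#' @param run_reverse Run the reverse pass (default TRUE).
#' @return A `study_bundle`: forward/reverse tables, `bma` result,
#'   `mediation` table, `enrichment` table, and a run `log`.
#' @export
run_full_study <- function(config, gmt = NULL, enrichment_hits = NULL,
                           enrichment_background = NULL, run_reverse = TRUE) {
  log <- list()
  note <- function(stage, message) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, message = message,
                                          stringsAsFactors = FALSE)
  }
  forward <- run_forward_mr(config)
  note("forward", sprintf("%d pair(s), %d with instruments", length(forward),
                          sum(vapply(forward, function(r) r$status == "ok",
                                     logical(1)))))
  reverse <- NULL
  if (run_reverse) {
    reverse <- run_reverse_mr(config)
    note("reverse", sprintf("%d pair(s), %d with instruments",
                            length(reverse),
                            sum(vapply(reverse, function(r) r$status == "ok",
                                       logical(1)))))
  }

  # MR-BMA over suggestive exposures on their pooled instruments
  bma <- NULL
  suggestive <- names(forward)[vapply(forward, function(r)
    isTRUE(r$suggestive), logical(1))]
  if (length(suggestive) >= 2) {
    bma <- tryCatch({
      snps <- unique(unlist(lapply(forward[suggestive],
                                   function(r) r$set$snp_id)))
      present <- Reduce(intersect, c(list(snps),
                                     lapply(config$exposures[suggestive],
                                            function(t) t$snp_id),
                                     list(config$outcome$snp_id)))
      if (length(present) < 3) stop("too few shared instruments for MR-BMA")
      bx <- vapply(config$exposures[suggestive], function(t)
        t$beta[match(present, t$snp_id)], numeric(length(present)))
      oc <- config$outcome[match(present, config$outcome$snp_id), ]
      cfg <- bma_config(seed = derive_seed(config$seed, 21))
      fit <- mr_bma(oc$beta, oc$se, bx, config = cfg)
      bma_empirical_pvalues(fit, oc$beta, oc$se, bx, config = cfg)
    }, error = function(e) e)
    note("bma", if (inherits(bma, "error")) conditionMessage(bma)
         else sprintf("%d exposures averaged", length(suggestive)))
  } else {
    note("bma", "skipped: fewer than 2 suggestive exposures")
  }

  # mediation for exposure-mediator pairs with both legs suggestive
  mediation_rows <- list()
  if (!is.null(config$mediators)) {
    for (ex in names(config$exposures)) {
      fwd <- forward[[ex]]
      if (fwd$status != "ok" || !isTRUE(fwd$suggestive)) next
      for (md in names(config$mediators)) {
        leg1 <- prepare_instruments(config$exposures[[ex]],
                                    config$mediators[[md]], config)
        if (nrow(leg1$set) == 0) next
        f1 <- mr_ivw(leg1$set)
        if (f1$pvalue >= config$alpha_suggestive) next
        leg2 <- prepare_instruments(config$mediators[[md]], config$outcome,
                                    config, p_threshold = config$p_reverse)
        if (nrow(leg2$set) == 0) next
        f2 <- mr_ivw(leg2$set)
        if (f2$pvalue >= config$alpha_suggestive) next
        f3 <- mr_ivw(fwd$set)
        med <- tryCatch(
          two_step_mediation(f1$beta, f1$se, f2$beta, f2$se, f3$beta, f3$se),
          error = function(e) e)
        if (inherits(med, "error")) {
          note("mediation", sprintf("%s via %s: %s", ex, md,
                                    conditionMessage(med)))
          next
        }
        mediation_rows[[paste(ex, md)]] <- data.frame(
          exposure = ex, mediator = md,
          beta1 = med$beta1, beta2 = med$beta2, beta3 = med$beta3,
          indirect = med$indirect, indirect_se = med$indirect_se,
          proportion = med$proportion, proportion_se = med$proportion_se,
          ci_low = med$ci_low, ci_high = med$ci_high, pvalue = med$pvalue,
          stringsAsFactors = FALSE)
      }
    }
  }
  mediation <- if (length(mediation_rows) > 0) {
    do.call(rbind, mediation_rows)
  } else {
    NULL
  }
  note("mediation", sprintf("%d triple(s) evaluated",
                            length(mediation_rows)))

  enrichment <- NULL
  if (!is.null(gmt) && !is.null(enrichment_hits)) {
    enrichment <- tryCatch(
      enrich(enrichment_hits, gmt, background = enrichment_background),
      error = function(e) e)
    note("enrichment", if (inherits(enrichment, "error"))
      conditionMessage(enrichment) else
        sprintf("%d pathway(s) tested", nrow(enrichment)))
  }

  structure(
    list(forward = forward, reverse = reverse, bma = bma,
         mediation = mediation, enrichment = enrichment,
         log = do.call(rbind, log), seed = config$seed),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("MR study bundle\n")
  print(x$log, row.names = FALSE)
  invisible(x)
}
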