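# Synthetic two-sample GWAS summary statistics with known ground truth.
# The generator emulates the statistical structure of the study's three
# inputs — a quantitative exposure GWAS (microbial taxon abundance or
# metabolite level), and a rare binary outcome GWAS on the log-odds scale —
# without simulating individual genotypes.

#' Scenario configuration for the synthetic GWAS generator
#'
#' Defaults emulate the study conditions: a taxon GWAS of 7,738 individuals,
#' a metabolite GWAS of 8,299 and a case-control outcome GWAS of 314,355
#' individuals with a rare outcome (case fraction 1,472 / 314,355). True
#' per-SNP instrument effects are drawn half-normal with scale
#' `instrument_scale` so every instrument has a defined effect-allele
#' direction.
#'
#' @param n_snps Number of candidate instruments (>= 1).
#' @param n_exposure_sample,n_outcome_sample GWAS sample sizes.
#' @param true_beta Causal effect of exposure on outcome (log-odds per
#'   exposure SD).
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_sd SD of per-SNP direct (pleiotropic) effects.
#' @param pleiotropy_mean Mean direct effect; nonzero only for
#'   `"directional"`.
#' @param maf_range Interval for simulated effect-allele frequencies, a
#'   subset of (0, 0.5].
#' @param ld_block_size SNPs per LD block (1 = no LD).
#' @param ld_r2_within Pairwise r-squared inside a block.
#' @param instrument_scale Half-normal scale of true instrument effects;
#'   the default 0.15 gives strong instruments (mean F far above 10) at the
#'   default exposure sample size.
#' @param case_fraction Outcome case fraction (binary outcome); the default
#'   matches a rare-cancer case-control ratio.
#' @param seed Integer RNG seed.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(n_snps = 200,
                            n_exposure_sample = 7738,
                            n_outcome_sample = 314355,
                            true_beta = 0,
                            pleiotropy_mode = c("none", "balanced", "directional"),
                            pleiotropy_sd = 0,
                            pleiotropy_mean = 0,
                            maf_range = c(0.05, 0.5),
                            ld_block_size = 1,
                            ld_r2_within = 0,
                            instrument_scale = 0.15,
                            case_fraction = 1472 / 314355,
                            seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (!is.numeric(n_snps) || n_snps < 1) stop_field("n_snps", "must be >= 1")
  if (n_exposure_sample <= 2) stop_field("n_exposure_sample", "must exceed 2")
  if (n_outcome_sample <= 2) stop_field("n_outcome_sample", "must exceed 2")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop_field("maf_range", "must be an interval within (0, 0.5]")
  }
  if (ld_r2_within < 0 || ld_r2_within > 1) {
    stop_field("ld_r2_within", "must be in [0, 1]")
  }
  if (pleiotropy_sd < 0) stop_field("pleiotropy_sd", "must be >= 0")
  if (pleiotropy_mode != "directional" && pleiotropy_mean != 0) {
    stop_field("pleiotropy_mean", "nonzero only for directional pleiotropy")
  }
  if (ld_block_size < 1) stop_field("ld_block_size", "must be >= 1")
  if (instrument_scale <= 0) stop_field("instrument_scale", "must be > 0")
  if (case_fraction <= 0 || case_fraction >= 1) {
    stop_field("case_fraction", "must be in (0, 1)")
  }
  structure(
    list(n_snps = as.integer(n_snps),
         n_exposure_sample = n_exposure_sample,
         n_outcome_sample = n_outcome_sample,
         true_beta = true_beta,
         pleiotropy_mode = pleiotropy_mode,
         pleiotropy_sd = pleiotropy_sd,
         pleiotropy_mean = pleiotropy_mean,
         maf_range = maf_range,
         ld_block_size = as.integer(ld_block_size),
         ld_r2_within = ld_r2_within,
         instrument_scale = instrument_scale,
         case_fraction = case_fraction,
         seed = seed),
    class = "scenario_config"
  )
}

# Per-SNP GWAS standard error for a standardized quantitative trait:
# se = 1 / sqrt(n * 2 maf (1 - maf)).
quant_se <- function(n, maf) {
  1 / sqrt(n * 2 * maf * (1 - maf))
}

# Log-odds SE for a case-control GWAS with effective sample size
# n_cases * n_controls / n.
binary_se <- function(n, case_fraction, maf) {
  n_eff <- n * case_fraction * (1 - case_fraction)
  1 / sqrt(n_eff * 2 * maf * (1 - maf))
}

draw_direct_effects <- function(config) {
  switch(config$pleiotropy_mode,
         none = rep(0, config$n_snps),
         balanced = stats::rnorm(config$n_snps, 0, config$pleiotropy_sd),
         directional = stats::rnorm(config$n_snps, config$pleiotropy_mean,
                                    config$pleiotropy_sd))
}

snp_positions <- function(config) {
  # one block per chromosome stretch; blocks separated by > 10 Mb so the
  # clumping window never spans blocks
  n <- config$n_snps
  block <- (seq_len(n) - 1) %/% config$ld_block_size
  within <- (seq_len(n) - 1) %% config$ld_block_size
  data.frame(
    snp_id = sprintf("rs%06d", seq_len(n)),
    chrom = as.character(1 + (block %% 22)),
    pos = 1e6 + (block %/% 22) * 25e6 + within * 1000,
    stringsAsFactors = FALSE
  )
}

build_ld_reference <- function(config, positions) {
  n <- config$n_snps
  block <- (seq_len(n) - 1) %/% config$ld_block_size
  pairs_a <- character(0); pairs_b <- character(0); r2 <- numeric(0)
  if (config$ld_block_size > 1) {
    for (b in unique(block)) {
      idx <- which(block == b)
      if (length(idx) < 2) next
      cmb <- utils::combn(idx, 2)
      pairs_a <- c(pairs_a, positions$snp_id[cmb[1, ]])
      pairs_b <- c(pairs_b, positions$snp_id[cmb[2, ]])
      r2 <- c(r2, rep(config$ld_r2_within, ncol(cmb)))
    }
  }
  ld_reference(pairs_a, pairs_b, r2, positions = positions)
}

gwas_frame <- function(positions, eaf, beta, se, n) {
  data.frame(
    snp_id = positions$snp_id,
    chrom = positions$chrom,
    pos = positions$pos,
    effect_allele = rep(c("A", "C", "G", "T"),
                        length.out = nrow(positions)),
    other_allele = rep(c("G", "T", "A", "C"),
                       length.out = nrow(positions)),
    eaf = eaf,
    beta = beta,
    se = se,
    pvalue = pmax(z_pvalue(beta, se), 1e-300),
    n = n,
    stringsAsFactors = FALSE
  )
}

#' Simulate a two-sample GWAS study with known ground truth
#'
#' Per-SNP true instrument effects `gamma_j` are drawn half-normal
#' (scale `instrument_scale`); true outcome effects are
#' `Gamma_j = true_beta * gamma_j + alpha_j` with direct effects `alpha_j`
#' set by the pleiotropy mode. Reported betas add sampling noise with
#' standard errors consistent with sample size and allele frequency (the
#' outcome on the log-odds scale using the effective case-control sample
#' size). Identical seeds give identical output.
#'
#' @param config A [scenario_config()].
#' @return A `simulated_study`: list with `exposure_stats`, `outcome_stats`
#'   (canonical GWAS tables), `ld_reference`, and `truth` (the config plus
#'   per-SNP `gamma`, `alpha`, `eaf`).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, {
    n <- config$n_snps
    eaf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    gamma <- abs(stats::rnorm(n, 0, config$instrument_scale))
    alpha <- draw_direct_effects(config)
    Gamma <- config$true_beta * gamma + alpha

    positions <- snp_positions(config)
    se_x <- quant_se(config$n_exposure_sample, eaf)
    se_y <- binary_se(config$n_outcome_sample, config$case_fraction, eaf)
    beta_x <- stats::rnorm(n, gamma, se_x)
    beta_y <- stats::rnorm(n, Gamma, se_y)

    structure(
      list(
        exposure_stats = gwas_frame(positions, eaf, beta_x, se_x,
                                    config$n_exposure_sample),
        outcome_stats = gwas_frame(positions, eaf, beta_y, se_y,
                                   config$n_outcome_sample),
        ld_reference = build_ld_reference(config, positions),
        truth = list(config = config, gamma = gamma, alpha = alpha,
                     eaf = eaf, Gamma = Gamma)
      ),
      class = "simulated_study"
    )
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(
    "Simulated two-sample study: %d SNPs, true beta = %g, pleiotropy = %s\n",
    cfg$n_snps, cfg$true_beta, cfg$pleiotropy_mode))
  invisible(x)
}

#' Simulate summary statistics for correlated exposures
#'
#' Exposures share the instrument set: per-SNP true effects across exposures
#' are drawn jointly multivariate normal with the supplied genetic
#' correlation, and only the exposure at `causal_index` affects the outcome
#' (with effect `config$true_beta`). This reproduces the setting in which
#' Bayesian model averaging must prioritize the truly causal risk factor
#' among correlated candidates.
#'
#' @param config A [scenario_config()].
#' @param n_exposures Number of exposures (>= 1).
#' @param exposure_correlation Positive semi-definite correlation matrix
#'   (`n_exposures` x `n_exposures`), or a single off-diagonal value.
#' @param causal_index Index of the single causal exposure.
#' @return A `simulated_study` whose `exposure_stats` is a list of GWAS
#'   tables (one per exposure); `truth$gamma` is the n_snps x n_exposures
#'   matrix of true effects.
#' @export
simulate_correlated_exposures <- function(config, n_exposures,
                                          exposure_correlation = 0,
                                          causal_index = 1) {
  stopifnot(inherits(config, "scenario_config"))
  if (n_exposures < 1) stop_field("n_exposures", "must be >= 1")
  if (length(exposure_correlation) == 1) {
    R <- matrix(exposure_correlation, n_exposures, n_exposures)
    diag(R) <- 1
  } else {
    R <- as.matrix(exposure_correlation)
  }
  if (!isTRUE(all.equal(R, t(R))) || any(eigen(R, symmetric = TRUE,
                                               only.values = TRUE)$values < -1e-8)) {
    stop_field("exposure_correlation", "must be positive semi-definite")
  }
  if (causal_index < 1 || causal_index > n_exposures) {
    stop_field("causal_index", "must index one of the exposures")
  }
  with_seed(config$seed, {
    n <- config$n_snps
    eaf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    # jointly correlated signed effects (the half-normal convention is a
    # single-exposure device; correlation requires signed draws)
    ev <- eigen(R, symmetric = TRUE)
    rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n_exposures) %*%
      t(ev$vectors)
    z <- matrix(stats::rnorm(n * n_exposures), n, n_exposures)
    gamma <- config$instrument_scale * (z %*% rt)
    alpha <- draw_direct_effects(config)
    Gamma <- config$true_beta * gamma[, causal_index] + alpha

    positions <- snp_positions(config)
    se_x <- quant_se(config$n_exposure_sample, eaf)
    se_y <- binary_se(config$n_outcome_sample, config$case_fraction, eaf)
    exposure_stats <- lapply(seq_len(n_exposures), function(k) {
      gwas_frame(positions, eaf,
                 stats::rnorm(n, gamma[, k], se_x), se_x,
                 config$n_exposure_sample)
    })
    names(exposure_stats) <- sprintf("exposure_%d", seq_len(n_exposures))
    if (n_exposures == 1) exposure_stats <- exposure_stats[[1]]
    structure(
      list(
        exposure_stats = exposure_stats,
        outcome_stats = gwas_frame(positions, eaf,
                                   stats::rnorm(n, Gamma, se_y), se_y,
                                   config$n_outcome_sample),
        ld_reference = build_ld_reference(config, positions),
        truth = list(config = config, gamma = gamma, alpha = alpha,
                     eaf = eaf, Gamma = Gamma,
                     causal_index = causal_index,
                     exposure_correlation = R)
      ),
      class = "simulated_study"
    )
  })
}

#' Simulate the three studies of a two-step mediation design
#'
#' Generates independent instrument sets for the taxon and the mediator and
#' three two-sample studies: taxon to mediator (effect `beta1`), mediator to
#' outcome (effect `beta2`), and taxon to outcome with total effect
#' `beta1 * beta2 + direct_effect` by construction, so the true proportion
#' mediated is `beta1 * beta2 / (beta1 * beta2 + direct_effect)`.
#'
#' @param config A [scenario_config()]; `true_beta` is ignored in favour of
#'   the leg effects.
#' @param beta1 Taxon-to-mediator effect.
#' @param beta2 Mediator-to-outcome effect (log-odds).
#' @param direct_effect Taxon-to-outcome effect not through the mediator.
#' @return List of three `simulated_study` objects
#'   (`exposure_mediator`, `mediator_outcome`, `exposure_outcome`) plus
#'   `truth` with the generating effects and the true proportion mediated.
#' @export
simulate_mediation_triple <- function(config, beta1, beta2, direct_effect = 0) {
  stopifnot(inherits(config, "scenario_config"))
  total <- beta1 * beta2 + direct_effect
  mk <- function(stream, true_beta, n_outcome, binary) {
    cfg <- config
    cfg$true_beta <- true_beta
    cfg$seed <- derive_seed(config$seed, stream)
    if (!binary) {
      # mediator leg: balanced design so the log-odds SE formula degrades to
      # a constant multiple of the quantitative-trait SE
      cfg$case_fraction <- 0.5
    }
    cfg$n_outcome_sample <- n_outcome
    simulate_two_sample(cfg)
  }
  exposure_mediator <- mk(1, beta1, config$n_exposure_sample, binary = FALSE)
  mediator_outcome <- mk(2, beta2, config$n_outcome_sample, binary = TRUE)
  exposure_outcome <- mk(3, total, config$n_outcome_sample, binary = TRUE)
  list(
    exposure_mediator = exposure_mediator,
    mediator_outcome = mediator_outcome,
    exposure_outcome = exposure_outcome,
    truth = list(beta1 = beta1, beta2 = beta2, direct_effect = direct_effect,
                 total = total,
                 proportion = if (total != 0) beta1 * beta2 / total else NA_real_)
  )
}

#' Harmonize a simulated study directly
#'
#' Simulated exposure and outcome tables share SNP identifiers and allele
#' coding by construction, so the aligned instrument set can be assembled
#' without the general allele-matching pass of [harmonize()] (which gives an
#' identical result on these tables).
#'
#' @param study A `simulated_study`.
#' @param exposure_index For multi-exposure studies, which exposure table to
#'   use.
#' @return A `harmonized_set`.
#' @export
harmonize_simulated <- function(study, exposure_index = 1) {
  ex <- study$exposure_stats
  if (!is.data.frame(ex)) ex <- ex[[exposure_index]]
  oc <- study$outcome_stats
  set <- data.frame(
    snp_id = ex$snp_id,
    effect_allele = ex$effect_allele,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    p_exposure = ex$pvalue,
    beta_outcome = oc$beta,
    se_outcome = oc$se,
    p_outcome = oc$pvalue,
    eaf = ex$eaf,
    n_exposure = ex$n,
    n_outcome = oc$n,
    stringsAsFactors = FALSE
  )
  set$f_stat <- (set$beta_exposure / set$se_exposure)^2
  set$steiger_direction <-
    steiger_r2(set$beta_exposure, set$se_exposure, set$n_exposure) >
    steiger_r2(set$beta_outcome, set$se_outcome, set$n_outcome)
  attr(set, "dropped") <- data.frame(snp_id = character(),
                                     reason = character(),
                                     stringsAsFactors = FALSE)
  class(set) <- c("harmonized_set", "data.frame")
  set
}
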