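# Two-step MR mediation: how much of an exposure -> outcome effect flows
# through a mediator. beta1 = exposure -> mediator, beta2 = mediator ->
# outcome, beta3 = exposure -> outcome (total). Indirect effect beta1*beta2;
# proportion mediated = beta1*beta2 / beta3, with first-order delta-method
# standard errors treating the three estimates as independent (they come
# from non-overlapping GWAS samples).

#' Two-step MR mediation with delta-method standard errors
#'
#' Computes the indirect effect `beta1 * beta2`, its first-order
#' (Sobel-type) delta-method standard error
#' `sqrt(beta2^2 se1^2 + beta1^2 se2^2)`, the proportion mediated
#' `beta1 * beta2 / beta3` with a delta-method SE propagating all three
#' uncertainties (optionally only the numerator's, see
#' `include_total_uncertainty`), a 95\% confidence interval
#' `proportion -/+ 1.96 * SE`, and a normal-approximation p-value for the
#' indirect effect. Proportions outside \[0, 1\] are reported with a warning
#' flag, never truncated.
#'
#' @param beta1,se1 Exposure-to-mediator estimate and SE.
#' @param beta2,se2 Mediator-to-outcome estimate and SE.
#' @param beta3,se3 Exposure-to-outcome total-effect estimate and SE.
#' @param include_total_uncertainty Propagate `se3` into the proportion's SE
#'   (default `TRUE`).
#' @return An object of class `mediation_result`.
#' @export
two_step_mediation <- function(beta1, se1, beta2, se2, beta3, se3,
                               include_total_uncertainty = TRUE) {
  if (beta3 == 0) {
    stop("two_step_mediation: beta3 = 0, proportion mediated undefined",
         call. = FALSE)
  }
  if (any(c(se1, se2, se3) < 0)) stop_field("se", "must be >= 0")
  indirect <- beta1 * beta2
  indirect_se <- sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)
  proportion <- indirect / beta3
  grad <- c(beta2 / beta3, beta1 / beta3, -indirect / beta3^2)
  var_terms <- grad^2 * c(se1^2, se2^2, se3^2)
  if (!include_total_uncertainty) var_terms[3] <- 0
  proportion_se <- sqrt(sum(var_terms))
  out_of_range <- proportion < 0 || proportion > 1
  if (out_of_range) {
    warning(sprintf("proportion mediated %.3f lies outside [0, 1]",
                    proportion), call. = FALSE)
  }
  structure(
    list(beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
         beta3 = beta3, se3 = se3,
         indirect = indirect, indirect_se = indirect_se,
         proportion = proportion, proportion_se = proportion_se,
         ci_low = proportion - 1.96 * proportion_se,
         ci_high = proportion + 1.96 * proportion_se,
         pvalue = z_pvalue(indirect, indirect_se),
         out_of_range = out_of_range,
         include_total_uncertainty = include_total_uncertainty),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step MR mediation\n")
  cat(sprintf("  beta1 (exposure -> mediator) = %.4f (SE %.4f)\n", x$beta1, x$se1))
  cat(sprintf("  beta2 (mediator -> outcome)  = %.4f (SE %.4f)\n", x$beta2, x$se2))
  cat(sprintf("  beta3 (total effect)         = %.4f (SE %.4f)\n", x$beta3, x$se3))
  cat(sprintf("  indirect effect = %.4f (SE %.4f), p = %.3g\n",
              x$indirect, x$indirect_se, x$pvalue))
  cat(sprintf("  proportion mediated = %.2f%% (95%% CI %.2f%%-%.2f%%)%s\n",
              100 * x$proportion, 100 * x$ci_low, 100 * x$ci_high,
              if (x$out_of_range) " [outside 0-100%]" else ""))
  if (!x$include_total_uncertainty) {
    cat("  (total-effect uncertainty excluded from the proportion SE)\n")
  }
  invisible(x)
}

#' Mediation analysis from three harmonized instrument sets
#'
#' Runs IVW on each leg (exposure to mediator, mediator to outcome, exposure
#' to outcome) and feeds the three estimates into [two_step_mediation()].
#'
#' @param set_exposure_mediator,set_mediator_outcome,set_exposure_outcome
#'   `harmonized_set` objects for the three legs.
#' @param ivw_model Passed to [mr_ivw()].
#' @param ... Passed to [two_step_mediation()].
#' @return A `mediation_result`.
#' @export
mediation_from_sets <- function(set_exposure_mediator, set_mediator_outcome,
                                set_exposure_outcome,
                                ivw_model = "multiplicative_random", ...) {
  f1 <- mr_ivw(set_exposure_mediator, model = ivw_model)
  f2 <- mr_ivw(set_mediator_outcome, model = ivw_model)
  f3 <- mr_ivw(set_exposure_outcome, model = ivw_model)
  two_step_mediation(f1$beta, f1$se, f2$beta, f2$se, f3$beta, f3$se, ...)
}
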