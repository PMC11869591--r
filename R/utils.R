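#' @keywords internal
"_PACKAGE"

# Run an expression under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic functions in the package route through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministically derive a sub-stream seed from a master seed; keeps every
# derived seed a valid 32-bit integer.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) {
    return(NULL)
  }
  (as.numeric(seed) * 48271 + stream * 1009) %% 2147483647
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sided normal p-value for an estimate/SE pair.
z_pvalue <- function(beta, se) {
  2 * stats::pnorm(-abs(beta / se))
}

#' Convert a log-odds estimate to an odds ratio with 95\% confidence interval
#'
#' @param beta Estimate on the log-odds scale.
#' @param se Standard error (non-negative).
#' @return Named list with `or`, `ci_low`, `ci_high` where the interval is
#'   `exp(beta -/+ 1.96 * se)`.
#' @examples
#' beta_to_or_ci(-0.274, 0.129)
#' @export
beta_to_or_ci <- function(beta, se) {
  if (any(se < 0)) stop_field("se", "must be >= 0")
  list(
    or = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se)
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests in the family.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 207)   # microbial taxa family
#' bonferroni_threshold(0.05, 1400)  # metabolites + metabolite ratios
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_field("alpha", "must be in (0, 1)")
  }
  if (!is.numeric(n_tests) || n_tests < 1) {
    stop_field("n_tests", "must be >= 1")
  }
  alpha / n_tests
}
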