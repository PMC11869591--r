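# Bivariate LD-score regression: SNP heritability from the regression of
# association chi-square on LD scores, and cross-trait genetic correlation
# from the regression of z-score products. Simplified implementation:
# user-supplied LD scores, no annotation partitioning, block-jackknife
# standard errors.

ldsc_weights <- function(x, h2, intercept = 1) {
  # heteroskedasticity weights 1 / E[z^2]^2, updated once from an initial
  # unweighted fit (x = (n/m) * ell)
  1 / pmax(intercept + h2 * x, 0.1)^2
}

wls_fit <- function(y, x, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  slope <- sum(w * (x - mx) * (y - my)) / sum(w * (x - mx)^2)
  list(slope = slope, intercept = my - slope * mx)
}

jackknife_blocks <- function(n, n_blocks) {
  n_blocks <- min(n_blocks, n)
  split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
}

#' SNP heritability by LD-score regression
#'
#' Weighted regression of squared z-scores on `(n / m) * ld_score`, with an
#' intercept: the slope estimates SNP heritability, the intercept captures
#' confounding inflation (1 under the null). Weights
#' `1 / (1 + (n/m) h2 l)^2` are updated once from an initial unweighted
#' fit. Standard errors by delete-a-block jackknife.
#'
#' @param z Per-SNP association z-scores.
#' @param ld_scores Per-SNP LD scores (same length and order).
#' @param n GWAS sample size.
#' @param m Number of SNPs the LD scores were computed over.
#' @param n_blocks Jackknife blocks, default 200 (reduced with a warning if
#'   there are fewer SNPs).
#' @return List with `h2`, `h2_se`, `intercept`, `intercept_se`.
#' @export
ldsc_h2 <- function(z, ld_scores, n, m, n_blocks = 200) {
  if (length(z) != length(ld_scores)) {
    stop_field("ld_scores", "must match length of z")
  }
  if (n <= 0 || m <= 0) stop_field("n", "sample sizes must be positive")
  if (length(z) < n_blocks) {
    warning(sprintf("fewer SNPs (%d) than jackknife blocks; reducing to %d",
                    length(z), max(2, length(z) %/% 2)), call. = FALSE)
    n_blocks <- max(2, length(z) %/% 2)
  }
  x <- (n / m) * ld_scores
  y <- z^2
  fit0 <- wls_fit(y, x, rep(1, length(y)))
  w <- ldsc_weights(x, max(fit0$slope, 0), max(fit0$intercept, 0.5))
  fit <- wls_fit(y, x, w)
  blocks <- jackknife_blocks(length(y), n_blocks)
  jk <- vapply(blocks, function(idx) {
    f <- wls_fit(y[-idx], x[-idx], w[-idx])
    c(f$slope, f$intercept)
  }, numeric(2))
  nb <- length(blocks)
  se <- sqrt((nb - 1) / nb * rowSums((jk - rowMeans(jk))^2))
  list(h2 = fit$slope, h2_se = se[1],
       intercept = fit$intercept, intercept_se = se[2],
       weights = w)
}

#' Cross-trait genetic correlation by bivariate LD-score regression
#'
#' The genetic covariance is the slope of the regression of `z1 * z2` on
#' `sqrt(n1 * n2) / m * ld_score`; the genetic correlation is
#' `rg = gcov / sqrt(h2_1 * h2_2)` using the single-trait heritability fits.
#' Jackknife standard errors recompute all three regressions per deleted
#' block. `|rg| > 1` is reported with a warning flag; rg is undefined when
#' either heritability estimate is non-positive.
#'
#' @param z1,z2 Per-SNP z-scores of the two traits on a shared SNP set.
#' @param ld_scores Per-SNP LD scores.
#' @param n1,n2 GWAS sample sizes.
#' @param m Number of SNPs behind the LD scores.
#' @param n_blocks Jackknife blocks.
#' @return An object of class `ldsc_result` with `h2_trait1`, `h2_trait2`
#'   (and SEs), `gcov`, `gcov_se`, `rg`, `rg_se`, `rg_pvalue`, `intercepts`,
#'   and flags `rg_defined`, `rg_out_of_range`.
#' @export
ldsc_rg <- function(z1, z2, ld_scores, n1, n2, m, n_blocks = 200) {
  if (length(z1) != length(z2) || length(z1) != length(ld_scores)) {
    stop_field("z2", "z1, z2 and ld_scores must have equal length")
  }
  h1 <- ldsc_h2(z1, ld_scores, n1, m, n_blocks)
  h2 <- ldsc_h2(z2, ld_scores, n2, m, n_blocks)
  x <- sqrt(n1 * n2) / m * ld_scores
  y <- z1 * z2
  # geometric mean of the two traits' final h2 regression weights, so an
  # identical trait pair reproduces the h2 fit (and rg = 1) exactly
  w <- sqrt(h1$weights * h2$weights)
  fit <- wls_fit(y, x, w)
  gcov <- fit$slope

  rg_defined <- h1$h2 > 0 && h2$h2 > 0
  rg <- if (rg_defined) gcov / sqrt(h1$h2 * h2$h2) else NA_real_

  blocks <- jackknife_blocks(length(y), min(n_blocks, length(y)))
  x1 <- (n1 / m) * ld_scores
  x2 <- (n2 / m) * ld_scores
  y1 <- z1^2
  y2 <- z2^2
  w1 <- h1$weights
  w2 <- h2$weights
  jk <- vapply(blocks, function(idx) {
    g <- wls_fit(y[-idx], x[-idx], w[-idx])$slope
    a <- wls_fit(y1[-idx], x1[-idx], w1[-idx])$slope
    b <- wls_fit(y2[-idx], x2[-idx], w2[-idx])$slope
    c(g, if (a > 0 && b > 0) g / sqrt(a * b) else NA_real_)
  }, numeric(2))
  nb <- length(blocks)
  gcov_se <- sqrt((nb - 1) / nb * sum((jk[1, ] - mean(jk[1, ]))^2))
  rg_jk <- jk[2, ][is.finite(jk[2, ])]
  rg_se <- if (rg_defined && length(rg_jk) > 1) {
    sqrt((length(rg_jk) - 1) / length(rg_jk) * sum((rg_jk - mean(rg_jk))^2))
  } else {
    NA_real_
  }
  out_of_range <- rg_defined && abs(rg) > 1
  if (out_of_range) {
    warning(sprintf("|rg| = %.3f exceeds 1", abs(rg)), call. = FALSE)
  }
  structure(
    list(h2_trait1 = h1$h2, h2_trait1_se = h1$h2_se,
         h2_trait2 = h2$h2, h2_trait2_se = h2$h2_se,
         gcov = gcov, gcov_se = gcov_se,
         rg = rg, rg_se = rg_se,
         rg_pvalue = if (rg_defined && is.finite(rg_se)) z_pvalue(rg, rg_se)
                     else NA_real_,
         intercepts = c(trait1 = h1$intercept, trait2 = h2$intercept),
         rg_defined = rg_defined, rg_out_of_range = out_of_range),
    class = "ldsc_result"
  )
}

#' @export
print.ldsc_result <- function(x, ...) {
  cat("Bivariate LD-score regression\n")
  cat(sprintf("  h2 trait 1 = %.4f (SE %.4f), intercept %.3f\n",
              x$h2_trait1, x$h2_trait1_se, x$intercepts["trait1"]))
  cat(sprintf("  h2 trait 2 = %.4f (SE %.4f), intercept %.3f\n",
              x$h2_trait2, x$h2_trait2_se, x$intercepts["trait2"]))
  if (x$rg_defined) {
    cat(sprintf("  rg = %.4f (SE %.4f), p = %.3g%s\n", x$rg, x$rg_se,
                x$rg_pvalue, if (x$rg_out_of_range) " [|rg| > 1]" else ""))
  } else {
    cat("  rg undefined (non-positive heritability estimate)\n")
  }
  invisible(x)
}

#' Simulate LD scores and z-scores under the LD-score regression model
#'
#' Generates per-SNP LD scores and (optionally correlated) z-scores for two
#' traits under the standard polygenic model:
#' `E[z^2] = 1 + n h2 l / m`, cross-trait
#' `E[z1 z2] = rg sqrt(h2_1 h2_2) sqrt(n1 n2) l / m`.
#'
#' @param m_snps SNPs to simulate (regression SNPs; also the LD-score
#'   denominator m).
#' @param h2_1,h2_2 Generating heritabilities.
#' @param rg Generating genetic correlation.
#' @param n1,n2 Sample sizes.
#' @param ld_range Range of simulated LD scores.
#' @param seed RNG seed.
#' @return List with `ld_scores`, `z1`, `z2` and the generating parameters.
#' @export
simulate_ldsc_traits <- function(m_snps = 10000, h2_1 = 0.3, h2_2 = 0.3,
                                 rg = 0, n1 = 50000, n2 = 50000,
                                 ld_range = c(1, 200), seed = 1) {
  with_seed(seed, {
    ell <- stats::runif(m_snps, ld_range[1], ld_range[2])
    v1 <- 1 + n1 * h2_1 * ell / m_snps
    v2 <- 1 + n2 * h2_2 * ell / m_snps
    cov12 <- rg * sqrt(h2_1 * h2_2) * sqrt(n1 * n2) * ell / m_snps
    rho <- cov12 / sqrt(v1 * v2)
    rho <- pmin(pmax(rho, -0.999), 0.999)
    a <- stats::rnorm(m_snps)
    b <- stats::rnorm(m_snps)
    z1 <- sqrt(v1) * a
    z2 <- sqrt(v2) * (rho * a + sqrt(1 - rho^2) * b)
    list(ld_scores = ell, z1 = z1, z2 = z2, m = m_snps,
         h2_1 = h2_1, h2_2 = h2_2, rg = rg, n1 = n1, n2 = n2)
  })
}
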