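# Univariable two-sample MR estimators and sensitivity analyses.
# All estimators consume a harmonized_set (or any data frame with the
# beta/se columns) and return an object of class "mr_result".

check_set <- function(set, min_snp, method) {
  n <- nrow(set)
  if (n == 0) stop(sprintf("%s: no instruments", method), call. = FALSE)
  if (n < min_snp) {
    stop(sprintf("%s: insufficient instruments (%d < %d)", method, n, min_snp),
         call. = FALSE)
  }
  if (any(set$se_outcome <= 0) || any(set$se_exposure <= 0)) {
    stop(sprintf("%s: standard errors must be > 0", method), call. = FALSE)
  }
  invisible(n)
}

mr_result <- function(method, n_snp, beta, se, pvalue = NULL, ...) {
  pvalue <- pvalue %||% z_pvalue(beta, se)
  orci <- beta_to_or_ci(beta, se)
  structure(
    c(list(method = method, n_snp = n_snp, beta = beta, se = se,
           pvalue = pvalue, or = orci$or, ci_low = orci$ci_low,
           ci_high = orci$ci_high),
      list(...)),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s (%d SNPs)\n", x$method, x$n_snp))
  cat(sprintf("  beta = %.4f (SE %.4f), p = %.3g\n", x$beta, x$se, x$pvalue))
  cat(sprintf("  OR = %.3f, 95%% CI = %.3f-%.3f\n", x$or, x$ci_low, x$ci_high))
  if (!is.null(x$q_stat)) {
    cat(sprintf("  Cochran's Q = %.3f on %d df, p = %.3g\n",
                x$q_stat, x$q_df, x$q_pvalue))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4f, p = %.3g\n",
                x$egger_intercept, x$egger_intercept_p))
  }
  invisible(x)
}

#' @export
coef.mr_result <- function(object, ...) {
  stats::setNames(object$beta, object$method)
}

#' @export
confint.mr_result <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$beta - z * object$se, object$beta + z * object$se),
              nrow = 1,
              dimnames = list(object$method,
                              paste0(format(100 * c((1 - level) / 2,
                                                    1 - (1 - level) / 2)), "%")))
  m
}

#' Inverse-variance weighted (IVW) estimator
#'
#' The primary two-sample MR estimator: a weighted regression of outcome
#' betas on exposure betas through the origin with weights
#' `1 / se_outcome^2`, equivalent to the inverse-variance weighted
#' meta-analysis of per-SNP Wald ratios. With a single instrument it reduces
#' exactly to the Wald ratio. The multiplicative random-effects model (the
#' default, and the conservative convention) inflates the fixed-effects
#' standard error by `max(1, sqrt(Q / df))` where Q is Cochran's
#' heterogeneity statistic.
#'
#' @param set A `harmonized_set` (or data frame with `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`).
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_result` with heterogeneity fields `q_stat`, `q_df`,
#'   `q_pvalue` when `n_snp >= 2`.
#' @export
mr_ivw <- function(set, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  check_set(set, if (model == "fixed") 1 else 2, "IVW")
  bx <- set$beta_exposure
  by <- set$beta_outcome
  w <- 1 / set$se_outcome^2
  est <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  n <- length(bx)
  q <- sum(w * (by - est * bx)^2)
  q_df <- n - 1L
  se <- se_fixed
  if (model == "multiplicative_random" && q_df > 0) {
    se <- se_fixed * max(1, sqrt(q / q_df))
  }
  q_p <- if (q_df > 0) stats::pchisq(q, q_df, lower.tail = FALSE) else NA_real_
  mr_result(
    method = sprintf("IVW (%s)", gsub("_", " ", model)),
    n_snp = n, beta = est, se = se,
    q_stat = if (q_df > 0) q else NA_real_,
    q_df = q_df,
    q_pvalue = q_p
  )
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (ratio_j - estimate)^2` with Wald-ratio weights
#' `w_j = (beta_exposure / se_outcome)^2`, compared against a chi-square with
#' `n_snp - 1` degrees of freedom. Algebraically identical to the weighted
#' residual sum of squares of the IVW regression.
#'
#' @param set A `harmonized_set`.
#' @param estimate The causal estimate to measure heterogeneity around
#'   (defaults to the fixed-effects IVW estimate).
#' @return List with `q_stat`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(set, estimate = NULL) {
  check_set(set, 2, "Cochran's Q")
  if (is.null(estimate)) estimate <- mr_ivw(set, model = "fixed")$beta
  w <- (set$beta_exposure / set$se_outcome)^2
  ratio <- set$beta_outcome / set$beta_exposure
  q <- sum(w * (ratio - estimate)^2)
  q_df <- nrow(set) - 1L
  list(q_stat = q, q_df = q_df,
       q_pvalue = stats::pchisq(q, q_df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an intercept,
#' weights `1 / se_outcome^2`. Instruments are first oriented so every
#' exposure beta is non-negative (flipping the outcome beta with it), which
#' the intercept's interpretation as average directional pleiotropy requires.
#' The slope is the causal estimate; the intercept and its p-value form the
#' standard test of directional pleiotropy. Standard errors use the
#' multiplicative random-effects convention (residual dispersion truncated
#' below at 1).
#'
#' @param set A `harmonized_set` with at least 3 SNPs.
#' @return An `mr_result` with `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p`.
#' @export
mr_egger <- function(set) {
  check_set(set, 3, "MR-Egger")
  flip <- sign(set$beta_exposure)
  flip[flip == 0] <- 1
  bx <- set$beta_exposure * flip
  by <- set$beta_outcome * flip
  w <- 1 / set$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  disp <- max(1, sigma)
  coefs <- sm$coefficients
  slope <- coefs["bx", "Estimate"]
  slope_se <- coefs["bx", "Std. Error"] / sigma * disp
  icpt <- coefs["(Intercept)", "Estimate"]
  icpt_se <- coefs["(Intercept)", "Std. Error"] / sigma * disp
  mr_result(
    method = "MR-Egger", n_snp = nrow(set),
    beta = slope, se = slope_se,
    egger_intercept = icpt,
    egger_intercept_se = icpt_se,
    egger_intercept_p = z_pvalue(icpt, icpt_se)
  )
}

# Weighted median of values x with weights w: order by x, return the value
# where the normalized cumulative weight crosses 1/2 (linear interpolation
# between bracketing order statistics, the standard MR convention).
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cs <- cumsum(w) - w / 2
  cs <- cs / sum(w)
  if (cs[1] >= 0.5) return(x[1])
  if (cs[length(cs)] <= 0.5) return(x[length(x)])
  below <- max(which(cs < 0.5))
  x[below] + (x[below + 1] - x[below]) * (0.5 - cs[below]) /
    (cs[below + 1] - cs[below])
}

#' Weighted-median estimator
#'
#' Weighted median of per-SNP Wald ratios with inverse-variance weights
#' `(beta_exposure / se_outcome)^2`; consistent when at least half the weight
#' comes from valid instruments. The standard error is obtained by parametric
#' bootstrap: exposure and outcome betas are resampled from normal
#' distributions centred on the observed values with the reported standard
#' errors, and the estimator recomputed.
#'
#' @param set A `harmonized_set` with at least 3 SNPs.
#' @param n_boot Bootstrap resamples for the SE (default 1000; must be >= 1).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = 1) {
  check_set(set, 3, "weighted median")
  if (n_boot < 2) {
    stop("weighted median: n_boot must be >= 2 for a defined SE",
         call. = FALSE)
  }
  ratio <- set$beta_outcome / set$beta_exposure
  w <- (set$beta_exposure / set$se_outcome)^2
  est <- weighted_median_point(ratio, w)
  n <- nrow(set)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(n, set$beta_exposure, set$se_exposure)
      by <- stats::rnorm(n, set$beta_outcome, set$se_outcome)
      weighted_median_point(by / bx, (bx / set$se_outcome)^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_result(method = "Weighted median", n_snp = n, beta = est, se = se)
}

# Profile log-likelihood of the overdispersed two-sample MR model at causal
# effect b and overdispersion tau2: residual by - b*bx has variance
# se_y^2 + b^2 se_x^2 + tau2 (measurement error in both betas).
raps_loglik <- function(b, tau2, bx, by, sx2, sy2) {
  v <- sy2 + b^2 * sx2 + tau2
  -0.5 * sum((by - b * bx)^2 / v + log(v))
}

#' Robust adjusted profile score (RAPS) estimator
#'
#' Maximum profile likelihood for the causal effect accounting for sampling
#' error in the exposure betas, with a non-negative overdispersion parameter
#' tau-squared absorbing systematic (balanced) pleiotropy. This is the
#' simple quadratic-loss form of the adjusted-profile-score family. The
#' standard error is the sandwich of the per-SNP score contributions
#' evaluated at the optimum.
#'
#' @param set A `harmonized_set` with at least 3 SNPs.
#' @param max_iter Iteration cap for the optimizer.
#' @return An `mr_result` with the fitted `tau2`.
#' @export
mr_raps <- function(set, max_iter = 500) {
  check_set(set, 3, "RAPS")
  bx <- set$beta_exposure
  by <- set$beta_outcome
  sx2 <- set$se_exposure^2
  sy2 <- set$se_outcome^2
  start_b <- mr_ivw(set, model = "fixed")$beta
  # parametrize tau2 = t^2 to keep it non-negative
  nll <- function(par) -raps_loglik(par[1], par[2]^2, bx, by, sx2, sy2)
  opt <- stats::optim(c(start_b, 0.01), nll, method = "BFGS",
                      control = list(maxit = max_iter))
  if (opt$convergence != 0) {
    stop(sprintf("RAPS: optimizer failed to converge (last iterate b = %.4g)",
                 opt$par[1]), call. = FALSE)
  }
  b <- opt$par[1]
  tau2 <- opt$par[2]^2
  # sandwich SE from the per-SNP profile scores in b (tau2 profiled out)
  eps <- 1e-6 * max(1, abs(b))
  score_j <- function(bb) {
    v <- sy2 + bb^2 * sx2 + tau2
    r <- by - bb * bx
    # d/db of per-SNP log-density
    (r * bx) / v + bb * sx2 * (r^2 / v^2 - 1 / v)
  }
  s_hi <- score_j(b + eps)
  s_lo <- score_j(b - eps)
  A <- sum((s_hi - s_lo) / (2 * eps))   # observed information (negative)
  Bmat <- sum(score_j(b)^2)
  se <- sqrt(Bmat / A^2)
  mr_result(method = "RAPS", n_snp = nrow(set), beta = b, se = se,
            tau2 = tau2)
}

# One cML fit for a fixed number K of invalid instruments.
# Model: bx_j ~ N(gamma_j, sx2), by_j ~ N(b*gamma_j + r_j, sy2) with at most
# K nonzero direct effects r_j, chosen as the K SNPs whose removal most
# reduces the constrained likelihood.
cml_fit_k <- function(bx, by, sx2, sy2, k, b_start, max_iter = 200,
                      tol = 1e-8) {
  m <- length(bx)
  b <- b_start
  invalid <- integer(0)
  for (iter in seq_len(max_iter)) {
    # profile gamma given b assuming r = 0
    gamma0 <- (bx / sx2 + b * by / sy2) / (1 / sx2 + b^2 / sy2)
    # likelihood gain from freeing r_j: residual chi-square of by_j
    gain <- (by - b * gamma0)^2 / sy2
    invalid_new <- if (k > 0) order(gain, decreasing = TRUE)[seq_len(k)] else integer(0)
    valid <- setdiff(seq_len(m), invalid_new)
    # with r_j free, gamma_j = bx_j and r_j = by_j - b*bx_j (those SNPs carry
    # no information about b)
    gamma <- gamma0
    gamma[invalid_new] <- bx[invalid_new]
    b_new <- sum(gamma[valid] * by[valid] / sy2[valid]) /
      sum(gamma[valid]^2 / sy2[valid])
    done <- abs(b_new - b) < tol && identical(sort(invalid_new), sort(invalid))
    b <- b_new
    invalid <- invalid_new
    if (done) break
    if (iter == max_iter) {
      stop("cML: inner fit failed to converge", call. = FALSE)
    }
  }
  gamma0 <- (bx / sx2 + b * by / sy2) / (1 / sx2 + b^2 / sy2)
  gamma <- gamma0
  gamma[invalid] <- bx[invalid]
  r <- rep(0, m)
  r[invalid] <- by[invalid] - b * bx[invalid]
  negloglik <- 0.5 * sum((bx - gamma)^2 / sx2 + (by - b * gamma - r)^2 / sy2)
  valid <- setdiff(seq_len(m), invalid)
  # Fisher information for b from the valid instruments
  info <- sum(gamma[valid]^2 / sy2[valid])
  list(b = b, invalid = sort(invalid), negloglik = negloglik,
       se = sqrt(1 / info))
}

#' Constrained maximum likelihood with model averaging (cML-MA)
#'
#' For each assumed count K of invalid instruments (K = 0 ... n_snp - 2) the
#' constrained likelihood is maximized, selecting as invalid the K SNPs with
#' the largest likelihood violation; fits are then combined across K by
#' BIC-based model-averaging weights. The averaged standard error includes
#' the between-model spread of the estimates.
#'
#' @param set A `harmonized_set` with at least 3 SNPs.
#' @param k_max Largest K considered (default `n_snp - 2`).
#' @return An `mr_result` with `k_weights` (per-K weights) and
#'   `invalid_snps` (ids selected invalid at the highest-weight K).
#' @export
mr_cml_ma <- function(set, k_max = NULL) {
  check_set(set, 3, "cML-MA")
  bx <- set$beta_exposure
  by <- set$beta_outcome
  sx2 <- set$se_exposure^2
  sy2 <- set$se_outcome^2
  m <- length(bx)
  k_max <- min(k_max %||% (m - 2L), m - 2L)
  b_start <- mr_ivw(set, model = "fixed")$beta
  fits <- lapply(0:k_max, function(k)
    cml_fit_k(bx, by, sx2, sy2, k, b_start))
  bic <- vapply(fits, function(f) 2 * f$negloglik, numeric(1)) +
    (0:k_max) * log(m)
  wts <- exp(-(bic - min(bic)) / 2)
  wts <- wts / sum(wts)
  bs <- vapply(fits, function(f) f$b, numeric(1))
  ses <- vapply(fits, function(f) f$se, numeric(1))
  b_ma <- sum(wts * bs)
  se_ma <- sqrt(sum(wts * (ses^2 + (bs - b_ma)^2)))
  best <- which.max(wts)
  mr_result(
    method = "cML-MA", n_snp = m, beta = b_ma, se = se_ma,
    k_weights = stats::setNames(wts, paste0("K", 0:k_max)),
    invalid_snps = set$snp_id[fits[[best]]$invalid]
  )
}

# Leave-one-out fixed-effect IVW slopes for every SNP at once, via sum
# updates (used by MR-PRESSO's residual-sum statistic).
loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Global test: the observed residual sum of squares (each SNP's squared,
#' inverse-variance standardized residual from the IVW fit that excludes it)
#' is compared with its null distribution obtained from `n_sim` parametric
#' simulations under the no-pleiotropy model. Per-SNP outlier p-values come
#' from the same simulations; SNPs significant after Bonferroni correction
#' over instruments are removed and the IVW estimate recomputed. A
#' distortion test compares the change in estimate against removals of
#' random subsets of the same size.
#'
#' @param set A `harmonized_set` with at least 4 SNPs.
#' @param n_sim Parametric simulations for the null distribution.
#' @param outlier_alpha Significance level for outlier calls (Bonferroni
#'   corrected across SNPs).
#' @param seed RNG seed.
#' @return A `presso_result` list: `global_rss`, `global_pvalue`,
#'   `outlier_indices`, `outlier_pvalues`, `corrected` (an `mr_result` after
#'   outlier removal, or `NULL` when none), `distortion_pvalue`.
#' @export
mr_presso <- function(set, n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  check_set(set, 4, "MR-PRESSO")
  bx <- set$beta_exposure
  by <- set$beta_outcome
  sx <- set$se_exposure
  sy <- set$se_outcome
  w <- 1 / sy^2
  m <- length(bx)

  slopes <- loo_slopes(bx, by, w)
  res_obs <- w * (by - slopes * bx)^2
  rss_obs <- sum(res_obs)

  b_full <- sum(w * bx * by) / sum(w * bx^2)

  sim <- with_seed(seed, {
    rss_sim <- numeric(n_sim)
    exceed <- numeric(m)   # per-SNP count of simulated residual >= observed
    for (s in seq_len(n_sim)) {
      bx_s <- stats::rnorm(m, bx, sx)
      by_s <- stats::rnorm(m, slopes * bx_s, sy)
      sl_s <- loo_slopes(bx_s, by_s, w)
      res_s <- w * (by_s - sl_s * bx_s)^2
      rss_sim[s] <- sum(res_s)
      exceed <- exceed + (res_s >= res_obs)
    }
    list(rss_sim = rss_sim, exceed = exceed)
  })
  global_p <- (1 + sum(sim$rss_sim >= rss_obs)) / (n_sim + 1)
  outlier_p <- (1 + sim$exceed) / (n_sim + 1)
  outliers <- which(outlier_p * m < outlier_alpha)

  corrected <- NULL
  distortion_p <- NA_real_
  if (length(outliers) > 0 && m - length(outliers) >= 2) {
    keep <- setdiff(seq_len(m), outliers)
    corrected <- mr_ivw(set[keep, , drop = FALSE])
    # distortion: compare the shift against removing random same-size subsets
    obs_shift <- corrected$beta - b_full
    n_d <- 500
    shifts <- with_seed(derive_seed(seed, 7), {
      vapply(seq_len(n_d), function(i) {
        drop <- sample.int(m, length(outliers))
        kp <- setdiff(seq_len(m), drop)
        b_i <- sum(w[kp] * bx[kp] * by[kp]) / sum(w[kp] * bx[kp]^2)
        b_i - b_full
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(shifts) >= abs(obs_shift))) / (n_d + 1)
  }
  structure(
    list(global_rss = rss_obs, global_pvalue = global_p,
         outlier_indices = outliers,
         outlier_snps = set$snp_id[outliers],
         outlier_pvalues = outlier_p,
         corrected = corrected,
         distortion_pvalue = distortion_p,
         n_snp = m),
    class = "presso_result"
  )
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO (%d SNPs)\n", x$n_snp))
  cat(sprintf("  Global RSS = %.3f, p = %.3g\n", x$global_rss, x$global_pvalue))
  if (length(x$outlier_indices) > 0) {
    cat(sprintf("  Outliers: %s\n", paste(x$outlier_snps, collapse = ", ")))
    cat(sprintf("  Distortion p = %.3g\n", x$distortion_pvalue))
    cat("  Outlier-corrected estimate:\n")
    print(x$corrected)
  } else {
    cat("  No outliers detected\n")
  }
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' @param set A `harmonized_set` with at least 2 SNPs.
#' @return Data frame with one row per excluded SNP: the IVW estimate, SE and
#'   p-value on the remaining instruments.
#' @export
leave_one_out <- function(set) {
  check_set(set, 2, "leave-one-out")
  rows <- lapply(seq_len(nrow(set)), function(j) {
    fit <- mr_ivw(set[-j, , drop = FALSE],
                  model = if (nrow(set) - 1 >= 2) "multiplicative_random" else "fixed")
    data.frame(excluded_snp = set$snp_id[j], beta = fit$beta, se = fit$se,
               pvalue = fit$pvalue, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Single-SNP (Wald ratio) analysis
#'
#' Per-SNP causal estimates `beta_outcome / beta_exposure` with first-order
#' standard errors `se_outcome / |beta_exposure|`; the standard input for
#' funnel plots.
#'
#' @param set A `harmonized_set`.
#' @return Data frame with `snp_id`, `ratio`, `se`, `pvalue`.
#' @export
single_snp <- function(set) {
  check_set(set, 1, "single SNP")
  ratio <- set$beta_outcome / set$beta_exposure
  se <- set$se_outcome / abs(set$beta_exposure)
  data.frame(snp_id = set$snp_id, ratio = ratio, se = se,
             pvalue = z_pvalue(ratio, se), stringsAsFactors = FALSE)
}

#' Fit a panel of univariable MR estimators
#'
#' Convenience wrapper running the requested estimators on one harmonized
#' set and collecting results into a tidy table.
#'
#' @param set A `harmonized_set`.
#' @param methods Character vector from `"ivw"`, `"egger"`,
#'   `"weighted_median"`, `"raps"`, `"cml_ma"`.
#' @param ivw_model Passed to [mr_ivw()].
#' @param seed Seed for the bootstrap-based methods.
#' @return An object of class `mr_fit`: a list of `mr_result`s with a
#'   `summary`/`print` method producing one row per method.
#' @export
mr_fit <- function(set, methods = c("ivw", "egger", "weighted_median",
                                    "raps", "cml_ma"),
                   ivw_model = "multiplicative_random", seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  fits <- list()
  for (mth in methods) {
    fit <- tryCatch(
      switch(mth,
             ivw = mr_ivw(set, model = ivw_model),
             egger = mr_egger(set),
             weighted_median = mr_weighted_median(set, seed = seed),
             raps = mr_raps(set),
             cml_ma = mr_cml_ma(set)),
      error = function(e) e
    )
    fits[[mth]] <- fit
  }
  structure(list(fits = fits, n_snp = nrow(set)), class = "mr_fit")
}

#' @export
summary.mr_fit <- function(object, ...) {
  rows <- lapply(object$fits, function(f) {
    if (inherits(f, "error")) return(NULL)
    data.frame(method = f$method, n_snp = f$n_snp, beta = f$beta, se = f$se,
               pvalue = f$pvalue, or = f$or, ci_low = f$ci_low,
               ci_high = f$ci_high,
               q_pvalue = f$q_pvalue %||% NA_real_,
               egger_intercept = f$egger_intercept %||% NA_real_,
               egger_intercept_p = f$egger_intercept_p %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Univariable MR fit (%d SNPs)\n", x$n_snp))
  failed <- names(x$fits)[vapply(x$fits, inherits, logical(1), "error")]
  print(summary(x), digits = 4)
  if (length(failed) > 0) {
    cat("Failed methods:", paste(failed, collapse = ", "), "\n")
  }
  invisible(x)
}
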