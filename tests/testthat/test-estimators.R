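test_that("IVW equals the closed-form weighted mean of Wald ratios", {
  set <- make_hset(c(0.1, 0.2, 0.1), c(0.05, 0.08, 0.03),
                   c(0.01, 0.02, 0.01))
  fit <- mr_ivw(set, model = "fixed")
  # equal ratio weights (beta_x / se_y)^2 = 100 -> mean of 0.5, 0.4, 0.3
  expect_equal(fit$beta, 0.4, tolerance = 1e-12)
  expect_equal(fit$beta, ivw_oracle(set), tolerance = 1e-12)
  expect_equal(fit$q_df, 2L)
})

test_that("single-instrument IVW is exactly the Wald ratio", {
  set <- make_hset(0.1, 0.05, 0.01)
  fit <- mr_ivw(set, model = "fixed")
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$se, 0.01 / 0.1, tolerance = 1e-12)
  expect_error(mr_ivw(set, model = "multiplicative_random"), "insufficient")
  expect_error(mr_ivw(make_hset(numeric(0), numeric(0), numeric(0))),
               "no instruments")
})

test_that("identical ratios give zero heterogeneity and equal fixed/random SEs", {
  set <- make_hset(c(0.1, 0.2, 0.3), c(0.04, 0.08, 0.12), rep(0.01, 3))
  fixed <- mr_ivw(set, "fixed")
  random <- mr_ivw(set, "multiplicative_random")
  expect_equal(fixed$q_stat, 0, tolerance = 1e-20)
  expect_equal(random$se, fixed$se)
  q <- cochran_q(set)
  expect_equal(q$q_stat, 0, tolerance = 1e-20)
  expect_equal(q$q_pvalue, 1)
})

test_that("Cochran's Q matches the hand-evaluated formula and is monotone", {
  # 2 SNPs, ratios 0.3 and 0.5, weights (beta_x/se_y)^2 = 100, IVW = 0.4:
  # Q = 100 * 0.01 + 100 * 0.01 = 2 on 1 df
  set <- make_hset(c(1, 1), c(0.3, 0.5), c(0.1, 0.1))
  q <- cochran_q(set)
  expect_equal(q$q_stat, 2, tolerance = 1e-12)
  expect_equal(q$q_df, 1L)
  # moving one ratio away from the centre only increases Q
  qs <- sapply(seq(0.5, 1.5, by = 0.25), function(r) {
    cochran_q(make_hset(c(1, 1), c(0.3, r), c(0.1, 0.1)))$q_stat
  })
  expect_true(all(diff(qs) > 0))
})

test_that("random-effects IVW never reports a smaller SE than fixed effects", {
  set.seed(11)
  for (i in 1:10) {
    m <- sample(3:30, 1)
    set <- make_hset(runif(m, 0.05, 0.3), rnorm(m, 0.05, 0.05),
                     runif(m, 0.01, 0.1))
    expect_gte(mr_ivw(set, "multiplicative_random")$se,
               mr_ivw(set, "fixed")$se)
  }
})

test_that("MR-Egger recovers exact linear data and rejects tiny sets", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  set <- make_hset(bx, 0.02 + 0.4 * bx, rep(0.01, 4))
  fit <- mr_egger(set)
  expect_equal(fit$beta, 0.4, tolerance = 1e-10)
  expect_equal(fit$egger_intercept, 0.02, tolerance = 1e-10)
  expect_error(mr_egger(make_hset(c(0.1, 0.2), c(0.04, 0.08), rep(0.01, 2))),
               "insufficient")
})

test_that("Egger orientation makes the fit invariant to per-SNP sign flips", {
  set.seed(21)
  m <- 20
  bx <- abs(rnorm(m, 0.2, 0.05))
  set <- make_hset(bx, 0.01 + 0.3 * bx + rnorm(m, 0, 0.02), rep(0.02, m))
  flip <- rep(c(1, -1), length.out = m)
  set2 <- set
  set2$beta_exposure <- set$beta_exposure * flip
  set2$beta_outcome <- set$beta_outcome * flip
  f1 <- mr_egger(set)
  f2 <- mr_egger(set2)
  expect_equal(f1$beta, f2$beta)
  expect_equal(f1$egger_intercept, f2$egger_intercept)
})

test_that("weighted median reduces to the median and needs a bootstrap", {
  set <- make_hset(c(0.1, 0.1, 0.1), c(0.03, 0.04, 0.05), rep(0.01, 3))
  fit <- mr_weighted_median(set, n_boot = 50, seed = 5)
  expect_equal(fit$beta, 0.4, tolerance = 1e-12)
  expect_error(mr_weighted_median(set, n_boot = 0), "n_boot")
  expect_equal(mr_weighted_median(set, n_boot = 50, seed = 5)$se, fit$se)
})

test_that("weighted median resists a corrupted minority of weight", {
  set.seed(31)
  rates <- replicate(40, {
    m <- 30
    bx <- abs(rnorm(m, 0.25, 0.03))
    by <- 0.4 * bx + rnorm(m, 0, 0.01)
    bad <- 1:12  # 40% of (equal) weight corrupted upward
    by[bad] <- by[bad] + 0.3
    set <- make_hset(bx, by, rep(0.02, m), se_exposure = rep(1e-4, m))
    mr_weighted_median(set, n_boot = 5, seed = 1)$beta
  })
  expect_lt(abs(median(rates) - 0.4), 0.05)
})

test_that("RAPS matches the truth on clean data and approaches IVW as se_x -> 0", {
  set.seed(41)
  m <- 50
  bx <- abs(rnorm(m, 0.2, 0.05))
  set <- make_hset(bx, 0.35 * bx + rnorm(m, 0, 1e-4) , rep(0.02, m),
                   se_exposure = rep(1e-6, m))
  set$beta_outcome <- 0.35 * bx  # exact proportionality, tiny noise regime
  fit <- mr_raps(set)
  expect_equal(fit$beta, 0.35, tolerance = 1e-3)
  # se_x -> 0, tau2 = 0 limit: estimate approaches IVW
  set2 <- make_hset(bx, 0.35 * bx + rnorm(m, 0, 0.02), rep(0.02, m),
                    se_exposure = rep(1e-8, m))
  expect_equal(mr_raps(set2)$beta, mr_ivw(set2, "fixed")$beta,
               tolerance = 5e-3)
})

test_that("RAPS overdispersion picks up balanced pleiotropy", {
  set.seed(51)
  taus <- replicate(20, {
    m <- 80
    bx <- abs(rnorm(m, 0.2, 0.05))
    by <- 0.3 * bx + rnorm(m, 0, 0.05) + rnorm(m, 0, 0.02)
    set <- make_hset(bx, by, rep(0.02, m), se_exposure = rep(0.005, m))
    mr_raps(set)$tau2
  })
  expect_gt(mean(taus > 0.001), 0.75)
})

test_that("cML-MA matches the weighted regression slope on clean data", {
  set <- make_hset(c(0.1, 0.2, 0.3), c(0.04, 0.08, 0.12), rep(0.01, 3),
                   se_exposure = rep(1e-5, 3))
  fit <- mr_cml_ma(set)
  expect_equal(fit$beta, 0.4, tolerance = 1e-4)
  expect_equal(unname(which.max(fit$k_weights)), 1L)  # K = 0 dominates
})

test_that("cML-MA identifies planted invalid instruments", {
  set.seed(61)
  m <- 30
  bx <- abs(rnorm(m, 0.25, 0.03))
  by <- 0.3 * bx + rnorm(m, 0, 0.005)
  by[c(7, 19)] <- by[c(7, 19)] + 0.4  # large direct effects
  set <- make_hset(bx, by, rep(0.02, m), se_exposure = rep(0.005, m))
  fit <- mr_cml_ma(set)
  expect_true(all(c("rs007", "rs019") %in% fit$invalid_snps))
  expect_lt(abs(fit$beta - 0.3), 0.05)
})

test_that("all estimators are sign-equivariant in the outcome", {
  set.seed(71)
  m <- 25
  bx <- abs(rnorm(m, 0.2, 0.05))
  by <- 0.3 * bx + rnorm(m, 0, 0.02)
  set <- make_hset(bx, by, rep(0.02, m), se_exposure = rep(0.005, m))
  neg <- set
  neg$beta_outcome <- -neg$beta_outcome
  expect_equal(mr_ivw(neg)$beta, -mr_ivw(set)$beta)
  expect_equal(mr_egger(neg)$beta, -mr_egger(set)$beta)
  expect_equal(mr_weighted_median(neg, 200, seed = 3)$beta,
               -mr_weighted_median(set, 200, seed = 3)$beta)
  expect_equal(mr_raps(neg)$beta, -mr_raps(set)$beta, tolerance = 1e-6)
  expect_equal(mr_cml_ma(neg)$beta, -mr_cml_ma(set)$beta, tolerance = 1e-8)
})

test_that("leave-one-out matches independent subset recomputation", {
  set.seed(81)
  m <- 8
  set <- make_hset(abs(rnorm(m, 0.2, 0.05)), rnorm(m, 0.06, 0.02),
                   runif(m, 0.01, 0.05))
  loo <- leave_one_out(set)
  for (j in seq_len(m)) {
    expect_equal(loo$beta[j], mr_ivw(set[-j, ])$beta)
  }
  # exchangeable SNPs: every LOO estimate equals the full IVW
  same <- make_hset(rep(0.2, 5), rep(0.06, 5), rep(0.02, 5))
  loo2 <- leave_one_out(same)
  expect_true(all(abs(loo2$beta - mr_ivw(same)$beta) < 1e-12))
  # n = 2 reduces to the two Wald ratios
  two <- make_hset(c(0.1, 0.2), c(0.05, 0.04), c(0.01, 0.01))
  loo3 <- leave_one_out(two)
  expect_equal(loo3$beta, c(0.04 / 0.2, 0.05 / 0.1))
})

test_that("single-SNP table carries Wald ratios with first-order SEs", {
  set <- make_hset(c(0.1, -0.2), c(0.05, 0.04), c(0.01, 0.02))
  tab <- single_snp(set)
  expect_equal(tab$ratio, c(0.5, -0.2))
  expect_equal(tab$se, c(0.1, 0.1))
})

test_that("log-odds to odds-ratio conversion matches the reporting convention", {
  expect_equal(beta_to_or_ci(0, 0.1)$or, 1)
  ci <- beta_to_or_ci(0, 0.1)
  expect_equal(ci$ci_low * ci$ci_high, 1, tolerance = 1e-12)  # symmetric on log scale
  degenerate <- beta_to_or_ci(log(2), 0)
  expect_equal(degenerate$or, 2)
  expect_equal(degenerate$ci_low, 2)
  expect_equal(degenerate$ci_high, 2)
  reported <- beta_to_or_ci(-0.274, 0.129)
  expect_equal(round(reported$or, 2), 0.76)
  expect_equal(round(reported$ci_low, 2), 0.59)
  expect_equal(round(reported$ci_high, 2), 0.98)
})

test_that("estimators agree within joint uncertainty on clean strong-instrument data", {
  cfg <- scenario_config(n_snps = 150, true_beta = 0.3, seed = 91)
  set <- harmonize_simulated(simulate_two_sample(cfg))
  fits <- list(ivw = mr_ivw(set), egger = mr_egger(set),
               med = mr_weighted_median(set, 300, seed = 2),
               raps = mr_raps(set), cml = mr_cml_ma(set))
  for (a in seq_along(fits)) {
    for (b in seq_len(a - 1)) {
      delta <- abs(fits[[a]]$beta - fits[[b]]$beta)
      joint <- 2 * sqrt(fits[[a]]$se^2 + fits[[b]]$se^2)
      expect_lt(delta, joint)
    }
  }
})

test_that("mr_fit collects a tidy one-row-per-method table", {
  cfg <- scenario_config(n_snps = 60, true_beta = 0.2, seed = 101)
  set <- harmonize_simulated(simulate_two_sample(cfg))
  fit <- mr_fit(set, methods = c("ivw", "egger", "weighted_median"))
  tab <- summary(fit)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("method", "beta", "se", "pvalue", "or") %in% names(tab)))
  expect_true(all(tab$ci_low <= tab$or & tab$or <= tab$ci_high))
})
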