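test_that("configuration invariants are enforced with the offending field named", {
  expect_error(scenario_config(n_snps = 0), "n_snps")
  expect_error(scenario_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(scenario_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(scenario_config(ld_r2_within = 1.5), "ld_r2_within")
  expect_error(scenario_config(pleiotropy_sd = -1), "pleiotropy_sd")
  expect_error(scenario_config(pleiotropy_mode = "balanced",
                               pleiotropy_mean = 0.1), "pleiotropy_mean")
})

test_that("identical seeds give identical studies; different seeds differ", {
  cfg <- scenario_config(n_snps = 50, true_beta = 0.2, seed = 123)
  s1 <- simulate_two_sample(cfg)
  s2 <- simulate_two_sample(cfg)
  expect_identical(s1$exposure_stats, s2$exposure_stats)
  expect_identical(s1$outcome_stats, s2$outcome_stats)
  expect_identical(s1$truth$gamma, s2$truth$gamma)
  cfg3 <- scenario_config(n_snps = 50, true_beta = 0.2, seed = 124)
  s3 <- simulate_two_sample(cfg3)
  expect_false(identical(s1$exposure_stats$beta, s3$exposure_stats$beta))
})

test_that("construction identity: outcome effects are beta * gamma before noise", {
  cfg <- scenario_config(n_snps = 80, true_beta = 0.37, seed = 5)
  st <- simulate_two_sample(cfg)
  expect_equal(st$truth$Gamma, 0.37 * st$truth$gamma, tolerance = 1e-15)
  cfgp <- scenario_config(n_snps = 80, true_beta = 0.37, seed = 5,
                          pleiotropy_mode = "balanced", pleiotropy_sd = 0.05)
  stp <- simulate_two_sample(cfgp)
  expect_equal(stp$truth$Gamma, 0.37 * stp$truth$gamma + stp$truth$alpha,
               tolerance = 1e-15)
})

test_that("reported SEs match the empirical spread of reported betas", {
  # (beta_hat - gamma) / se should be standard normal across SNPs and seeds
  z <- unlist(lapply(1:20, function(s) {
    cfg <- scenario_config(n_snps = 100, true_beta = 0.2, seed = s)
    st <- simulate_two_sample(cfg)
    (st$exposure_stats$beta - st$truth$gamma) / st$exposure_stats$se
  }))
  expect_lt(abs(sd(z) - 1), 0.1)
  expect_lt(abs(mean(z)), 0.05)
})

test_that("the LD reference reflects the configured block structure", {
  cfg <- scenario_config(n_snps = 9, ld_block_size = 3, ld_r2_within = 0.9,
                         seed = 2)
  st <- simulate_two_sample(cfg)
  ld <- st$ld_reference
  expect_equal(ld_r2(ld, "rs000001", "rs000002"), 0.9)
  expect_equal(ld_r2(ld, "rs000001", "rs000003"), 0.9)
  expect_true(is.na(ld_r2(ld, "rs000001", "rs000004")))  # across blocks
  # clumping a fully linked block keeps one SNP per block
  sel <- st$exposure_stats
  sel$pvalue <- pmin(sel$pvalue, 1e-6)
  clumped <- ld_clump(sel, ld, r2_max = 0.5, window_kb = 10000)
  expect_equal(nrow(clumped), 3)
})

test_that("correlated-exposure studies share instruments with the requested correlation", {
  cfg <- scenario_config(n_snps = 4000, true_beta = 0.3, seed = 8)
  st <- simulate_correlated_exposures(cfg, 3, exposure_correlation = 0.6,
                                      causal_index = 2)
  g <- st$truth$gamma
  cors <- cor(g)
  expect_lt(max(abs(cors[upper.tri(cors)] - 0.6)), 0.05)
  # only the causal exposure drives the outcome
  expect_equal(st$truth$Gamma, 0.3 * g[, 2], tolerance = 1e-15)
  expect_error(
    simulate_correlated_exposures(cfg, 2, matrix(c(1, 2, 2, 1), 2), 1),
    "positive semi-definite")
  # degenerate single-exposure case collapses to the two-sample shape
  one <- simulate_correlated_exposures(
    scenario_config(n_snps = 20, seed = 3), 1, 0, 1)
  expect_true(is.data.frame(one$exposure_stats))
  expect_named(one$exposure_stats, names(simulate_two_sample(
    scenario_config(n_snps = 20, seed = 3))$exposure_stats))
})

test_that("mediation triples encode the stated effect decomposition", {
  cfg <- scenario_config(n_snps = 40, seed = 4)
  tri <- simulate_mediation_triple(cfg, beta1 = 0.2, beta2 = 0.5,
                                   direct_effect = 0.3)
  expect_equal(tri$truth$total, 0.4)
  expect_equal(tri$truth$proportion, 0.25)
  full <- simulate_mediation_triple(cfg, beta1 = 0.2, beta2 = 0.5,
                                    direct_effect = 0)
  expect_equal(full$truth$proportion, 1)
  # instrument sets of the two exposures are independent draws
  expect_false(identical(tri$exposure_mediator$truth$gamma,
                         tri$mediator_outcome$truth$gamma))
})

test_that("null-scenario IVW estimates centre on zero across replicates", {
  ests <- ses <- numeric(60)
  for (i in 1:60) {
    cfg <- scenario_config(n_snps = 100, true_beta = 0, seed = 1000 + i)
    set <- harmonize_simulated(simulate_two_sample(cfg))
    fit <- mr_ivw(set)
    ests[i] <- fit$beta
    ses[i] <- fit$se
  }
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests)), 3 * mc_se)
  # reported analytic SEs agree with the Monte-Carlo spread
  expect_lt(abs(mean(ses) / sd(ests) - 1), 0.25)
})

test_that("directional pleiotropy surfaces in the Egger intercept", {
  # a large exposure GWAS keeps every observed instrument effect positive,
  # so Egger's orientation step never flips a truly positive instrument
  icpts <- numeric(40)
  for (i in 1:40) {
    cfg <- scenario_config(n_snps = 150, true_beta = 0.2, seed = 2000 + i,
                           n_exposure_sample = 2e5, instrument_scale = 0.3,
                           pleiotropy_mode = "directional",
                           pleiotropy_mean = 0.05, pleiotropy_sd = 0.01)
    set <- harmonize_simulated(simulate_two_sample(cfg))
    icpts[i] <- mr_egger(set)$egger_intercept
  }
  mc_se <- sd(icpts) / sqrt(length(icpts))
  expect_lt(abs(mean(icpts) - 0.05), 4 * mc_se)
})
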