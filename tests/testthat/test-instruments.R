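test_that("instrument screening applies p-value and both-tail EAF rules", {
  df <- make_gwas(sprintf("rs%d", 1:4),
                  beta = rep(0.1, 4), se = rep(0.02, 4),
                  pvalue = c(2e-6, 2e-5, 2e-6, 2e-6))
  df$eaf <- c(0.2, 0.2, 0.005, 0.995)
  out <- select_instruments(df, p_threshold = 1e-5, eaf_min = 0.01)
  expect_equal(out$snp_id, "rs1")
  # genome-wide threshold retains a subset of the lenient selection
  df2 <- make_gwas(sprintf("rs%d", 1:3), beta = rep(0.1, 3),
                   se = rep(0.02, 3), pvalue = c(1e-9, 1e-6, 1e-4))
  lenient <- select_instruments(df2, 1e-5)$snp_id
  strict <- select_instruments(df2, 5e-8)$snp_id
  expect_true(all(strict %in% lenient))
  expect_equal(strict, "rs1")
  expect_error(select_instruments(df2, 2), "p_threshold")
})

test_that("clumping keeps the lowest-p SNP of a linked cluster and all unlinked SNPs", {
  recs <- make_gwas(c("rs1", "rs2", "rs3"), beta = rep(0.1, 3),
                    se = rep(0.02, 3), pvalue = c(1e-8, 1e-6, 1e-7),
                    pos = c(1e6, 1.1e6, 1.2e6))
  linked <- ld_reference(c("rs1", "rs1", "rs2"), c("rs2", "rs3", "rs3"),
                         rep(0.9, 3))
  expect_equal(ld_clump(recs, linked, 0.001, 10000)$snp_id, "rs1")
  unlinked <- ld_reference(c("rs1", "rs1", "rs2"), c("rs2", "rs3", "rs3"),
                           rep(0, 3))
  expect_setequal(ld_clump(recs, unlinked, 0.001, 10000)$snp_id,
                  c("rs1", "rs2", "rs3"))
})

test_that("clumping matches the exhaustive pairwise oracle on randomized LD", {
  for (rep_i in 1:8) {
    set.seed(rep_i)
    n <- 6
    recs <- make_gwas(sprintf("rs%d", 1:n), beta = rep(0.1, n),
                      se = rep(0.02, n), pvalue = runif(n, 1e-10, 1e-5),
                      pos = sort(runif(n, 1e6, 3e7)))
    pairs <- t(combn(n, 2))
    r2 <- runif(nrow(pairs))
    ld <- ld_reference(recs$snp_id[pairs[, 1]], recs$snp_id[pairs[, 2]], r2)
    r2_max <- 0.3
    got <- ld_clump(recs, ld, r2_max, 10000)$snp_id
    want <- clump_oracle(recs, function(a, b) ld_r2(ld, a, b), r2_max, 10000)
    expect_equal(got, want)
    # invariant: no retained pair within the window is linked
    for (i in seq_along(got)) {
      for (j in seq_len(i - 1)) {
        a <- recs[recs$snp_id == got[i], ]
        b <- recs[recs$snp_id == got[j], ]
        if (abs(a$pos - b$pos) <= 1e7) {
          expect_lt(ld_r2(ld, got[i], got[j]), r2_max)
        }
      }
    }
  }
})

test_that("missing-LD pairs are fail-safe within a window, unlinked across chromosomes", {
  recs <- make_gwas(c("rs1", "rs2", "rs3"), beta = rep(0.1, 3),
                    se = rep(0.02, 3), pvalue = c(1e-8, 1e-7, 1e-6),
                    chrom = c("1", "1", "2"), pos = c(1e6, 2e6, 1e6))
  ld <- ld_reference()  # no LD data at all
  out <- ld_clump(recs, ld, 0.001, 10000)
  # rs2 shares a window with rs1 and has no LD entry -> dropped;
  # rs3 sits on another chromosome -> kept
  expect_setequal(out$snp_id, c("rs1", "rs3"))
})

test_that("proxy search returns the argmax r2 with deterministic tie-breaks", {
  cands <- make_gwas(c("rsA", "rsB", "rsC"), beta = rep(0.1, 3),
                     se = rep(0.02, 3), pvalue = c(0.5, 0.01, 0.2))
  ld <- ld_reference(rep("rsX", 3), c("rsA", "rsB", "rsC"),
                     c(0.95, 0.85, 0.5))
  expect_equal(find_proxy("rsX", cands, ld, 0.8)$snp_id, "rsA")
  ld_low <- ld_reference(rep("rsX", 3), c("rsA", "rsB", "rsC"),
                         c(0.7, 0.6, 0.5))
  expect_null(find_proxy("rsX", cands, ld_low, 0.8))
  ld_tie <- ld_reference(rep("rsX", 2), c("rsA", "rsB"), c(0.9, 0.9))
  expect_equal(find_proxy("rsX", cands, ld_tie, 0.8)$snp_id, "rsB")
})

test_that("harmonization aligns alleles, flips swapped codings, drops ambiguity", {
  ex <- make_gwas(c("rs1", "rs2", "rs3", "rs4"),
                  beta = c(0.1, 0.2, 0.3, 0.15), se = rep(0.02, 4),
                  effect_allele = c("A", "A", "A", "A"),
                  other_allele = c("G", "G", "T", "C"))
  ex$eaf <- c(0.3, 0.3, 0.5, 0.3)
  oc <- make_gwas(c("rs1", "rs2", "rs3", "rs4"),
                  beta = c(0.05, 0.08, 0.02, 0.1), se = rep(0.03, 4),
                  effect_allele = c("A", "G", "A", "A"),
                  other_allele = c("G", "A", "T", "G"))
  oc$eaf <- c(0.3, 0.7, 0.5, 0.3)
  hs <- harmonize(ex, oc)
  # rs1 aligned: untouched; rs2 swapped: negated; rs3 palindromic at 0.5:
  # dropped; rs4 irreconcilable (A/C vs A/G): dropped
  expect_equal(hs$snp_id, c("rs1", "rs2"))
  expect_equal(hs$beta_outcome, c(0.05, -0.08))
  dropped <- attr(hs, "dropped")
  expect_setequal(dropped$snp_id, c("rs3", "rs4"))
  expect_match(dropped$reason[dropped$snp_id == "rs3"], "palindromic")
  expect_match(dropped$reason[dropped$snp_id == "rs4"], "irreconcilable")
})

test_that("harmonization is involution-safe: a pre-flipped outcome gives the same set", {
  ex <- make_gwas(c("rs1", "rs2"), beta = c(0.1, 0.2), se = rep(0.02, 2))
  oc <- make_gwas(c("rs1", "rs2"), beta = c(0.05, 0.08), se = rep(0.03, 2))
  oc_flipped <- oc
  oc_flipped$effect_allele <- oc$other_allele
  oc_flipped$other_allele <- oc$effect_allele
  oc_flipped$beta <- -oc$beta
  oc_flipped$eaf <- 1 - oc$eaf
  h1 <- harmonize(ex, oc)
  h2 <- harmonize(ex, oc_flipped)
  expect_equal(as.data.frame(h1), as.data.frame(h2))
})

test_that("F-statistic computation and weak-instrument filtering", {
  expect_equal(compute_f(0.1, 0.03), (0.1 / 0.03)^2)
  expect_gt(compute_f(0.1, 0.03), 10)
  expect_equal(compute_f(0.1, 0.05), 4)
  expect_error(compute_f(0.1, 0), "se")
  set <- make_hset(c(0.1, 0.1), c(0.05, 0.04), c(0.01, 0.01),
                   se_exposure = c(0.03, 0.05))
  out <- filter_weak(set, 10)
  expect_equal(out$snp_id, "rs001")
  empty <- filter_weak(set, 1e9)
  expect_error(mr_ivw(empty), "no instruments")
})

test_that("Steiger filtering compares variance explained between traits", {
  # r2 = t^2/(t^2 + n - 2): direct evaluation at t = 10, n = 1000
  set <- make_hset(c(0.1, 0.01), c(0.01, 0.1), c(0.01, 0.01),
                   se_exposure = c(0.01, 0.01),
                   n_exposure = 1000, n_outcome = 1000)
  out <- steiger_filter(set)
  expect_equal(out$snp_id, "rs001")
  t2 <- (0.1 / 0.01)^2
  expect_equal(t2 / (t2 + 1000 - 2), 100 / 1098)
  # invariance under simultaneous sign flips of both betas
  flipped <- set
  flipped$beta_exposure <- -flipped$beta_exposure
  flipped$beta_outcome <- -flipped$beta_outcome
  expect_equal(steiger_filter(flipped)$snp_id, out$snp_id)
  bad <- set
  bad$n_exposure <- 2
  expect_error(steiger_filter(bad), "exceed 2")
})
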