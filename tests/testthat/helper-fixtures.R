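# Shared fixtures: hand-built harmonized sets and small GWAS tables,
# constructed in code so tests carry their own data.

make_hset <- function(beta_exposure, beta_outcome, se_outcome,
                      se_exposure = rep(1e-4, length(beta_exposure)),
                      n_exposure = 10000, n_outcome = 10000) {
  m <- length(beta_exposure)
  set <- data.frame(
    snp_id = sprintf("rs%03d", seq_len(m)),
    effect_allele = rep("A", m),
    beta_exposure = beta_exposure,
    se_exposure = se_exposure,
    p_exposure = 2 * pnorm(-abs(beta_exposure / se_exposure)),
    beta_outcome = beta_outcome,
    se_outcome = se_outcome,
    p_outcome = 2 * pnorm(-abs(beta_outcome / se_outcome)),
    eaf = rep(0.3, m),
    n_exposure = rep_len(n_exposure, m),
    n_outcome = rep_len(n_outcome, m),
    stringsAsFactors = FALSE
  )
  set$f_stat <- (set$beta_exposure / set$se_exposure)^2
  set$steiger_direction <- rep_len(TRUE, m)
  class(set) <- c("harmonized_set", "data.frame")
  set
}

make_gwas <- function(snp_id, beta, se, pvalue = NULL, eaf = 0.3,
                      chrom = "1", pos = NULL, effect_allele = "A",
                      other_allele = "G", n = 10000) {
  m <- length(snp_id)
  data.frame(
    snp_id = snp_id,
    chrom = rep_len(chrom, m),
    pos = pos %||% seq(1e6, by = 1e4, length.out = m),
    effect_allele = rep_len(effect_allele, m),
    other_allele = rep_len(other_allele, m),
    eaf = rep_len(eaf, m),
    beta = beta,
    se = se,
    pvalue = pvalue %||% (2 * pnorm(-abs(beta / se))),
    n = rep_len(n, m),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent IVW oracle: inverse-variance weighted mean of Wald ratios
ivw_oracle <- function(set) {
  ratio <- set$beta_outcome / set$beta_exposure
  w <- (set$beta_exposure / set$se_outcome)^2
  sum(w * ratio) / sum(w)
}

# independent greedy-clumping oracle: literal restatement of the rule,
# checking every retained/dropped pair explicitly
clump_oracle <- function(records, r2_lookup, r2_max, window_kb) {
  remaining <- records[order(records$pvalue, records$snp_id), , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    idx <- remaining[1, ]
    kept <- c(kept, idx$snp_id)
    keep_row <- rep(TRUE, nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      row <- remaining[i, ]
      if (row$snp_id == idx$snp_id) { keep_row[i] <- FALSE; next }
      if (row$chrom != idx$chrom) next
      if (abs(row$pos - idx$pos) > window_kb * 1000) next
      r2 <- r2_lookup(idx$snp_id, row$snp_id)
      if (is.na(r2) || r2 >= r2_max) keep_row[i] <- FALSE
    }
    remaining <- remaining[keep_row, , drop = FALSE]
  }
  kept
}
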