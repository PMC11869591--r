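# Instrument selection and processing: p-value/EAF screening, greedy LD
# clumping, proxy lookup, allele harmonization between the exposure and
# outcome GWAS, F-statistic and Steiger directionality filtering.

#' Construct a pairwise LD reference
#'
#' Stores pairwise r-squared values keyed by unordered SNP pair, with optional
#' positions for distance windowing. Self-r2 is 1 by definition; unknown pairs
#' are handled by the clumping policy (see [ld_clump()]).
#'
#' @param snp_a,snp_b Character vectors of SNP identifiers (pairwise).
#' @param r2 Numeric vector of r-squared values in \[0, 1\].
#' @param positions Optional data frame with columns `snp_id`, `chrom`, `pos`.
#' @return An object of class `ld_reference`.
#' @export
ld_reference <- function(snp_a = character(), snp_b = character(),
                         r2 = numeric(), positions = NULL) {
  if (length(snp_a) != length(snp_b) || length(snp_a) != length(r2)) {
    stop_field("r2", "snp_a, snp_b and r2 must have equal length")
  }
  if (length(r2) > 0 && (any(!is.finite(r2)) || any(r2 < 0 | r2 > 1))) {
    stop_field("r2", "values must lie in [0, 1]")
  }
  pairs <- data.frame(snp_a = as.character(snp_a),
                      snp_b = as.character(snp_b),
                      r2 = as.numeric(r2),
                      stringsAsFactors = FALSE)
  # canonical unordered key so lookup is symmetric
  key <- ifelse(pairs$snp_a <= pairs$snp_b,
                paste(pairs$snp_a, pairs$snp_b, sep = "\r"),
                paste(pairs$snp_b, pairs$snp_a, sep = "\r"))
  lookup <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(pairs))) assign(key[i], pairs$r2[i], envir = lookup)
  structure(
    list(pairs = pairs, lookup = lookup, positions = positions),
    class = "ld_reference"
  )
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("LD reference: %d SNP pairs%s\n", nrow(x$pairs),
              if (is.null(x$positions)) "" else
                sprintf(", positions for %d SNPs", nrow(x$positions))))
  invisible(x)
}

#' Look up pairwise r-squared in an LD reference
#'
#' @param ld An [ld_reference()].
#' @param a,b SNP identifiers.
#' @return r2 if the pair is known (1 when `a == b`), otherwise `NA`.
#' @export
ld_r2 <- function(ld, a, b) {
  if (a == b) return(1)
  key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
  if (exists(key, envir = ld$lookup, inherits = FALSE)) {
    get(key, envir = ld$lookup)
  } else {
    NA_real_
  }
}

#' Screen candidate instruments on association p-value and allele frequency
#'
#' Retains SNPs with `pvalue < p_threshold` and an effect-allele frequency
#' bounded away from both ends: `eaf > eaf_min` and `1 - eaf > eaf_min`
#' (so both the effect and other allele are common enough).
#'
#' @param records GWAS table (canonical columns, see [read_gwas_table()]).
#' @param p_threshold Association p-value cut-off; `1e-5` is the conventional
#'   microbiome-GWAS choice and `5e-8` genome-wide significance.
#' @param eaf_min Minimum allele frequency, default 0.01.
#' @return The retained rows, original order preserved.
#' @export
select_instruments <- function(records, p_threshold = 1e-5, eaf_min = 0.01) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    stop_field("p_threshold", "must be in (0, 1)")
  }
  keep <- records$pvalue < p_threshold &
    records$eaf > eaf_min & (1 - records$eaf) > eaf_min
  records[keep, , drop = FALSE]
}

#' Greedy LD clumping of instruments
#'
#' Repeatedly keeps the remaining SNP with the smallest p-value and drops all
#' SNPs within `window_kb` of it whose pairwise r-squared is at least
#' `r2_max`. Missing-LD policy: a pair on different chromosomes is treated as
#' unlinked (r2 = 0); a pair inside the window on the same chromosome with no
#' LD entry is conservatively treated as linked (dropped), guarding against
#' false independence. SNPs without position information fall back to the
#' LD lookup alone.
#'
#' @param records GWAS table, must contain `chrom` and `pos`.
#' @param ld An [ld_reference()].
#' @param r2_max Clumping threshold, default 0.001.
#' @param window_kb Window half-width in kilobases, default 10000.
#' @return Retained rows in retention (p-value) order, with an attribute
#'   `dropped` listing removed SNP ids and the index SNP responsible.
#' @export
ld_clump <- function(records, ld, r2_max = 0.001, window_kb = 10000) {
  if (nrow(records) == 0) return(records)
  ord <- order(records$pvalue, records$snp_id)
  pending <- records[ord, , drop = FALSE]
  kept <- pending[0, , drop = FALSE]
  dropped <- data.frame(snp_id = character(), index_snp = character(),
                        stringsAsFactors = FALSE)
  while (nrow(pending) > 0) {
    index <- pending[1, , drop = FALSE]
    kept <- rbind(kept, index)
    pending <- pending[-1, , drop = FALSE]
    if (nrow(pending) == 0) break
    same_chr <- pending$chrom == index$chrom
    in_window <- same_chr & abs(pending$pos - index$pos) <= window_kb * 1000
    r2 <- vapply(pending$snp_id, function(s) ld_r2(ld, index$snp_id, s),
                 numeric(1))
    linked <- in_window & (is.na(r2) | r2 >= r2_max)
    linked[!in_window] <- FALSE
    if (any(linked)) {
      dropped <- rbind(dropped, data.frame(
        snp_id = pending$snp_id[linked],
        index_snp = index$snp_id,
        stringsAsFactors = FALSE
      ))
      pending <- pending[!linked, , drop = FALSE]
    }
  }
  rownames(kept) <- NULL
  attr(kept, "dropped") <- dropped
  kept
}

#' Find the best LD proxy for a SNP absent from the outcome GWAS
#'
#' Among `candidates` (SNPs present in the outcome table), returns the one
#' with the largest r-squared with `snp_id`, provided it reaches `r2_min`.
#' Ties are broken by smaller outcome p-value, then lexicographic SNP id.
#'
#' @param snp_id The missing SNP.
#' @param candidates GWAS table of outcome SNPs eligible as proxies.
#' @param ld An [ld_reference()].
#' @param r2_min Minimum r-squared, default 0.8.
#' @return A one-row data frame (the proxy row with an `r2_proxy` column), or
#'   `NULL` when no candidate qualifies.
#' @export
find_proxy <- function(snp_id, candidates, ld, r2_min = 0.8) {
  if (nrow(candidates) == 0) return(NULL)
  r2 <- vapply(candidates$snp_id, function(s) ld_r2(ld, snp_id, s), numeric(1))
  eligible <- !is.na(r2) & r2 >= r2_min & candidates$snp_id != snp_id
  if (!any(eligible)) return(NULL)
  cand <- candidates[eligible, , drop = FALSE]
  cand$r2_proxy <- r2[eligible]
  ord <- order(-cand$r2_proxy, cand$pvalue, cand$snp_id)
  out <- cand[ord[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

flip_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

#' Harmonize exposure and outcome summary statistics onto shared instruments
#'
#' Aligns the outcome effects to the exposure's effect allele. When the
#' outcome's effect/other alleles are swapped, the outcome beta is negated and
#' its EAF complemented; strand flips (both alleles complemented) are
#' recognised and resolved. Palindromic SNPs (A/T, C/G) cannot be resolved
#' from alleles alone: they are dropped when the exposure EAF is in
#' \[0.42, 0.58\] and otherwise aligned by allele frequency. Irreconcilable
#' allele pairs and SNPs absent from either table are dropped and reported.
#'
#' @param exposure_records,outcome_records GWAS tables (canonical columns).
#' @param palindrome_window Ambiguity band for palindromic SNP frequencies.
#' @return A `harmonized_set`: a data frame with columns `snp_id`,
#'   `effect_allele`, `beta_exposure`, `se_exposure`, `p_exposure`,
#'   `beta_outcome`, `se_outcome`, `p_outcome`, `eaf`, `n_exposure`,
#'   `n_outcome`, `f_stat`, `steiger_direction`, plus a `dropped` attribute
#'   naming excluded SNPs and reasons.
#' @export
harmonize <- function(exposure_records, outcome_records,
                      palindrome_window = c(0.42, 0.58)) {
  shared <- intersect(exposure_records$snp_id, outcome_records$snp_id)
  dropped <- data.frame(snp_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop_snp <- function(id, reason) {
    rbind(dropped, data.frame(snp_id = id, reason = reason,
                              stringsAsFactors = FALSE))
  }
  for (id in setdiff(exposure_records$snp_id, shared)) {
    dropped <- drop_snp(id, "absent from outcome")
  }
  exp <- exposure_records[match(shared, exposure_records$snp_id), , drop = FALSE]
  out <- outcome_records[match(shared, outcome_records$snp_id), , drop = FALSE]

  rows <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    e <- exp[i, ]
    o <- out[i, ]
    ea <- e$effect_allele; oa <- e$other_allele
    beta_o <- o$beta
    status <- "ok"
    if (o$effect_allele == ea && o$other_allele == oa) {
      # aligned as-is
    } else if (o$effect_allele == oa && o$other_allele == ea) {
      beta_o <- -beta_o
      o$eaf <- 1 - o$eaf
    } else if (o$effect_allele == flip_allele(ea) &&
               o$other_allele == flip_allele(oa)) {
      # opposite strand, same orientation
    } else if (o$effect_allele == flip_allele(oa) &&
               o$other_allele == flip_allele(ea)) {
      beta_o <- -beta_o
      o$eaf <- 1 - o$eaf
    } else {
      status <- "irreconcilable alleles"
    }
    if (status == "ok" && is_palindromic(ea, oa)) {
      if (e$eaf >= palindrome_window[1] && e$eaf <= palindrome_window[2]) {
        status <- "palindromic with ambiguous frequency"
      } else if ((e$eaf < 0.5) != (o$eaf < 0.5)) {
        # frequencies disagree on which allele is minor: assume strand flip
        beta_o <- -beta_o
        o$eaf <- 1 - o$eaf
      }
    }
    if (status != "ok") {
      dropped <- drop_snp(e$snp_id, status)
      next
    }
    rows[[i]] <- data.frame(
      snp_id = e$snp_id,
      effect_allele = ea,
      beta_exposure = e$beta,
      se_exposure = e$se,
      p_exposure = e$pvalue,
      beta_outcome = beta_o,
      se_outcome = o$se,
      p_outcome = o$pvalue,
      eaf = e$eaf,
      n_exposure = e$n,
      n_outcome = o$n,
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  set <- if (length(rows) > 0) do.call(rbind, rows) else data.frame(
    snp_id = character(), effect_allele = character(),
    beta_exposure = numeric(), se_exposure = numeric(), p_exposure = numeric(),
    beta_outcome = numeric(), se_outcome = numeric(), p_outcome = numeric(),
    eaf = numeric(), n_exposure = numeric(), n_outcome = numeric(),
    stringsAsFactors = FALSE
  )
  set$f_stat <- if (nrow(set) > 0) (set$beta_exposure / set$se_exposure)^2 else numeric(0)
  set$steiger_direction <- if (nrow(set) > 0) {
    steiger_r2(set$beta_exposure, set$se_exposure, set$n_exposure) >
      steiger_r2(set$beta_outcome, set$se_outcome, set$n_outcome)
  } else {
    logical(0)
  }
  rownames(set) <- NULL
  attr(set, "dropped") <- dropped
  class(set) <- c("harmonized_set", "data.frame")
  set
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized instrument set: %d SNPs (mean F = %.1f)\n",
              nrow(x), if (nrow(x) > 0) mean(x$f_stat) else NA_real_))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Approximate per-SNP instrument F-statistic
#'
#' The standard single-SNP approximation `F = (beta / se)^2`.
#'
#' @param beta,se Effect and standard error (se > 0).
#' @return F-statistic(s).
#' @export
compute_f <- function(beta, se) {
  if (any(se <= 0)) stop_field("se", "must be > 0")
  (beta / se)^2
}

#' Remove weak instruments from a harmonized set
#'
#' @param set A `harmonized_set`.
#' @param f_min Minimum F-statistic; the conventional weak-instrument cut-off
#'   is 10.
#' @return The filtered set (possibly empty; estimators reject empty sets).
#' @export
filter_weak <- function(set, f_min = 10) {
  keep <- set$f_stat >= f_min
  res <- set[keep, , drop = FALSE]
  attr(res, "dropped") <- data.frame(
    snp_id = set$snp_id[!keep],
    reason = rep("F-statistic below threshold", sum(!keep)),
    stringsAsFactors = FALSE
  )
  class(res) <- c("harmonized_set", "data.frame")
  res
}

# Variance explained by one SNP from its t-statistic and GWAS sample size:
# r2 = t^2 / (t^2 + n - 2).
steiger_r2 <- function(beta, se, n) {
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Steiger directionality filtering
#'
#' Removes variants that explain more variance in the outcome than in the
#' exposure, guarding against reverse causation. Variance explained is
#' approximated from the t-statistic, `r2 = t^2 / (t^2 + n - 2)`, for both
#' traits; a SNP is retained iff `r2_exposure > r2_outcome`.
#'
#' @param set A `harmonized_set` with sample sizes for both traits.
#' @return The filtered set, with a `dropped` attribute.
#' @export
steiger_filter <- function(set) {
  if (any(set$n_exposure <= 2) || any(set$n_outcome <= 2)) {
    stop_field("n", "sample sizes must exceed 2 for Steiger filtering")
  }
  r2_exp <- steiger_r2(set$beta_exposure, set$se_exposure, set$n_exposure)
  r2_out <- steiger_r2(set$beta_outcome, set$se_outcome, set$n_outcome)
  keep <- r2_exp > r2_out
  res <- set[keep, , drop = FALSE]
  attr(res, "dropped") <- data.frame(
    snp_id = set$snp_id[!keep],
    reason = rep("outcome variance explained exceeds exposure", sum(!keep)),
    stringsAsFactors = FALSE
  )
  class(res) <- c("harmonized_set", "data.frame")
  res
}
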