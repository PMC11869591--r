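# Metabolite-set over-representation analysis: for each pathway, the count
# of significant metabolites ("hits") is compared with the count expected
# under random draws from the background, with a one-sided hypergeometric
# upper-tail p-value.

#' Enrichment ratio of a metabolite set
#'
#' `ratio = hits / expect`, where `expect` is the hit count expected under
#' random sampling from the background. Tabular output displays the ratio
#' at two decimals.
#'
#' @param hits Observed significant metabolites in the set.
#' @param expect Expected count (> 0).
#' @return The ratio, full precision.
#' @export
enrichment_ratio <- function(hits, expect) {
  if (any(expect <= 0)) stop_field("expect", "must be > 0")
  hits / expect
}

#' Metabolite-set over-representation analysis
#'
#' For each pathway: `total` is the number of its members present in the
#' background, `hits` the number present in the hit list,
#' `expect = total * |hit list| / |background|`, `ratio = hits / expect`,
#' and the p-value is the hypergeometric upper tail
#' `P[X >= hits]` for X ~ Hypergeometric(N = |background|, K = total,
#' n = |hit list|). One-sided over-representation only; raw p-values are
#' compared to `alpha` without multiplicity adjustment.
#'
#' @param hit_list Character vector of significant metabolite identifiers
#'   (must be a subset of `background`).
#' @param background Character vector of all analysable metabolite
#'   identifiers. Defaults to the union of all pathway members.
#' @param pathways List of pathway sets from [read_gmt()] (each with `name`
#'   and `members`).
#' @param alpha Significance level for the `significant` flag (default 0.10).
#' @return A data frame of class `enrichment_result` with columns
#'   `set_name`, `total`, `expect`, `hits`, `ratio`, `pvalue`,
#'   `significant`, sorted by p-value. Pathways with no background overlap
#'   are omitted.
#' @export
enrich <- function(hit_list, pathways, background = NULL, alpha = 0.10) {
  if (length(pathways) == 0) stop_field("pathways", "must be non-empty")
  hit_list <- unique(as.character(hit_list))
  if (is.null(background)) {
    background <- unique(unlist(lapply(pathways, `[[`, "members")))
  }
  background <- unique(as.character(background))
  stray <- setdiff(hit_list, background)
  if (length(stray) > 0) {
    stop(sprintf("hits absent from the background: %s",
                 paste(utils::head(stray, 5), collapse = ", ")), call. = FALSE)
  }
  N <- length(background)
  n_hit <- length(hit_list)
  rows <- lapply(pathways, function(pw) {
    members <- intersect(pw$members, background)
    total <- length(members)
    if (total == 0) return(NULL)
    hits <- length(intersect(members, hit_list))
    expect <- total * n_hit / N
    # P[X >= hits]; 1 when hits = 0
    pvalue <- stats::phyper(hits - 1, total, N - total, n_hit,
                            lower.tail = FALSE)
    data.frame(set_name = pw$name, total = total, expect = expect,
               hits = hits,
               ratio = if (expect > 0) hits / expect else NA_real_,
               pvalue = pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    stop("no pathway overlaps the background", call. = FALSE)
  }
  out <- out[order(out$pvalue, out$set_name), , drop = FALSE]
  out$significant <- out$pvalue < alpha
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "n_background") <- N
  attr(out, "n_hits") <- n_hit
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Over-representation analysis: %d hits in a background of %d\n",
              attr(x, "n_hits"), attr(x, "n_background")))
  df <- as.data.frame(x)
  df$expect <- round(df$expect, 3)
  df$ratio <- round(df$ratio, 2)
  df$pvalue <- signif(df$pvalue, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
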