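# Reading and writing the flat-file formats the pipeline touches:
# tab-delimited GWAS summary tables, GMT pathway sets, and the 3-column
# LD (r^2) table. Validation is strict: malformed rows fail with the
# offending line number rather than being silently clamped.

GWAS_COLUMNS <- c(
  "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pvalue", "n"
)

validate_gwas_rows <- function(df, source = "gwas table") {
  bad <- function(rows, what) {
    if (any(rows)) {
      stop(sprintf(
        "%s: row %d: %s", source, which(rows)[1], what
      ), call. = FALSE)
    }
  }
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  ok_allele <- c("A", "C", "G", "T")
  bad(!(df$effect_allele %in% ok_allele), "effect_allele must be one of A/C/G/T")
  bad(!(df$other_allele %in% ok_allele), "other_allele must be one of A/C/G/T")
  bad(df$effect_allele == df$other_allele, "effect and other allele identical")
  bad(!is.finite(df$eaf) | df$eaf <= 0 | df$eaf >= 1, "eaf must be in (0, 1)")
  bad(!is.finite(df$se) | df$se <= 0, "se must be > 0")
  bad(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1,
      "pvalue must be in (0, 1]")
  bad(!is.finite(df$beta), "beta must be finite")
  bad(!is.finite(df$pos) | df$pos < 1, "pos must be a positive 1-based position")
  bad(!is.finite(df$n) | df$n <= 0, "n must be > 0")
  df
}

#' Read a tab-delimited GWAS summary-statistics table
#'
#' Reads one row per SNP and maps the file's column names onto the canonical
#' schema (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pvalue`, `n`). Alleles are upper-cased; indels and any row
#' violating the record invariants (se > 0, 0 < eaf < 1, p in (0,1]) are
#' rejected with the row number. P-values of exactly 0 are rejected, not
#' clamped, so upstream export artifacts fail loudly.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(snp_id = "SNP", beta = "b", ...)`. Omit (or
#'   pass `NULL`) when the file already uses the canonical names.
#' @return A `data.frame` with the canonical columns, row order preserved.
#' @export
read_gwas_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(column_map)) {
    column_map <- stats::setNames(GWAS_COLUMNS, GWAS_COLUMNS)
  }
  missing_map <- setdiff(GWAS_COLUMNS, names(column_map))
  if (length(missing_map) > 0) {
    stop(sprintf("column_map lacks required columns: %s",
                 paste(missing_map, collapse = ", ")), call. = FALSE)
  }
  missing_col <- setdiff(unname(column_map[GWAS_COLUMNS]), names(raw))
  if (length(missing_col) > 0) {
    stop(sprintf("%s: missing columns: %s", path,
                 paste(missing_col, collapse = ", ")), call. = FALSE)
  }
  df <- raw[, unname(column_map[GWAS_COLUMNS]), drop = FALSE]
  names(df) <- GWAS_COLUMNS
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  validate_gwas_rows(df, source = path)
}

#' Write a GWAS summary-statistics table
#'
#' Inverse of [read_gwas_table()]: writes the canonical tab-delimited layout
#' so that write-then-read is the identity on valid tables.
#'
#' @param df Data frame with the canonical GWAS columns.
#' @param path Output path.
#' @export
write_gwas_table <- function(df, path) {
  df <- validate_gwas_rows(df[, GWAS_COLUMNS, drop = FALSE], source = "write_gwas_table")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pathway definitions in GMT format
#'
#' Broad-dialect GMT: one tab-delimited line per set — name, description,
#' then member identifiers. Duplicate members on a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A list of pathway sets, each a list with `name`, `description`,
#'   `members` (unique character vector) and `total` (= length of members).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("%s: line %d: GMT line needs name, description and >= 1 member",
                   path, i), call. = FALSE)
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop(sprintf("%s: line %d: pathway has no members", path, i), call. = FALSE)
    }
    out[[i]] <- list(
      name = fields[1],
      description = fields[2],
      members = members,
      total = length(members)
    )
  }
  out
}

#' Read a pairwise LD table into an LD reference
#'
#' @param path Tab-delimited file with header `snp_a`, `snp_b`, `r2`.
#' @param positions Optional data frame with `snp_id`, `chrom`, `pos` used for
#'   windowing during clumping.
#' @return An [ld_reference()] object.
#' @export
read_ld_table <- function(path, positions = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("snp_a", "snp_b", "r2")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: LD table needs columns snp_a, snp_b, r2", path),
         call. = FALSE)
  }
  ld_reference(df$snp_a, df$snp_b, as.numeric(df$r2), positions = positions)
}

#' Write an LD reference as a 3-column table
#'
#' @param ld An [ld_reference()] object.
#' @param path Output path.
#' @export
write_ld_table <- function(ld, path) {
  utils::write.table(ld$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
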