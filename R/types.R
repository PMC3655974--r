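#' @keywords internal
"_PACKAGE"

## Classed conditions so the CLI can map failures to exit codes
## (2 = format error, 3 = config error).
stop_format <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("interactome_format_error", "error", "condition")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("interactome_config_error", "error", "condition")))
}

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix (any case) and upper-cases non-numeric
#' labels, so that `"chr6"` and `"6"` (or `"chrx"` and `"X"`) compare equal.
#' Mixed dialects between GWAS files, BED annotations and masks are the norm;
#' a single internal label avoids silent non-overlap.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @examples
#' normalize_chrom(c("chr6", "6", "chrX", "mt"))
#' @export
normalize_chrom <- function(x) {
  s <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  ifelse(grepl("^[0-9]+$", s), s, toupper(s))
}

#' Construct a gene set (interactome)
#'
#' A named set of human gene symbols with a source tag. Symbols are trimmed,
#' upper-cased and de-duplicated; an empty set is an error (a gene set with no
#' members cannot be tested for enrichment).
#'
#' @param name set name (e.g. `"EBV"`).
#' @param genes character vector of gene symbols.
#' @param source free-text provenance tag; conventionally one of
#'   `"literature"`, `"curated"`, `"database"`.
#' @return an object of class `gene_set`: a list with elements `name`,
#'   `source`, `genes`.
#' @export
gene_set <- function(name, genes, source = "curated") {
  genes <- toupper(trimws(as.character(genes)))
  genes <- genes[nzchar(genes)]
  dup <- duplicated(genes)
  if (any(dup)) {
    warning(sprintf("gene set '%s': %d duplicate symbol(s) removed", name, sum(dup)))
    genes <- genes[!dup]
  }
  if (length(genes) < 1L)
    stop_format(sprintf("gene set '%s' has no members", name))
  structure(list(name = as.character(name), source = as.character(source),
                 genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s], %d genes\n", x$name, x$source, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

## Validate a SNP table (rsid, chrom, pos, pvalue). Returns the valid rows;
## invalid rows are dropped with one warning carrying the count (strict = TRUE
## upgrades to an error). Mirrors upstream GWAS QC: records failing basic
## checks are filtered out rather than aborting the run.
validate_snp_table <- function(df, strict = FALSE) {
  df$rsid <- as.character(df$rsid)
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- suppressWarnings(as.numeric(df$pos))
  df$pvalue <- suppressWarnings(as.numeric(df$pvalue))
  bad <- is.na(df$rsid) | !nzchar(df$rsid) |
    is.na(df$pos) | df$pos < 1 | df$pos != floor(df$pos) |
    is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1
  bad <- bad | duplicated(df$rsid)
  if (any(bad)) {
    msg <- sprintf("%d SNP record(s) failed validation (position, p-value range or duplicate rsid) and were removed", sum(bad))
    if (strict) stop_format(msg) else warning(msg)
    df <- df[!bad, , drop = FALSE]
  }
  df$pos <- as.integer(df$pos)
  rownames(df) <- NULL
  df[, c("rsid", "chrom", "pos", "pvalue")]
}
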