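#' Read GWAS summary statistics
#'
#' Reads a tab-delimited table of per-SNP association results (PLINK
#' `.assoc`-like) into the internal SNP table: one row per tested variant with
#' `rsid`, normalized `chrom`, 1-based `pos` and `pvalue` in (0, 1]. Rows
#' failing validation (non-positive or >1 p-values, non-integer or <1
#' positions, duplicate rsids) are dropped with a warning carrying the count,
#' emulating the quality filtering applied upstream of association studies;
#' `strict = TRUE` turns the warning into an error.
#'
#' @param path path to a delimited text file with a header.
#' @param cols named character vector mapping the internal names
#'   `rsid`, `chrom`, `pos`, `pvalue` to the column names used in the file.
#'   Common PLINK aliases (`SNP`, `CHR`, `BP`, `P`) are tried automatically.
#' @param sep field separator (default tab).
#' @param strict reject files with any invalid row instead of warning.
#' @return a `data.frame` with columns `rsid`, `chrom`, `pos`, `pvalue`.
#' @export
read_gwas_summary <- function(path,
                              cols = c(rsid = "rsid", chrom = "chrom",
                                       pos = "pos", pvalue = "p"),
                              sep = "\t", strict = FALSE) {
  if (!file.exists(path)) stop_format("GWAS file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  aliases <- list(rsid = c("rsid", "SNP", "snp", "ID"),
                  chrom = c("chrom", "CHR", "chr", "chromosome"),
                  pos = c("pos", "BP", "bp", "position"),
                  pvalue = c("p", "P", "pvalue", "pval", "P_VALUE"))
  pick <- function(field) {
    cands <- unique(c(cols[[field]], aliases[[field]]))
    hit <- cands[cands %in% names(raw)]
    if (length(hit) == 0L)
      stop_format(sprintf("GWAS file %s: no column for '%s' (looked for: %s)",
                          path, field, paste(cands, collapse = ", ")))
    hit[[1L]]
  }
  df <- data.frame(rsid = raw[[pick("rsid")]], chrom = raw[[pick("chrom")]],
                   pos = raw[[pick("pos")]], pvalue = raw[[pick("pvalue")]],
                   stringsAsFactors = FALSE)
  validate_snp_table(df, strict = strict)
}

#' Read gene annotation from a BED file
#'
#' BED input is half-open and 0-based; records are converted on read to the
#' package-wide 1-based inclusive convention (`start = start_bed + 1`,
#' `end = end_bed`), so a BED line `1 999 2000 G1` becomes the interval
#' \[1000, 2000\] of length 1001. Gene symbols are upper-cased and must be
#' unique within an annotation.
#'
#' @param path BED file (chrom, start, end, name; no header).
#' @return a `data.frame` with columns `symbol`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop_format("gene annotation not found: ", path)
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
    warning("gene annotation ", path, " is empty")
    return(data.frame(symbol = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 4L)
    stop_format("gene annotation ", path, " must have >= 4 BED columns (chrom, start, end, name)")
  df <- data.frame(symbol = toupper(trimws(as.character(raw[[4L]]))),
                   chrom = normalize_chrom(raw[[1L]]),
                   start = as.integer(raw[[2L]]) + 1L,
                   end = as.integer(raw[[3L]]),
                   stringsAsFactors = FALSE)
  bad <- is.na(df$start) | is.na(df$end) | df$start > df$end
  if (any(bad))
    stop_format(sprintf("gene annotation %s: %d record(s) with start > end after BED conversion (first: %s)",
                        path, sum(bad), df$symbol[which(bad)[1L]]))
  dup <- unique(df$symbol[duplicated(df$symbol)])
  if (length(dup) > 0L)
    stop_format("duplicate gene symbol(s) in annotation: ",
                paste(utils::head(dup, 5L), collapse = ", "))
  df
}

## 1-based inclusive genes -> BED (0-based half-open)
write_gene_annotation <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$symbol)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, source/description, then member gene symbols.
#' Duplicate members within a set are removed with a warning; a set with no
#' members is a format error.
#'
#' @param path GMT file.
#' @return a list of [gene_set] objects.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_format("gene set file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_format("gene set file ", path, " is empty")
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop_format("GMT line with no members: ", substr(ln, 1L, 40L))
    gene_set(name = f[[1L]], source = f[[2L]], genes = f[-(1:2)])
  })
}

#' Write gene sets to a GMT file
#'
#' @param sets a [gene_set] or list of them.
#' @param path output path.
#' @param append append to an existing file (used by the curation CLI).
#' @export
write_gene_sets <- function(sets, path, append = FALSE) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$source, s$genes), collapse = "\t"), character(1L))
  if (append && file.exists(path)) {
    cat(lines, file = path, sep = "\n", append = TRUE)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a pairwise LD table
#'
#' PLINK `.ld`-style whitespace- or tab-delimited table with columns `SNP_A`,
#' `SNP_B`, `R2` (extra columns such as `CHR_A`/`BP_A` are ignored). The
#' resulting lookup is symmetric; any pair absent from the table has r^2 = 0
#' by contract and the diagonal is 1. Rows with r^2 outside \[0, 1\] are
#' dropped with a warning.
#'
#' @param path LD table file with header.
#' @return an object of class `ld_table`.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop_format("LD table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("SNP_A", "SNP_B", "R2")
  if (!all(need %in% names(raw)))
    stop_format("LD table ", path, " must have columns SNP_A, SNP_B, R2")
  df <- data.frame(SNP_A = as.character(raw$SNP_A),
                   SNP_B = as.character(raw$SNP_B),
                   R2 = as.numeric(raw$R2), stringsAsFactors = FALSE)
  bad <- is.na(df$R2) | df$R2 < 0 | df$R2 > 1
  if (any(bad)) {
    warning(sprintf("%d LD record(s) with r2 outside [0, 1] removed", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  ld_table(df)
}

#' Construct an LD lookup from a pair table
#'
#' @param pairs data.frame with columns `SNP_A`, `SNP_B`, `R2`. May be empty
#'   (no LD: every pair independent).
#' @return an object of class `ld_table`.
#' @export
ld_table <- function(pairs = data.frame(SNP_A = character(),
                                        SNP_B = character(),
                                        R2 = numeric())) {
  ## rsids are coded as integers and each pair as one sorted numeric key, so
  ## lookups are a binary search (findInterval) with no per-key allocation
  if (nrow(pairs) > 0L) {
    ids <- sort(unique(c(pairs$SNP_A, pairs$SNP_B)))
    a <- match(pairs$SNP_A, ids)
    b <- match(pairs$SNP_B, ids)
    key <- pmin(a, b) * 2^26 + pmax(a, b)
    ## duplicated (possibly symmetric) entries: keep the last occurrence
    last <- rev(!duplicated(rev(key)))
    key <- key[last]
    r2 <- pairs$R2[last]
    ord <- order(key)
    obj <- list(ids = ids, keys = key[ord], r2 = r2[ord],
                n_pairs = length(key))
  } else {
    obj <- list(ids = character(), keys = numeric(), r2 = numeric(),
                n_pairs = 0L)
  }
  structure(obj, class = "ld_table")
}

#' Query pairwise r-squared
#'
#' Vectorized over `b`. `ld_r2(ld, a, a)` is 1; unlisted pairs are 0.
#'
#' @param ld an `ld_table`.
#' @param a single rsid.
#' @param b character vector of rsids.
#' @return numeric vector of r^2 values.
#' @export
ld_r2 <- function(ld, a, b) {
  if (!inherits(ld, "ld_table") || length(a) != 1L)
    stop("ld_r2 expects an ld_table and a single rsid 'a'")
  out <- numeric(length(b))
  diag <- b == a
  out[diag] <- 1
  todo <- which(!diag)
  if (length(todo) > 0L && ld$n_pairs > 0L) {
    ia <- match(a, ld$ids)
    if (!is.na(ia)) {
      ib <- match(b[todo], ld$ids)
      known <- !is.na(ib)
      if (any(known)) {
        key <- pmin(ia, ib[known]) * 2^26 + pmax(ia, ib[known])
        pos <- findInterval(key, ld$keys)
        hit <- pos > 0L & ld$keys[pmax(pos, 1L)] == key
        vals <- numeric(sum(known))
        vals[hit] <- ld$r2[pos[hit]]
        out[todo[known]] <- vals
      }
    }
  }
  out
}

#' @export
print.ld_table <- function(x, ...) {
  cat(sprintf("<ld_table> %d stored pair(s); absent pairs have r2 = 0\n", x$n_pairs))
  invisible(x)
}

#' Read a genomic region mask from a BED file
#'
#' Used for MHC-style exclusion runs: the analysis is repeated with SNPs inside
#' the masked intervals removed. BED coordinates are converted to the internal
#' 1-based inclusive convention.
#'
#' @param path BED file (chrom, start, end, optional label).
#' @param label mask label; default taken from the file's 4th column or the
#'   file name.
#' @return a `data.frame` with columns `chrom`, `start`, `end` and a `label`
#'   attribute.
#' @export
read_region_mask <- function(path, label = NULL) {
  if (!file.exists(path)) stop_format("region mask not found: ", path)
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  df <- data.frame(chrom = normalize_chrom(raw[[1L]]),
                   start = as.integer(raw[[2L]]) + 1L,
                   end = as.integer(raw[[3L]]), stringsAsFactors = FALSE)
  if (any(df$start > df$end))
    stop_format("region mask ", path, ": interval with start > end")
  if (is.null(label))
    label <- if (ncol(raw) >= 4L) as.character(raw[[4L]][1L]) else basename(path)
  attr(df, "label") <- label
  df
}

write_region_mask <- function(mask, path) {
  bed <- data.frame(mask$chrom, mask$start - 1L, mask$end,
                    rep(attr(mask, "label") %||% "mask", nrow(mask)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an interaction-evidence table
#'
#' Tab-delimited with header columns `env_protein`, `human_gene`, `source_id`,
#' `method`, `interaction_class` — one row per reported physical interaction
#' between an environmental-factor protein and a human gene product, tagged
#' with the publication/dataset it came from, the experimental method, and
#' whether the interaction is direct.
#'
#' @param path evidence TSV.
#' @return a validated `data.frame` with the five columns above.
#' @export
read_evidence_table <- function(path) {
  if (!file.exists(path)) stop_format("evidence table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("env_protein", "human_gene", "source_id", "method", "interaction_class")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L)
    stop_format("evidence table ", path, " missing column(s): ",
                paste(miss, collapse = ", "))
  df <- raw[, need]
  bad <- !nzchar(trimws(df$human_gene)) | !nzchar(trimws(df$source_id))
  if (any(bad)) {
    warning(sprintf("%d evidence record(s) with empty human_gene or source_id removed", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  cls <- tolower(trimws(df$interaction_class))
  cls[!cls %in% c("direct", "indirect")] <- "unknown"
  df$interaction_class <- cls
  rownames(df) <- NULL
  df
}

#' Write the per-interactome results table
#'
#' Writes the main report in the familiar five-column layout — Interactome,
#' Size, Source, and the empirical enrichment p-values of the runs with and
#' without the region mask — with p-values printed to four decimals, plus a
#' JSON sidecar (`<path>.json`) carrying the seeds, parameters, and observed /
#' mappable gene counts needed to reproduce the run.
#'
#' @param results data.frame as returned in `run_enrichment()$results`.
#' @param path output TSV path; the sidecar goes to `paste0(path, ".json")`.
#' @param parameters named list echoed into the sidecar (config, seeds).
#' @return invisibly, the TSV path.
#' @export
write_results_table <- function(results, path, parameters = list()) {
  out <- data.frame(Interactome = results$name,
                    Size = results$size,
                    Source = results$source,
                    `p-value with mask` = sprintf("%.4f", results$p_masked),
                    `p-value without mask` = sprintf("%.4f", results$p_unmasked),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(parameters = parameters,
                  counts = results[, intersect(c("name", "size", "n_mappable_unmasked",
                                                 "n_mappable_masked",
                                                 "n_sig_unmasked", "n_sig_masked",
                                                 "p_masked", "p_unmasked"),
                                               names(results))])
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read the JSON sidecar written next to a results table
#'
#' @param path the results TSV path (the sidecar is `<path>.json`) or the
#'   sidecar path itself.
#' @return the parsed list.
#' @export
read_results_sidecar <- function(path) {
  p <- if (grepl("\\.json$", path)) path else paste0(path, ".json")
  jsonlite::read_json(p, simplifyVector = TRUE)
}
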