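#' Remove SNPs inside masked regions
#'
#' Drops every SNP whose position falls inside any mask interval (bounds
#' inclusive on both sides). Used to repeat an analysis without the extended
#' MHC region, whose long-range haplotypes otherwise dominate the gene counts;
#' genes are kept — a gene whose only signal lay in the mask simply loses it.
#'
#' @param snps SNP table (`rsid`, `chrom`, `pos`, `pvalue`).
#' @param mask mask data.frame from [read_region_mask()], or `NULL`/empty for
#'   a no-op.
#' @return the SNP table restricted to unmasked SNPs.
#' @export
apply_region_mask <- function(snps, mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(snps)
  gr_snps <- GenomicRanges::GRanges(snps$chrom,
                                    IRanges::IRanges(snps$pos, snps$pos))
  gr_mask <- GenomicRanges::GRanges(mask$chrom,
                                    IRanges::IRanges(mask$start, mask$end))
  hit <- suppressWarnings(IRanges::overlapsAny(gr_snps, gr_mask))
  out <- snps[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign SNPs to genes within a window
#'
#' A SNP is assigned to every gene on the same chromosome whose interval,
#' extended by `window_bp` on each side, contains it (bounds inclusive, so a
#' SNP exactly 20 kb from a gene end is assigned under the default). A SNP may
#' be assigned to several genes; genes with no assigned SNP are recorded as
#' unmappable and never enter the analysis universe.
#'
#' @param snps SNP table.
#' @param genes gene annotation from [read_gene_annotation()].
#' @param window_bp flanking window in bp (default 20000).
#' @return an object of class `gene_snp_index`: list with `assignments` (one
#'   row per SNP-gene pair: `symbol`, `rsid`, `chrom`, `pos`, `pvalue`),
#'   `snp_counts` (named integer vector per mappable gene, used as sampling
#'   weights), `unmappable`, `genes`, `window_bp`, and (after
#'   [select_index_snps()]) `index_snps`.
#' @export
map_snps_to_genes <- function(snps, genes, window_bp = 20000) {
  stopifnot(window_bp >= 0)
  if (nrow(genes) == 0L || nrow(snps) == 0L) {
    assignments <- data.frame(symbol = character(), rsid = character(),
                              chrom = character(), pos = integer(),
                              pvalue = numeric(), stringsAsFactors = FALSE)
  } else {
    gr_genes <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(pmax(1L, genes$start - as.integer(window_bp)),
                       genes$end + as.integer(window_bp)))
    gr_snps <- GenomicRanges::GRanges(snps$chrom,
                                      IRanges::IRanges(snps$pos, snps$pos))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_snps, gr_genes))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    pv <- if (is.null(snps$pvalue)) rep(NA_real_, nrow(snps)) else snps$pvalue
    assignments <- data.frame(symbol = genes$symbol[si],
                              rsid = snps$rsid[qi],
                              chrom = snps$chrom[qi],
                              pos = snps$pos[qi],
                              pvalue = pv[qi],
                              stringsAsFactors = FALSE)
  }
  counts <- table(assignments$symbol)
  snp_counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(assignments = assignments,
                 snp_counts = snp_counts,
                 unmappable = setdiff(genes$symbol, names(snp_counts)),
                 genes = genes,
                 window_bp = window_bp,
                 index_snps = NULL),
            class = "gene_snp_index")
}

#' @export
print.gene_snp_index <- function(x, ...) {
  cat(sprintf("<gene_snp_index> %d mappable gene(s), %d unmappable, %d SNP-gene assignment(s), window %d bp\n",
              length(x$snp_counts), length(x$unmappable),
              nrow(x$assignments), as.integer(x$window_bp)))
  invisible(x)
}

#' Select each gene's index SNP
#'
#' The index SNP — the single most representative signal of a gene — is the
#' assigned SNP with the smallest p-value; ties are broken by smaller
#' position, then lexicographically smaller rsid, so selection is
#' deterministic. Unmappable genes stay unmappable.
#'
#' @param index a `gene_snp_index` from [map_snps_to_genes()].
#' @return the index with `index_snps` filled in (one row per mappable gene:
#'   `symbol`, `rsid`, `chrom`, `pos`, `pvalue`).
#' @export
select_index_snps <- function(index) {
  stopifnot(inherits(index, "gene_snp_index"))
  a <- index$assignments
  if (nrow(a) == 0L) {
    index$index_snps <- a
    return(index)
  }
  ord <- order(a$symbol, a$pvalue, a$pos, a$rsid, method = "radix")
  a <- a[ord, , drop = FALSE]
  first <- !duplicated(a$symbol)
  idx <- a[first, , drop = FALSE]
  rownames(idx) <- NULL
  index$index_snps <- idx
  index
}

#' Flag significant genes at a p-value cutoff
#'
#' A gene is significant when its index SNP's p-value is *strictly* below the
#' cutoff ("stronger than" the cutoff; an index p equal to the cutoff is
#' excluded). The result is ordered by increasing index p (ties: position,
#' then rsid), which is also the priority order used by [ld_prune()].
#'
#' @param index a `gene_snp_index` with index SNPs selected.
#' @param pcut SNP-level p-value cutoff in (0, 1) (P-CUT; default analyses use
#'   0.05, with 0.005 and 0.03 as sensitivity cutoffs).
#' @param masked logical flag recorded on the result (was a region mask
#'   applied upstream).
#' @return a `significant_genes` data.frame (`symbol`, `rsid`, `chrom`, `pos`,
#'   `pvalue`) with attributes `pcut` and `masked`.
#' @export
flag_significant_genes <- function(index, pcut, masked = FALSE) {
  stopifnot(inherits(index, "gene_snp_index"), pcut > 0, pcut < 1)
  if (is.null(index$index_snps))
    index <- select_index_snps(index)
  idx <- index$index_snps
  sig <- idx[idx$pvalue < pcut, , drop = FALSE]
  ord <- order(sig$pvalue, sig$pos, sig$rsid, method = "radix")
  sig <- sig[ord, , drop = FALSE]
  rownames(sig) <- NULL
  structure(sig, pcut = pcut, masked = masked,
            class = c("significant_genes", "data.frame"))
}

#' LD-prune a significant-gene list
#'
#' Greedy clumping in ascending index-p order: the strongest gene is always
#' retained, and each further gene is retained only if its index SNP is
#' independent of the index SNP of *every* already-retained gene. Two index
#' SNPs are independent when they lie on different chromosomes, or are farther
#' apart than `dist_bp` (strict: exactly 1000 kb is still dependent-range), or
#' have r^2 <= `r2_max` (r^2 of exactly 0.2 counts as independent). Dropped
#' genes are recorded with the retained gene that absorbed them.
#'
#' @param sig a `significant_genes` list from [flag_significant_genes()].
#' @param ld an `ld_table`.
#' @param snps optional SNP table used to resolve index-SNP coordinates when
#'   `sig` lacks `chrom`/`pos` columns; an unresolvable rsid is an error.
#' @param r2_max LD threshold (default 0.2).
#' @param dist_bp distance beyond which SNPs are unconditionally independent
#'   (default 1e6, i.e. 1000 kb).
#' @return the pruned `significant_genes` list; dropped genes are in the
#'   `"dropped"` attribute (`symbol`, `absorbed_by`).
#' @export
ld_prune <- function(sig, ld, snps = NULL, r2_max = 0.2, dist_bp = 1e6) {
  stopifnot(inherits(sig, "significant_genes"), inherits(ld, "ld_table"))
  if ((is.null(sig$chrom) || is.null(sig$pos))) {
    if (is.null(snps)) stop_format("ld_prune: no coordinates in list and no SNP table given")
    m <- match(sig$rsid, snps$rsid)
    if (anyNA(m))
      stop_format("ld_prune: unknown rsid(s): ",
                  paste(utils::head(sig$rsid[is.na(m)], 5L), collapse = ", "))
    sig$chrom <- snps$chrom[m]
    sig$pos <- snps$pos[m]
  }
  n <- nrow(sig)
  keep <- logical(n)
  absorbed_by <- character(0L)
  dropped <- character(0L)
  for (i in seq_len(n)) {
    r <- which(keep)
    if (length(r) == 0L) { keep[i] <- TRUE; next }
    near <- r[sig$chrom[r] == sig$chrom[i] &
                abs(sig$pos[r] - sig$pos[i]) <= dist_bp]
    if (length(near) == 0L) { keep[i] <- TRUE; next }
    r2 <- ld_r2(ld, sig$rsid[i], sig$rsid[near])
    dep <- r2 > r2_max
    if (any(dep)) {
      dropped <- c(dropped, sig$symbol[i])
      absorbed_by <- c(absorbed_by, sig$symbol[near[which(dep)[1L]]])
    } else keep[i] <- TRUE
  }
  out <- sig[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pcut") <- attr(sig, "pcut")
  attr(out, "masked") <- attr(sig, "masked")
  attr(out, "dropped") <- data.frame(symbol = dropped,
                                     absorbed_by = absorbed_by,
                                     stringsAsFactors = FALSE)
  class(out) <- c("significant_genes", "data.frame")
  out
}

#' Run the full SNP-to-significant-genes stage
#'
#' Convenience wrapper chaining [apply_region_mask()], [map_snps_to_genes()],
#' [select_index_snps()], [flag_significant_genes()] and [ld_prune()]. Returns
#' everything the enrichment stage needs: the pruned significant-gene list,
#' the mappable-gene universe, and per-gene SNP counts (sampling weights).
#'
#' @inheritParams map_snps_to_genes
#' @inheritParams ld_prune
#' @param mask optional region mask (`NULL` for the unmasked run).
#' @param pcut index-SNP p-value cutoff.
#' @return list with `sig` (pruned `significant_genes`), `index`
#'   (`gene_snp_index`), `universe` (character vector of mappable genes) and
#'   `weights` (SNP counts aligned with `universe`).
#' @export
significant_genes <- function(snps, genes, ld, mask = NULL, pcut = 0.05,
                              window_bp = 20000, r2_max = 0.2, dist_bp = 1e6) {
  snps2 <- apply_region_mask(snps, mask)
  index <- select_index_snps(map_snps_to_genes(snps2, genes, window_bp))
  sig <- flag_significant_genes(index, pcut, masked = !is.null(mask) && nrow(mask) > 0L)
  pruned <- ld_prune(sig, ld, snps = snps2, r2_max = r2_max, dist_bp = dist_bp)
  universe <- names(index$snp_counts)
  list(sig = pruned, index = index, universe = universe,
       weights = as.numeric(index$snp_counts))
}
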