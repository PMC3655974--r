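#' Curate an interactome from an interaction-evidence table
#'
#' Applies the manual-curation rule used to build the hand-curated viral
#' interactomes: a human gene enters the interactome only if, among its
#' *physical-direct* interaction records with the environmental factor, the
#' interaction is either (a) reported by at least two independent sources
#' (distinct `source_id`), or (b) confirmed by a single source with at least
#' two distinct experimental approaches (distinct `method` terms). Records
#' whose `interaction_class` is `indirect` or `unknown` never contribute.
#'
#' Sources are compared as trimmed strings; methods case-insensitively after
#' trimming. Gene symbols are matched case-insensitively and emitted
#' upper-case. The result is invariant to record order and to duplicated
#' records, and removing evidence can only shrink it.
#'
#' @param evidence data.frame as returned by [read_evidence_table()].
#' @param name name for the resulting interactome.
#' @return a [gene_set] with `source = "curated"`; the per-gene rule that
#'   admitted it is attached as the `"provenance"` attribute (a data.frame
#'   with columns `gene`, `n_sources`, `max_methods_one_source`, `rule`).
#' @export
curate_interactome <- function(evidence, name) {
  if (is.null(evidence) || nrow(evidence) == 0L)
    stop_format("curation: evidence table is empty")
  ev <- evidence
  ev$human_gene <- toupper(trimws(as.character(ev$human_gene)))
  ev$source_id <- trimws(as.character(ev$source_id))
  ev$method <- tolower(trimws(as.character(ev$method)))
  ev$interaction_class <- tolower(trimws(as.character(ev$interaction_class)))
  direct <- ev[ev$interaction_class == "direct", , drop = FALSE]
  prov <- if (nrow(direct) > 0L) {
    do.call(rbind, lapply(split(direct, direct$human_gene), function(d) {
      n_src <- length(unique(d$source_id))
      max_meth <- max(vapply(split(d$method, d$source_id),
                             function(m) length(unique(m)), integer(1L)))
      rule <- if (n_src >= 2L) "two_sources"
              else if (max_meth >= 2L) "two_methods_one_source"
              else NA_character_
      data.frame(gene = d$human_gene[1L], n_sources = n_src,
                 max_methods_one_source = max_meth, rule = rule,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene = character(), n_sources = integer(),
               max_methods_one_source = integer(), rule = character())
  }
  kept <- prov[!is.na(prov$rule), , drop = FALSE]
  if (nrow(kept) == 0L)
    stop_format(sprintf("curation of '%s': no gene satisfies the evidence rule (two independent sources, or one source with two distinct methods, on direct interactions)", name))
  kept <- kept[order(kept$gene), , drop = FALSE]
  rownames(kept) <- NULL
  gs <- gene_set(name, kept$gene, source = "curated")
  attr(gs, "provenance") <- kept
  gs
}
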