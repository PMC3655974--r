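#' One synthetic-data validation run of the enrichment test
#'
#' Generates one synthetic dataset under the default simulation conditions,
#' runs the full observed-data scoring stage, and computes the empirical
#' enrichment p-value of one 30-gene set against size-matched random sets.
#' This is the unit of the package's calibration, power and size-bias
#' experiments (see the methods vignette):
#'
#' * `observed = "weighted"` — the observed set is drawn by the same
#'   SNP-count-weighted sampler as the replicates, so observed and replicate
#'   counts are exchangeable and the p-value is calibrated by construction;
#' * `observed = "uniform"` — the observed set is drawn uniformly;
#' * `observed = "densest_decile"` — the observed set is the `set_size` genes
#'   with the most assigned SNPs (the gene-size-bias stress case);
#' * `spike = TRUE` — the observed set is drawn uniformly and then spiked with
#'   true signal per the generator's `spike_fraction`/`alt_shape`.
#'
#' @param seed integer seed for this run (generator and bootstrap).
#' @param B random replicate sets per p-value.
#' @param observed how the observed set is chosen (see above).
#' @param spike add true signal to the observed set before scoring.
#' @param nulls which replicate samplers to evaluate: `"weighted"`
#'   (SNP-count weights), `"uniform"`, or both.
#' @param set_size observed/replicate set size (default 30).
#' @param cfg a [sim_config]; its `seed` is overridden by `seed`.
#' @return list with `p` (named by sampler), `observed` (significant-gene
#'   count), `set` (gene symbols) and `n_sig` (pruned-list size).
#' @export
enrichment_validation_run <- function(seed, B = 500,
                                      observed = c("weighted", "uniform",
                                                   "densest_decile"),
                                      spike = FALSE,
                                      nulls = "weighted",
                                      set_size = 30,
                                      cfg = sim_config()) {
  observed <- match.arg(observed)
  stopifnot(all(nulls %in% c("weighted", "uniform")))
  cfg$seed <- as.integer(seed)
  cfg$n_decoy_sets <- 0L
  cfg$spiked_set_size <- set_size
  set.seed(cfg$seed)
  genome <- generate_genome(cfg)
  nullp <- generate_null_pvalues(genome$snps, cfg)
  gwas <- nullp$gwas
  set <- if (spike || observed == "uniform")
    sample(genome$genes$symbol, set_size)
  else NULL
  if (spike)
    gwas <- spike_signal(gwas, genome$genes, set, cfg)
  sg <- significant_genes(gwas, genome$genes, ld_table(nullp$ld),
                          pcut = 0.05)
  if (is.null(set)) {
    set <- if (observed == "weighted")
      sample_random_gene_set(set_size, sg$universe, sg$weights)$genes
    else  ## densest decile: top set_size genes by assigned-SNP count
      sg$universe[order(-sg$weights, sg$universe)][seq_len(set_size)]
  }
  obs <- observed_count(set, sg$sig)
  n_map <- sum(toupper(set) %in% sg$universe)
  p <- vapply(nulls, function(mode) {
    set.seed(derive_seed(cfg$seed, if (mode == "weighted") 1L else 2L))
    empirical_enrichment_p(obs, n_map, sg$sig, sg$universe,
                           weights = if (mode == "weighted") sg$weights,
                           B = B)
  }, numeric(1L))
  list(p = p, observed = obs, set = set, n_sig = nrow(sg$sig))
}
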