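#' Enrichment run configuration
#'
#' Parameters of the two-level bootstrap. `n_replicates` random size-matched
#' gene sets are drawn per interactome to form its empirical null;
#' `n_studies` simulated studies assess how many interactomes would reach
#' `alpha_category` by chance study-wide. With `size_weighted = TRUE`
#' (default) random sets are sampled with per-gene weights equal to the number
#' of assigned SNPs, correcting the gene-size/SNP-density bias (a long,
#' SNP-dense gene contains a sub-cutoff SNP far more often than a short one).
#'
#' @param pcut index-SNP p-value cutoff (P-CUT), default 0.05.
#' @param n_replicates random sets per interactome (default 5000).
#' @param n_studies simulated studies (default 1000).
#' @param alpha_category per-interactome significance level used in the
#'   study-wide count (default 0.05).
#' @param seed master seed; all stage seeds are derived from it.
#' @param size_weighted weight random-set sampling by per-gene SNP counts.
#' @return a list of class `enrichment_config`.
#' @export
enrichment_config <- function(pcut = 0.05, n_replicates = 5000,
                              n_studies = 1000, alpha_category = 0.05,
                              seed = 1L, size_weighted = TRUE) {
  if (!(pcut > 0 && pcut < 1)) stop_config("pcut must be in (0, 1)")
  if (n_replicates < 1L) stop_config("n_replicates must be >= 1")
  if (n_studies < 1L) stop_config("n_studies must be >= 1")
  if (!(alpha_category > 0 && alpha_category <= 1))
    stop_config("alpha_category must be in (0, 1]")
  structure(list(pcut = pcut, n_replicates = as.integer(n_replicates),
                 n_studies = as.integer(n_studies),
                 alpha_category = alpha_category,
                 seed = as.integer(seed),
                 size_weighted = isTRUE(size_weighted)),
            class = "enrichment_config")
}

#' Count an interactome's significant genes
#'
#' The observed statistic: how many of the set's genes survive in the pruned
#' significant-gene list.
#'
#' @param set a [gene_set] (or plain character vector of symbols).
#' @param pruned a `significant_genes` list (or character vector of symbols).
#' @return integer count.
#' @export
observed_count <- function(set, pruned) {
  genes <- if (inherits(set, "gene_set")) set$genes else unique(toupper(set))
  sig <- if (is.character(pruned)) pruned else pruned$symbol
  sum(genes %in% sig)
}

#' Draw a random gene set from the mappable universe
#'
#' Samples `size` distinct genes without replacement. With weights, genes are
#' drawn sequentially with probability proportional to weight among those not
#' yet drawn, so inclusion probability increases with weight — with SNP counts
#' as weights this mimics picking random SNPs and taking their genes, the
#' standard correction for gene-size bias in gene-set tests of GWAS signals.
#'
#' @param size number of genes to draw.
#' @param universe character vector of candidate genes (mappable genes only).
#' @param weights non-negative numeric weights aligned with `universe`, or
#'   `NULL` for uniform sampling. At least `size` weights must be positive.
#' @param name name of the resulting set.
#' @return a [gene_set] with `source = "random"`.
#' @export
sample_random_gene_set <- function(size, universe, weights = NULL,
                                   name = "random") {
  n <- length(universe)
  if (size > n) stop_config("random set size exceeds universe size")
  if (!is.null(weights)) {
    if (length(weights) != n) stop_config("weights must align with universe")
    if (any(weights < 0)) stop_config("weights must be non-negative")
    if (sum(weights > 0) < size)
      stop_config("fewer positively weighted genes than requested set size")
  }
  idx <- sample.int(n, size, replace = FALSE, prob = weights)
  gene_set(name, universe[idx], source = "random")
}

## B replicate counts for one interactome: each replicate draws a size-matched
## random set and counts its overlap with the pruned list. sig01 is the
## indicator of pruned membership over the universe.
replicate_counts <- function(B, size, sig01, weights = NULL) {
  n <- length(sig01)
  if (size == 0L) return(integer(B))
  vapply(seq_len(B), function(b)
    sum(sig01[sample.int(n, size, prob = weights)]), integer(1L))
}

#' Empirical enrichment p-value for one interactome
#'
#' Draws `B` random gene sets matched to the interactome's mappable size,
#' counts each replicate's significant genes against the same pruned list, and
#' returns the add-one empirical tail probability
#' `(1 + #\{count_b >= observed\}) / (B + 1)`. The estimator never returns
#' exactly 0 (minimum `1/(B+1)`) and returns 1 when the observed count is 0.
#'
#' @param observed observed significant-gene count of the interactome.
#' @param set_size number of the interactome's genes in the universe.
#' @param pruned `significant_genes` list or character vector of symbols.
#' @param universe mappable-gene universe.
#' @param weights sampling weights aligned with `universe` (`NULL` = uniform).
#' @param B number of random replicate sets.
#' @return the empirical p-value, a single number in `[1/(B+1), 1]`.
#' @export
empirical_enrichment_p <- function(observed, set_size, pruned, universe,
                                   weights = NULL, B = 5000) {
  sigset <- if (is.character(pruned)) pruned else pruned$symbol
  sig01 <- universe %in% sigset
  counts <- replicate_counts(B, set_size, sig01, weights)
  (1 + sum(counts >= observed)) / (B + 1)
}

#' Study-wide assessment over simulated studies
#'
#' Second bootstrap level: each simulated study elects, per interactome, one
#' replicate count as pseudo-observed and computes its empirical p-value
#' against `B` counts resampled with replacement from the remaining
#' replicates; the study's statistic is the number of interactomes reaching
#' `alpha_category`. The count of resampled replicates at or above the
#' pseudo-observed value is Binomial(`B`, tail fraction among the remaining
#' replicates), which is drawn directly. The observed number of significant
#' interactomes is then compared with this null distribution.
#'
#' @param counts_list list (one element per interactome) of replicate-count
#'   vectors, as produced internally by [run_enrichment()].
#' @param observed_ps observed per-interactome empirical p-values.
#' @param cfg an [enrichment_config] (uses `n_studies`, `alpha_category`).
#' @return list of class `study_wide_result`: `observed_n_significant`,
#'   `expected_n_significant` (mean over simulated studies), `study_p`
#'   (add-one fraction of studies with at least the observed count) and
#'   `null_counts` (per-study counts).
#' @export
simulate_studies <- function(counts_list, observed_ps, cfg) {
  S <- cfg$n_studies
  alpha <- cfg$alpha_category
  n_sets <- length(counts_list)
  observed_n <- sum(observed_ps <= alpha)
  if (n_sets == 0L) {
    return(structure(list(observed_n_significant = 0L,
                          expected_n_significant = 0,
                          study_p = 1,
                          null_counts = integer(S)),
                     class = "study_wide_result"))
  }
  study_sig <- matrix(FALSE, nrow = S, ncol = n_sets)
  for (k in seq_len(n_sets)) {
    counts <- counts_list[[k]]
    B <- length(counts)
    j <- sample.int(B, S, replace = TRUE)
    obs <- counts[j]
    ## tail fraction among the B-1 remaining replicates (>= always counts
    ## the elected replicate itself once in the full vector)
    tail_all <- vapply(obs, function(o) sum(counts >= o), integer(1L))
    q <- (tail_all - 1L) / (B - 1L)
    x <- stats::rbinom(S, B, q)
    study_sig[, k] <- (1 + x) / (B + 1) <= alpha
  }
  null_counts <- rowSums(study_sig)
  structure(list(observed_n_significant = observed_n,
                 expected_n_significant = mean(null_counts),
                 study_p = (1 + sum(null_counts >= observed_n)) / (S + 1),
                 null_counts = null_counts),
            class = "study_wide_result")
}

#' @export
print.study_wide_result <- function(x, ...) {
  cat(sprintf("<study_wide_result> observed %d significant interactome(s); expected %.2f under the null; study-wide p = %.4f\n",
              x$observed_n_significant, x$expected_n_significant, x$study_p))
  invisible(x)
}

## Deterministic per-set seed derived from a stage seed, identical across the
## masked and unmasked runs so their replicate draws are comparable.
derive_seed <- function(stage_seed, k) {
  as.integer((as.numeric(stage_seed) + 1000003 * k) %% 2147483647)
}

## One masked-or-unmasked pass: per-set observed counts, replicate counts and
## empirical p-values on a given significant_genes() result.
run_enrichment_pass <- function(sg, sets, cfg, stage_seed) {
  universe <- sg$universe
  weights <- if (cfg$size_weighted) sg$weights else NULL
  sig01 <- universe %in% sg$sig$symbol
  B <- cfg$n_replicates
  res <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    in_univ <- s$genes %in% universe
    n_map <- sum(in_univ)
    obs <- observed_count(s, sg$sig)
    set.seed(derive_seed(stage_seed, k))
    counts <- replicate_counts(B, n_map, sig01, weights)
    res[[k]] <- list(name = s$name, source = s$source,
                     size = length(s$genes), n_mappable = n_map,
                     n_sig = obs, counts = counts,
                     p = (1 + sum(counts >= obs)) / (B + 1))
  }
  res
}

#' Run the full enrichment analysis
#'
#' Executes the pipeline twice — once with the region mask applied and once
#' without — on the same inputs and with identical derived seeds, so that a
#' mask touching no SNP gives identical p-values. For each interactome it
#' reports the observed significant-gene count and the empirical enrichment
#' p-value of both runs, plus the study-wide bootstrap summary.
#'
#' @param gwas SNP table from [read_gwas_summary()].
#' @param genes gene annotation from [read_gene_annotation()].
#' @param ld an `ld_table`.
#' @param sets list of [gene_set] interactomes.
#' @param cfg an [enrichment_config].
#' @param mask optional region mask; `NULL` means the masked run equals the
#'   unmasked one.
#' @param out optional path: write the Table-1-style results TSV (+ JSON
#'   sidecar) via [write_results_table()].
#' @param window_bp,r2_max,dist_bp mapping/pruning parameters, see
#'   [significant_genes()].
#' @return list with `results` (one row per interactome: `name`, `size`,
#'   `source`, `n_mappable_unmasked`, `n_mappable_masked`, `n_sig_unmasked`,
#'   `n_sig_masked`, `p_unmasked`, `p_masked`), `study` (per-variant
#'   `study_wide_result`s), `sig` (per-variant pruned lists), `config`, and
#'   `seeds`.
#' @export
run_enrichment <- function(gwas, genes, ld, sets, cfg = enrichment_config(),
                           mask = NULL, out = NULL,
                           window_bp = 20000, r2_max = 0.2, dist_bp = 1e6) {
  stopifnot(inherits(cfg, "enrichment_config"))
  if (inherits(sets, "gene_set")) sets <- list(sets)
  set.seed(cfg$seed)
  seeds <- list(replicates = sample.int(2147483646L, 1L),
                studies = sample.int(2147483646L, 1L))

  sg_u <- significant_genes(gwas, genes, ld, mask = NULL, pcut = cfg$pcut,
                            window_bp = window_bp, r2_max = r2_max,
                            dist_bp = dist_bp)
  pass_u <- run_enrichment_pass(sg_u, sets, cfg, seeds$replicates)
  has_mask <- !is.null(mask) && nrow(mask) > 0L
  if (has_mask) {
    sg_m <- significant_genes(gwas, genes, ld, mask = mask, pcut = cfg$pcut,
                              window_bp = window_bp, r2_max = r2_max,
                              dist_bp = dist_bp)
    pass_m <- run_enrichment_pass(sg_m, sets, cfg, seeds$replicates)
  } else {
    sg_m <- sg_u
    pass_m <- pass_u
  }

  results <- data.frame(
    name = vapply(pass_u, `[[`, character(1L), "name"),
    size = vapply(pass_u, `[[`, integer(1L), "size"),
    source = vapply(pass_u, `[[`, character(1L), "source"),
    n_mappable_unmasked = vapply(pass_u, `[[`, integer(1L), "n_mappable"),
    n_mappable_masked = vapply(pass_m, `[[`, integer(1L), "n_mappable"),
    n_sig_unmasked = vapply(pass_u, `[[`, integer(1L), "n_sig"),
    n_sig_masked = vapply(pass_m, `[[`, integer(1L), "n_sig"),
    p_unmasked = vapply(pass_u, `[[`, numeric(1L), "p"),
    p_masked = vapply(pass_m, `[[`, numeric(1L), "p"),
    stringsAsFactors = FALSE)

  set.seed(seeds$studies)
  study_u <- simulate_studies(lapply(pass_u, `[[`, "counts"),
                              results$p_unmasked, cfg)
  set.seed(seeds$studies)
  study_m <- simulate_studies(lapply(pass_m, `[[`, "counts"),
                              results$p_masked, cfg)

  ans <- list(results = results,
              study = list(unmasked = study_u, masked = study_m),
              sig = list(unmasked = sg_u$sig, masked = sg_m$sig),
              config = cfg, seeds = seeds)
  if (!is.null(out)) {
    write_results_table(results, out,
                        parameters = c(unclass(cfg), seeds,
                                       list(window_bp = window_bp,
                                            r2_max = r2_max,
                                            dist_bp = dist_bp,
                                            mask_label = if (has_mask) attr(mask, "label") %||% "mask" else NA)))
  }
  ans
}

#' Multi-cutoff sensitivity scan
#'
#' Repeats the enrichment analysis at several index-SNP p-value cutoffs to
#' check that a set's association does not hinge on the choice of cutoff. By
#' default only the interactomes significant at `cfg$pcut` (in either the
#' masked or the unmasked run, at `cfg$alpha_category`) are re-analysed at the
#' other cutoffs, as in the original sensitivity analysis; `all_sets = TRUE`
#' re-analyses everything.
#'
#' @inheritParams run_enrichment
#' @param pcuts cutoffs to scan (default `c(0.005, 0.03, 0.05)`).
#' @param all_sets re-analyse all sets at all cutoffs.
#' @return long-format data.frame: `name`, `pcut`, `masked` (logical), `p`.
#' @export
sensitivity_scan <- function(gwas, genes, ld, sets, cfg = enrichment_config(),
                             mask = NULL, pcuts = c(0.005, 0.03, 0.05),
                             all_sets = FALSE,
                             window_bp = 20000, r2_max = 0.2, dist_bp = 1e6) {
  stopifnot(all(pcuts > 0 & pcuts < 1))
  if (inherits(sets, "gene_set")) sets <- list(sets)
  base <- run_enrichment(gwas, genes, ld, sets, cfg, mask = mask,
                         window_bp = window_bp, r2_max = r2_max,
                         dist_bp = dist_bp)
  keep <- if (all_sets) rep(TRUE, nrow(base$results)) else
    (base$results$p_unmasked <= cfg$alpha_category |
       base$results$p_masked <= cfg$alpha_category)
  long <- function(res, pcut) {
    rbind(data.frame(name = res$results$name, pcut = pcut, masked = FALSE,
                     p = res$results$p_unmasked, stringsAsFactors = FALSE),
          data.frame(name = res$results$name, pcut = pcut, masked = TRUE,
                     p = res$results$p_masked, stringsAsFactors = FALSE))
  }
  out <- long(base, cfg$pcut)
  sel <- sets[keep]
  for (pc in setdiff(pcuts, cfg$pcut)) {
    if (length(sel) == 0L) break
    cfg_pc <- cfg
    cfg_pc$pcut <- pc
    res <- run_enrichment(gwas, genes, ld, sel, cfg_pc, mask = mask,
                          window_bp = window_bp, r2_max = r2_max,
                          dist_bp = dist_bp)
    out <- rbind(out, long(res, pc))
  }
  out <- out[order(out$name, out$pcut, out$masked), , drop = FALSE]
  rownames(out) <- NULL
  out
}
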