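## A 20-gene toy genome with one SNP per gene, no LD, genes far apart:
## mapping is the identity and the bootstrap reduces to subset sampling.
one_snp_genome <- function(n_genes = 20, pvalues = NULL) {
  genes <- toy_genes(sprintf("G%02d", seq_len(n_genes)), "1",
                     seq_len(n_genes) * 3000000L,
                     seq_len(n_genes) * 3000000L + 1000L)
  if (is.null(pvalues)) pvalues <- runif(n_genes)
  snps <- toy_snps(sprintf("rs%02d", seq_len(n_genes)), "1",
                   genes$start + 500L, pvalues)
  list(genes = genes, snps = snps)
}

test_that("observed count is the set/pruned-list intersection size", {
  pruned <- c("G1", "G2", "G3")
  expect_equal(observed_count(gene_set("s", c("X1", "X2")), pruned), 0L)
  expect_equal(observed_count(gene_set("s", c("G1", "G2", "G3", "X4")), pruned), 3L)
  expect_equal(observed_count(c("g1", "x9"), pruned), 1L)  # case-insensitive
})

test_that("weighted sampling honors the inclusion-probability contract", {
  universe <- c("A", "B", "C")
  ## zero-weight gene is never drawn
  set.seed(1)
  for (i in 1:200) {
    s <- sample_random_gene_set(2, universe, weights = c(1, 1, 0))
    expect_false("C" %in% s$genes)
  }
  ## size = |universe| returns the whole universe
  expect_setequal(sample_random_gene_set(3, universe)$genes, universe)
  ## 3:1 weights give ~3:1 inclusion frequencies for size-1 draws
  set.seed(2)
  draws <- replicate(20000, sample_random_gene_set(1, c("H", "L"),
                                                   weights = c(3, 1))$genes)
  ratio <- sum(draws == "H") / sum(draws == "L")
  expect_gt(ratio, 2.7)
  expect_lt(ratio, 3.3)
  ## errors: infeasible requests
  expect_error(sample_random_gene_set(4, universe),
               class = "interactome_config_error")
  expect_error(sample_random_gene_set(2, universe, weights = c(1, 0, 0)),
               class = "interactome_config_error")
})

test_that("empirical p-values hit their analytic anchors", {
  universe <- sprintf("G%02d", 1:20)
  pruned <- universe[1:8]
  set.seed(4)
  ## observed 0: every replicate count >= 0, so p = 1 exactly
  expect_equal(empirical_enrichment_p(0, 5, pruned, universe, B = 200), 1)
  ## observed above the maximum possible count: p = 1/(B+1)
  expect_equal(empirical_enrichment_p(6, 5, pruned, universe, B = 200),
               1 / 201)
  ## p is non-increasing in the observed count, all else fixed
  set.seed(4)
  p3 <- empirical_enrichment_p(3, 5, pruned, universe, B = 500)
  set.seed(4)
  p4 <- empirical_enrichment_p(4, 5, pruned, universe, B = 500)
  expect_lte(p4, p3)
  ## range contract
  expect_gte(p4, 1 / 501)
  expect_lte(p3, 1)
})

test_that("bootstrap p matches the exhaustively enumerated tail probability", {
  set.seed(8)
  g <- one_snp_genome(12)
  sg <- significant_genes(g$snps, g$genes, ld_table(), pcut = 0.5)
  for (n_set in c(3, 5)) {
    set <- sample(sg$universe, n_set)
    obs <- observed_count(set, sg$sig)
    exact <- enum_overlap_tail(sg$universe, sg$sig$symbol, n_set, obs)
    B <- 2000
    p_hat <- empirical_enrichment_p(obs, n_set, sg$sig, sg$universe,
                                    weights = NULL, B = B)
    expect_lt(abs(p_hat - exact), 3 * sqrt(exact * (1 - exact) / B) + 1 / (B + 1))
  }
})

test_that("study-wide bootstrap anchors and calibration hold", {
  cfg <- enrichment_config(seed = 1, n_replicates = 200, n_studies = 300)
  ## no interactomes
  s0 <- simulate_studies(list(), numeric(0), cfg)
  expect_equal(s0$expected_n_significant, 0)
  expect_equal(s0$study_p, 1)
  ## alpha = 1: every interactome significant in every study
  set.seed(2)
  counts <- lapply(1:3, function(i) rbinom(200, 10, 0.3))
  cfg1 <- enrichment_config(seed = 1, n_replicates = 200, n_studies = 300,
                            alpha_category = 1)
  s1 <- simulate_studies(counts, rep(0.5, 3), cfg1)
  expect_equal(s1$expected_n_significant, 3)
  ## under a complete null the expected number of significant categories is
  ## about n_sets * alpha (discreteness makes it conservative, never larger)
  set.seed(3)
  counts2 <- lapply(1:3, function(i) rbinom(1000, 40, 0.5))
  cfg2 <- enrichment_config(seed = 1, n_replicates = 1000, n_studies = 2000)
  s2 <- simulate_studies(counts2, rep(0.5, 3), cfg2)
  expect_lt(s2$expected_n_significant, 3 * 0.05 * 1.6)
  expect_gt(s2$expected_n_significant, 0)
})

test_that("run_enrichment: disjoint mask reproduces unmasked p-values exactly", {
  set.seed(12)
  g <- one_snp_genome(15)
  sets <- list(gene_set("S1", sample(g$genes$symbol, 5)),
               gene_set("S2", sample(g$genes$symbol, 7)))
  cfg <- enrichment_config(seed = 7, n_replicates = 300, n_studies = 50)
  far_mask <- data.frame(chrom = "22", start = 1L, end = 1000000L)
  r <- run_enrichment(g$snps, g$genes, ld_table(), sets, cfg, mask = far_mask)
  expect_equal(r$results$p_masked, r$results$p_unmasked)
  expect_equal(r$results$n_sig_masked, r$results$n_sig_unmasked)
})

test_that("identical master seeds give byte-identical results tables", {
  set.seed(31)
  g <- one_snp_genome(15)
  sets <- list(gene_set("S1", sample(g$genes$symbol, 5)))
  cfg <- enrichment_config(seed = 99, n_replicates = 200, n_studies = 50)
  f1 <- tempfile(); f2 <- tempfile()
  run_enrichment(g$snps, g$genes, ld_table(), sets, cfg, out = f1)
  run_enrichment(g$snps, g$genes, ld_table(), sets, cfg, out = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(paste0(f1, ".json")),
                   readLines(paste0(f2, ".json")))
})

test_that("a cutoff below every SNP p-value yields all-1 p-values", {
  g <- one_snp_genome(10, pvalues = seq(0.2, 0.9, length.out = 10))
  sets <- list(gene_set("S1", g$genes$symbol[1:4]))
  cfg <- enrichment_config(pcut = 0.01, seed = 5, n_replicates = 100,
                           n_studies = 10)
  r <- run_enrichment(g$snps, g$genes, ld_table(), sets, cfg)
  expect_equal(nrow(r$sig$unmasked), 0L)
  expect_equal(r$results$n_sig_unmasked, 0L)
  expect_equal(r$results$p_unmasked, 1)
})

test_that("sensitivity scan reduces to run_enrichment at a single cutoff", {
  set.seed(41)
  g <- one_snp_genome(15)
  sets <- list(gene_set("S1", sample(g$genes$symbol, 5)),
               gene_set("S2", sample(g$genes$symbol, 6)))
  cfg <- enrichment_config(seed = 13, n_replicates = 200, n_studies = 20)
  base <- run_enrichment(g$snps, g$genes, ld_table(), sets, cfg)
  scan <- sensitivity_scan(g$snps, g$genes, ld_table(), sets, cfg,
                           pcuts = 0.05, all_sets = TRUE)
  expect_equal(scan$p[scan$name == "S1" & !scan$masked & scan$pcut == 0.05],
               base$results$p_unmasked[base$results$name == "S1"])
  expect_setequal(unique(scan$pcut), 0.05)
  ## multi-cutoff long format covers requested cutoffs for re-analysed sets
  scan3 <- sensitivity_scan(g$snps, g$genes, ld_table(), sets, cfg,
                            pcuts = c(0.005, 0.03, 0.05), all_sets = TRUE)
  expect_setequal(unique(scan3$pcut), c(0.005, 0.03, 0.05))
  expect_equal(nrow(scan3), 2 * 2 * 3)
})
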