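test_that("region mask removes SNPs with inclusive interval bounds", {
  snps <- toy_snps(sprintf("rs%d", 1:4), "1", c(1000L, 2000L, 3000L, 3001L),
                   rep(0.5, 4))
  mask <- data.frame(chrom = "1", start = 2000L, end = 3000L)
  out <- apply_region_mask(snps, mask)
  expect_equal(out$rsid, c("rs1", "rs4"))  # both bounds inclusive
  expect_equal(apply_region_mask(snps, NULL), snps)
  expect_equal(apply_region_mask(snps, mask[0, ]), snps)

  set.seed(3)
  snps10 <- toy_snps(sprintf("rs%d", 1:10), "2", sample.int(10000, 10),
                     runif(10))
  mask2 <- data.frame(chrom = "2", start = 1L, end = sort(snps10$pos)[3])
  expect_equal(nrow(apply_region_mask(snps10, mask2)), 7L)
})

test_that("SNP-gene window assignment is inclusive at exactly 20 kb", {
  genes <- toy_genes("G1", "1", 10000L, 20000L)
  snps <- toy_snps(c("rs_in", "rs_edge", "rs_out", "rs_up"), "1",
                   c(15000L, 40000L, 40001L, 5000L), rep(0.5, 4))
  idx <- map_snps_to_genes(snps, genes)
  expect_setequal(idx$assignments$rsid, c("rs_in", "rs_edge", "rs_up"))

  ## different chromosome never assigns; a SNP may hit several genes
  genes2 <- rbind(genes, toy_genes("G2", "1", 30000L, 50000L),
                  toy_genes("G3", "2", 10000L, 20000L))
  idx2 <- map_snps_to_genes(snps, genes2)
  a <- idx2$assignments
  expect_setequal(a$symbol[a$rsid == "rs_edge"], c("G1", "G2"))
  expect_false("G3" %in% a$symbol)
  expect_equal(idx2$unmappable, "G3")
})

test_that("index SNP selection takes the minimum p with deterministic ties", {
  genes <- toy_genes("G1", "1", 1000L, 9000L)
  snps <- toy_snps(c("rsa", "rsb", "rsc"), "1", c(2000L, 3000L, 4000L),
                   c(0.2, 0.01, 0.04))
  idx <- select_index_snps(map_snps_to_genes(snps, genes))
  expect_equal(idx$index_snps$rsid, "rsb")
  expect_equal(idx$index_snps$pvalue, 0.01)

  ## tie on p: smaller position wins; tie on both: lexicographic rsid
  snps2 <- toy_snps(c("rsz", "rsy"), "1", c(200L, 100L), c(0.01, 0.01))
  idx2 <- select_index_snps(map_snps_to_genes(snps2, genes))
  expect_equal(idx2$index_snps$rsid, "rsy")
})

test_that("significance at P-CUT is strict ('stronger than')", {
  genes <- rbind(toy_genes("GA", "1", 1000L, 2000L),
                 toy_genes("GB", "1", 200000L, 201000L),
                 toy_genes("GC", "1", 400000L, 401000L))
  snps <- toy_snps(c("rs1", "rs2", "rs3"), "1",
                   c(1500L, 200500L, 400500L), c(0.05, 0.049, 0.6))
  idx <- select_index_snps(map_snps_to_genes(snps, genes))
  sig <- flag_significant_genes(idx, pcut = 0.05)
  expect_equal(sig$symbol, "GB")  # 0.05 excluded, 0.049 included
  expect_equal(attr(sig, "pcut"), 0.05)
})

test_that("LD pruning drops the weaker of two dependent signals", {
  genes <- rbind(toy_genes("GA", "1", 100000L, 110000L),
                 toy_genes("GB", "1", 600000L, 610000L))
  snps <- toy_snps(c("rsA", "rsB"), "1", c(105000L, 605000L), c(0.001, 0.01))
  idx <- select_index_snps(map_snps_to_genes(snps, genes, window_bp = 0))
  sig <- flag_significant_genes(idx, 0.05)

  ## 500 kb apart, r2 = 0.5 -> dependent: larger-p gene dropped
  ld1 <- ld_table(data.frame(SNP_A = "rsA", SNP_B = "rsB", R2 = 0.5))
  pr1 <- ld_prune(sig, ld1)
  expect_equal(pr1$symbol, "GA")
  expect_equal(attr(pr1, "dropped")$symbol, "GB")
  expect_equal(attr(pr1, "dropped")$absorbed_by, "GA")

  ## r2 exactly 0.2 counts as independent: both retained
  ld2 <- ld_table(data.frame(SNP_A = "rsA", SNP_B = "rsB", R2 = 0.2))
  expect_setequal(ld_prune(sig, ld2)$symbol, c("GA", "GB"))

  ## strong LD but farther than 1000 kb: both retained
  genes3 <- rbind(toy_genes("GA", "1", 100000L, 110000L),
                  toy_genes("GB", "1", 1400000L, 1410000L))
  snps3 <- toy_snps(c("rsA", "rsB"), "1", c(105000L, 1405000L), c(0.001, 0.01))
  sig3 <- flag_significant_genes(
    select_index_snps(map_snps_to_genes(snps3, genes3, window_bp = 0)), 0.05)
  ld3 <- ld_table(data.frame(SNP_A = "rsA", SNP_B = "rsB", R2 = 0.9))
  expect_setequal(ld_prune(sig3, ld3)$symbol, c("GA", "GB"))
  ## exactly 1000 kb is still dependent range
  snps4 <- toy_snps(c("rsA", "rsB"), "1", c(105000L, 1105000L), c(0.001, 0.01))
  sig4 <- flag_significant_genes(
    select_index_snps(map_snps_to_genes(snps4, genes3, window_bp = 300000)), 0.05)
  expect_equal(ld_prune(sig4, ld3)$symbol, "GA")
})

test_that("pruning is idempotent, empty LD retains all, unknown rsid errors", {
  set.seed(21)
  inst <- random_mapping_instance()
  sig <- flag_significant_genes(
    select_index_snps(map_snps_to_genes(inst$snps, inst$genes)), inst$pcut)
  ld <- ld_table(inst$ld_pairs)
  pr <- ld_prune(sig, ld)
  expect_lte(nrow(pr), nrow(sig))
  expect_equal(ld_prune(pr, ld)$symbol, pr$symbol)
  expect_equal(nrow(ld_prune(sig, ld_table())), nrow(sig))

  bare <- data.frame(symbol = "GX", rsid = "rs_unknown", pvalue = 0.01,
                     stringsAsFactors = FALSE)
  class(bare) <- c("significant_genes", "data.frame")
  expect_error(ld_prune(bare, ld, snps = inst$snps),
               class = "interactome_format_error")
})

test_that("full mapping stage matches the brute-force oracle on random instances", {
  set.seed(99)
  for (i in 1:25) {
    inst <- random_mapping_instance()
    got <- significant_genes(inst$snps, inst$genes, ld_table(inst$ld_pairs),
                             mask = inst$mask, pcut = inst$pcut)
    expected <- bf_significant_genes(inst$snps, inst$genes, inst$ld_pairs,
                                     mask = inst$mask, pcut = inst$pcut)
    expect_equal(got$sig$symbol, expected)
  }
})

test_that("a mask disjoint from all SNPs leaves the significant list unchanged", {
  set.seed(5)
  inst <- random_mapping_instance()
  far_mask <- data.frame(chrom = "9", start = 1L, end = 500000L)
  with_mask <- significant_genes(inst$snps, inst$genes, ld_table(inst$ld_pairs),
                                 mask = far_mask, pcut = 0.5)
  without <- significant_genes(inst$snps, inst$genes, ld_table(inst$ld_pairs),
                               pcut = 0.5)
  expect_equal(with_mask$sig$symbol, without$sig$symbol)
})
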