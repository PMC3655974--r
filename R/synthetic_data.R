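#' Simulation configuration
#'
#' Parameters of the synthetic GWAS generator. The generator emulates the
#' statistical structure the analysis assumes — genome-wide SNP p-values that
#' are uniform under the null but correlated within LD blocks, genes of
#' variable length (hence variable SNP density), intergenic SNPs that map to
#' no gene, and a spiked gene set carrying true signal.
#'
#' Defaults: 300 genes over 4 chromosomes, log-normal gene lengths (median
#' 20 kb, sdlog 1 — gene lengths span orders of magnitude, which is what makes
#' gene-size bias worth correcting), intergenic gaps exponential with mean
#' 20 kb, 1 SNP per kb, LD blocks of 10 consecutive SNPs with latent Gaussian
#' correlation 0.7 (reported in the LD table as r^2 = 0.49), a spiked set of
#' 30 genes of which a fraction 0.3 carry signal drawn from Beta(0.1, 1).
#'
#' @param n_genes total genes.
#' @param gene_length_median,gene_length_sdlog log-normal gene-length
#'   parameters (bp).
#' @param snp_density_per_kb expected SNPs per kb (uniform Poisson process, so
#'   SNPs per gene are Poisson with mean length x density).
#' @param n_chromosomes chromosomes; genes are split evenly.
#' @param intergenic_gap_mean mean intergenic gap (bp).
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho latent within-block correlation in \[0, 1).
#' @param spiked_set_size genes in the spiked set.
#' @param spike_fraction fraction of spiked-set genes carrying signal.
#' @param alt_shape shape `a` of the Beta(a, 1) signal p-value distribution
#'   (a < 1 concentrates p near 0).
#' @param n_decoy_sets additional null gene sets written next to the spiked
#'   one.
#' @param decoy_size_range size range the decoy sets are drawn from.
#' @param seed master seed of the generator.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300, gene_length_median = 20000,
                       gene_length_sdlog = 1.0, snp_density_per_kb = 1,
                       n_chromosomes = 4, intergenic_gap_mean = 20000,
                       ld_block_size = 10, ld_rho = 0.7,
                       spiked_set_size = 30, spike_fraction = 0.3,
                       alt_shape = 0.1, n_decoy_sets = 12,
                       decoy_size_range = c(10, 110), seed = 1L) {
  if (n_genes < 1 || n_chromosomes < 1 || ld_block_size < 1 ||
      spiked_set_size < 1 || gene_length_median <= 0 ||
      snp_density_per_kb < 0 || intergenic_gap_mean < 0)
    stop_config("sim_config: all sizes must be positive")
  if (spike_fraction < 0 || spike_fraction > 1)
    stop_config("sim_config: spike_fraction must be in [0, 1]")
  if (alt_shape <= 0 || alt_shape > 1)
    stop_config("sim_config: alt_shape must be in (0, 1]")
  if (ld_rho < 0 || ld_rho >= 1)
    stop_config("sim_config: ld_rho must be in [0, 1)")
  if (spiked_set_size > n_genes)
    stop_config("sim_config: spiked set larger than the genome")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic genome
#'
#' Lays out non-overlapping genes chromosome by chromosome (log-normal
#' lengths, exponential intergenic gaps) and scatters SNPs as a uniform
#' Poisson process over each chromosome, so the SNP count of a gene is
#' Poisson with mean length x density and intergenic SNPs exist that map to
#' no gene. Uses the current RNG state.
#'
#' @param cfg a [sim_config].
#' @return list with `genes` (symbol, chrom, start, end; 1-based inclusive)
#'   and `snps` (rsid, chrom, pos).
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chromosomes + 1L)))
  genes <- list()
  snps <- list()
  gi <- 0L
  ri <- 0L
  for (ch in seq_len(cfg$n_chromosomes)) {
    k <- per_chrom[ch]
    if (k == 0L) next
    lens <- pmax(200L, round(stats::rlnorm(k, log(cfg$gene_length_median),
                                           cfg$gene_length_sdlog)))
    gaps <- round(stats::rexp(k + 1L, 1 / max(1, cfg$intergenic_gap_mean))) + 1L
    starts <- cumsum(gaps[seq_len(k)]) + cumsum(c(0L, lens[-k]))
    ends <- starts + lens - 1L
    chrom_len <- ends[k] + gaps[k + 1L]
    n_snp <- stats::rpois(1L, chrom_len * cfg$snp_density_per_kb / 1000)
    if (n_snp > chrom_len)
      stop_config("generate_genome: SNP density too high to place distinct positions")
    pos <- sort(sample.int(chrom_len, n_snp))
    genes[[ch]] <- data.frame(symbol = sprintf("G%04d", gi + seq_len(k)),
                              chrom = as.character(ch),
                              start = as.integer(starts),
                              end = as.integer(ends),
                              stringsAsFactors = FALSE)
    snps[[ch]] <- data.frame(rsid = sprintf("rs%06d", ri + seq_len(n_snp)),
                             chrom = rep(as.character(ch), n_snp),
                             pos = as.integer(pos),
                             stringsAsFactors = FALSE)
    gi <- gi + k
    ri <- ri + n_snp
  }
  list(genes = do.call(rbind, genes), snps = do.call(rbind, snps))
}

#' Generate null p-values with LD blocks
#'
#' Within each block of `ld_block_size` consecutive SNPs (per chromosome) a
#' shared latent Gaussian factor induces pairwise correlation `ld_rho`
#' (Gaussian copula: `z = sqrt(rho) b + sqrt(1 - rho) e`); p-values are the
#' normal CDF of the latent variable, so marginals are exactly uniform. The
#' LD table lists all within-block pairs with r^2 = `ld_rho^2`; with
#' `ld_rho = 0` it is empty and p-values are independent uniforms.
#'
#' @param snps SNP table from [generate_genome()].
#' @param cfg a [sim_config].
#' @return list with `gwas` (rsid, chrom, pos, pvalue) and `ld` (SNP_A,
#'   SNP_B, R2 data.frame).
#' @export
generate_null_pvalues <- function(snps, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(snps)
  bs <- cfg$ld_block_size
  rho <- cfg$ld_rho
  ## block ids restart at chromosome boundaries so no block spans two chromosomes
  block <- integer(n)
  off <- 0L
  for (ch in unique(snps$chrom)) {
    i <- which(snps$chrom == ch)
    block[i] <- off + (seq_along(i) - 1L) %/% bs + 1L
    off <- max(block[i])
  }
  nb <- max(block, 0L)
  b <- stats::rnorm(nb)
  z <- sqrt(rho) * b[block] + sqrt(1 - rho) * stats::rnorm(n)
  gwas <- snps
  gwas$pvalue <- stats::pnorm(z)
  ld <- if (rho > 0 && bs > 1L && n > 1L) {
    ## vectorized within-block pair enumeration: for a block whose SNPs sit at
    ## rows s..s+m-1, emit the m*(m-1)/2 index pairs from a combn template
    size_of <- tabulate(block, nbins = nb)
    start_of <- cumsum(c(1L, size_of[-nb]))
    templates <- lapply(unique(size_of[size_of >= 2L]), function(m)
      list(m = m, cmb = utils::combn(m, 2L)))
    ai <- integer(0L); bi <- integer(0L)
    for (tp in templates) {
      blocks_m <- which(size_of == tp$m)
      offs <- rep(start_of[blocks_m] - 1L, each = ncol(tp$cmb))
      ai <- c(ai, offs + tp$cmb[1L, ])
      bi <- c(bi, offs + tp$cmb[2L, ])
    }
    ord <- order(ai, bi)
    data.frame(SNP_A = gwas$rsid[ai[ord]], SNP_B = gwas$rsid[bi[ord]],
               R2 = rho^2, stringsAsFactors = FALSE)
  } else {
    data.frame(SNP_A = character(), SNP_B = character(), R2 = numeric())
  }
  list(gwas = gwas, ld = ld)
}

#' Spike association signal into a gene set
#'
#' For a randomly chosen fraction `spike_fraction` of the set's genes, every
#' index-eligible SNP (any SNP within `window_bp` of the gene, i.e. any SNP
#' that could become the gene's index SNP) has its p-value replaced by a draw
#' from Beta(`alt_shape`, 1). All other SNPs are untouched; with
#' `spike_fraction = 0` the input is returned unchanged.
#'
#' @param gwas SNP table with p-values.
#' @param genes gene annotation.
#' @param set_genes character vector of gene symbols to spike (must all exist
#'   in `genes`).
#' @param cfg a [sim_config].
#' @param window_bp index-eligibility window (default 20000, matching the
#'   mapping stage).
#' @return the modified SNP table; spiked gene symbols in attribute
#'   `"spiked_genes"`.
#' @export
spike_signal <- function(gwas, genes, set_genes, cfg, window_bp = 20000) {
  stopifnot(inherits(cfg, "sim_config"))
  unknown <- setdiff(set_genes, genes$symbol)
  if (length(unknown) > 0L)
    stop_format("spike_signal: unknown gene(s): ",
                paste(utils::head(unknown, 5L), collapse = ", "))
  n_spike <- round(cfg$spike_fraction * length(set_genes))
  if (n_spike == 0L) {
    attr(gwas, "spiked_genes") <- character(0L)
    return(gwas)
  }
  chosen <- sample(set_genes, n_spike)
  g <- genes[match(chosen, genes$symbol), , drop = FALSE]
  hit <- rep(FALSE, nrow(gwas))
  for (i in seq_len(nrow(g)))
    hit <- hit | (gwas$chrom == g$chrom[i] &
                    gwas$pos >= g$start[i] - window_bp &
                    gwas$pos <= g$end[i] + window_bp)
  gwas$pvalue[hit] <- stats::rbeta(sum(hit), cfg$alt_shape, 1)
  attr(gwas, "spiked_genes") <- chosen
  gwas
}

#' Generate a synthetic interaction-evidence table
#'
#' Emits evidence records spanning the four curation cases with a planted
#' ground truth: genes reported by two independent sources (kept), by one
#' source with one method (dropped), by one source with two distinct methods
#' (kept), and genes with only indirect records (dropped). Used to exercise
#' [curate_interactome()] end to end.
#'
#' @param n_per_case genes per case (default 3).
#' @return evidence data.frame; the planted kept genes are in attribute
#'   `"expected_kept"`.
#' @export
generate_evidence_table <- function(n_per_case = 3L) {
  rec <- function(gene, src, method, cls)
    data.frame(env_protein = "ENVP1", human_gene = gene, source_id = src,
               method = method, interaction_class = cls,
               stringsAsFactors = FALSE)
  out <- list()
  kept <- character(0L)
  for (i in seq_len(n_per_case)) {
    g <- sprintf("KEEPSRC%d", i)   # two independent sources, direct
    out[[length(out) + 1L]] <- rec(g, sprintf("PMID%d1", i), "y2h", "direct")
    out[[length(out) + 1L]] <- rec(g, sprintf("PMID%d2", i), "y2h", "direct")
    kept <- c(kept, g)
    g <- sprintf("DROPONE%d", i)   # one source, one method
    out[[length(out) + 1L]] <- rec(g, sprintf("PMID%d3", i), "y2h", "direct")
    g <- sprintf("KEEPMETH%d", i)  # one source, two distinct methods
    out[[length(out) + 1L]] <- rec(g, sprintf("PMID%d4", i), "y2h", "direct")
    out[[length(out) + 1L]] <- rec(g, sprintf("PMID%d4", i), "co-ip", "direct")
    kept <- c(kept, g)
    g <- sprintf("DROPIND%d", i)   # indirect only
    out[[length(out) + 1L]] <- rec(g, sprintf("PMID%d5", i), "y2h", "indirect")
    out[[length(out) + 1L]] <- rec(g, sprintf("PMID%d6", i), "co-ip", "indirect")
  }
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  attr(ev, "expected_kept") <- sort(kept)
  ev
}

#' Generate one complete synthetic dataset
#'
#' Runs the whole generator under `cfg$seed`: genome, null p-values with LD
#' blocks, gene sets (one spiked set plus `n_decoy_sets` null decoys), spiked
#' signal, an MHC-like mask covering a run of ten genes in the middle of
#' chromosome 1, and an evidence table. With `outdir` set, writes
#' `gwas.tsv`, `genes.bed`, `ld.tsv`, `sets.gmt`, `mask.bed`, `evidence.tsv`
#' — all in the formats the readers expect; identical seeds give
#' byte-identical files.
#'
#' @param cfg a [sim_config].
#' @param outdir optional output directory (created if needed).
#' @return (invisibly when writing) list with `gwas`, `genes`, `ld` (pair
#'   data.frame), `sets` (list of [gene_set]; the first is the spiked set,
#'   named `"SPIKED"`), `mask`, `evidence`, `spiked_genes`, `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genome <- generate_genome(cfg)
  nullp <- generate_null_pvalues(genome$snps, cfg)
  spike_set <- sample(genome$genes$symbol, cfg$spiked_set_size)
  sets <- list(gene_set("SPIKED", spike_set, source = "synthetic"))
  if (cfg$n_decoy_sets > 0L) {
    szs <- sample(seq(cfg$decoy_size_range[1L],
                      min(cfg$decoy_size_range[2L], cfg$n_genes)),
                  cfg$n_decoy_sets, replace = TRUE)
    for (d in seq_len(cfg$n_decoy_sets))
      sets[[d + 1L]] <- gene_set(sprintf("DECOY%02d", d),
                                 sample(genome$genes$symbol, szs[d]),
                                 source = "synthetic")
  }
  gwas <- spike_signal(nullp$gwas, genome$genes, spike_set, cfg)
  ## MHC-like mask: a run of ten consecutive genes mid-chromosome-1
  g1 <- genome$genes[genome$genes$chrom == "1", , drop = FALSE]
  mid <- max(1L, nrow(g1) %/% 2L - 5L)
  idx <- mid:min(nrow(g1), mid + 9L)
  mask <- data.frame(chrom = "1",
                     start = min(g1$start[idx]) - 20000L,
                     end = max(g1$end[idx]) + 20000L,
                     stringsAsFactors = FALSE)
  attr(mask, "label") <- "synthetic-MHC"
  evidence <- generate_evidence_table()
  ans <- list(gwas = gwas, genes = genome$genes, ld = nullp$ld, sets = sets,
              mask = mask, evidence = evidence,
              spiked_genes = attr(gwas, "spiked_genes"), cfg = cfg)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    gw <- data.frame(rsid = gwas$rsid, chrom = gwas$chrom, pos = gwas$pos,
                     p = sprintf("%.10g", gwas$pvalue))
    utils::write.table(gw, file.path(outdir, "gwas.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gene_annotation(genome$genes, file.path(outdir, "genes.bed"))
    ld_out <- ans$ld
    if (nrow(ld_out) > 0L) ld_out$R2 <- sprintf("%.6g", ld_out$R2)
    utils::write.table(ld_out, file.path(outdir, "ld.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gene_sets(sets, file.path(outdir, "sets.gmt"))
    write_region_mask(mask, file.path(outdir, "mask.bed"))
    utils::write.table(evidence, file.path(outdir, "evidence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(ans))
  }
  ans
}
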