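## Independent brute-force oracles, written with plain loops and no calls into
## the package's mapping/enrichment code paths.

## Full observed-data scoring stage: mask -> window assignment -> index SNP ->
## cutoff -> greedy LD pruning. Returns the retained gene symbols in retention
## order.
bf_significant_genes <- function(snps, genes, ld_pairs, mask = NULL,
                                 pcut = 0.05, window = 20000,
                                 r2_max = 0.2, dist_bp = 1e6) {
  keep_snp <- rep(TRUE, nrow(snps))
  if (!is.null(mask) && nrow(mask) > 0) {
    for (i in seq_len(nrow(snps))) {
      for (j in seq_len(nrow(mask))) {
        if (snps$chrom[i] == mask$chrom[j] &&
            snps$pos[i] >= mask$start[j] && snps$pos[i] <= mask$end[j])
          keep_snp[i] <- FALSE
      }
    }
  }
  snps <- snps[keep_snp, , drop = FALSE]
  idx <- data.frame(symbol = character(), rsid = character(),
                    chrom = character(), pos = integer(), pvalue = numeric(),
                    stringsAsFactors = FALSE)
  for (g in seq_len(nrow(genes))) {
    best <- NULL
    for (s in seq_len(nrow(snps))) {
      if (snps$chrom[s] == genes$chrom[g] &&
          snps$pos[s] >= genes$start[g] - window &&
          snps$pos[s] <= genes$end[g] + window) {
        cand <- snps[s, ]
        if (is.null(best) ||
            cand$pvalue < best$pvalue ||
            (cand$pvalue == best$pvalue && cand$pos < best$pos) ||
            (cand$pvalue == best$pvalue && cand$pos == best$pos &&
               cand$rsid < best$rsid))
          best <- cand
      }
    }
    if (!is.null(best) && best$pvalue < pcut)
      idx <- rbind(idx, data.frame(symbol = genes$symbol[g], rsid = best$rsid,
                                   chrom = best$chrom, pos = best$pos,
                                   pvalue = best$pvalue,
                                   stringsAsFactors = FALSE))
  }
  if (nrow(idx) == 0) return(character(0))
  idx <- idx[order(idx$pvalue, idx$pos, idx$rsid, method = "radix"), ,
             drop = FALSE]
  lookup_r2 <- function(a, b) {
    if (a == b) return(1)
    for (r in seq_len(nrow(ld_pairs))) {
      if ((ld_pairs$SNP_A[r] == a && ld_pairs$SNP_B[r] == b) ||
          (ld_pairs$SNP_A[r] == b && ld_pairs$SNP_B[r] == a))
        return(ld_pairs$R2[r])
    }
    0
  }
  retained <- integer(0)
  for (i in seq_len(nrow(idx))) {
    ok <- TRUE
    for (r in retained) {
      if (idx$chrom[i] == idx$chrom[r] &&
          abs(idx$pos[i] - idx$pos[r]) <= dist_bp &&
          lookup_r2(idx$rsid[i], idx$rsid[r]) > r2_max)
        ok <- FALSE
    }
    if (ok) retained <- c(retained, i)
  }
  idx$symbol[retained]
}

## Exact tail probability of the overlap between a fixed significant-gene set
## and a uniformly drawn size-n subset of the universe, by exhaustive
## enumeration of all subsets.
enum_overlap_tail <- function(universe, sig_genes, n, observed) {
  subsets <- utils::combn(length(universe), n)
  hits <- 0
  for (j in seq_len(ncol(subsets))) {
    if (sum(universe[subsets[, j]] %in% sig_genes) >= observed)
      hits <- hits + 1
  }
  hits / ncol(subsets)
}

## Direct re-statement of the curation rule, evaluated record-by-record.
bf_curate <- function(evidence) {
  ev <- evidence
  ev$human_gene <- toupper(trimws(ev$human_gene))
  ev$method <- tolower(trimws(ev$method))
  ev <- ev[tolower(trimws(ev$interaction_class)) == "direct", , drop = FALSE]
  kept <- character(0)
  for (g in unique(ev$human_gene)) {
    d <- ev[ev$human_gene == g, , drop = FALSE]
    two_sources <- length(unique(trimws(d$source_id))) >= 2
    two_methods <- FALSE
    for (s in unique(d$source_id))
      if (length(unique(d$method[d$source_id == s])) >= 2) two_methods <- TRUE
    if (two_sources || two_methods) kept <- c(kept, g)
  }
  sort(kept)
}

## Small toy builders -------------------------------------------------------

toy_snps <- function(rsid, chrom, pos, pvalue) {
  data.frame(rsid = rsid, chrom = as.character(chrom), pos = as.integer(pos),
             pvalue = pvalue, stringsAsFactors = FALSE)
}

toy_genes <- function(symbol, chrom, start, end) {
  data.frame(symbol = symbol, chrom = as.character(chrom),
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

## A random 5-gene / 20-SNP instance for the mapping oracle tests.
random_mapping_instance <- function() {
  genes <- toy_genes(sprintf("G%d", 1:5), chrom = sample(c("1", "2"), 5, TRUE),
                     start = sample.int(200000, 5), end = 0L)
  genes$end <- genes$start + sample.int(30000, 5)
  snps <- toy_snps(sprintf("rs%02d", 1:20), chrom = sample(c("1", "2"), 20, TRUE),
                   pos = sample.int(260000, 20), pvalue = runif(20))
  n_ld <- sample(0:6, 1)
  ld_pairs <- if (n_ld > 0) {
    pr <- t(replicate(n_ld, sample(snps$rsid, 2)))
    df <- data.frame(SNP_A = pr[, 1], SNP_B = pr[, 2],
                     R2 = runif(n_ld), stringsAsFactors = FALSE)
    df[!duplicated(paste(pmin(df$SNP_A, df$SNP_B),
                         pmax(df$SNP_A, df$SNP_B))), , drop = FALSE]
  } else {
    data.frame(SNP_A = character(), SNP_B = character(), R2 = numeric())
  }
  mask <- if (runif(1) < 0.5) {
    st <- sample.int(200000, 1)
    data.frame(chrom = sample(c("1", "2"), 1), start = st,
               end = st + 40000L, stringsAsFactors = FALSE)
  } else NULL
  list(genes = genes, snps = snps, ld_pairs = ld_pairs, mask = mask,
       pcut = sample(c(0.05, 0.2, 0.5, 0.9), 1))
}
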