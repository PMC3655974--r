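#' Run the pipeline end to end
#'
#' Orchestrates `simulate -> curate -> map -> enrich -> sensitivity` from a
#' single configuration (a YAML file or an equivalent nested list), persisting
#' every stage's intermediates in the documented flat-file formats so stages
#' can be re-run individually. The final report is a Table-1-style TSV (one
#' row per interactome with masked and unmasked p-values) plus a JSON sidecar
#' embedding the fully resolved configuration and all seeds.
#'
#' Configuration schema (`*` = required):
#' \preformatted{
#' outdir*:      output directory
#' seed*:        master seed (integer)
#' stages:       subset of [simulate, curate, map, enrich, sensitivity]
#'               (default: all)
#' sim:          overrides for sim_config() fields
#' inputs:       gwas/genes/ld/sets/mask/evidence file paths (required for
#'               stages run without 'simulate')
#' enrichment:   pcut, n_replicates, n_studies, alpha_category, size_weighted,
#'               window_bp, r2_max, dist_bp
#' sensitivity:  pcuts (default [0.005, 0.03, 0.05]), all_sets (default false)
#' }
#'
#' @param config path to a YAML file, or a nested list.
#' @return invisibly, a list with `results`, `study`, `sensitivity` (if run),
#'   `curated` (if run), `paths` of all persisted files, and the resolved
#'   `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- resolve_pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  log_msg <- function(...) message(sprintf("[interactomeScan] %s", sprintf(...)))
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
        class = c(class(e)[1L], "error", "condition")))
    })
  }

  in_path <- function(name, default) {
    cfg$inputs[[name]] %||% file.path(cfg$outdir, default)
  }

  if ("simulate" %in% cfg$stages) {
    log_msg("simulate: seed %d", cfg$seed)
    sim <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
    with_stage("simulate", simulate_dataset(sim, outdir = cfg$outdir))
    paths$simulated <- file.path(cfg$outdir,
                                 c("gwas.tsv", "genes.bed", "ld.tsv",
                                   "sets.gmt", "mask.bed", "evidence.tsv"))
  }

  curated <- NULL
  if ("curate" %in% cfg$stages) {
    ev_path <- in_path("evidence", "evidence.tsv")
    log_msg("curate: %s", ev_path)
    curated <- with_stage("curate", {
      ev <- read_evidence_table(ev_path)
      cur <- curate_interactome(ev, cfg$curation_name %||% "CURATED")
      write_gene_sets(cur, file.path(cfg$outdir, "curated.gmt"))
      cur
    })
    paths$curated <- file.path(cfg$outdir, "curated.gmt")
  }

  result <- NULL
  sens <- NULL
  need_data <- any(c("map", "enrich", "sensitivity") %in% cfg$stages)
  if (need_data) {
    dat <- with_stage("read-inputs", list(
      gwas = read_gwas_summary(in_path("gwas", "gwas.tsv")),
      genes = read_gene_annotation(in_path("genes", "genes.bed")),
      ld = read_ld_table(in_path("ld", "ld.tsv")),
      sets = read_gene_sets(in_path("sets", "sets.gmt")),
      mask = read_region_mask(in_path("mask", "mask.bed"))))
    e <- cfg$enrichment
    ecfg <- enrichment_config(pcut = e$pcut, n_replicates = e$n_replicates,
                              n_studies = e$n_studies,
                              alpha_category = e$alpha_category,
                              seed = cfg$seed, size_weighted = e$size_weighted)
    if ("map" %in% cfg$stages) {
      log_msg("map: pcut %g, window %d bp", e$pcut, e$window_bp)
      for (variant in c("unmasked", "masked")) {
        sg <- with_stage("map",
          significant_genes(dat$gwas, dat$genes, dat$ld,
                            mask = if (variant == "masked") dat$mask,
                            pcut = e$pcut, window_bp = e$window_bp,
                            r2_max = e$r2_max, dist_bp = e$dist_bp))
        f <- file.path(cfg$outdir, sprintf("siglist_%s.tsv", variant))
        utils::write.table(as.data.frame(sg$sig), f, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        paths[[paste0("siglist_", variant)]] <- f
      }
    }
    if ("enrich" %in% cfg$stages) {
      log_msg("enrich: B = %d, S = %d, seed %d",
              ecfg$n_replicates, ecfg$n_studies, ecfg$seed)
      out_tsv <- file.path(cfg$outdir, "results.tsv")
      result <- with_stage("enrich",
        run_enrichment(dat$gwas, dat$genes, dat$ld, dat$sets, ecfg,
                       mask = dat$mask, out = out_tsv,
                       window_bp = e$window_bp, r2_max = e$r2_max,
                       dist_bp = e$dist_bp))
      paths$results <- out_tsv
      ## study-wide summary + resolved config into the run log
      jsonlite::write_json(
        list(config = cfg,
             study = lapply(result$study, function(s)
               s[c("observed_n_significant", "expected_n_significant", "study_p")])),
        file.path(cfg$outdir, "run_log.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      paths$run_log <- file.path(cfg$outdir, "run_log.json")
    }
    if ("sensitivity" %in% cfg$stages) {
      s <- cfg$sensitivity
      log_msg("sensitivity: pcuts %s", paste(s$pcuts, collapse = ", "))
      sens <- with_stage("sensitivity",
        sensitivity_scan(dat$gwas, dat$genes, dat$ld, dat$sets, ecfg,
                         mask = dat$mask, pcuts = s$pcuts,
                         all_sets = s$all_sets, window_bp = e$window_bp,
                         r2_max = e$r2_max, dist_bp = e$dist_bp))
      f <- file.path(cfg$outdir, "sensitivity.tsv")
      utils::write.table(sens, f, sep = "\t", quote = FALSE, row.names = FALSE)
      paths$sensitivity <- f
    }
  }
  invisible(list(results = result$results, study = result$study,
                 sensitivity = sens, curated = curated,
                 paths = paths, config = cfg))
}

## Validate and fill in the pipeline configuration; errors are config errors
## naming the offending field.
resolve_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_config("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a YAML file path or a list")
  for (f in c("outdir", "seed"))
    if (is.null(config[[f]])) stop_config("config missing required field '", f, "'")
  if (!is.numeric(config$seed) || config$seed != floor(config$seed))
    stop_config("config field 'seed' must be an integer")
  all_stages <- c("simulate", "curate", "map", "enrich", "sensitivity")
  stages <- config$stages %||% all_stages
  if ("all" %in% stages) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L)
    stop_config("config field 'stages': unknown stage(s) ",
                paste(bad, collapse = ", "))
  e_defaults <- list(pcut = 0.05, n_replicates = 5000, n_studies = 1000,
                     alpha_category = 0.05, size_weighted = TRUE,
                     window_bp = 20000, r2_max = 0.2, dist_bp = 1e6)
  e <- utils::modifyList(e_defaults, config$enrichment %||% list())
  unknown <- setdiff(names(e), names(e_defaults))
  if (length(unknown) > 0L)
    stop_config("config field 'enrichment': unknown option(s) ",
                paste(unknown, collapse = ", "))
  s_defaults <- list(pcuts = c(0.005, 0.03, 0.05), all_sets = FALSE)
  s <- utils::modifyList(s_defaults, config$sensitivity %||% list())
  s$pcuts <- as.numeric(unlist(s$pcuts))
  list(outdir = config$outdir, seed = as.integer(config$seed),
       stages = stages, sim = config$sim %||% list(),
       inputs = config$inputs %||% list(),
       curation_name = config$curation_name,
       enrichment = e, sensitivity = s)
}
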