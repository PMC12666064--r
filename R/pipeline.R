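# End-to-end pipeline: simulate -> build db -> qc -> score ->
# cell-type tests -> power sweep -> bulk DE -> classify, with a
# reproducibility manifest (config snapshot, derived seeds, checksums).

PIPELINE_SECTIONS <- c("synthetic_data", "drug_db", "qc", "scoring",
                       "celltype_stats", "perturb_sim", "bulk_de",
                       "classify_eval")

#' Default pipeline configuration
#'
#' A nested list with one section per stage; any entry can be overridden
#' before passing the config to [run_pipeline()]. All randomness derives
#' from the single master `seed`.
#'
#' @param seed Master seed.
#' @return Named list of stage sections.
#' @export
default_pipeline_config <- function(seed = 42) {
  list(
    seed = as.integer(seed),
    synthetic_data = list(n_genes = 2000, n_samples = 24,
                          cells_per_sample = 500),
    drug_db = list(n_toxic = 40, n_nontoxic = 120,
                   toxic_target_enrichment = 0.7,
                   susceptible_type = "Endothelium"),
    qc = list(min_umi = 500, min_genes = 250,
              min_log10_genes_per_umi = 0.85, min_cells_per_gene = 10,
              scale_factor = 10000, n_hvg = 2000),
    scoring = list(pseudocount = 1e-9),
    celltype_stats = list(levels = c("abstract", "detailed")),
    perturb_sim = list(sample_fraction = 0.10,
                       response_rates = c(0.3, 0.8, 0.95),
                       effect_sizes = 10^seq(-3, 1, length.out = 9),
                       mediator = "Endothelium", level = "abstract",
                       alpha = 0.05, fdr = TRUE),
    bulk_de = list(n_drugs = 80, reps_per_drug = 3, n_genes = 500,
                   toxic_fraction = 0.25, effect_genes = 10,
                   effect_logfc = 2, p_threshold = 0.05,
                   lfc_threshold = 1.0),
    classify_eval = list(models = c("logistic", "boosted_trees"),
                         split_fraction = 0.8, n_bootstrap = 200)
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with the sections of
#'   [default_pipeline_config()].
#' @return Config list (validated by [run_pipeline()]).
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop("config must be a list")
  missing_sections <- setdiff(PIPELINE_SECTIONS, names(config))
  if (length(missing_sections)) {
    stop("config section '", missing_sections[1], "' is missing",
         if (length(missing_sections) > 1) {
       paste0(" (also: ", paste(missing_sections[-1], collapse = ", "), ")")
         } else "")
  }
  if (is.null(config$seed)) stop("config field 'seed' is missing")
  invisible(config)
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order on synthetic inputs, writes
#' every stage output as TSV/MTX under `outdir`, and returns a run
#' manifest (config snapshot, per-stage seeds, md5 checksums of every
#' output file, timestamps, package version). Re-running with the same
#' config reproduces all outputs checksum-identically.
#'
#' @param config Config list (see [default_pipeline_config()]) or a path
#'   to a YAML file.
#' @param outdir Output directory.
#' @return The manifest, invisibly; also written to
#'   `manifest.yaml` in `outdir`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  t0 <- Sys.time()

  # synthetic population + drug panel
  sd_cfg <- config$synthetic_data
  cfg <- do.call(synth_config, c(sd_cfg, list(seed = derive_seed(seed, 11))))
  population <- generate_cell_population(cfg)
  write_counts_mtx(population, file.path(outdir, "counts"))

  panel_cfg <- do.call(drug_panel_config,
                       c(config$drug_db, list(seed = derive_seed(seed, 12))))
  db <- generate_drug_panel(panel_cfg, population)
  write_drug_db(db, file.path(outdir, "drug_db.tsv"))

  # qc + normalization
  thr <- do.call(qc_thresholds, config$qc)
  qc <- run_qc(population, thr)
  write_tsv_file(qc$report, file.path(outdir, "qc_report.tsv"))

  # drug scoring
  scores <- log_transform_scores(score_drugs(qc$data, db),
                                 pseudocount = config$scoring$pseudocount)

  # cell-type statistics at both levels
  labels <- drug_labels(db)
  ct_tables <- list()
  for (lvl in config$celltype_stats$levels) {
    ct <- aggregate_by_celltype(scores, level = lvl)
    ct_tables[[lvl]] <- ct
    res <- test_celltypes(ct, labels)
    write_celltype_test(res, file.path(outdir,
                                       sprintf("celltype_test_%s.tsv", lvl)))
  }

  # dilution power sweep
  ps <- config$perturb_sim
  scfg <- sim_config(sample_fraction = ps$sample_fraction,
                     response_rates = ps$response_rates,
                     effect_sizes = ps$effect_sizes,
                     mediator = ps$mediator, level = ps$level,
                     alpha = ps$alpha, fdr = ps$fdr,
                     seed = derive_seed(seed, 13))
  sweep <- run_power_sweep(qc$data, scfg)
  write_tsv_file(as.data.frame(sweep), file.path(outdir, "power_sweep.tsv"))

  # bulk DE on synthetic signatures
  bd <- config$bulk_de
  bulk <- generate_bulk_signatures(n_drugs = bd$n_drugs,
                                   reps_per_drug = bd$reps_per_drug,
                                   n_genes = bd$n_genes,
                                   toxic_fraction = bd$toxic_fraction,
                                   effect_genes = bd$effect_genes,
                                   effect_logfc = bd$effect_logfc,
                                   seed = derive_seed(seed, 14))
  de <- bulk_differential_expression(bulk, p_threshold = bd$p_threshold,
                                     lfc_threshold = bd$lfc_threshold)
  write_tsv_file(as.data.frame(de), file.path(outdir, "bulk_de.tsv"))
  de_collapsed <- bulk_differential_expression(
    collapse_replicates(bulk), p_threshold = bd$p_threshold,
    lfc_threshold = bd$lfc_threshold)
  write_tsv_file(as.data.frame(de_collapsed),
                 file.path(outdir, "bulk_de_collapsed.tsv"))

  # classifiers on the abstract-level features
  ce <- config$classify_eval
  feats <- build_feature_table(ct_tables[[1]], labels)
  eval_res <- train_and_evaluate(feats, models = ce$models,
                                 split_fraction = ce$split_fraction,
                                 seed = derive_seed(seed, 15),
                                 n_bootstrap = ce$n_bootstrap)
  write_tsv_file(eval_res$reports, file.path(outdir, "classifier_reports.tsv"))

  outputs <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(outdir, "manifest.yaml"))
  checksums <- tools::md5sum(sort(outputs))
  names(checksums) <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1",
                                           outdir), "/?"), "", names(checksums))
  manifest <- list(
    package_version = as.character(utils::packageVersion("celltox")),
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = seed,
    stage_seeds = list(synthetic_data = derive_seed(seed, 11),
                       drug_db = derive_seed(seed, 12),
                       perturb_sim = derive_seed(seed, 13),
                       bulk_de = derive_seed(seed, 14),
                       classify_eval = derive_seed(seed, 15)),
    config = config,
    checksums = as.list(checksums))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
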