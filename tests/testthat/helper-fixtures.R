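# Shared fixtures and independent oracles, built in code at test time.

# Down-scaled generator config: same structure as the defaults, small
# enough for replicate loops.
small_cfg <- function(seed = 1, n_genes = 400, n_samples = 4,
                      cells_per_sample = 150, markers_per_type = 30, ...) {
  synth_config(n_genes = n_genes, n_samples = n_samples,
               cells_per_sample = cells_per_sample,
               markers_per_type = markers_per_type, seed = seed, ...)
}

# QC thresholds proportionate to the small config's library sizes.
small_thr <- function(...) {
  qc_thresholds(min_umi = 50, min_genes = 25, min_log10_genes_per_umi = 0.8,
                min_cells_per_gene = 3, n_hvg = 200, ...)
}

# Generator -> QC -> panel -> scores in one call for replicate loops.
small_run <- function(seed, enrichment = 0.7) {
  pop <- generate_cell_population(small_cfg(seed = seed))
  qc <- run_qc(pop, small_thr())
  db <- generate_drug_panel(
    drug_panel_config(toxic_target_enrichment = enrichment,
                      seed = seed + 20000), pop)
  scores <- log_transform_scores(score_drugs(qc$data, db))
  list(pop = pop, norm = qc$data, db = db, scores = scores)
}

# Independent largest-remainder oracle: explicit share/floor/sort steps.
lr_oracle <- function(weights, total) {
  share <- weights / sum(weights) * total
  out <- floor(share)
  left <- total - sum(out)
  rem <- share - out
  while (left > 0) {
    i <- which(rem == max(rem))[1]
    out[i] <- out[i] + 1
    rem[i] <- -1
    left <- left - 1
  }
  as.integer(out)
}

# Independent Benjamini-Hochberg oracle: sort, scale by m/i, cummin
# from the largest p, unsort.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  pmin(1, adj)[order(o)]
}

# Hand-built drug_scores object (logged matrix set directly) for
# aggregation/testing oracles.
fake_scores <- function(logged, abstract_type,
                        sample = rep("S01", nrow(logged)),
                        detailed_type = abstract_type) {
  structure(list(
    raw = exp(logged), logged = logged,
    drug_ids = colnames(logged),
    cell_ids = rownames(logged),
    cell_meta = data.frame(cell_id = rownames(logged), sample = sample,
                           abstract_type = abstract_type,
                           detailed_type = detailed_type,
                           stringsAsFactors = FALSE),
    detailed_to_abstract = NULL,
    coverage = stats::setNames(rep(1L, ncol(logged)), colnames(logged)),
    dropped_drugs = character(0), pseudocount = 1e-9),
    class = "drug_scores")
}

# Random sparse annotated counts with uniform annotations, for QC tests.
random_counts <- function(n_genes = 60, n_cells = 40, lambda = 2, seed = 7) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    m <- matrix(rpois(n_genes * n_cells, lambda), nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("c%03d", seq_len(n_cells))))
    meta <- data.frame(cell_id = colnames(m),
                       sample = rep(c("SA", "SB"), length.out = n_cells),
                       abstract_type = rep(c("T1", "T2"), length.out = n_cells),
                       detailed_type = rep(c("T1_1", "T2_1"), length.out = n_cells),
                       stringsAsFactors = FALSE)
    annotated_counts(m, meta)
  })
}

# A normalized_matrix with prescribed cell-type sizes, for the
# simulation-module tests; values are linear-ish (ln(1+x) of lognormal).
fixed_type_norm <- function(sizes = c(A = 800, B = 150, C = 50),
                            n_genes = 50, n_samples = 4, seed = 11) {
  set.seed(seed)
  n_cells <- sum(sizes)
  counts <- matrix(rpois(n_genes * n_cells, 5), nrow = n_genes,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                   sprintf("c%04d", seq_len(n_cells))))
  meta <- data.frame(
    cell_id = colnames(counts),
    sample = rep_len(sprintf("S%02d", seq_len(n_samples)), n_cells),
    abstract_type = rep(names(sizes), times = sizes),
    detailed_type = paste0(rep(names(sizes), times = sizes), "_1"),
    stringsAsFactors = FALSE)
  ac <- annotated_counts(counts, meta)
  log_normalize(ac, qc_thresholds(min_umi = 0, min_genes = 0,
                                  min_log10_genes_per_umi = 0,
                                  min_cells_per_gene = 0))
}
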