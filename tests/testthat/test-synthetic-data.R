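# Synthetic population, drug panel and bulk signature generators.

test_that("per-sample abstract composition equals largest-remainder quotas", {
  cfg <- synth_config(n_samples = 1, cells_per_sample = 500, seed = 3)
  pop <- generate_cell_population(cfg)
  tab <- table(pop$cell_meta$abstract_type)
  expect_equal(as.integer(tab[c("Nephron", "Endothelium", "Immune", "Stroma")]),
               c(412L, 39L, 36L, 13L))
  # every sample of a multi-sample run carries the identical quota
  pop4 <- generate_cell_population(small_cfg(seed = 5))
  per_sample <- table(pop4$cell_meta$sample, pop4$cell_meta$abstract_type)
  quota <- lr_oracle(cfg$abstract_prevalences, 150)
  for (s in rownames(per_sample)) {
    expect_equal(as.integer(per_sample[s, c("Nephron", "Endothelium",
                                            "Immune", "Stroma")]), quota)
  }
})

test_that("largest_remainder matches the explicit share/floor/sort oracle", {
  set.seed(42)
  for (i in 1:50) {
    w <- runif(sample(2:8, 1), 0.01, 5)
    n <- sample(1:500, 1)
    expect_equal(largest_remainder(w, n), lr_oracle(w, n))
    expect_equal(sum(largest_remainder(w, n)), n)
  }
})

test_that("generation is deterministic for a fixed config and seed", {
  cfg <- small_cfg(seed = 9)
  a <- generate_cell_population(cfg)
  b <- generate_cell_population(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$cell_meta, b$cell_meta)
  expect_identical(a$marker_genes, b$marker_genes)
})

test_that("detailed labels nest inside abstract labels", {
  pop <- generate_cell_population(small_cfg(seed = 2))
  pairs <- unique(pop$cell_meta[, c("detailed_type", "abstract_type")])
  expect_equal(anyDuplicated(pairs$detailed_type), 0L)
  expect_true(all(pop$detailed_to_abstract[pairs$detailed_type] ==
                    pairs$abstract_type))
})

test_that("with marker_fold = 1 marker genes show no cell-type signal", {
  # one large sample so even the rarest type has enough cells for the
  # t-approximation to hold in the far tail
  pop <- generate_cell_population(small_cfg(seed = 17, marker_fold = 1.0,
                                            n_samples = 1,
                                            cells_per_sample = 1500))
  counts <- as.matrix(pop$counts)
  types <- pop$cell_meta$abstract_type
  pvals <- unlist(lapply(names(pop$marker_genes), function(tp) {
    sapply(pop$marker_genes[[tp]], function(g) {
      stats::t.test(counts[g, types == tp], counts[g, types != tp])$p.value
    })
  }))
  expect_gte(mean(pvals >= 0.001), 0.99)
})

test_that("invalid generator configs are rejected", {
  expect_error(synth_config(n_genes = 100, markers_per_type = 30),
               "markers_per_type")
  expect_error(synth_config(abstract_prevalences = c(0.5, 0.5, 0, 0)),
               "positive")
  expect_error(synth_config(detailed_split = c(Nephron = 0, Endothelium = 5,
                                               Immune = 5, Stroma = 2)),
               "detailed subtype")
  # renormalized prevalences sum to one
  cfg <- synth_config()
  expect_equal(sum(cfg$abstract_prevalences), 1, tolerance = 1e-12)
  expect_equal(sum(cfg$detailed_split), 32L)
})

test_that("drug panel echoes configured sizes and plants enrichment", {
  pop <- generate_cell_population(small_cfg(seed = 4))
  db <- generate_drug_panel(drug_panel_config(seed = 8), pop)
  expect_equal(sum(db$label == "toxic"), 40L)
  expect_equal(sum(db$label == "nontoxic"), 120L)
  expect_true(all(lengths(db$targets) >= 1))
  expect_true(all(unlist(db$targets) %in% pop$gene_ids))

  # forced construction: a single toxic drug with one fully enriched target
  db1 <- generate_drug_panel(
    drug_panel_config(n_toxic = 1, n_nontoxic = 2, targets_min = 1,
                      targets_max = 1, toxic_target_enrichment = 1,
                      seed = 10), pop)
  tox_target <- db1$targets[[which(db1$label == "toxic")]]
  expect_length(tox_target, 1)
  expect_true(tox_target %in% pop$marker_genes$Endothelium)

  # enrichment 0 -> every target avoids every marker set
  db0 <- generate_drug_panel(
    drug_panel_config(toxic_target_enrichment = 0, seed = 11), pop)
  expect_length(intersect(unlist(db0$targets),
                          unlist(pop$marker_genes)), 0)
})

test_that("panel generation errors without markers or susceptible type", {
  pop <- generate_cell_population(small_cfg(seed = 4))
  bare <- annotated_counts(pop$counts, pop$cell_meta)
  expect_error(generate_drug_panel(drug_panel_config(seed = 1), bare),
               "no marker genes")
  expect_error(generate_drug_panel(
    drug_panel_config(susceptible_type = "Podocyte", seed = 1), pop),
    "not present")
})

test_that("bulk signatures have replicate structure and planted effects", {
  bulk <- generate_bulk_signatures(n_drugs = 10, reps_per_drug = 3,
                                   n_genes = 50, toxic_fraction = 0.3,
                                   effect_genes = 0, seed = 5)
  expect_equal(nrow(bulk$values), 30)
  expect_true(all(grepl("^DRUG[0-9]+_rep[123]$", bulk$sample_ids)))
  expect_error(generate_bulk_signatures(n_genes = 5, effect_genes = 10),
               "effect_genes")

  # null: no planted effect anywhere -> the joint p/LFC filter fires on
  # essentially nothing across seeds
  n_sig <- sapply(1:10, function(s) {
    b <- generate_bulk_signatures(n_drugs = 40, reps_per_drug = 2,
                                  n_genes = 200, toxic_fraction = 0.25,
                                  effect_logfc = 0, seed = s)
    sum(bulk_differential_expression(b)$significant)
  })
  expect_gte(mean(n_sig == 0), 0.95)
})
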