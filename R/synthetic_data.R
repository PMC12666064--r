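# Synthetic inputs: annotated single-cell counts with a kidney-like
# composition, drug panels with planted toxicity signal, and
# replicate-structured bulk signature matrices.

ABSTRACT_TYPES <- c("Nephron", "Endothelium", "Immune", "Stroma")

#' Configuration for the synthetic single-cell generator
#'
#' Defaults emulate the composition of an integrated healthy-kidney
#' single-cell dataset: 24 samples, four abstract cell types at
#' prevalences of roughly 82.4/7.8/7.1/2.6 percent (renormalized to sum
#' to one), with 32 nested detailed subtypes. Counts are drawn from a
#' negative-binomial model: per-gene log-normal base means, per-type
#' marker genes inflated by `marker_fold`, a per-sample per-gene
#' log-normal factor (donor effect, `sample_effect_logsd`), and a
#' per-cell log-normal library-size factor.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (donors).
#' @param cells_per_sample Cells generated per sample.
#' @param abstract_prevalences Four positive fractions, renormalized to sum
#'   to one; ordered as Nephron, Endothelium, Immune, Stroma.
#' @param detailed_split Named integer vector: number of nested detailed
#'   subtypes per abstract type (defaults total 32).
#' @param markers_per_type Marker genes assigned to each abstract type.
#' @param marker_fold Multiplier applied to a type's marker-gene means in
#'   cells of that type.
#' @param nb_dispersion Negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2).
#' @param library_size_logsd Log-sd of the per-cell library-size factor.
#' @param sample_effect_logsd Log-sd of the per-sample per-gene factor;
#'   this is the between-donor variance that makes pseudo-bulk testing
#'   realistically noisy.
#' @param base_mean_log Mean of log base expression (log scale).
#' @param base_mean_logsd Sd of log base expression.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000,
                         n_samples = 24,
                         cells_per_sample = 500,
                         abstract_prevalences = c(0.824, 0.078, 0.071, 0.026),
                         detailed_split = c(Nephron = 20, Endothelium = 5,
                                            Immune = 5, Stroma = 2),
                         markers_per_type = 50,
                         marker_fold = 3.0,
                         nb_dispersion = 0.5,
                         library_size_logsd = 0.3,
                         sample_effect_logsd = 0.8,
                         base_mean_log = log(0.5),
                         base_mean_logsd = 1.0,
                         seed = 42) {
  if (length(abstract_prevalences) != length(ABSTRACT_TYPES)) {
    stop("abstract_prevalences must have ", length(ABSTRACT_TYPES), " entries")
  }
  if (any(abstract_prevalences <= 0)) stop("prevalences must be strictly positive")
  if (is.null(names(detailed_split))) names(detailed_split) <- ABSTRACT_TYPES
  if (!setequal(names(detailed_split), ABSTRACT_TYPES)) {
    stop("detailed_split must be named by the abstract types")
  }
  if (any(detailed_split < 1)) stop("each abstract type needs >= 1 detailed subtype")
  stopifnot(n_genes >= 1, n_samples >= 1, cells_per_sample >= 1,
            markers_per_type >= 0, marker_fold > 0, nb_dispersion > 0,
            library_size_logsd > 0, sample_effect_logsd >= 0)
  if (markers_per_type * length(ABSTRACT_TYPES) > n_genes) {
    stop("markers_per_type x number of types exceeds n_genes")
  }
  prev <- abstract_prevalences / sum(abstract_prevalences)
  names(prev) <- ABSTRACT_TYPES
  structure(list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    cells_per_sample = as.integer(cells_per_sample),
    abstract_prevalences = prev,
    detailed_split = as.integer(detailed_split[ABSTRACT_TYPES]) |>
      stats::setNames(ABSTRACT_TYPES),
    markers_per_type = as.integer(markers_per_type),
    marker_fold = marker_fold, nb_dispersion = nb_dispersion,
    library_size_logsd = library_size_logsd,
    sample_effect_logsd = sample_effect_logsd,
    base_mean_log = base_mean_log, base_mean_logsd = base_mean_logsd,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Generate an annotated single-cell count population
#'
#' Per-sample abstract-type composition follows deterministic
#' largest-remainder quotas of the (renormalized) prevalences, so realized
#' per-sample proportions equal the quota proportions exactly. Detailed
#' subtypes are assigned uniformly within each abstract type. Counts are
#' negative-binomial around means built from per-gene base expression,
#' marker-fold inflation, per-sample donor factors and per-cell library
#' sizes.
#'
#' @param cfg A [synth_config()].
#' @return An `annotated_counts` object: sparse `counts` (genes x cells),
#'   `gene_ids`, `cell_ids`, a `cell_meta` data.frame with `cell_id`,
#'   `sample`, `abstract_type`, `detailed_type`, a `detailed_to_abstract`
#'   named character vector, and `marker_genes` (list of marker gene ids
#'   per abstract type — generator truth used to plant drug-panel signal).
#' @export
generate_cell_population <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    types <- ABSTRACT_TYPES
    # detailed subtype labels "<Abstract>_k", nested within abstract types
    detailed_names <- unlist(lapply(types, function(tp) {
      sprintf("%s_%d", tp, seq_len(cfg$detailed_split[[tp]]))
    }))
    detailed_to_abstract <- stats::setNames(
      rep(types, times = cfg$detailed_split[types]), detailed_names)

    marker_pool <- sample(gene_ids, cfg$markers_per_type * length(types))
    marker_genes <- split(marker_pool,
                          rep(types, each = cfg$markers_per_type))[types]

    base_mean <- stats::rlnorm(cfg$n_genes, cfg$base_mean_log, cfg$base_mean_logsd)
    names(base_mean) <- gene_ids
    size <- 1 / cfg$nb_dispersion

    quota <- largest_remainder(cfg$abstract_prevalences, cfg$cells_per_sample)
    type_of_cell <- rep(types, times = quota)

    blocks <- vector("list", cfg$n_samples)
    meta <- vector("list", cfg$n_samples)
    for (s in seq_len(cfg$n_samples)) {
      sample_id <- sprintf("S%02d", s)
      sfac <- stats::rlnorm(cfg$n_genes, 0, cfg$sample_effect_logsd)
      lib <- stats::rlnorm(cfg$cells_per_sample, 0, cfg$library_size_logsd)
      detailed <- vapply(type_of_cell, function(tp) {
        k <- cfg$detailed_split[[tp]]
        sprintf("%s_%d", tp, sample.int(k, 1))
      }, character(1))
      mu <- (base_mean * sfac) %o% lib
      for (tp in types) {
        idx <- which(type_of_cell == tp)
        if (length(idx) && cfg$markers_per_type > 0) {
          mu[marker_genes[[tp]], idx] <- mu[marker_genes[[tp]], idx] * cfg$marker_fold
        }
      }
      cnt <- stats::rnbinom(length(mu), size = size, mu = mu)
      dim(cnt) <- dim(mu)
      blocks[[s]] <- methods::as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix")
      meta[[s]] <- data.frame(
        cell_id = sprintf("%s_C%04d", sample_id, seq_len(cfg$cells_per_sample)),
        sample = sample_id,
        abstract_type = type_of_cell,
        detailed_type = detailed,
        stringsAsFactors = FALSE)
    }
    counts <- do.call(cbind, blocks)
    cell_meta <- do.call(rbind, meta)
    rownames(counts) <- gene_ids
    colnames(counts) <- cell_meta$cell_id
    annotated_counts(counts, cell_meta,
                     detailed_to_abstract = detailed_to_abstract,
                     marker_genes = marker_genes)
  })
}

#' Construct an annotated counts object
#'
#' @param counts Non-negative integer matrix (genes x cells), dense or sparse;
#'   rownames are gene ids, colnames cell ids.
#' @param cell_meta data.frame with columns `cell_id`, `sample`,
#'   `abstract_type`, `detailed_type` (detailed may be NA for data annotated
#'   at one level only).
#' @param detailed_to_abstract Optional named character vector mapping each
#'   detailed label to its abstract label; inferred from `cell_meta` when
#'   omitted. Every detailed label must map to exactly one abstract label.
#' @param marker_genes Optional list of marker gene ids per abstract type.
#' @return An `annotated_counts` object.
#' @export
annotated_counts <- function(counts, cell_meta, detailed_to_abstract = NULL,
                             marker_genes = NULL) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  gene_ids <- rownames(counts)
  cell_ids <- colnames(counts)
  if (is.null(gene_ids) || anyDuplicated(gene_ids)) {
    stop("counts must carry unique gene ids as rownames")
  }
  if (is.null(cell_ids) || anyDuplicated(cell_ids)) {
    stop("counts must carry unique cell ids as colnames")
  }
  need <- c("cell_id", "sample", "abstract_type", "detailed_type")
  if (!all(need %in% names(cell_meta))) {
    stop("cell_meta must have columns: ", paste(need, collapse = ", "))
  }
  if (!identical(cell_meta$cell_id, cell_ids)) {
    stop("cell_meta rows must align with the columns of counts")
  }
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (is.null(detailed_to_abstract)) {
    pairs <- unique(cell_meta[!is.na(cell_meta$detailed_type),
                              c("detailed_type", "abstract_type")])
    detailed_to_abstract <- stats::setNames(pairs$abstract_type, pairs$detailed_type)
  }
  obs <- cell_meta[!is.na(cell_meta$detailed_type), ]
  if (nrow(obs)) {
    mapped <- unname(detailed_to_abstract[obs$detailed_type])
    if (anyNA(mapped) || !all(mapped == obs$abstract_type)) {
      stop("each detailed label must map to exactly one abstract label")
    }
  }
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta,
                 detailed_to_abstract = detailed_to_abstract,
                 marker_genes = marker_genes),
            class = "annotated_counts")
}

#' @export
print.annotated_counts <- function(x, ...) {
  cat(sprintf("annotated_counts: %d genes x %d cells, %d samples\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample))))
  tab <- table(x$cell_meta$abstract_type)
  cat("abstract composition:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.annotated_counts <- function(x) dim(x$counts)

#' Configuration for the synthetic drug panel
#'
#' Emulates a curated drug-target panel with planted signal: toxic drugs
#' draw a fraction of their target genes from the marker genes of a
#' designated susceptible cell type; all remaining targets (and all targets
#' of non-toxic drugs) come uniformly from non-marker genes.
#'
#' @param n_toxic,n_nontoxic Panel sizes.
#' @param targets_min,targets_max Per-drug target count range (uniform).
#' @param toxic_target_enrichment Fraction of toxic-drug targets drawn from
#'   the susceptible type's markers (in `[0, 1]`).
#' @param susceptible_type Cell-type label whose markers carry the signal.
#' @param seed Integer seed.
#' @return An object of class `drug_panel_config`.
#' @export
drug_panel_config <- function(n_toxic = 40, n_nontoxic = 120,
                              targets_min = 1, targets_max = 5,
                              toxic_target_enrichment = 0.7,
                              susceptible_type = "Endothelium",
                              seed = 42) {
  stopifnot(n_toxic >= 1, n_nontoxic >= 1,
            targets_min >= 1, targets_max >= targets_min,
            toxic_target_enrichment >= 0, toxic_target_enrichment <= 1)
  structure(list(n_toxic = as.integer(n_toxic),
                 n_nontoxic = as.integer(n_nontoxic),
                 targets_min = as.integer(targets_min),
                 targets_max = as.integer(targets_max),
                 toxic_target_enrichment = toxic_target_enrichment,
                 susceptible_type = susceptible_type,
                 seed = as.integer(seed)),
            class = "drug_panel_config")
}

#' Generate a drug panel with planted toxicity signal
#'
#' @param cfg A [drug_panel_config()].
#' @param population An `annotated_counts` with `marker_genes` metadata
#'   (required whenever `toxic_target_enrichment > 0`).
#' @return A `drug_db` table (see [build_drug_database()]): one row per drug
#'   with its target-gene set and toxic/nontoxic label.
#' @export
generate_drug_panel <- function(cfg, population) {
  stopifnot(inherits(cfg, "drug_panel_config"),
            inherits(population, "annotated_counts"))
  types <- unique(c(population$cell_meta$abstract_type,
                    population$cell_meta$detailed_type))
  if (!cfg$susceptible_type %in% types) {
    stop("susceptible_type '", cfg$susceptible_type,
         "' not present in the population annotations")
  }
  markers <- population$marker_genes[[cfg$susceptible_type]]
  if (cfg$toxic_target_enrichment > 0 && length(markers) == 0) {
    stop("enrichment requested but the susceptible type has no marker genes")
  }
  all_markers <- unique(unlist(population$marker_genes))
  nonmarker <- setdiff(population$gene_ids, all_markers)
  if (length(nonmarker) == 0) stop("no non-marker genes available for target draws")
  with_seed(cfg$seed, {
    n <- cfg$n_toxic + cfg$n_nontoxic
    drug_id <- c(sprintf("tox%03d", seq_len(cfg$n_toxic)),
                 sprintf("ntx%03d", seq_len(cfg$n_nontoxic)))
    label <- rep(c("toxic", "nontoxic"), c(cfg$n_toxic, cfg$n_nontoxic))
    k <- if (cfg$targets_max > cfg$targets_min) {
      sample(seq(cfg$targets_min, cfg$targets_max), n, replace = TRUE)
    } else rep(cfg$targets_min, n)
    targets <- vector("list", n)
    for (i in seq_len(n)) {
      if (label[i] == "toxic") {
        n_m <- stats::rbinom(1, k[i], cfg$toxic_target_enrichment)
        n_m <- min(n_m, length(markers))
        tg <- c(sample(markers, n_m),
                sample(nonmarker, k[i] - n_m))
      } else {
        tg <- sample(nonmarker, k[i])
      }
      targets[[i]] <- sort(unique(tg))
    }
    new_drug_db(data.frame(drug_id = drug_id, label = label,
                           label_sources = "synthetic",
                           target_sources = "synthetic",
                           approval_status = "approved",
                           stringsAsFactors = FALSE),
                targets)
  })
}

#' Generate a replicate-structured bulk signature matrix
#'
#' Emulates an already-normalized bulk signature matrix (samples x genes)
#' with replicate-encoded sample ids (`DRUG001_rep1`, ...): standard-normal
#' noise per sample x gene, with toxic-drug samples shifted by
#' `effect_logfc` on the first `effect_genes` genes.
#'
#' @param n_drugs Number of drugs.
#' @param reps_per_drug Replicates per drug.
#' @param n_genes Number of genes.
#' @param toxic_fraction Fraction of drugs labeled toxic.
#' @param effect_genes Number of genes carrying the planted shift.
#' @param effect_logfc Shift added to toxic samples on the planted genes.
#' @param seed Integer seed.
#' @return A `bulk_signatures` object: `values` (samples x genes),
#'   `sample_ids`, `drug_of_sample`, `gene_ids`, `drug_labels` (named
#'   toxic/nontoxic per drug), `effect_gene_ids`.
#' @export
generate_bulk_signatures <- function(n_drugs = 80, reps_per_drug = 3,
                                     n_genes = 500, toxic_fraction = 0.25,
                                     effect_genes = 10, effect_logfc = 0,
                                     seed = 42) {
  stopifnot(n_drugs >= 2, reps_per_drug >= 1, n_genes >= 1,
            toxic_fraction > 0, toxic_fraction < 1, effect_genes >= 0)
  if (effect_genes > n_genes) stop("effect_genes exceeds n_genes")
  with_seed(seed, {
    drugs <- sprintf("DRUG%03d", seq_len(n_drugs))
    n_toxic <- max(1L, round(toxic_fraction * n_drugs))
    labels <- stats::setNames(
      rep(c("toxic", "nontoxic"), c(n_toxic, n_drugs - n_toxic)), drugs)
    sample_ids <- as.vector(t(outer(drugs, seq_len(reps_per_drug),
                                    function(d, r) sprintf("%s_rep%d", d, r))))
    drug_of_sample <- rep(drugs, each = reps_per_drug)
    gene_ids <- sprintf("BG%04d", seq_len(n_genes))
    values <- matrix(stats::rnorm(length(sample_ids) * n_genes),
                     nrow = length(sample_ids),
                     dimnames = list(sample_ids, gene_ids))
    eff <- gene_ids[seq_len(effect_genes)]
    toxic_rows <- labels[drug_of_sample] == "toxic"
    if (effect_genes > 0 && effect_logfc != 0) {
      values[toxic_rows, eff] <- values[toxic_rows, eff] + effect_logfc
    }
    structure(list(values = values, sample_ids = sample_ids,
                   drug_of_sample = stats::setNames(drug_of_sample, sample_ids),
                   gene_ids = gene_ids, drug_labels = labels,
                   effect_gene_ids = if (effect_genes > 0) eff else character(0)),
              class = "bulk_signatures")
  })
}

#' @export
print.bulk_signatures <- function(x, ...) {
  cat(sprintf("bulk_signatures: %d samples x %d genes, %d drugs (%d toxic)\n",
              nrow(x$values), ncol(x$values), length(x$drug_labels),
              sum(x$drug_labels == "toxic")))
  invisible(x)
}
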