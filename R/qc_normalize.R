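# Cell/gene quality control, log-normalization and highly-variable-gene
# selection for annotated single-cell counts.

#' Quality-control thresholds
#'
#' Defaults follow standard single-cell best practice: cells need at least
#' 500 UMIs, at least 250 detected genes, and a novelty score
#' log10(genes)/log10(UMIs) strictly greater than 0.85; genes must be
#' detected in at least 10 cells. Normalization divides by the cell total,
#' multiplies by `scale_factor` (10,000) and takes ln(1 + x); the top
#' `n_hvg` (2000) genes by standardized variance are flagged as highly
#' variable.
#'
#' @param min_umi Minimum UMI count per cell (inclusive).
#' @param min_genes Minimum detected genes per cell (inclusive).
#' @param min_log10_genes_per_umi Novelty-score lower bound (exclusive).
#' @param min_cells_per_gene Minimum cells a gene must be detected in
#'   (inclusive).
#' @param scale_factor Normalization scale factor.
#' @param n_hvg Number of highly variable genes to flag.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_umi = 500, min_genes = 250,
                          min_log10_genes_per_umi = 0.85,
                          min_cells_per_gene = 10,
                          scale_factor = 10000, n_hvg = 2000) {
  stopifnot(min_umi >= 0, min_genes >= 0, min_log10_genes_per_umi >= 0,
            min_cells_per_gene >= 0, scale_factor > 0, n_hvg >= 1)
  structure(list(min_umi = min_umi, min_genes = min_genes,
                 min_log10_genes_per_umi = min_log10_genes_per_umi,
                 min_cells_per_gene = min_cells_per_gene,
                 scale_factor = scale_factor, n_hvg = as.integer(n_hvg)),
            class = "qc_thresholds")
}

subset_annotated <- function(x, genes = NULL, cells = NULL) {
  counts <- x$counts
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(cells)) counts <- counts[, cells, drop = FALSE]
  meta <- x$cell_meta[match(colnames(counts), x$cell_meta$cell_id), , drop = FALSE]
  rownames(meta) <- NULL
  annotated_counts(counts, meta,
                   detailed_to_abstract = x$detailed_to_abstract,
                   marker_genes = if (is.null(x$marker_genes)) NULL else
                     lapply(x$marker_genes, intersect, y = rownames(counts)))
}

#' Filter cells on UMI count, detected genes and novelty score
#'
#' A cell is kept when UMIs >= `min_umi`, detected genes >= `min_genes`,
#' and log10(detected genes)/log10(UMIs) > `min_log10_genes_per_umi`.
#'
#' @param data An `annotated_counts` object.
#' @param thr A [qc_thresholds()].
#' @return List with `data` (the filtered `annotated_counts`) and
#'   `removed`, the per-criterion removal counts (a cell failing several
#'   criteria is counted once under each).
#' @export
filter_cells <- function(data, thr = qc_thresholds()) {
  stopifnot(inherits(data, "annotated_counts"), inherits(thr, "qc_thresholds"))
  umi <- Matrix::colSums(data$counts)
  ngene <- Matrix::colSums(data$counts > 0)
  ratio <- ifelse(umi > 1 & ngene > 0, log10(ngene) / log10(umi), 0)
  fail_umi <- umi < thr$min_umi
  fail_genes <- ngene < thr$min_genes
  fail_ratio <- ratio <= thr$min_log10_genes_per_umi
  keep <- !(fail_umi | fail_genes | fail_ratio)
  if (!any(keep)) stop("empty after QC: all cells removed by the cell filters")
  removed <- c(min_umi = sum(fail_umi), min_genes = sum(fail_genes),
               min_log10_genes_per_umi = sum(fail_ratio))
  list(data = subset_annotated(data, cells = which(keep)), removed = removed)
}

#' Filter genes by detection frequency
#'
#' Keeps genes detected (nonzero) in at least `min_cells_per_gene` cells.
#' Apply after [filter_cells()] so presence is counted among surviving
#' cells.
#'
#' @inheritParams filter_cells
#' @return The filtered `annotated_counts`.
#' @export
filter_genes <- function(data, thr = qc_thresholds()) {
  stopifnot(inherits(data, "annotated_counts"), inherits(thr, "qc_thresholds"))
  ncell <- Matrix::rowSums(data$counts > 0)
  keep <- ncell >= thr$min_cells_per_gene
  if (!any(keep)) stop("empty after QC: all genes removed by the gene filter")
  subset_annotated(data, genes = which(keep))
}

#' Log-normalize counts
#'
#' value(g, c) = ln(1 + count(g, c) * scale_factor / total(c)); zeros stay
#' zero, so the result remains sparse.
#'
#' @inheritParams filter_cells
#' @return A `normalized_matrix` object carrying `values` (sparse
#'   genes x cells, natural-log scale), the source `counts` (used by
#'   [select_hvg()]), and the cell annotations.
#' @export
log_normalize <- function(data, thr = qc_thresholds()) {
  stopifnot(inherits(data, "annotated_counts"))
  totals <- Matrix::colSums(data$counts)
  if (any(totals == 0)) stop("cell with zero total counts; run filter_cells first")
  values <- data$counts
  values@x <- log1p(values@x * thr$scale_factor /
                      rep.int(totals, diff(values@p)))
  structure(list(values = values, counts = data$counts,
                 gene_ids = data$gene_ids, cell_ids = data$cell_ids,
                 cell_meta = data$cell_meta,
                 detailed_to_abstract = data$detailed_to_abstract,
                 marker_genes = data$marker_genes,
                 scale_factor = thr$scale_factor, hvg = NULL),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells (ln(1+x) scale)%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$hvg)) sprintf(", %d HVGs flagged", sum(x$hvg)) else ""))
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

# Standardized variance under a fitted mean-variance trend: per-gene mean
# and variance of raw counts; second-degree polynomial fit of log10(var)
# on log10(mean) over genes with positive variance gives the expected sd;
# counts standardized with that sd are clipped at sqrt(n_cells) and their
# variance is the ranking statistic.
vst_standardized_variance <- function(counts) {
  n <- ncol(counts)
  m <- Matrix::rowMeans(counts)
  ex2 <- Matrix::rowMeans(counts^2)
  v <- (ex2 - m^2) * n / (n - 1)
  fit_idx <- which(v > 0 & m > 0)
  if (length(fit_idx) < 3) stop("degenerate variance: not enough variable genes")
  lm_fit <- stats::lm(lv ~ lm10 + I(lm10^2),
                      data = data.frame(lv = log10(v[fit_idx]),
                                        lm10 = log10(m[fit_idx])))
  sd_exp <- rep(NA_real_, length(m))
  sd_exp[fit_idx] <- sqrt(10^stats::predict(
    lm_fit, newdata = data.frame(lm10 = log10(m[fit_idx]))))
  clip <- sqrt(n)

  tr <- methods::as(counts, "TsparseMatrix")
  g <- tr@i + 1L
  ok <- !is.na(sd_exp[g])
  g <- g[ok]
  z <- pmin((tr@x[ok] - m[g]) / sd_exp[g], clip)
  sum_z <- rowsum_by(z, g, length(m))
  sum_z2 <- rowsum_by(z^2, g, length(m))
  nnz <- rowsum_by(rep(1, length(g)), g, length(m))
  # zero entries standardize to -m/sd (never clipped upward)
  z0 <- ifelse(is.na(sd_exp), 0, pmin(-m / sd_exp, clip))
  n0 <- n - nnz
  tot <- sum_z + n0 * z0
  tot2 <- sum_z2 + n0 * z0^2
  std_var <- (tot2 - tot^2 / n) / (n - 1)
  std_var[is.na(sd_exp)] <- 0
  stats::setNames(std_var, rownames(counts))
}

rowsum_by <- function(x, idx, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Flag highly variable genes
#'
#' Ranks genes by variance-stabilized standardized variance (clipped
#' standardized counts under a polynomial mean-variance trend) and flags
#' the top `n_hvg`. If fewer than `n_hvg` genes are present, all are
#' flagged. Flags are advisory: downstream drug scoring uses all surviving
#' genes unless restricted explicitly.
#'
#' @param data A `normalized_matrix` from [log_normalize()].
#' @param thr A [qc_thresholds()].
#' @return `data` with a logical `hvg` flag per gene.
#' @export
select_hvg <- function(data, thr = qc_thresholds()) {
  stopifnot(inherits(data, "normalized_matrix"))
  n_genes <- nrow(data$values)
  if (n_genes <= thr$n_hvg) {
    data$hvg <- stats::setNames(rep(TRUE, n_genes), data$gene_ids)
    return(data)
  }
  sv <- vst_standardized_variance(data$counts)
  if (all(sv == 0)) stop("degenerate variance: all genes constant")
  ord <- order(-sv, seq_along(sv), method = "radix")
  flags <- rep(FALSE, n_genes)
  flags[ord[seq_len(thr$n_hvg)]] <- TRUE
  data$hvg <- stats::setNames(flags, data$gene_ids)
  data
}

#' Run the full QC and normalization stage
#'
#' [filter_cells()], [filter_genes()], [log_normalize()] and
#' [select_hvg()] chained, with a QC report.
#'
#' @inheritParams filter_cells
#' @return List with `data` (a `normalized_matrix` with HVG flags) and
#'   `report`, a data.frame of per-criterion removals and remaining
#'   dimensions.
#' @export
run_qc <- function(data, thr = qc_thresholds()) {
  n_cells0 <- ncol(data$counts); n_genes0 <- nrow(data$counts)
  fc <- filter_cells(data, thr)
  fg <- filter_genes(fc$data, thr)
  norm <- select_hvg(log_normalize(fg, thr), thr)
  report <- data.frame(
    criterion = c(names(fc$removed), "min_cells_per_gene"),
    removed = c(unname(fc$removed), n_genes0 - nrow(fg$counts)),
    remaining = c(rep(ncol(fc$data$counts), length(fc$removed)),
                  nrow(fg$counts)),
    unit = c(rep("cells", length(fc$removed)), "genes"),
    stringsAsFactors = FALSE)
  list(data = norm, report = report)
}
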