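# Per-cell drug scores: the mean log-normalized expression of each drug's
# target genes, followed by a natural-log transform.

#' Score drugs against a normalized expression matrix
#'
#' For every drug, the raw score of a cell is the arithmetic mean of the
#' log-normalized expression of the drug's target genes present in the
#' matrix (targets absent from the matrix are dropped; the per-drug count
#' of targets found is reported as `coverage`). Drugs with no target in
#' the matrix are removed with a warning.
#'
#' @param expr A `normalized_matrix` from [log_normalize()].
#' @param db A `drug_db` table.
#' @param restrict_hvg If `TRUE`, score only over genes flagged highly
#'   variable (default `FALSE`: all surviving genes are used).
#' @return A `drug_scores` object: `raw` (cells x drugs), `logged`
#'   (filled by [log_transform_scores()]), `drug_ids`, `cell_ids`,
#'   `cell_meta`, `coverage`, `dropped_drugs`.
#' @export
score_drugs <- function(expr, db, restrict_hvg = FALSE) {
  stopifnot(inherits(expr, "normalized_matrix"), inherits(db, "drug_db"))
  values <- expr$values
  if (restrict_hvg) {
    if (is.null(expr$hvg)) stop("restrict_hvg = TRUE but no HVG flags; run select_hvg()")
    values <- values[expr$hvg, , drop = FALSE]
  }
  gene_ids <- rownames(values)
  hits <- lapply(db$targets, intersect, y = gene_ids)
  coverage <- lengths(hits)
  keep <- coverage >= 1
  if (!any(keep)) {
    stop("zero drugs retained: no drug target matches the expression matrix ",
         "gene identifiers (symbol-vocabulary mismatch?)")
  }
  dropped <- db$drug_id[!keep]
  if (length(dropped)) {
    warning(length(dropped), " drug(s) dropped with no target in the matrix: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  drug_ids <- db$drug_id[keep]
  hits <- hits[keep]
  cov <- coverage[keep]
  # weight matrix genes x drugs with 1/coverage entries: raw = t(values) %*% W
  gi <- match(unlist(hits), gene_ids)
  di <- rep(seq_along(hits), times = cov)
  w <- Matrix::sparseMatrix(i = gi, j = di, x = 1 / cov[di],
                            dims = c(length(gene_ids), length(hits)),
                            dimnames = list(gene_ids, drug_ids))
  raw <- as.matrix(Matrix::crossprod(values, w))
  structure(list(raw = raw, logged = NULL,
                 drug_ids = drug_ids, cell_ids = expr$cell_ids,
                 cell_meta = expr$cell_meta,
                 detailed_to_abstract = expr$detailed_to_abstract,
                 coverage = stats::setNames(cov, drug_ids),
                 dropped_drugs = dropped, pseudocount = NULL),
            class = "drug_scores")
}

#' Natural-log transform of drug scores
#'
#' logged(c, d) = ln(raw(c, d) + pseudocount). Raw scores of zero occur
#' whenever a drug's targets are undetected in a cell, so a strictly
#' positive pseudocount is required.
#'
#' @param scores A `drug_scores` object.
#' @param pseudocount Strictly positive offset added before logging.
#' @return `scores` with the `logged` matrix filled and the pseudocount
#'   recorded.
#' @export
log_transform_scores <- function(scores, pseudocount = 1e-9) {
  stopifnot(inherits(scores, "drug_scores"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    stop("pseudocount must be a single positive number")
  }
  scores$logged <- log(scores$raw + pseudocount)
  scores$pseudocount <- pseudocount
  scores
}

#' @export
print.drug_scores <- function(x, ...) {
  cat(sprintf("drug_scores: %d cells x %d drugs%s\n",
              nrow(x$raw), ncol(x$raw),
              if (is.null(x$logged)) " (raw only)" else
                sprintf(" (logged, pseudocount %g)", x$pseudocount)))
  if (length(x$dropped_drugs)) {
    cat(length(x$dropped_drugs), "drugs dropped (no matching targets)\n")
  }
  invisible(x)
}

#' @export
dim.drug_scores <- function(x) dim(x$raw)
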