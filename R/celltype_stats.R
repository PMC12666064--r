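# Cell-type level aggregation of logged drug scores and toxic vs
# non-toxic testing at both annotation resolutions.

#' Aggregate logged drug scores to cell-type level
#'
#' score(t, d) = mean of logged(c, d) over cells c of type t, at the
#' requested annotation level; cell types are ordered alphabetically so
#' the table is deterministic.
#'
#' @param scores A `drug_scores` object with the logged matrix filled
#'   (see [log_transform_scores()]).
#' @param level `"abstract"` or `"detailed"`.
#' @return A `celltype_scores` object: `score` (celltypes x drugs),
#'   `n_cells_per_type`, `level`, `drug_ids`.
#' @export
aggregate_by_celltype <- function(scores, level = c("abstract", "detailed")) {
  stopifnot(inherits(scores, "drug_scores"))
  if (is.null(scores$logged)) stop("logged scores missing; run log_transform_scores()")
  level <- match.arg(level)
  col <- paste0(level, "_type")
  types <- scores$cell_meta[[col]]
  if (anyNA(types)) {
    bad <- scores$cell_meta$cell_id[is.na(types)]
    stop("cells without a ", level, " annotation: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "")
  }
  f <- factor(types, levels = sort(unique(types)))
  sums <- rowsum(scores$logged, f)
  n_per <- as.vector(table(f))
  structure(list(score = sums / n_per,
                 n_cells_per_type = stats::setNames(n_per, levels(f)),
                 level = level, drug_ids = scores$drug_ids,
                 detailed_to_abstract = scores$detailed_to_abstract),
            class = "celltype_scores")
}

#' @export
print.celltype_scores <- function(x, ...) {
  cat(sprintf("celltype_scores (%s level): %d cell types x %d drugs\n",
              x$level, nrow(x$score), ncol(x$score)))
  invisible(x)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up BH correction with monotonicity enforcement; input order is
#' preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (no NaN/NA).
#' @return Corrected p-values in the input order.
#' @export
fdr_correct <- function(p_values) {
  if (anyNA(p_values)) stop("NaN/NA p-values are not allowed")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Test toxic vs non-toxic drug scores per cell type
#'
#' For every cell type, a two-sample t-test (Welch by default) compares
#' the aggregated logged scores of toxic drugs against non-toxic drugs.
#' The log fold change is the difference of group means (toxic minus
#' non-toxic, natural-log scale); the fold change is its exponential, and
#' the 95% CI on the fold change exponentiates the t-test CI of the mean
#' difference. P-values are BH-corrected across the cell types of the
#' level and rows are sorted by raw p-value.
#'
#' @param table A `celltype_scores` object.
#' @param labels Named character vector (`toxic`/`nontoxic`) keyed by drug
#'   id, e.g. from [drug_labels()]; every drug in `table` must be labeled.
#' @param var_equal If `TRUE`, use the pooled-variance (Student) test
#'   instead of Welch.
#' @param conf_level Confidence level of the fold-change CI.
#' @return A `celltype_test` data.frame: `cell_type`, `level`,
#'   `t_statistic`, `log_fold_change`, `fold_change`, `ci_lower`,
#'   `ci_upper`, `p_value`, `p_corrected`, `n_toxic`, `n_nontoxic`.
#' @export
test_celltypes <- function(table, labels, var_equal = FALSE, conf_level = 0.95) {
  stopifnot(inherits(table, "celltype_scores"))
  lab <- labels[table$drug_ids]
  if (anyNA(lab)) {
    stop("unlabeled drugs: ",
         paste(utils::head(table$drug_ids[is.na(lab)], 5), collapse = ", "))
  }
  toxic <- lab == "toxic"
  if (sum(toxic) < 2 || sum(!toxic) < 2) {
    stop("each label group needs at least 2 drugs")
  }
  rows <- lapply(rownames(table$score), function(tp) {
    x <- table$score[tp, toxic]
    y <- table$score[tp, !toxic]
    tt <- stats::t.test(x, y, var.equal = var_equal, conf.level = conf_level)
    lfc <- mean(x) - mean(y)
    data.frame(cell_type = tp, level = table$level,
               t_statistic = unname(tt$statistic),
               log_fold_change = lfc, fold_change = exp(lfc),
               ci_lower = exp(tt$conf.int[1]), ci_upper = exp(tt$conf.int[2]),
               p_value = tt$p.value,
               n_toxic = sum(toxic), n_nontoxic = sum(!toxic),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- fdr_correct(out$p_value)
  out <- out[order(out$p_value, out$cell_type), ]
  out <- out[, c("cell_type", "level", "t_statistic", "log_fold_change",
                 "fold_change", "ci_lower", "ci_upper", "p_value",
                 "p_corrected", "n_toxic", "n_nontoxic")]
  rownames(out) <- NULL
  class(out) <- c("celltype_test", "data.frame")
  out
}

#' @export
print.celltype_test <- function(x, digits = 3, ...) {
  cat(sprintf("Cell-type toxic vs non-toxic drug-score tests (%s level, %d toxic vs %d non-toxic drugs)\n",
              x$level[1], x$n_toxic[1], x$n_nontoxic[1]))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df[, c("cell_type", "t_statistic", "log_fold_change",
                          "fold_change", "ci_lower", "ci_upper", "p_value",
                          "p_corrected")], row.names = FALSE)
  invisible(x)
}
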