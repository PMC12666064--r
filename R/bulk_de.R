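# Bulk signature processing: regex replicate collapsing and per-gene
# toxic vs non-toxic differential expression.

#' Collapse replicate samples by drug
#'
#' Sample ids are parsed with a regex whose first capturing group is the
#' drug name (default: everything before a trailing `_rep<k>`); replicate
#' rows of the same drug are averaged.
#'
#' @param bulk A `bulk_signatures` object (or a list with `values`
#'   samples x genes and rownames as sample ids).
#' @param pattern Regex with one capturing group for the drug id.
#' @return A `bulk_signatures` object with one row per drug.
#' @export
collapse_replicates <- function(bulk, pattern = "^(.*)_rep[0-9]+$") {
  values <- bulk$values
  ids <- rownames(values)
  m <- regmatches(ids, regexec(pattern, ids))
  bad <- ids[lengths(m) < 2]
  if (length(bad)) {
    stop("sample ids not matching the replicate pattern: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "")
  }
  drug <- vapply(m, `[`, character(1), 2)
  f <- factor(drug, levels = unique(drug))
  collapsed <- rowsum(values, f) / as.vector(table(f))
  collapsed <- collapsed[levels(f), , drop = FALSE]
  structure(list(values = collapsed, sample_ids = rownames(collapsed),
                 drug_of_sample = stats::setNames(rownames(collapsed),
                                                  rownames(collapsed)),
                 gene_ids = colnames(collapsed),
                 drug_labels = bulk$drug_labels,
                 effect_gene_ids = bulk$effect_gene_ids),
            class = "bulk_signatures")
}

#' Differential expression between toxic and non-toxic bulk samples
#'
#' Per-gene Welch t-tests between samples of toxic and non-toxic drugs;
#' the log2 fold change is the difference of group means (the signature
#' values are assumed to be log2 scale already). The significant set
#' requires both p < `p_threshold` and |log2FC| >= `lfc_threshold`.
#' BH-corrected p-values are reported and rows are sorted by p.
#'
#' @param bulk A `bulk_signatures` object.
#' @param labels Named toxic/nontoxic vector keyed by drug; defaults to the
#'   labels carried by `bulk`.
#' @param p_threshold Raw p-value threshold.
#' @param lfc_threshold Absolute log2-fold-change threshold (inclusive).
#' @return A `bulk_de` data.frame: `gene`, `p_value`, `log2_fold_change`,
#'   `mean_toxic`, `mean_nontoxic`, `fdr`, `significant`.
#' @export
bulk_differential_expression <- function(bulk, labels = bulk$drug_labels,
                                         p_threshold = 0.05,
                                         lfc_threshold = 1.0) {
  values <- bulk$values
  lab <- labels[unname(bulk$drug_of_sample[rownames(values)])]
  if (anyNA(lab)) stop("unlabeled drugs among the samples")
  toxic <- lab == "toxic"
  if (sum(toxic) < 2 || sum(!toxic) < 2) {
    stop("each label group needs at least 2 samples")
  }
  res <- welch_test_cols(values[toxic, , drop = FALSE],
                         values[!toxic, , drop = FALSE])
  out <- data.frame(gene = colnames(values),
                    p_value = res$p_value,
                    log2_fold_change = res$mean_x - res$mean_y,
                    mean_toxic = res$mean_x, mean_nontoxic = res$mean_y,
                    stringsAsFactors = FALSE)
  out$fdr <- fdr_correct(out$p_value)
  out$significant <- out$p_value < p_threshold &
    abs(out$log2_fold_change) >= lfc_threshold
  out <- out[order(out$p_value, out$gene), ]
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(p = p_threshold, lfc = lfc_threshold)
  class(out) <- c("bulk_de", "data.frame")
  out
}

#' @export
print.bulk_de <- function(x, n = 10, ...) {
  thr <- attr(x, "thresholds")
  cat(sprintf("bulk_de: %d genes tested, %d significant (p < %g & |log2FC| >= %g)\n",
              nrow(x), sum(x$significant), thr["p"], thr["lfc"]))
  df <- utils::head(as.data.frame(x), n)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
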