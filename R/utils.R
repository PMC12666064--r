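# Shared numerical helpers.

#' Largest-remainder apportionment
#'
#' Deterministically apportions `total` integer units among categories in
#' proportion to `weights`: floors of the exact shares, then the leftover
#' units go to the categories with the largest fractional remainders
#' (ties broken by category index).
#'
#' @param weights Positive numeric weights (need not sum to 1).
#' @param total Non-negative integer total to apportion.
#' @return Integer vector of the same length as `weights`, summing to `total`.
#' @export
largest_remainder <- function(weights, total) {
  stopifnot(length(weights) >= 1, all(weights > 0), total >= 0)
  target <- weights / sum(weights) * total
  base <- floor(target)
  shortfall <- as.integer(round(total - sum(base)))
  if (shortfall > 0) {
    rem <- target - base
    ord <- order(-rem, seq_along(rem), method = "radix")
    take <- ord[seq_len(shortfall)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      get(".Random.seed", envir = .GlobalEnv)
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
          rm(".Random.seed", envir = .GlobalEnv)
        }
      } else {
        assign(".Random.seed", old, envir = .GlobalEnv)
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a per-stage seed from a master seed; keeps results reproducible
# while decorrelating stages. Stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483629)
}

#' Vectorized per-column Welch t-tests
#'
#' Welch (unequal-variance) two-sample t-tests applied column-wise to two
#' matrices with matching columns (typically replicates x genes). Columns
#' with zero variance in both groups get p = 1 when the group means agree
#' and p = 0 when they differ.
#'
#' @param x,y Numeric matrices with the same number of columns; rows are
#'   replicates (samples or cells), columns are features (genes).
#' @return A data.frame with one row per column: `statistic`, `df`,
#'   `p_value`, `mean_x`, `mean_y`.
#' @export
welch_test_cols <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), ncol(x) == ncol(y))
  n1 <- nrow(x); n2 <- nrow(y)
  if (n1 < 2 || n2 < 2) stop("Welch test needs at least 2 replicates per group")
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- (colSums(x^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(y^2) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    same <- degenerate & (m1 == m2)
    tt[degenerate] <- 0
    df[degenerate] <- n1 + n2 - 2
    p[same] <- 1
    p[degenerate & !same] <- 0
  }
  data.frame(statistic = tt, df = df, p_value = p, mean_x = m1, mean_y = m2,
             row.names = colnames(x))
}

# Rank-based AUROC (probability that a positive outranks a negative;
# ties count 1/2). Used for bootstrap resampling where calling pROC
# thousands of times would dominate runtime.
auroc_rank <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n0 <- length(scores_neg)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
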