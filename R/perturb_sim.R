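# Simulated drug effects on single cells, pseudo-bulking, and the power
# analysis contrasting single-cell with pseudo-bulk detection.

#' Simulation configuration for the power sweep
#'
#' Defaults match the study conditions: a 10% prevalence-preserving
#' subsample, response rates 0.3/0.8/0.95, and nine effect sizes log-spaced
#' from 0.001 to 10 (applied as multipliers 1 + effect to responding
#' mediator cells).
#'
#' @param sample_fraction Fraction of cells subsampled (prevalence
#'   preserved per cell type).
#' @param response_rates Fractions of mediator cells that respond.
#' @param effect_sizes Positive effect sizes; default
#'   `10^seq(-3, 1, length.out = 9)`.
#' @param mediator Cell-type label mediating the toxicity.
#' @param level Annotation level of `mediator` (`"abstract"`/`"detailed"`).
#' @param alpha Significance level.
#' @param fdr Apply BH-FDR at `alpha` (default) instead of raw p.
#' @param pseudobulk_mode `"allcells"` (prevalence-weighted per-sample mean
#'   over all cells, the default) or `"typemean"` (unweighted mean of
#'   cell-type means).
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sample_fraction = 0.10,
                       response_rates = c(0.3, 0.8, 0.95),
                       effect_sizes = 10^seq(-3, 1, length.out = 9),
                       mediator = "Endothelium",
                       level = c("abstract", "detailed"),
                       alpha = 0.05, fdr = TRUE,
                       pseudobulk_mode = c("allcells", "typemean"),
                       seed = 42) {
  stopifnot(sample_fraction > 0, sample_fraction <= 1,
            all(response_rates > 0), all(response_rates <= 1),
            all(effect_sizes > 0), alpha > 0, alpha < 1)
  structure(list(sample_fraction = sample_fraction,
                 response_rates = response_rates,
                 effect_sizes = effect_sizes, mediator = mediator,
                 level = match.arg(level), alpha = alpha, fdr = fdr,
                 pseudobulk_mode = match.arg(pseudobulk_mode),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Subsample cells while preserving cell-type prevalence
#'
#' Per-type quotas are the largest-remainder apportionment of
#' `fraction * type size` (total = round(fraction * n_cells)); cells are
#' drawn uniformly without replacement within each type, so realized type
#' proportions equal the original proportions up to quota rounding.
#'
#' @param expr A `normalized_matrix`.
#' @param fraction Fraction of cells to keep (`(0, 1]`; 1 is the identity).
#' @param level Annotation level whose composition is preserved.
#' @param seed Integer seed.
#' @return The subsampled `normalized_matrix`.
#' @export
sample_preserving_prevalence <- function(expr, fraction, level = "abstract",
                                         seed = NULL) {
  stopifnot(inherits(expr, "normalized_matrix"))
  if (fraction > 1 || fraction <= 0) stop("fraction must lie in (0, 1]")
  if (fraction == 1) return(expr)
  types <- expr$cell_meta[[paste0(level, "_type")]]
  sizes <- table(types)
  total <- round(fraction * length(types))
  quota <- largest_remainder(as.numeric(sizes), total)
  names(quota) <- names(sizes)
  with_seed(seed, {
    keep <- unlist(lapply(names(sizes), function(tp) {
      idx <- which(types == tp)
      idx[sample.int(length(idx), quota[[tp]])]
    }))
    keep <- sort(keep)
    out <- expr
    out$values <- expr$values[, keep, drop = FALSE]
    out$counts <- expr$counts[, keep, drop = FALSE]
    out$cell_meta <- expr$cell_meta[keep, , drop = FALSE]
    rownames(out$cell_meta) <- NULL
    out$cell_ids <- out$cell_meta$cell_id
    out
  })
}

#' Apply a multiplicative drug effect to responding mediator cells
#'
#' Exactly `round(response_rate * n_mediator)` mediator-type cells are
#' chosen uniformly; every gene of those cells is multiplied by
#' `1 + effect_size`. All other cells are untouched. Values are perturbed
#' on whatever scale they are supplied (the power sweep passes
#' linear-scale normalized expression).
#'
#' @param values Numeric matrix genes x cells (dense or sparse).
#' @param types Cell-type label per column of `values`.
#' @param mediator Mediating cell-type label; must occur in `types`.
#' @param response_rate Fraction of mediator cells that respond.
#' @param effect_size Non-negative effect size (multiplier `1 + effect`).
#' @param seed Integer seed for the responder draw.
#' @return List with `values` (perturbed matrix) and `affected` (logical
#'   mask per cell).
#' @export
apply_drug_effect <- function(values, types, mediator, response_rate,
                              effect_size, seed = NULL) {
  stopifnot(ncol(values) == length(types),
            response_rate >= 0, response_rate <= 1, effect_size >= 0)
  med_idx <- which(types == mediator)
  if (!length(med_idx)) stop("mediator '", mediator, "' absent at this level")
  n_affected <- round(response_rate * length(med_idx))
  affected <- rep(FALSE, ncol(values))
  with_seed(seed, {
    if (n_affected > 0) {
      hit <- med_idx[sample.int(length(med_idx), n_affected)]
      affected[hit] <- TRUE
      values[, hit] <- values[, hit] * (1 + effect_size)
    }
  })
  list(values = values, affected = affected)
}

#' Pseudo-bulk a single-cell matrix by sample
#'
#' value(s, g) = mean over all cells of sample s of expr(g, c): the
#' prevalence-weighted (all-cells) mean, with cell-type identity
#' discarded. `mode = "typemean"` instead averages the per-cell-type mean
#' profiles (unweighted), which undoes prevalence weighting.
#'
#' @param values Numeric matrix genes x cells.
#' @param samples Sample id per column of `values`.
#' @param mode `"allcells"` (default) or `"typemean"`.
#' @param types Cell-type label per column; required for `"typemean"`.
#' @return Dense matrix samples x genes.
#' @export
pseudobulk <- function(values, samples, mode = c("allcells", "typemean"),
                       types = NULL) {
  mode <- match.arg(mode)
  stopifnot(ncol(values) == length(samples))
  values <- as.matrix(values)
  if (mode == "allcells") {
    f <- factor(samples)
    agg <- rowsum(t(values), f) / as.vector(table(f))
    as.matrix(agg)
  } else {
    if (is.null(types)) stop("mode 'typemean' needs cell-type labels")
    f <- interaction(samples, types, drop = TRUE, sep = "\r")
    per_type <- rowsum(t(values), f) / as.vector(table(f))
    sample_of <- sub("\r.*$", "", rownames(per_type))
    f2 <- factor(sample_of)
    as.matrix(rowsum(as.matrix(per_type), f2) / as.vector(table(f2)))
  }
}

#' Per-gene power of a treated vs control comparison
#'
#' Per-gene Welch t-tests on ln(1 + x) of the supplied linear-scale
#' values; a gene is significant at BH-FDR < `alpha` (or raw p < `alpha`
#' when `fdr = FALSE`). Power is the fraction of genes called significant
#' (the number of differentially expressed genes divided by the total
#' number of genes).
#'
#' @param treated,control Matrices replicates x genes (pseudo-bulk:
#'   samples; single-cell: cells), linear scale.
#' @param data_level `"single_cell"` or `"pseudo_bulk"` (annotation only).
#' @param alpha Significance level.
#' @param fdr Apply BH-FDR (default) instead of raw p.
#' @return One-row data.frame: `data_level`, `power`, `n_genes`,
#'   `n_significant`.
#' @export
compute_power <- function(treated, control, data_level = "single_cell",
                          alpha = 0.05, fdr = TRUE) {
  if (nrow(treated) < 2 || nrow(control) < 2) {
    stop("need at least 2 replicates per arm")
  }
  res <- welch_test_cols(log1p(as.matrix(treated)), log1p(as.matrix(control)))
  p <- if (fdr) fdr_correct(res$p_value) else res$p_value
  n_sig <- sum(p < alpha)
  data.frame(data_level = data_level, power = n_sig / length(p),
             n_genes = length(p), n_significant = n_sig,
             stringsAsFactors = FALSE)
}

#' Run the full dilution power sweep
#'
#' Subsamples the data once (prevalence-preserving, `sample_fraction`),
#' randomly halves the samples into a treated and a control arm, and for
#' every (effect size, response rate) grid point applies the drug effect
#' to the treated arm's mediator cells and measures power twice: at
#' single-cell resolution (treated-arm cells vs control-arm cells) and
#' after pseudo-bulking each arm per sample. Expression is perturbed on
#' the linear normalized scale and tested on ln(1 + x).
#'
#' @param expr A `normalized_matrix` (values on the ln(1+x) scale).
#' @param cfg A [sim_config()].
#' @return A `power_sweep` data.frame: `effect_size`, `response_rate`,
#'   `mediator`, `level`, `data_level`, `power`, `n_genes`,
#'   `n_significant`.
#' @export
run_power_sweep <- function(expr, cfg = sim_config()) {
  stopifnot(inherits(expr, "normalized_matrix"), inherits(cfg, "sim_config"))
  types_all <- unique(expr$cell_meta[[paste0(cfg$level, "_type")]])
  if (!cfg$mediator %in% types_all) {
    stop("mediator '", cfg$mediator, "' absent at level '", cfg$level, "'")
  }
  sub <- sample_preserving_prevalence(expr, cfg$sample_fraction, cfg$level,
                                      seed = derive_seed(cfg$seed, 1))
  samples <- sub$cell_meta$sample
  sample_ids <- sort(unique(samples))
  if (length(sample_ids) < 4) stop("need at least 4 samples (2 per arm)")
  arm_split <- with_seed(derive_seed(cfg$seed, 2), sample(sample_ids))
  treated_samples <- arm_split[seq_len(floor(length(arm_split) / 2))]
  in_treated <- samples %in% treated_samples

  linear <- expm1(sub$values)
  types <- sub$cell_meta[[paste0(cfg$level, "_type")]]
  trt_lin <- as.matrix(linear[, in_treated, drop = FALSE])
  ctl_lin <- as.matrix(linear[, !in_treated, drop = FALSE])
  trt_types <- types[in_treated]
  ctl_samples <- samples[!in_treated]
  trt_samples <- samples[in_treated]

  ctl_sc <- t(ctl_lin)
  ctl_pb <- pseudobulk(ctl_lin, ctl_samples, mode = cfg$pseudobulk_mode,
                       types = types[!in_treated])

  grid <- expand.grid(effect_size = cfg$effect_sizes,
                      response_rate = cfg$response_rates,
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid) * 2)
  for (i in seq_len(nrow(grid))) {
    e <- grid$effect_size[i]; r <- grid$response_rate[i]
    pert <- apply_drug_effect(trt_lin, trt_types, cfg$mediator, r, e,
                              seed = derive_seed(cfg$seed, 100 + i))
    sc <- compute_power(t(pert$values), ctl_sc, "single_cell",
                        cfg$alpha, cfg$fdr)
    pb <- compute_power(
      pseudobulk(pert$values, trt_samples, mode = cfg$pseudobulk_mode,
                 types = trt_types),
      ctl_pb, "pseudo_bulk", cfg$alpha, cfg$fdr)
    res <- rbind(sc, pb)
    res$effect_size <- e; res$response_rate <- r
    out[[i]] <- res
  }
  sweep <- do.call(rbind, out[seq_len(nrow(grid))])
  sweep$mediator <- cfg$mediator
  sweep$level <- cfg$level
  sweep <- sweep[, c("effect_size", "response_rate", "mediator", "level",
                     "data_level", "power", "n_genes", "n_significant")]
  rownames(sweep) <- NULL
  class(sweep) <- c("power_sweep", "data.frame")
  sweep
}

#' @export
print.power_sweep <- function(x, ...) {
  cat(sprintf("power_sweep: mediator %s (%s level), %d grid points x 2 data levels\n",
              x$mediator[1], x$level[1], nrow(x) / 2))
  df <- as.data.frame(x)
  df$power <- round(df$power, 3)
  print.data.frame(df[, c("effect_size", "response_rate", "data_level", "power")],
                   row.names = FALSE)
  invisible(x)
}

#' Plot power curves from a sweep
#'
#' Power against effect size (log x-axis), one panel set per response
#' rate: filled points/solid lines for single-cell, hollow points/dashed
#' lines for pseudo-bulk.
#'
#' @param x A `power_sweep`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.power_sweep <- function(x, ...) {
  rates <- sort(unique(x$response_rate))
  cols <- grDevices::hcl.colors(max(3, length(rates)), "Dark 3")[seq_along(rates)]
  graphics::plot(range(x$effect_size), c(0, 1), type = "n", log = "x",
                 xlab = "effect size", ylab = "power",
                 main = sprintf("Signal dilution: %s-mediated effect", x$mediator[1]),
                 ...)
  for (j in seq_along(rates)) {
    for (lvl in c("single_cell", "pseudo_bulk")) {
      d <- x[x$response_rate == rates[j] & x$data_level == lvl, ]
      d <- d[order(d$effect_size), ]
      graphics::lines(d$effect_size, d$power, col = cols[j],
                      lty = if (lvl == "single_cell") 1 else 2)
      graphics::points(d$effect_size, d$power, col = cols[j],
                       pch = if (lvl == "single_cell") 19 else 1)
    }
  }
  graphics::legend("topleft", bty = "n",
                   legend = c(sprintf("response %.2f", rates),
                              "single-cell", "pseudo-bulk"),
                   col = c(cols, "black", "black"),
                   lty = c(rep(1, length(rates)), 1, 2),
                   pch = c(rep(NA, length(rates)), 19, 1))
  invisible(x)
}
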