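# Cell/gene filtering, log-normalization, HVG selection.

make_counts <- function(m) {
  n <- ncol(m)
  meta <- data.frame(cell_id = colnames(m), sample = "S1",
                     abstract_type = "T", detailed_type = "T_1",
                     stringsAsFactors = FALSE)
  annotated_counts(m, meta)
}

test_that("cell filter boundaries follow the stated thresholds", {
  # 300 detected genes; one cell with 499 UMIs (fails), one with 500 (passes)
  m <- matrix(1, nrow = 300, ncol = 2,
              dimnames = list(sprintf("g%03d", 1:300), c("lo", "hi")))
  m[1, ] <- c(200, 201)  # totals 499 and 500
  thr <- qc_thresholds(min_cells_per_gene = 0)
  res <- filter_cells(make_counts(m), thr)
  expect_equal(res$data$cell_ids, "hi")
  expect_equal(unname(res$removed["min_umi"]), 1)
  # ratio identity: 1000 UMIs over 1000 genes -> ratio 1 > 0.85, kept
  m2 <- matrix(1, nrow = 1000, ncol = 1,
               dimnames = list(sprintf("g%04d", 1:1000), "c1"))
  expect_equal(filter_cells(make_counts(m2), thr)$data$cell_ids, "c1")
  # removing everything is an explicit error
  expect_error(filter_cells(make_counts(m * 0 + 1), qc_thresholds(min_umi = 1e6)),
               "empty after QC")
})

test_that("cell filter matches a brute-force per-cell oracle with planted violations", {
  set.seed(23)
  thr <- qc_thresholds(min_umi = 50, min_genes = 20,
                       min_log10_genes_per_umi = 0.85,
                       min_cells_per_gene = 0)
  # 20 cells: 13 healthy, 3 low-UMI, 2 low-gene-count, 1 low-ratio, 1 both
  healthy <- replicate(13, rbinom(60, 2, 0.8))
  low_umi <- replicate(3, { x <- rep(0, 60); x[sample(60, 30)] <- 1; x })
  low_gene <- replicate(2, { x <- rep(0, 60); x[sample(60, 10)] <- 20; x })
  low_ratio <- { x <- rep(0, 60); x[sample(60, 21)] <- 1; x[1] <- 400; x }
  both <- { x <- rep(0, 60); x[sample(60, 10)] <- 2; x }
  m <- cbind(healthy, low_umi, low_gene, low_ratio, both)
  dimnames(m) <- list(sprintf("g%02d", 1:60), sprintf("c%02d", 1:20))
  res <- filter_cells(make_counts(m), thr)

  keep_oracle <- removed_oracle <- c(min_umi = 0, min_genes = 0, ratio = 0)
  kept <- character(0)
  for (j in seq_len(ncol(m))) {
    umi <- sum(m[, j]); ng <- sum(m[, j] > 0)
    f_umi <- umi < 50; f_ng <- ng < 20
    f_r <- !(log10(ng) / log10(umi) > 0.85)
    removed_oracle <- removed_oracle + c(f_umi, f_ng, f_r)
    if (!f_umi && !f_ng && !f_r) kept <- c(kept, colnames(m)[j])
  }
  expect_equal(res$data$cell_ids, kept)
  expect_equal(unname(res$removed), unname(removed_oracle))
})

test_that("gene filter keeps genes detected in at least min_cells_per_gene cells", {
  m <- matrix(0, nrow = 3, ncol = 20,
              dimnames = list(c("in10", "in9", "in20"), sprintf("c%02d", 1:20)))
  m["in10", 1:10] <- 1
  m["in9", 1:9] <- 5
  m["in20", ] <- 1
  thr <- qc_thresholds(min_cells_per_gene = 10)
  out <- filter_genes(make_counts(m), thr)
  expect_equal(out$gene_ids, c("in10", "in20"))
  # dense recount oracle on a random sparse fixture
  rc <- random_counts(n_genes = 80, n_cells = 30, lambda = 0.3, seed = 99)
  kept <- filter_genes(rc, qc_thresholds(min_cells_per_gene = 4))$gene_ids
  oracle <- rownames(rc$counts)[rowSums(as.matrix(rc$counts) > 0) >= 4]
  expect_equal(kept, oracle)
  expect_error(filter_genes(rc, qc_thresholds(min_cells_per_gene = 1e5)),
               "empty after QC")
})

test_that("filters are idempotent and commute with cell permutation", {
  rc <- random_counts(n_genes = 50, n_cells = 30, lambda = 1, seed = 5)
  thr <- qc_thresholds(min_umi = 30, min_genes = 10,
                       min_log10_genes_per_umi = 0.5, min_cells_per_gene = 3)
  once <- filter_genes(filter_cells(rc, thr)$data, thr)
  twice <- filter_genes(filter_cells(once, thr)$data, thr)
  expect_identical(once$counts, twice$counts)
  perm <- sample(ncol(rc$counts))
  rc_p <- annotated_counts(rc$counts[, perm], rc$cell_meta[perm, ])
  once_p <- filter_genes(filter_cells(rc_p, thr)$data, thr)
  expect_setequal(once_p$cell_ids, once$cell_ids)
  expect_identical(once_p$gene_ids, once$gene_ids)
})

test_that("log-normalization matches its closed form", {
  m <- matrix(c(0, 1, 3,
                2, 0, 6,
                5, 5, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3")))
  thr <- qc_thresholds(scale_factor = 10000)
  norm <- log_normalize(make_counts(m), thr)
  totals <- colSums(m)
  expected <- log1p(sweep(m, 2, totals, "/") * 10000)
  expect_equal(as.matrix(norm$values), expected, ignore_attr = TRUE)
  # count equal to the cell total -> ln(10001); zero stays zero
  single <- matrix(c(7, 0), nrow = 2,
                   dimnames = list(c("g1", "g2"), "c1"))
  v <- as.matrix(log_normalize(make_counts(single), thr)$values)
  expect_equal(v["g1", 1], log(10001))
  expect_equal(v["g2", 1], 0)
  # within-cell rank order of nonzero counts is preserved
  rc <- random_counts(n_genes = 40, n_cells = 10, lambda = 3, seed = 13)
  nv <- as.matrix(log_normalize(rc, thr)$values)
  cv <- as.matrix(rc$counts)
  for (j in 1:10) {
    nz <- cv[, j] > 0
    expect_equal(rank(nv[nz, j]), rank(cv[nz, j]))
  }
  # zero-total cells are a hard error
  zm <- matrix(c(1, 0), nrow = 1, dimnames = list("g1", c("a", "b")))
  expect_error(log_normalize(make_counts(zm), thr), "zero total")
})

test_that("HVG selection recovers planted high-variance genes", {
  set.seed(77)
  n_cells <- 200
  # realistic spread of means, with 10 genes given ~100x inflated variance
  # at matched means (overdispersed instead of Poisson)
  mu_q <- rlnorm(190, log(3), 1)
  mu_v <- rlnorm(10, log(3), 1)
  quiet <- matrix(rpois(190 * n_cells, rep(mu_q, n_cells)), nrow = 190)
  noisy <- matrix(rnbinom(10 * n_cells, mu = rep(mu_v, n_cells), size = 0.05),
                  nrow = 10)
  m <- rbind(quiet, noisy)
  dimnames(m) <- list(c(sprintf("q%03d", 1:190), sprintf("v%02d", 1:10)),
                      sprintf("c%03d", seq_len(n_cells)))
  thr <- qc_thresholds(min_cells_per_gene = 0, n_hvg = 10)
  norm <- select_hvg(log_normalize(make_counts(m), thr), thr)
  expect_setequal(names(which(norm$hvg)), sprintf("v%02d", 1:10))
  # permuting gene order leaves the flagged set unchanged
  perm <- sample(nrow(m))
  norm_p <- select_hvg(log_normalize(make_counts(m[perm, ]), thr), thr)
  expect_setequal(names(which(norm_p$hvg)), names(which(norm$hvg)))
  # n_hvg >= n_genes flags everything
  all_flag <- select_hvg(log_normalize(make_counts(m), thr),
                         qc_thresholds(min_cells_per_gene = 0, n_hvg = 500))
  expect_true(all(all_flag$hvg))
})
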