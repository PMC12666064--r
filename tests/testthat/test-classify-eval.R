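# Feature tables, classifier training/evaluation, external validation.

feature_fixture <- function(seed = 5, n_toxic = 40, n_nontoxic = 120,
                            shift = 0, n_types = 4) {
  set.seed(seed)
  n <- n_toxic + n_nontoxic
  x <- matrix(rnorm(n * n_types), nrow = n,
              dimnames = list(sprintf("d%03d", seq_len(n)),
                              sprintf("type%d", seq_len(n_types))))
  lab <- rep(c("toxic", "nontoxic"), c(n_toxic, n_nontoxic))
  x[lab == "toxic", 1] <- x[lab == "toxic", 1] + shift
  structure(list(x = x, label = factor(lab, levels = c("nontoxic", "toxic")),
                 level = "abstract"),
            class = "feature_table")
}

test_that("metric computations match closed forms on a confusion fixture", {
  # TP=3 FP=1 FN=2 TN=4 at threshold 0.5
  truth <- factor(rep(c("toxic", "nontoxic"), c(5, 5)),
                  levels = c("nontoxic", "toxic"))
  prob <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.3, 0.2, 0.1, 0.05)
  met <- celltox:::classification_metrics(truth, prob)
  expect_equal(unname(met["sensitivity"]), 0.6)
  expect_equal(unname(met["specificity"]), 0.8)
  expect_equal(unname(met["accuracy"]), 0.7)
  prec <- 3 / 4
  expect_equal(unname(met["f1"]), 2 * prec * 0.6 / (prec + 0.6))
  # AUROC from pROC equals the rank-sum closed form
  expect_equal(unname(met["auroc"]),
               celltox:::auroc_rank(prob[truth == "toxic"],
                                    prob[truth == "nontoxic"]))
})

test_that("feature tables transpose cell-type scores and drop unlabeled drugs", {
  set.seed(2)
  logged <- matrix(rnorm(40), nrow = 8,
                   dimnames = list(sprintf("c%d", 1:8), sprintf("d%d", 1:5)))
  ct <- aggregate_by_celltype(fake_scores(logged, rep(c("A", "B"), 4)),
                              "abstract")
  labels <- stats::setNames(rep(c("toxic", "nontoxic"), c(2, 2)),
                            sprintf("d%d", 1:4))
  expect_warning(ft <- build_feature_table(ct, labels), "unlabeled")
  expect_equal(dim(ft$x), c(4L, 2L))
  expect_equal(ft$x["d1", "A"], ct$score["A", "d1"])
  expect_equal(colMeans(ft$x), rowMeans(ct$score[, sprintf("d%d", 1:4)]))
})

test_that("perfectly separable features give internal AUROC 1", {
  ft <- feature_fixture(shift = 10)
  ev <- train_and_evaluate(ft, models = c("logistic", "boosted_trees"),
                           seed = 7, n_bootstrap = 100)
  expect_equal(ev$reports$auroc, c(1, 1))
  expect_true(all(ev$reports$auroc_ci_lower <= ev$reports$auroc))
  expect_true(all(ev$reports$auroc <= ev$reports$auroc_ci_upper))
})

test_that("shuffled labels give an AUROC whose bootstrap CI covers 0.5", {
  # a 95% CI misses the null value ~5% of the time by construction, so the
  # property is asserted over replicate shuffles: the CI must cover 0.5 in
  # a clear majority
  ft0 <- feature_fixture(shift = 3, seed = 9)
  covers <- vapply(1:10, function(i) {
    ft <- ft0
    set.seed(100 + i)
    ft$label <- sample(ft$label)
    ev <- train_and_evaluate(ft, models = "logistic", seed = 11,
                             n_bootstrap = 300)
    ev$reports$auroc_ci_lower <= 0.5 && ev$reports$auroc_ci_upper >= 0.5
  }, logical(1))
  expect_gte(sum(covers), 8)
})

test_that("external evaluation aligns columns by name without refitting", {
  ft <- feature_fixture(shift = 4, seed = 13)
  ev <- train_and_evaluate(ft, models = c("logistic", "svm"), seed = 3,
                           n_bootstrap = 100)
  # external set identical to the internal test fold -> identical metrics
  test_idx <- setdiff(seq_along(ft$label),
                      celltox:::stratified_split(ft$label, 0.8,
                                                 seed = celltox:::derive_seed(3, 1)))
  ext_same <- structure(list(x = ft$x[test_idx, , drop = FALSE],
                             label = ft$label[test_idx], level = "abstract"),
                        class = "feature_table")
  rep_same <- evaluate_external(ev, ext_same)
  met_cols <- c("accuracy", "f1", "auroc", "sensitivity", "specificity")
  expect_equal(rep_same[, met_cols], ev$reports[, met_cols],
               ignore_attr = TRUE)
  # permuting external columns changes nothing (name-based alignment)
  ext_perm <- ext_same
  ext_perm$x <- ext_perm$x[, rev(colnames(ext_perm$x))]
  expect_equal(evaluate_external(ev, ext_perm)[, met_cols],
               rep_same[, met_cols], ignore_attr = TRUE)
  # a missing feature column is an error
  ext_bad <- ext_same
  ext_bad$x <- ext_bad$x[, -1]
  expect_error(evaluate_external(ev, ext_bad), "missing cell-type")
  # independent draw from the same signal-bearing process stays above chance
  ext_new <- feature_fixture(shift = 4, seed = 99)
  expect_gt(evaluate_external(ev, ext_new)$auroc[1], 0.5)
})

test_that("reports are invariant to drug row order", {
  set.seed(44)
  logged <- matrix(rnorm(200), nrow = 10,
                   dimnames = list(sprintf("c%d", 1:10), sprintf("d%02d", 1:20)))
  types <- rep(c("A", "B"), 5)
  labels <- stats::setNames(rep(c("toxic", "nontoxic"), 10),
                            sprintf("d%02d", 1:20))
  ct <- aggregate_by_celltype(fake_scores(logged, types), "abstract")
  ft1 <- build_feature_table(ct, labels)
  ct_perm <- ct
  perm <- sample(ncol(ct$score))
  ct_perm$score <- ct$score[, perm]
  ct_perm$drug_ids <- ct$drug_ids[perm]
  ft2 <- build_feature_table(ct_perm, labels)
  ev1 <- train_and_evaluate(ft1, models = "logistic", seed = 5, n_bootstrap = 50)
  ev2 <- train_and_evaluate(ft2, models = "logistic", seed = 5, n_bootstrap = 50)
  expect_equal(ev1$reports, ev2$reports)
})
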