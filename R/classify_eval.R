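# Drug-level toxicity classification from cell-type score features:
# stratified train/test evaluation plus external validation.

#' Build a drug x cell-type feature table
#'
#' Transposes a cell-type score table so drugs are rows and cell types
#' are feature columns, attaching the toxicity label per drug. Unlabeled
#' drugs are dropped with a warning.
#'
#' @param table A `celltype_scores` object.
#' @param labels Named toxic/nontoxic vector keyed by drug id.
#' @return A `feature_table` object: `x` (drugs x cell types matrix) and
#'   `label` (factor with levels nontoxic, toxic).
#' @export
build_feature_table <- function(table, labels) {
  stopifnot(inherits(table, "celltype_scores"))
  lab <- labels[table$drug_ids]
  if (anyNA(lab)) {
    drop <- table$drug_ids[is.na(lab)]
    warning(length(drop), " unlabeled drug(s) dropped from the feature table")
  }
  keep <- !is.na(lab)
  x <- t(table$score[, keep, drop = FALSE])
  lab <- lab[keep]
  # canonical drug order so downstream splits ignore input row order
  ord <- order(rownames(x))
  structure(list(x = x[ord, , drop = FALSE],
                 label = factor(lab[ord], levels = c("nontoxic", "toxic")),
                 level = table$level),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d drugs x %d cell-type features (%d toxic)\n",
              nrow(x$x), ncol(x$x), sum(x$label == "toxic")))
  invisible(x)
}

# indices of a stratified split: `fraction` of each class into training
stratified_split <- function(label, fraction, seed = NULL) {
  with_seed(seed, {
    train <- unlist(lapply(levels(label), function(cl) {
      idx <- which(label == cl)
      n_train <- max(1L, min(length(idx) - 1L, round(fraction * length(idx))))
      idx[sample.int(length(idx), n_train)]
    }))
    sort(train)
  })
}

classification_metrics <- function(truth, prob, threshold = 0.5) {
  pos <- truth == "toxic"
  pred <- prob >= threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (!is.na(sens) && (prec + sens) > 0) 2 * prec * sens / (prec + sens) else 0
  auc <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = prob,
                                        levels = c(FALSE, TRUE),
                                        direction = "<", quiet = TRUE)))
  c(accuracy = (tp + tn) / length(truth), f1 = f1, auroc = auc,
    sensitivity = sens, specificity = spec)
}

bootstrap_auroc_ci <- function(truth, prob, n_bootstrap = 1000,
                               conf_level = 0.95, seed = NULL) {
  pos_idx <- which(truth == "toxic"); neg_idx <- which(truth == "nontoxic")
  with_seed(seed, {
    reps <- vapply(seq_len(n_bootstrap), function(i) {
      auroc_rank(prob[sample(pos_idx, replace = TRUE)],
                 prob[sample(neg_idx, replace = TRUE)])
    }, numeric(1))
  })
  a <- (1 - conf_level) / 2
  stats::quantile(reps, c(a, 1 - a), na.rm = TRUE, names = FALSE)
}

fit_model <- function(model, x, y, seed) {
  df <- data.frame(x, check.names = FALSE)
  switch(model,
    logistic = suppressWarnings(
      stats::glm(y ~ ., data = cbind(df, y = y), family = stats::binomial())),
    tree_ensemble = ranger::ranger(
      x = df, y = y, probability = TRUE, num.trees = 500, seed = seed),
    boosted_trees = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = 0.1,
                    max_depth = 3, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(as.matrix(x),
                                  label = as.integer(y == "toxic"),
                                  nthread = 1),
      nrounds = 100, verbose = 0),
    svm = e1071::svm(x = as.matrix(x), y = y, kernel = "radial",
                     probability = TRUE),
    stop("unknown model: ", model))
}

predict_prob <- function(model, fit, x) {
  df <- data.frame(x, check.names = FALSE)
  switch(model,
    logistic = unname(stats::predict(fit, newdata = df, type = "response")),
    tree_ensemble = unname(stats::predict(fit, data = df)$predictions[, "toxic"]),
    boosted_trees = unname(stats::predict(
      fit, xgboost::xgb.DMatrix(as.matrix(x), nthread = 1))),
    svm = {
      pr <- attr(stats::predict(fit, as.matrix(x), probability = TRUE),
                 "probabilities")
      unname(pr[, "toxic"])
    })
}

#' Train and evaluate toxicity classifiers
#'
#' Stratified train/test split, model fitting, and held-out evaluation
#' with accuracy, F1, AUROC (with a stratified-bootstrap 95% CI),
#' sensitivity and specificity at a 0.5 decision threshold.
#'
#' @param features A `feature_table` from [build_feature_table()].
#' @param models Subset of `"logistic"`, `"tree_ensemble"`,
#'   `"boosted_trees"`, `"svm"`.
#' @param split_fraction Fraction of each class assigned to training.
#' @param seed Integer seed (split, model fits, bootstrap).
#' @param n_bootstrap Bootstrap replicates for the AUROC CI.
#' @return A `classifier_eval` object: `reports` (one row per model:
#'   metrics on the held-out internal split) and `fits` (fitted models,
#'   reusable via [evaluate_external()]).
#' @export
train_and_evaluate <- function(features,
                               models = c("logistic", "tree_ensemble",
                                          "boosted_trees", "svm"),
                               split_fraction = 0.8, seed = 42,
                               n_bootstrap = 1000) {
  stopifnot(inherits(features, "feature_table"))
  models <- match.arg(models, several.ok = TRUE)
  train_idx <- stratified_split(features$label, split_fraction,
                                seed = derive_seed(seed, 1))
  test_idx <- setdiff(seq_along(features$label), train_idx)
  y_train <- droplevels(features$label[train_idx])
  y_test <- features$label[test_idx]
  if (nlevels(y_train) < 2 || length(unique(y_test)) < 2) {
    stop("single-class train or test fold; adjust split_fraction or data")
  }
  x_train <- features$x[train_idx, , drop = FALSE]
  x_test <- features$x[test_idx, , drop = FALSE]
  fits <- list()
  rows <- list()
  for (mdl in models) {
    fit <- with_seed(derive_seed(seed, 2), fit_model(mdl, x_train, y_train,
                                                     seed = derive_seed(seed, 2)))
    prob <- predict_prob(mdl, fit, x_test)
    met <- classification_metrics(y_test, prob)
    ci <- bootstrap_auroc_ci(y_test, prob, n_bootstrap,
                             seed = derive_seed(seed, 3))
    fits[[mdl]] <- fit
    rows[[mdl]] <- data.frame(model_name = mdl, split = "internal",
                              t(met), auroc_ci_lower = ci[1],
                              auroc_ci_upper = ci[2],
                              stringsAsFactors = FALSE)
  }
  reports <- do.call(rbind, rows)
  rownames(reports) <- NULL
  structure(list(reports = reports, fits = fits,
                 feature_names = colnames(features$x),
                 models = models, n_bootstrap = n_bootstrap, seed = seed),
            class = "classifier_eval")
}

#' Evaluate fitted classifiers on an external feature table
#'
#' Applies already-fitted models (no refitting) to an external drug set.
#' Feature columns are aligned by cell-type name; a missing column is an
#' error, extra columns are ignored.
#'
#' @param fit A `classifier_eval` from [train_and_evaluate()].
#' @param external_features A `feature_table` with matching cell types.
#' @return data.frame of metrics, one row per model, `split = "external"`.
#' @export
evaluate_external <- function(fit, external_features) {
  stopifnot(inherits(fit, "classifier_eval"),
            inherits(external_features, "feature_table"))
  missing_cols <- setdiff(fit$feature_names, colnames(external_features$x))
  if (length(missing_cols)) {
    stop("external table is missing cell-type feature(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- external_features$x[, fit$feature_names, drop = FALSE]
  y <- external_features$label
  rows <- lapply(fit$models, function(mdl) {
    prob <- predict_prob(mdl, fit$fits[[mdl]], x)
    met <- classification_metrics(y, prob)
    ci <- bootstrap_auroc_ci(y, prob, fit$n_bootstrap,
                             seed = derive_seed(fit$seed, 4))
    data.frame(model_name = mdl, split = "external", t(met),
               auroc_ci_lower = ci[1], auroc_ci_upper = ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat("classifier_eval (internal held-out split):\n")
  df <- x$reports
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
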