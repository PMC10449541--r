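#' Top-k (cumulative) classification accuracy
#'
#' Fraction of predictions whose true group sits within the k best-scored
#' groups. Non-decreasing in k and equal to 1 when k reaches the number of
#' groups.
#'
#' @param predictions List of `ranked_prediction` objects, each carrying a
#'   `true_group_rank` attribute (see [predict_skm()] / [predict_mlp()]).
#' @param k Rank cutoff (>= 1).
#' @return Fraction in [0, 1]. Predictions whose true group is unknown to the
#'   model count as misses at every k.
#' @export
topk_accuracy <- function(predictions, k) {
  if (k < 1) stop_fx("k must be >= 1", class = "fx_validation_error")
  ranks <- vapply(predictions, function(p) {
    r <- attr(p, "true_group_rank")
    if (is.null(r)) stop_fx("prediction lacks a true-group rank",
                            class = "fx_validation_error")
    as.numeric(r)
  }, numeric(1))
  mean(ranks <= k)
}

#' Built-in model specifications for the evaluation harness
#'
#' A model spec is a pair of closures — `fit(dimtable, labels, seed)` and
#' `predict(model, dimtable, true_groups)` returning a list of
#' `ranked_prediction` — so any classifier can be dropped into
#' [stratified_cv()]. `model_spec_skm()` and `model_spec_mlp()` wrap the
#' package's own classifiers; `model_spec_rf()` and `model_spec_xgb()` are
#' thin adapters over the off-the-shelf randomForest and xgboost packages
#' (suggested dependencies) applied to the same 10-feature input as the MLP.
#'
#' @param ... Extra arguments forwarded to the underlying fit function
#'   ([fit_mlp()] for `model_spec_mlp`; `randomForest()` / `xgboost()` for the
#'   adapters).
#' @return A `model_spec` list with elements `name`, `fit`, `predict`.
#' @export
model_spec_skm <- function() {
  structure(list(
    name = "skm",
    fit = function(dimtable, labels, seed) fit_skm(dimtable, labels),
    predict = function(model, dimtable, true_groups = NULL) {
      lapply(seq_len(nrow(dimtable$matrix)), function(i)
        predict_skm(model, dimtable$matrix[i, ],
                    if (is.null(true_groups)) NA_character_ else true_groups[i]))
    }), class = "model_spec")
}

#' @rdname model_spec_skm
#' @export
model_spec_mlp <- function(...) {
  args <- list(...)
  structure(list(
    name = "mlp",
    fit = function(dimtable, labels, seed)
      do.call(fit_mlp, c(list(dimtable = dimtable, labels = labels,
                              seed = seed), args)),
    predict = function(model, dimtable, true_groups = NULL)
      predict_mlp(model, dimtable, true_groups)), class = "model_spec")
}

#' @rdname model_spec_skm
#' @export
model_spec_rf <- function(...) {
  args <- list(...)
  structure(list(
    name = "rf",
    fit = function(dimtable, labels, seed) {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop_fx("the randomForest package is required for model_spec_rf",
                class = "fx_dependency_error")
      with_seed(seed, {
        fit <- do.call(randomForest::randomForest,
                       c(list(x = mlp_features(dimtable),
                              y = factor(labels)), args))
        list(fit = fit, groups = levels(factor(labels)))
      })
    },
    predict = function(model, dimtable, true_groups = NULL) {
      probs <- stats::predict(model$fit, mlp_features(dimtable), type = "prob")
      lapply(seq_len(nrow(probs)), function(i)
        ranked_prediction(colnames(probs), probs[i, ],
                          if (is.null(true_groups)) NA_character_ else true_groups[i]))
    }), class = "model_spec")
}

#' @rdname model_spec_skm
#' @export
model_spec_xgb <- function(nrounds = 50, ...) {
  args <- list(...)
  structure(list(
    name = "xgb",
    fit = function(dimtable, labels, seed) {
      if (!requireNamespace("xgboost", quietly = TRUE))
        stop_fx("the xgboost package is required for model_spec_xgb",
                class = "fx_dependency_error")
      groups <- unique(labels)
      fit <- do.call(xgboost::xgboost,
                     c(list(data = mlp_features(dimtable),
                            label = match(labels, groups) - 1L,
                            nrounds = nrounds,
                            objective = "multi:softprob",
                            num_class = length(groups),
                            nthread = 1, verbose = 0, seed = seed), args))
      list(fit = fit, groups = groups)
    },
    predict = function(model, dimtable, true_groups = NULL) {
      p <- stats::predict(model$fit, mlp_features(dimtable))
      probs <- matrix(p, ncol = length(model$groups), byrow = TRUE)
      lapply(seq_len(nrow(probs)), function(i)
        ranked_prediction(model$groups, probs[i, ],
                          if (is.null(true_groups)) NA_character_ else true_groups[i]))
    }), class = "model_spec")
}

# Deterministic stratified fold assignment: within each stratum the shuffled
# members are dealt round-robin over folds, so per-stratum fold counts differ
# by at most 1. Strata smaller than n_splits are pooled into an "other"
# stratum (assignment only; labels are untouched).
stratified_folds <- function(labels, n_splits) {
  strata <- labels
  small <- names(which(table(labels) < n_splits))
  if (length(small)) {
    warning(sprintf("group(s) smaller than n_splits pooled for fold assignment: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    strata[strata %in% small] <- ".other"
  }
  fold <- integer(length(labels))
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    fold[idx] <- rep_len(seq_len(n_splits), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of a group classifier
#'
#' Splits a labeled food table into `n_splits` folds preserving group
#' proportions (per-group fold counts differ by at most 1), and for each fold
#' refits everything — the dimensionless scale factors AND the model — on the
#' training portion only, projecting the held-out fold with the frozen
#' training scale. This keeps validation statistics out of the fitted space.
#'
#' @param table A labeled [food_table()].
#' @param model_spec A `model_spec` (default [model_spec_skm()]).
#' @param n_splits Number of folds (>= 2).
#' @param seed Integer seed for fold assignment (and model fitting).
#' @return List with `fold_accuracy` (top-1 per fold), `mean_accuracy`,
#'   `fold_assignment` (fold id per food), `fold_scales` (per-fold
#'   `scale_factors`, for audit), and `predictions` (per-fold lists of
#'   `ranked_prediction`).
#' @export
stratified_cv <- function(table, model_spec = model_spec_skm(),
                          n_splits = 5, seed = 1) {
  stopifnot(inherits(table, "food_table"))
  if (n_splits < 2) stop_fx("n_splits must be >= 2", class = "fx_validation_error")
  labels <- table$records$group
  if (anyNA(labels))
    stop_fx("stratified_cv requires a fully labeled table",
            class = "fx_validation_error")

  with_seed(seed, {
    fold <- stratified_folds(labels, n_splits)
    acc <- numeric(n_splits)
    scales <- vector("list", n_splits)
    preds <- vector("list", n_splits)
    for (f in seq_len(n_splits)) {
      tr <- fold != f
      dim_tr <- fit_dimensionless(table$vectors[tr, , drop = FALSE])
      scales[[f]] <- dim_tr$scale
      model <- model_spec$fit(dim_tr, labels[tr], seed + f)
      dim_va <- project_table(table$vectors[!tr, , drop = FALSE], dim_tr$scale)
      known <- labels[!tr] %in% unique(labels[tr])
      p <- model_spec$predict(model, dim_va,
                              ifelse(known, labels[!tr], NA_character_))
      top1 <- vapply(p, function(x) x$group[1], character(1))
      acc[f] <- mean(known & top1 == labels[!tr])
      preds[[f]] <- p
    }
    list(fold_accuracy = acc, mean_accuracy = mean(acc),
         fold_assignment = fold, fold_scales = scales, predictions = preds)
  })
}
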