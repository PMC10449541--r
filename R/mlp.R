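#' Feature matrix for the MLP classifier
#'
#' The MLP input is the 9 dimensionless components plus the Euclidean norm of
#' the dimensionless vector as a 10th feature. The norm restores magnitude
#' information that cosine-based scoring discards (foods with the same
#' nutrient proportions but very different concentrations differ only here).
#'
#' @param dimtable A `dimensionless_table`.
#' @return N x 10 numeric matrix.
#' @export
mlp_features <- function(dimtable) {
  stopifnot(inherits(dimtable, "dimensionless_table"))
  cbind(dimtable$matrix, magnitude = dimtable$magnitudes)
}

# Stratified index split: returns validation indices covering about
# `fraction` of each label. Deterministic given the current RNG state.
stratified_holdout <- function(labels, fraction) {
  val <- integer(0)
  for (g in unique(labels)) {
    idx <- which(labels == g)
    n_val <- floor(length(idx) * fraction + 0.5)
    if (length(idx) - n_val < 1)
      stop_fx("group '%s' would have no training members after stratification",
              g, class = "fx_stratification_error")
    if (n_val > 0) val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_forward <- function(params, X) {
  a1 <- relu(sweep(X %*% params$W1, 2, params$b1, `+`))
  a2 <- relu(sweep(a1 %*% params$W2, 2, params$b2, `+`))
  z3 <- sweep(a2 %*% params$W3, 2, params$b3, `+`)
  list(a1 = a1, a2 = a2, probs = softmax_rows(z3))
}

cross_entropy <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

#' Train the multilayer-perceptron group classifier
#'
#' A small feed-forward network over the 10-feature input (9 dimensionless
#' components + magnitude): two ReLU hidden layers and a softmax output with
#' cross-entropy loss, trained full-batch with the Adam optimizer. An internal
#' stratified split holds out a validation fraction; train and validation loss
#' are recorded every epoch. Training is deterministic given `seed`.
#'
#' @param dimtable A `dimensionless_table` of the training foods.
#' @param labels Group label per row.
#' @param topology Widths of the two hidden layers.
#' @param seed Integer seed controlling the split and weight initialization.
#' @param epochs Training epochs (full-batch steps).
#' @param split_fraction Fraction held out for validation (stratified).
#' @param learning_rate Adam step size.
#'
#' @return Object of class `mlp_model`: `params` (weights), `groups`,
#'   `feature_center`/`feature_scale` (input standardization), `topology`,
#'   `seed`, `training_log` (per-epoch train/validation loss), and
#'   `validation_accuracy` (top-1 on the held-out split).
#' @export
fit_mlp <- function(dimtable, labels, topology = c(32, 32), seed = 1,
                    epochs = 300, split_fraction = 0.2, learning_rate = 0.01) {
  stopifnot(inherits(dimtable, "dimensionless_table"))
  labels <- as.character(labels)
  if (anyNA(labels) || length(labels) != nrow(dimtable$matrix))
    stop_fx("need one non-missing label per row", class = "fx_validation_error")
  groups <- unique(labels)
  if (length(groups) < 2)
    stop_fx("need at least 2 groups to train a classifier",
            class = "fx_validation_error")
  if (length(topology) != 2 || any(topology < 1))
    stop_fx("topology must give two positive hidden-layer widths",
            class = "fx_validation_error")

  X_all <- mlp_features(dimtable)
  y_all <- match(labels, groups)

  with_seed(seed, {
    val_idx <- if (split_fraction > 0) stratified_holdout(labels, split_fraction)
               else integer(0)
    tr_idx <- setdiff(seq_len(nrow(X_all)), val_idx)
    if (length(unique(labels[tr_idx])) < length(groups))
      stop_fx("a group is absent from the training split",
              class = "fx_stratification_error")

    ctr <- colMeans(X_all[tr_idx, , drop = FALSE])
    scl <- apply(X_all[tr_idx, , drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    std <- function(X) sweep(sweep(X, 2, ctr), 2, scl, `/`)
    X_tr <- std(X_all[tr_idx, , drop = FALSE]); y_tr <- y_all[tr_idx]
    X_va <- std(X_all[val_idx, , drop = FALSE]); y_va <- y_all[val_idx]

    sizes <- c(ncol(X_all), topology, length(groups))
    he_init <- function(fan_in, fan_out)
      matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
             fan_in, fan_out)
    params <- list(W1 = he_init(sizes[1], sizes[2]), b1 = numeric(sizes[2]),
                   W2 = he_init(sizes[2], sizes[3]), b2 = numeric(sizes[3]),
                   W3 = he_init(sizes[3], sizes[4]), b3 = numeric(sizes[4]))
    m <- lapply(params, function(p) p * 0)
    v <- lapply(params, function(p) p * 0)
    b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
    n_tr <- length(y_tr)
    Y <- matrix(0, n_tr, length(groups)); Y[cbind(seq_len(n_tr), y_tr)] <- 1

    log_tr <- numeric(epochs); log_va <- rep(NA_real_, epochs)
    for (ep in seq_len(epochs)) {
      fw <- mlp_forward(params, X_tr)
      log_tr[ep] <- cross_entropy(fw$probs, y_tr)
      if (length(val_idx))
        log_va[ep] <- cross_entropy(mlp_forward(params, X_va)$probs, y_va)

      d3 <- (fw$probs - Y) / n_tr
      g <- list(W3 = t(fw$a2) %*% d3, b3 = colSums(d3))
      d2 <- (d3 %*% t(params$W3)) * (fw$a2 > 0)
      g$W2 <- t(fw$a1) %*% d2; g$b2 <- colSums(d2)
      d1 <- (d2 %*% t(params$W2)) * (fw$a1 > 0)
      g$W1 <- t(X_tr) %*% d1; g$b1 <- colSums(d1)

      for (nm in names(params)) {
        m[[nm]] <- b1m * m[[nm]] + (1 - b1m) * g[[nm]]
        v[[nm]] <- b2m * v[[nm]] + (1 - b2m) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - b1m^ep)
        vhat <- v[[nm]] / (1 - b2m^ep)
        params[[nm]] <- params[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }

    val_acc <- if (length(val_idx)) {
      pv <- mlp_forward(params, X_va)$probs
      mean(max.col(pv, ties.method = "first") == y_va)
    } else NA_real_

    structure(list(params = params, groups = groups,
                   feature_center = ctr, feature_scale = scl,
                   topology = topology, seed = seed,
                   training_log = data.frame(epoch = seq_len(epochs),
                                             train_loss = log_tr,
                                             validation_loss = log_va),
                   validation_accuracy = val_acc),
              class = "mlp_model")
  })
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> 10-%s-%d, %d epochs, validation accuracy %s\n",
              paste(x$topology, collapse = "-"), length(x$groups),
              nrow(x$training_log),
              ifelse(is.na(x$validation_accuracy), "NA",
                     sprintf("%.3f", x$validation_accuracy))))
  invisible(x)
}

#' Rank groups for foods with a trained MLP
#'
#' @param model An `mlp_model`.
#' @param dimtable A `dimensionless_table` of foods to classify (projected
#'   with the same scale the model was trained in).
#' @param true_groups Optional known labels (one per row); when given, each
#'   prediction carries its `true_group_rank` attribute.
#' @return List of `ranked_prediction` objects, one per row.
#' @export
predict_mlp <- function(model, dimtable, true_groups = NULL) {
  stopifnot(inherits(model, "mlp_model"))
  X <- mlp_features(dimtable)
  X <- sweep(sweep(X, 2, model$feature_center), 2, model$feature_scale, `/`)
  probs <- mlp_forward(model$params, X)$probs
  lapply(seq_len(nrow(X)), function(i)
    ranked_prediction(model$groups, probs[i, ],
                      if (is.null(true_groups)) NA_character_ else true_groups[i]))
}
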