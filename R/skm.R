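#' Fit spherical-k-means-style group centroids
#'
#' With group labels known, each exchange group's centroid is placed
#' supervised: the per-component mean of the group's dimensionless vectors,
#' normalized to unit length. Classification is then maximum cosine
#' similarity to these unit directions — equivalent to a single-layer linear
#' network with normalized weights and no activation.
#'
#' @param dimtable A `dimensionless_table` from [fit_dimensionless()].
#' @param labels Character vector of group names, one per row.
#'
#' @return Object of class `skm_model`: `centroids` (G x 9 unit-norm matrix,
#'   one row per group, in first-appearance order), `groups`, `support`
#'   (training foods per group), and the `scale` used to fit the space.
#' @export
fit_skm <- function(dimtable, labels) {
  stopifnot(inherits(dimtable, "dimensionless_table"))
  labels <- as.character(labels)
  if (length(labels) != nrow(dimtable$matrix))
    stop_fx("need one label per row", class = "fx_validation_error")
  if (anyNA(labels))
    stop_fx("every row must be labeled", class = "fx_validation_error")
  groups <- unique(labels)
  if (length(groups) < 2)
    stop_fx("need at least 2 groups", class = "fx_validation_error")

  centroids <- matrix(NA_real_, length(groups), ncol(dimtable$matrix),
                      dimnames = list(groups, colnames(dimtable$matrix)))
  support <- integer(length(groups))
  for (g in seq_along(groups)) {
    rows <- dimtable$matrix[labels == groups[g], , drop = FALSE]
    m <- colMeans(rows)
    nm <- vec_norm(m)
    if (nm == 0)
      stop_fx("group '%s' has an all-zero mean vector", groups[g],
              class = "fx_degenerate_group_error")
    centroids[g, ] <- m / nm
    support[g] <- nrow(rows)
  }
  structure(list(centroids = centroids, groups = groups,
                 support = support, scale = dimtable$scale),
            class = "skm_model")
}

#' @export
print.skm_model <- function(x, ...) {
  cat(sprintf("<skm_model> %d centroids over %d foods\n",
              length(x$groups), sum(x$support)))
  invisible(x)
}

# Build a ranked_prediction from per-group scores (model order), sorted
# descending with ties keeping model order. When the true label is known its
# rank is 1 + number of groups scoring STRICTLY higher (so tied groups share
# the best rank), deterministic.
ranked_prediction <- function(groups, scores, true_group = NA_character_) {
  ord <- order(-scores)                      # stable for ties
  rp <- data.frame(group = groups[ord], score = scores[ord],
                   stringsAsFactors = FALSE, row.names = NULL)
  attr(rp, "true_group") <- true_group
  if (!is.na(true_group)) {
    i <- match(true_group, groups)
    if (is.na(i))
      stop_fx("true group '%s' unknown to the model", true_group,
              class = "fx_validation_error")
    attr(rp, "true_group_rank") <- 1L + sum(scores > scores[i])
  }
  class(rp) <- c("ranked_prediction", "data.frame")
  rp
}

#' Classify a food by cosine similarity to the group centroids
#'
#' Scores every group as the cosine similarity between the food's
#' dimensionless vector and the group's unit centroid, and returns the full
#' ranking (best first). Ties break by model centroid order.
#'
#' @param model An `skm_model` from [fit_skm()].
#' @param vector Dimensionless 9-vector (e.g. `project_food(...)$vector`),
#'   nonzero.
#' @param true_group Optional known label; when given, the returned object
#'   carries attribute `true_group_rank` (1-based position of the true group,
#'   ties sharing the best rank).
#'
#' @return A `ranked_prediction`: data.frame of (group, score) sorted by
#'   non-increasing score.
#' @export
predict_skm <- function(model, vector, true_group = NA_character_) {
  stopifnot(inherits(model, "skm_model"))
  v <- as.numeric(vector)
  if (vec_norm(v) == 0)
    stop_fx("cannot classify a zero vector", class = "fx_degenerate_vector_error")
  scores <- as.numeric(model$centroids %*% v) / vec_norm(v)
  scores <- pmin(1, pmax(0, scores))
  ranked_prediction(model$groups, scores, true_group)
}

#' @export
print.ranked_prediction <- function(x, ...) {
  cat("<ranked_prediction>\n")
  print.data.frame(utils::head(as.data.frame(x), 5))
  r <- attr(x, "true_group_rank")
  if (!is.null(r)) cat(sprintf("true group '%s' at rank %d\n",
                               attr(x, "true_group"), r))
  invisible(x)
}

#' Save / load a fitted centroid model as JSON
#'
#' @param model An `skm_model`.
#' @param path JSON file path.
#' @return `write_skm_model`: invisibly, the path. `read_skm_model`: the model.
#' @export
write_skm_model <- function(model, path) {
  stopifnot(inherits(model, "skm_model"))
  jsonlite::write_json(
    list(groups = model$groups, support = model$support,
         centroids = apply(model$centroids, 1, as.list),
         scale = list(column_sums = as.list(model$scale$column_sums),
                      n = model$scale$n,
                      degenerate = as.list(model$scale$degenerate))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_skm_model
#' @export
read_skm_model <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = FALSE)
  cent <- do.call(rbind, lapply(x$centroids, unlist))
  rownames(cent) <- x$groups
  colnames(cent) <- nutrient_components()
  structure(list(centroids = cent, groups = x$groups,
                 support = as.integer(x$support),
                 scale = structure(list(column_sums = unlist(x$scale$column_sums),
                                        n = as.integer(x$scale$n),
                                        degenerate = unlist(x$scale$degenerate)),
                                   class = "scale_factors")),
            class = "skm_model")
}
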