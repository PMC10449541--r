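#' Fit the dimensionless transform on a food table
#'
#' Rescales every nutrient column so the transformed table is unit-free and
#' each non-degenerate column has mean exactly 1:
#' \deqn{\bar{x}_{ij} = N \, x_{ij} / \sum_{i=1}^{N} x_{ij}}
#' where N is the number of foods. Columns whose sum is 0 (a nutrient absent
#' from the whole table) are mapped to all-zeros and flagged as degenerate.
#' The per-column sums are retained so that unseen foods can be projected into
#' the same fitted space with [project_food()].
#'
#' @param table A [food_table()], or an N x 9 nonnegative matrix of expanded
#'   nutrient vectors.
#'
#' @return Object of class `dimensionless_table`: list with `matrix` (N x 9
#'   dimensionless values), `magnitudes` (per-row Euclidean norm of the
#'   dimensionless vector), and `scale` (class `scale_factors`: `column_sums`,
#'   `n`, `degenerate` flags).
#' @export
#' @examples
#' tab <- generate_food_table(n_per_group = 3, noise_scale = 0.1, seed = 1)
#' dt <- fit_dimensionless(tab)
#' colMeans(dt$matrix)   # all 1 (up to floating point) for active columns
fit_dimensionless <- function(table) {
  vectors <- if (inherits(table, "food_table")) table$vectors else as.matrix(table)
  if (is.null(dim(vectors)) || nrow(vectors) < 1)
    stop_fx("cannot fit dimensionless transform on an empty table",
            class = "fx_empty_input_error")
  if (ncol(vectors) != 9)
    stop_fx("expected 9 nutrient columns, got %d", ncol(vectors),
            class = "fx_validation_error")
  check_nonneg_finite(vectors, "nutrient matrix")
  colnames(vectors) <- nutrient_components()

  n <- nrow(vectors)
  sums <- colSums(vectors)
  degenerate <- sums == 0
  scale <- structure(list(column_sums = sums, n = n, degenerate = degenerate),
                     class = "scale_factors")
  denom <- ifelse(degenerate, 1, sums)
  mat <- sweep(vectors, 2, n / denom, `*`)
  mat[, degenerate] <- 0
  structure(list(matrix = mat,
                 magnitudes = sqrt(rowSums(mat^2)),
                 scale = scale),
            class = "dimensionless_table")
}

#' @export
print.dimensionless_table <- function(x, ...) {
  cat(sprintf("<dimensionless_table> %d x %d (reference N = %d, %d degenerate column(s))\n",
              nrow(x$matrix), ncol(x$matrix), x$scale$n, sum(x$scale$degenerate)))
  invisible(x)
}

#' Project a food vector into a fitted dimensionless space
#'
#' Applies the frozen per-column scale of a fitted reference table to a new
#' food, so classifying one food never changes the space. Component j becomes
#' `N * x_j / column_sums[j]`; degenerate columns map to 0. The Euclidean
#' norm of the dimensionless vector is returned as `magnitude` (this is the
#' extra feature the MLP receives, since cosine comparisons discard it).
#'
#' @param vector Expanded nonnegative 9-vector (see [expand_features()]).
#' @param scale A `scale_factors` object from [fit_dimensionless()].
#'
#' @return List with `vector` (dimensionless 9-vector) and `magnitude`.
#' @export
project_food <- function(vector, scale) {
  stopifnot(inherits(scale, "scale_factors"))
  v <- as_nutrient_vector(vector)
  check_nonneg_finite(v, "food vector")
  denom <- ifelse(scale$degenerate, 1, scale$column_sums)
  out <- v * (scale$n / denom)     # same op order as the fit: exact identity
  out[scale$degenerate] <- 0
  list(vector = out, magnitude = vec_norm(out))
}

# Project many expanded vectors at once; returns a dimensionless_table that
# reuses the frozen scale (used by the cross-validation harness so validation
# folds never contribute to the column sums).
project_table <- function(vectors, scale) {
  stopifnot(inherits(scale, "scale_factors"))
  vectors <- as.matrix(vectors)
  check_nonneg_finite(vectors, "nutrient matrix")
  denom <- ifelse(scale$degenerate, 1, scale$column_sums)
  mat <- sweep(vectors, 2, scale$n / denom, `*`)
  mat[, scale$degenerate] <- 0
  colnames(mat) <- nutrient_components()
  structure(list(matrix = mat, magnitudes = sqrt(rowSums(mat^2)), scale = scale),
            class = "dimensionless_table")
}

#' Serialize / restore scale factors
#'
#' A fitted dimensionless space is fully described by its per-column sums,
#' reference count and degenerate flags, so it can ship with a trained model.
#'
#' @param scale A `scale_factors` object.
#' @param path JSON file path.
#' @return `write_scale_factors`: invisibly, the path. `read_scale_factors`:
#'   the restored `scale_factors` object.
#' @export
write_scale_factors <- function(scale, path) {
  stopifnot(inherits(scale, "scale_factors"))
  jsonlite::write_json(
    list(column_sums = as.list(scale$column_sums), n = scale$n,
         degenerate = as.list(scale$degenerate)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scale_factors
#' @export
read_scale_factors <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(column_sums = unlist(x$column_sums),
                 n = as.integer(x$n),
                 degenerate = unlist(x$degenerate)),
            class = "scale_factors")
}
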