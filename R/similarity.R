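#' Cosine similarity between two food vectors
#'
#' The similarity between foods A and B is the cosine of the angle between
#' their nutrient vectors, \eqn{\langle A,B\rangle / (\|A\|\,\|B\|)}. It
#' depends on nutrient concentration (direction), not amount (magnitude), so
#' 50 g and 200 g of the same food are identical. For nonnegative vectors the
#' value lies in [0, 1]; it is clamped there against floating-point overshoot.
#'
#' @param u,v Nonnegative numeric vectors of equal length, each nonzero.
#' @return Similarity in [0, 1].
#' @export
#' @examples
#' cosine_similarity(c(3, 4, 0), c(4, 3, 0))  # 0.96
cosine_similarity <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v))
    stop_fx("vectors differ in length", class = "fx_validation_error")
  nu <- vec_norm(u); nv <- vec_norm(v)
  if (nu == 0 || nv == 0)
    stop_fx("cosine similarity is undefined for a zero vector",
            class = "fx_degenerate_vector_error")
  min(1, max(0, sum(u * v) / (nu * nv)))
}

#' Closed-form equivalence factor between two foods
#'
#' The scalar alpha that brings food B closest to food A, i.e. the
#' least-squares projection coefficient
#' \deqn{\alpha = \|A\| \cos\theta_{AB} / \|B\| = \langle A,B\rangle / \|B\|^2.}
#' alpha * 100 g of B is the portion of B equivalent to 100 g of A. Both
#' vectors must live in the same space; equivalence is computed in the
#' dimensionless space so no single unit (kcal vs mg) dominates.
#'
#' @param A Target food vector (nonnegative).
#' @param B Candidate food vector (nonnegative, nonzero).
#' @return alpha >= 0.
#' @export
#' @examples
#' equivalence_factor(c(3, 4, 0), c(4, 3, 0))  # 24/25
equivalence_factor <- function(A, B) {
  A <- as.numeric(A); B <- as.numeric(B)
  if (length(A) != length(B))
    stop_fx("vectors differ in length", class = "fx_validation_error")
  nb2 <- sum(B^2)
  if (nb2 == 0)
    stop_fx("equivalence factor is undefined for a zero candidate vector",
            class = "fx_degenerate_vector_error")
  sum(A * B) / nb2
}

#' Rank the foods most equivalent to a target
#'
#' Projects the target and every candidate into the fitted dimensionless
#' space, sorts candidates by cosine similarity to the target (descending,
#' ties broken by table order), and reports for each the dimensionless
#' equivalence factor `alpha`, the equivalent portion `grams = 100 * alpha`,
#' and the raw-space factor `alpha_raw` for inspection. A candidate with the
#' same name as the target is excluded; an identical composition under a
#' different name is retained.
#'
#' @param target A food name present in `table`, or a record (named list /
#'   one-row data.frame) accepted by [expand_features()].
#' @param table A [food_table()] of candidates.
#' @param scale Optional `scale_factors`; defaults to fitting on `table`.
#' @param k Number of equivalents to return (capped at the candidate count).
#' @param same_group_only Restrict candidates to the target's group (requires
#'   a labeled table and a target with a known group).
#'
#' @return data.frame with columns `target_name`, `candidate_name`, `group`,
#'   `similarity`, `alpha`, `grams`, `alpha_raw`, ordered best-first.
#' @export
rank_equivalents <- function(target, table, scale = NULL, k = 5,
                             same_group_only = FALSE) {
  stopifnot(inherits(table, "food_table"))
  if (k < 1) stop_fx("k must be >= 1", class = "fx_validation_error")
  if (is.null(scale)) scale <- fit_dimensionless(table)$scale

  if (is.character(target) && length(target) == 1) {
    idx <- which(table$records$name == target)
    if (!length(idx))
      stop_fx("food '%s' not found in table", target, class = "fx_validation_error")
    target_name <- target
    target_raw <- table$vectors[idx[1], ]
    target_group <- table$records$group[idx[1]]
  } else {
    target <- as.list(target)
    target_name <- as.character(target$name %||% "target")
    target_raw <- suppressWarnings(expand_features(target))
    target_group <- target$group %||% NA_character_
  }

  keep <- table$records$name != target_name
  if (same_group_only) {
    if (all(is.na(table$records$group)))
      stop_fx("same_group_only requires a labeled table",
              class = "fx_validation_error")
    if (is.na(target_group))
      stop_fx("same_group_only requires the target's group",
              class = "fx_validation_error")
    keep <- keep & !is.na(table$records$group) &
      table$records$group == target_group
  }
  cand_idx <- which(keep)
  if (!length(cand_idx))
    stop_fx("no candidate foods after exclusions", class = "fx_empty_input_error")

  tgt_dim <- project_food(target_raw, scale)$vector
  if (vec_norm(tgt_dim) == 0)
    stop_fx("target has a zero dimensionless vector",
            class = "fx_degenerate_vector_error")

  cand_dim <- project_table(table$vectors[cand_idx, , drop = FALSE], scale)$matrix
  sims <- numeric(length(cand_idx))
  alphas <- numeric(length(cand_idx))
  alphas_raw <- numeric(length(cand_idx))
  for (i in seq_along(cand_idx)) {
    b <- cand_dim[i, ]
    if (vec_norm(b) == 0) { sims[i] <- -Inf; next }
    sims[i] <- cosine_similarity(tgt_dim, b)
    alphas[i] <- equivalence_factor(tgt_dim, b)
    alphas_raw[i] <- equivalence_factor(target_raw, table$vectors[cand_idx[i], ])
  }
  ord <- order(-sims)                      # stable: ties keep table order
  ord <- ord[is.finite(sims[ord])]
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(
    target_name = target_name,
    candidate_name = table$records$name[cand_idx[ord]],
    group = table$records$group[cand_idx[ord]],
    similarity = sims[ord],
    alpha = alphas[ord],
    grams = 100 * alphas[ord],
    alpha_raw = alphas_raw[ord],
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Optimal two-food blend for a target composition
#'
#' Finds nonnegative coefficients (alpha, beta) so that alpha*A + beta*B is as
#' close as possible (least squares) to the target C. Solved by the 2x2 normal
#' equations; if the unconstrained optimum has a negative coefficient, the
#' solution falls back to the better single-food projection with the other
#' coefficient clamped at 0.
#'
#' @param C Target vector.
#' @param A,B Component food vectors; must be nonzero and not parallel.
#' @return List with `alpha`, `beta` (both >= 0) and `residual_norm`.
#' @export
#' @examples
#' blend_factors(c(2, 3, 0), c(1, 0, 0), c(0, 1, 0))  # alpha 2, beta 3
blend_factors <- function(C, A, B) {
  C <- as.numeric(C); A <- as.numeric(A); B <- as.numeric(B)
  if (length(unique(c(length(C), length(A), length(B)))) != 1)
    stop_fx("vectors differ in length", class = "fx_validation_error")
  na2 <- sum(A^2); nb2 <- sum(B^2)
  if (na2 == 0 || nb2 == 0)
    stop_fx("blend components must be nonzero",
            class = "fx_degenerate_vector_error")
  gram_det <- na2 * nb2 - sum(A * B)^2
  if (gram_det <= 1e-12 * na2 * nb2)
    stop_fx(paste("A and B are (nearly) parallel; use equivalence_factor()",
                  "for a single-food equivalent"),
            class = "fx_degenerate_vector_error")
  ca <- sum(C * A); cb <- sum(C * B); ab <- sum(A * B)
  alpha <- (ca * nb2 - cb * ab) / gram_det
  beta  <- (cb * na2 - ca * ab) / gram_det
  if (alpha < 0 || beta < 0) {
    # active set: best solution on each boundary of the nonnegative quadrant
    cand <- list(c(max(0, ca / na2), 0), c(0, max(0, cb / nb2)), c(0, 0))
    res <- vapply(cand, function(p) vec_norm(C - p[1] * A - p[2] * B), numeric(1))
    best <- cand[[which.min(res)]]
    alpha <- best[1]; beta <- best[2]
  }
  list(alpha = alpha, beta = beta,
       residual_norm = vec_norm(C - alpha * A - beta * B))
}
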