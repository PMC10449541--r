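unit9 <- function(...) { v <- c(c(...), rep(0, 9))[1:9]; v / sqrt(sum(v^2)) }

# wrap raw rows as a dimensionless_table for direct centroid tests
as_dimtable <- function(m) {
  colnames(m) <- nutrient_components()
  structure(list(matrix = m, magnitudes = sqrt(rowSums(m^2)),
                 scale = structure(list(column_sums = colSums(m), n = nrow(m),
                                        degenerate = colSums(m) == 0),
                                   class = "scale_factors")),
            class = "dimensionless_table")
}

test_that("centroids are unit-normalized group means", {
  m <- rbind(c(1, rep(0, 8)), c(0, 1, rep(0, 7)), c(0, 0, 2, rep(0, 6)),
             c(0, 0, 5, rep(0, 6)))
  model <- fit_skm(as_dimtable(m), c("g1", "g1", "g2", "g2"))
  # mean (0.5, 0.5, 0...) normalized -> (1/sqrt2, 1/sqrt2, 0...)
  expect_equal(unname(model$centroids["g1", ]), unit9(1, 1))
  # positive multiples of one direction keep that unit direction
  expect_equal(unname(model$centroids["g2", ]), unit9(0, 0, 1))
  expect_equal(model$support, c(2L, 2L))
  expect_equal(apply(model$centroids, 1, function(r) sqrt(sum(r^2))),
               c(g1 = 1, g2 = 1), tolerance = 1e-9)
  # single-food group: centroid is that food's unit vector
  m2 <- rbind(c(3, 4, rep(0, 7)), c(0, 2, rep(0, 7)))
  model2 <- fit_skm(as_dimtable(m2), c("a", "b"))
  expect_equal(unname(model2$centroids["a", ]), unit9(3, 4))
})

test_that("predict_skm ranks by cosine similarity with stable ties", {
  m <- rbind(c(1, rep(0, 8)), c(0, 1, rep(0, 7)))
  model <- fit_skm(as_dimtable(m), c("first", "second"))
  p <- predict_skm(model, c(0.9, 0.1, rep(0, 7)))
  expect_equal(p$group[1], "first")
  expect_error(predict_skm(model, rep(0, 9)),
               class = "fx_degenerate_vector_error")
  # exact centroid scores 1
  p2 <- predict_skm(model, model$centroids["second", ])
  expect_equal(p2$group[1], "second")
  expect_equal(p2$score[1], 1)
})

test_that("predict_skm agrees with a brute-force argmax oracle", {
  tab <- generate_food_table(n_per_group = 3, noise_scale = 0.2, seed = 13)
  dt <- fit_dimensionless(tab)
  model <- fit_skm(dt, tab$records$group)
  set.seed(17)
  for (rep in 1:100) {
    v <- runif(9, 0.001, 5)
    p <- predict_skm(model, v)
    sims <- vapply(seq_along(model$groups), function(j)
      cosine_similarity(v, model$centroids[j, ]), numeric(1))
    expect_identical(p$group, model$groups[order(-sims)])
  }
})

test_that("true-group ranks follow the strictly-greater rule", {
  m <- rbind(c(1, rep(0, 8)), c(0, 1, rep(0, 7)), c(0, 1, rep(0, 7)))
  model <- fit_skm(as_dimtable(m), c("a", "b", "c"))  # b and c identical
  p <- predict_skm(model, c(0, 1, rep(0, 7)), true_group = "c")
  expect_equal(attr(p, "true_group_rank"), 1L)  # tied at the top
  p2 <- predict_skm(model, c(1, 0.5, rep(0, 7)), true_group = "b")
  expect_equal(attr(p2, "true_group_rank"), 2L)
})

test_that("topk accuracy counts ranks at or below k and is monotone", {
  fake <- function(r) structure(data.frame(group = "x", score = 1),
                                true_group_rank = r,
                                class = c("ranked_prediction", "data.frame"))
  preds <- lapply(c(1, 2, 4), fake)
  expect_equal(topk_accuracy(preds, 1), 1 / 3)
  expect_equal(topk_accuracy(preds, 3), 2 / 3)
  expect_equal(topk_accuracy(lapply(c(1, 1, 1), fake), 1), 1)
  accs <- vapply(1:19, function(k) topk_accuracy(preds, k), numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_error(topk_accuracy(preds, 0), class = "fx_validation_error")
})

test_that("skm model survives a JSON round trip", {
  tab <- two_group_table()
  dt <- fit_dimensionless(tab)
  model <- fit_skm(dt, tab$records$group)
  path <- tempfile(fileext = ".json")
  write_skm_model(model, path)
  back <- read_skm_model(path)
  expect_equal(back$centroids, model$centroids)
  expect_equal(back$groups, model$groups)
  v <- dt$matrix[1, ]
  expect_equal(predict_skm(back, v)$score, predict_skm(model, v)$score)
})

test_that("MLP separates two clean groups and is deterministic", {
  tab <- two_group_table(n = 100, noise = 0.1, seed = 11)
  dt <- fit_dimensionless(tab)
  m1 <- fit_mlp(dt, tab$records$group, seed = 3)
  expect_gte(m1$validation_accuracy, 0.95)
  m2 <- fit_mlp(dt, tab$records$group, seed = 3)
  expect_identical(tail(m1$training_log$train_loss, 1),
                   tail(m2$training_log$train_loss, 1))
  expect_identical(m1$params$W3, m2$params$W3)
  expect_true(all(is.finite(m1$training_log$train_loss)))
  # loss broadly decreases over training
  expect_lt(tail(m1$training_log$train_loss, 1),
            m1$training_log$train_loss[1])
})

test_that("MLP rejects degenerate label sets", {
  tab <- two_group_table()
  dt <- fit_dimensionless(tab)
  expect_error(fit_mlp(dt, rep("only", tab$n), seed = 1),
               class = "fx_validation_error")
})

test_that("stratified_cv balances folds and refits scales per fold", {
  tab <- generate_food_table(n_per_group = 20, noise_scale = 0.05, seed = 19)
  cv <- stratified_cv(tab, model_spec_skm(), n_splits = 5, seed = 7)
  # 19 groups x 20 foods, 5 splits: exactly 4 per group in every fold
  counts <- table(tab$records$group, cv$fold_assignment)
  expect_true(all(counts == 4))
  # same seed reproduces the assignment
  cv2 <- stratified_cv(tab, model_spec_skm(), n_splits = 5, seed = 7)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  # leakage check: per-fold sums equal sums over that fold's training rows
  for (f in 1:5) {
    tr <- cv$fold_assignment != f
    expect_equal(cv$fold_scales[[f]]$column_sums,
                 colSums(tab$vectors[tr, ]), tolerance = 1e-12)
    expect_equal(cv$fold_scales[[f]]$n, sum(tr))
  }
})

test_that("noiseless synthetic groups cross-validate perfectly", {
  tab <- generate_food_table(n_per_group = 10, noise_scale = 0, seed = 23)
  cv <- stratified_cv(tab, model_spec_skm(), n_splits = 5, seed = 23)
  expect_equal(cv$fold_accuracy, rep(1, 5))
})

test_that("groups smaller than the fold count fall back with a warning", {
  profs <- default_group_profiles()[1:3]
  t_big <- generate_food_table(profs, n_per_group = 10, noise_scale = 0.05,
                               seed = 29)
  t_small <- generate_food_table(profs[3], n_per_group = 3, noise_scale = 0.05,
                                 seed = 30)
  rec <- rbind(t_big$records[t_big$records$group != profs[[3]]$group, ],
               t_small$records)
  tab <- food_table(rec)
  expect_warning(cv <- stratified_cv(tab, model_spec_skm(), n_splits = 5,
                                     seed = 31),
                 "pooled")
  expect_length(cv$fold_accuracy, 5)
})

test_that("the random-forest adapter plugs into the harness", {
  skip_if_not_installed("randomForest")
  tab <- two_group_table(n = 15, noise = 0.1, seed = 37)
  cv <- stratified_cv(tab, model_spec_rf(ntree = 50), n_splits = 3, seed = 5)
  expect_gte(cv$mean_accuracy, 0.9)
})
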