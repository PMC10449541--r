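lab <- function(...) label_food(basic_record(...))
flag <- function(res, which) res[[which]]

test_that("solid calorie cut point is inclusive at 275 kcal", {
  expect_true(flag(lab(energy = 300, sugar = 0, carbohydrates = 0, fiber = 0),
                   "excess_calories"))
  expect_true(flag(lab(energy = 275), "excess_calories"))
  expect_false(flag(lab(energy = 275 - 1e-9), "excess_calories"))
})

test_that("liquid calories trigger on energy or free sugar", {
  expect_true(flag(lab(state = "liquid", energy = 70), "excess_calories"))
  expect_false(flag(lab(state = "liquid", energy = 69.99, sugar = 4,
                        carbohydrates = 4, fiber = 0), "excess_calories"))
  # 8 g free sugar alone trips a liquid's calorie label
  expect_true(flag(lab(state = "liquid", energy = 30, sugar = 8,
                       carbohydrates = 8, fiber = 0), "excess_calories"))
})

test_that("share-of-energy rules use 4 and 9 kcal per gram", {
  # 3 g sugar in 100 kcal -> 12% >= 10%
  expect_true(flag(lab(energy = 100, sugar = 3, carbohydrates = 3, fiber = 0),
                   "excess_sugars"))
  expect_false(flag(lab(energy = 100, sugar = 2.4999, carbohydrates = 3,
                        fiber = 0), "excess_sugars"))
  # saturated fat: 10% of energy at 9 kcal/g
  expect_true(flag(lab(energy = 180, saturated_fat = 2, total_lipids = 5),
                   "excess_saturated_fat"))
  expect_false(flag(lab(energy = 180.1, saturated_fat = 2, total_lipids = 5),
                    "excess_saturated_fat"))
  # trans fat: 1% of energy
  expect_true(flag(lab(energy = 90, trans_fat = 0.1, total_lipids = 5),
                   "excess_trans_fat"))
  expect_false(flag(lab(energy = 90.1, trans_fat = 0.01, total_lipids = 5),
                    "excess_trans_fat"))
})

test_that("trans fat is skipped with a note when absent", {
  res <- label_food(basic_record())
  expect_true(is.na(res$excess_trans_fat))
  expect_true(any(grepl("trans", res$notes)))
})

test_that("sodium trips per-kcal, absolute, and calorie-free rules", {
  expect_false(flag(lab(energy = 200, sodium = 150), "excess_sodium"))
  expect_true(flag(lab(energy = 200, sodium = 200), "excess_sodium"))
  expect_true(flag(lab(energy = 500, sodium = 300), "excess_sodium"))
  expect_false(flag(lab(energy = 500, sodium = 299.99), "excess_sodium"))
  # calorie-free drink: 45 mg threshold
  expect_true(flag(lab(state = "liquid", energy = 2, sodium = 50,
                       sugar = 0, carbohydrates = 0, fiber = 0),
                   "excess_sodium"))
  expect_false(flag(lab(state = "liquid", energy = 2, sodium = 44,
                        sugar = 0, carbohydrates = 0, fiber = 0),
                    "excess_sodium"))
})

test_that("zero-energy foods skip share rules but keep absolute rules", {
  res <- lab(energy = 0, sugar = 5, carbohydrates = 5, fiber = 0, sodium = 350)
  expect_false(res$excess_sugars)
  expect_false(res$excess_saturated_fat)
  expect_true(res$excess_sodium)          # absolute 300 mg clause
  expect_true(any(grepl("zero energy", res$notes)))
})

test_that("raising a nutrient never clears its label (monotonicity)", {
  set.seed(61)
  for (i in 1:25) {
    base <- basic_record(energy = runif(1, 10, 600),
                         sugar = runif(1, 0, 30), carbohydrates = 40,
                         saturated_fat = runif(1, 0, 10), total_lipids = 20,
                         sodium = runif(1, 0, 600))
    res1 <- label_food(base)
    bumped <- base
    bumped$sodium <- base$sodium * 2 + 10
    bumped$sugar <- base$sugar + 5
    bumped$saturated_fat <- base$saturated_fat + 2
    res2 <- label_food(bumped)
    for (l in c("excess_sugars", "excess_saturated_fat", "excess_sodium"))
      if (isTRUE(res1[[l]])) expect_true(res2[[l]])
  }
})

test_that("evidence reproduces the computed quantities", {
  rec <- basic_record(energy = 150, sugar = 6, carbohydrates = 10, fiber = 1,
                      saturated_fat = 4, total_lipids = 9, sodium = 120)
  res <- label_food(rec)
  expect_equal(res$evidence$excess_sugars$quantity, 4 * 6 / 150)
  expect_equal(res$evidence$excess_saturated_fat$quantity, 9 * 4 / 150)
  expect_equal(res$evidence$excess_sodium$per_kcal, 120 / 150)
  expect_equal(res$evidence$excess_calories$quantity, 150)
})

test_that("label_table preserves order and tallies labels", {
  tab <- generate_food_table(n_per_group = 2, noise_scale = 0.1, seed = 67)
  res <- label_table(tab)
  expect_equal(res$labels$name, tab$records$name)
  expect_equal(unname(res$summary["excess_calories"]),
               sum(res$labels$excess_calories, na.rm = TRUE))
  # shuffling the input permutes but does not change per-food labels
  perm <- sample(tab$n)
  res2 <- label_table(food_table(tab$records[perm, ]))
  expect_equal(res2$labels$excess_sodium,
               res$labels$excess_sodium[perm])
  # a table below every cut yields all-false labels
  quiet <- food_table(data.frame(name = c("w1", "w2"), energy = c(20, 30),
                                 protein = 1, total_lipids = 0.1,
                                 saturated_fat = 0, cholesterol = 0,
                                 carbohydrates = 1, sugar = 0.1, fiber = 0.5,
                                 sodium = 5))
  resq <- label_table(quiet)
  expect_false(any(unlist(resq$labels[, c("excess_calories", "excess_sugars",
                                          "excess_saturated_fat",
                                          "excess_sodium")])))
})
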