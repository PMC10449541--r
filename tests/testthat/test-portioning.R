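spec_for <- function(group) {
  s <- default_portion_specs()
  s[s$group == group, ]
}

test_that("the eight group specs carry the reference amounts", {
  specs <- default_portion_specs()
  expect_equal(nrow(specs), 8L)
  milk <- spec_for("Milk")
  expect_equal(milk$key_nutrient, "protein")
  expect_equal(milk$key_amount, 9)
  expect_equal(milk$secondary_amount, 12)
  expect_equal(milk$reference_portion, "One cup")
  fats <- spec_for("Fat and oils")
  expect_equal(fats$key_nutrient, "fat")
  expect_equal(fats$key_amount, 5)
  expect_equal(fats$reference_food, "Oil")
  expect_equal(spec_for("Vegetables")$key_amount, 4)
  expect_equal(spec_for("Fruits")$key_amount, 15)
  expect_equal(spec_for("Legumes")$key_amount, 8)
  expect_equal(spec_for("Meats")$key_amount, 7)
  expect_equal(spec_for("Sugar, honey, and candy")$key_amount, 10)
})

test_that("portions follow raw = 100 * key / density with moisture rounding", {
  # sugars: 10 g carb from a 50 g/100 g food -> 20 g, already a multiple of 5
  p <- equivalent_portion(list(name = "s", carbohydrates = 50),
                          spec_for("Sugar, honey, and candy"), "high_moisture")
  expect_equal(p$raw_grams, 20)
  expect_equal(p$rounded_grams, 20)
  expect_equal(p$delivered_key_amount, 10)
  # fruits: 15 g carb from 10 g/100 g -> 150 g
  p2 <- equivalent_portion(list(carbohydrates = 10), spec_for("Fruits"),
                           "high_moisture")
  expect_equal(p2$raw_grams, 150)
  expect_equal(p2$rounded_grams, 150)
  expect_equal(p2$delivered_key_amount, 15)
  # dry/raw meats example: 7 g protein from 21 g/100 g -> 100/3 g, unrounded
  p3 <- equivalent_portion(list(protein = 21), spec_for("Meats"), "dry_raw")
  expect_equal(p3$raw_grams, 100 / 3)
  expect_identical(p3$rounded_grams, p3$raw_grams)
  expect_equal(p3$delivered_key_amount, 7)
})

test_that("half-gram ties round up and portions never round to zero", {
  # raw 32.5 g (key 13 g carb at 40 g/100 g) -> 35
  p <- equivalent_portion(list(carbohydrates = 40),
                          list(group = "Sugar, honey, and candy",
                               key_nutrient = "carbohydrates",
                               key_amount = 13), "high_moisture")
  expect_equal(p$raw_grams, 32.5)
  expect_equal(p$rounded_grams, 35)
  # a very dense food still yields the 5 g floor
  p2 <- equivalent_portion(list(carbohydrates = 99),
                           spec_for("Vegetables"), "high_moisture")
  expect_lt(p2$raw_grams, 5)
  expect_equal(p2$rounded_grams, 5)
})

test_that("portion arithmetic is exact and homogeneous on random densities", {
  set.seed(71)
  specs <- default_portion_specs()
  for (i in 1:40) {
    s <- specs[sample(nrow(specs), 1), ]
    d <- runif(1, 1, 90)
    field <- switch(s$key_nutrient, protein = "protein",
                    fat = "total_lipids", carbohydrates = "carbohydrates")
    rec <- setNames(list(d), field)
    p <- equivalent_portion(rec, s, "dry_raw")
    expect_equal(p$raw_grams * d / 100, s$key_amount, tolerance = 1e-12)
    # doubling density halves the raw portion
    p2 <- equivalent_portion(setNames(list(2 * d), field), s, "dry_raw")
    expect_equal(p2$raw_grams, p$raw_grams / 2, tolerance = 1e-12)
    # high-moisture: multiples of 5, delivery within the rounding bound
    ph <- equivalent_portion(rec, s, "high_moisture")
    expect_equal(ph$rounded_grams %% 5, 0)
    expect_lte(abs(ph$delivered_key_amount - s$key_amount),
               (max(2.5, 5 - ph$raw_grams) / ph$raw_grams) * s$key_amount + 1e-12)
  }
})

test_that("milk reports the secondary carbohydrate delivery", {
  p <- equivalent_portion(list(protein = 3.2, carbohydrates = 4.8),
                          spec_for("Milk"), "high_moisture")
  expect_equal(p$raw_grams, 100 * 9 / 3.2)
  expect_equal(p$secondary_delivered, p$rounded_grams * 4.8 / 100)
})

test_that("zero key-nutrient density has no finite portion", {
  expect_error(equivalent_portion(list(protein = 0), spec_for("Meats"),
                                  "high_moisture"),
               class = "fx_no_finite_portion_error")
})

test_that("tolerance band is inclusive at two standard deviations", {
  s <- spec_for("Legumes")
  expect_true(portion_tolerance_check(8, s, 0.5))
  expect_true(portion_tolerance_check(8 + 2 * 0.5, s, 0.5))
  expect_false(portion_tolerance_check(8 + 3 * 0.5, s, 0.5))
  expect_true(portion_tolerance_check(8, s, 0))
})

test_that("every classifier category maps to a portion group or none", {
  map <- category_portion_map()
  expect_setequal(map$category, exchange_groups())
  known <- !is.na(map$portion_group)
  expect_true(all(map$portion_group[known] %in% default_portion_specs()$group))
  expect_true(all(map$moisture_class[known] %in% c("high_moisture", "dry_raw")))
  expect_setequal(map$category[!known],
                  c("Free energy foods", "Alcoholic beverage"))
})
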