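#' The eight exchange-group portion specifications
#'
#' Each exchange group's portion is anchored to a reference food and defined
#' by the amount of a single key nutritional component: vegetables 4 g
#' carbohydrate (carrot, half cup), fruits 15 g (apple, one piece), cereals
#' 15 g (tortilla, one piece), legumes 8 g protein (cooked beans, half cup),
#' meats 7 g protein (egg, one piece), milk 9 g protein with 12 g
#' carbohydrate reported secondarily (one cup), fats and oils 5 g fat (oil,
#' one teaspoon), and sugars 10 g carbohydrate (sugar, two teaspoons).
#'
#' @return data.frame with columns `group`, `reference_food`,
#'   `reference_portion`, `key_nutrient` (`protein`/`fat`/`carbohydrates`),
#'   `key_amount` (g), `secondary_nutrient`, `secondary_amount`.
#' @export
default_portion_specs <- function() {
  data.frame(
    group = c("Vegetables", "Fruits", "Cereals and by-products", "Legumes",
              "Meats", "Milk", "Fat and oils", "Sugar, honey, and candy"),
    reference_food = c("Carrot", "Apple", "Tortilla", "Cooked beans",
                       "Egg", "Milk", "Oil", "Sugar"),
    reference_portion = c("1/2 cup", "One piece", "One piece", "1/2 cup",
                          "One piece", "One cup", "One teaspoon",
                          "2 teaspoons"),
    key_nutrient = c("carbohydrates", "carbohydrates", "carbohydrates",
                     "protein", "protein", "protein", "fat", "carbohydrates"),
    key_amount = c(4, 15, 15, 8, 7, 9, 5, 10),
    secondary_nutrient = c(NA, NA, NA, NA, NA, "carbohydrates", NA, NA),
    secondary_amount = c(NA, NA, NA, NA, NA, 12, NA, NA),
    stringsAsFactors = FALSE)
}

#' Household-measure unit equivalences
#'
#' Kitchen units used to phrase portions: 240 mL cup, 15 mL tablespoon,
#' 5 mL teaspoon (16 tablespoons per cup, 3 teaspoons per tablespoon).
#' Display aid only — gram output is authoritative.
#' @return Named numeric vector of volumes in mL.
#' @export
household_measures <- function() {
  c(cup = 240, tablespoon = 15, teaspoon = 5)
}

# nearest multiple of 5, half rounds up: 32.5 -> 35
round_to_five <- function(x) floor(x / 5 + 0.5) * 5

#' Equivalent portion of a food from its group's key component
#'
#' The portion of a food is the weight delivering its group's key nutritional
#' component amount: `raw_grams = 100 * key_amount / density`, where density
#' is grams of key nutrient per 100 g of food. High-moisture foods (fruits,
#' vegetables, animal foods, cooked cereals and legumes) are rounded to the
#' nearest multiple of 5 g (half up, floored at 5 g) for household use; dry or
#' raw foods keep the exact weight.
#'
#' @param record Named list / one-row data.frame with the relevant nutrient
#'   fields (`protein`, `total_lipids`, `carbohydrates`) and optionally `name`.
#' @param spec One row of [default_portion_specs()] (data.frame or list).
#' @param moisture_class `"high_moisture"` or `"dry_raw"`.
#' @param group_sd Optional standard deviation (g) of the delivered key amount
#'   within the group; when given, `tolerance_flag` marks whether the rounded
#'   portion stays within `key_amount +/- 2 * group_sd`.
#' @return A `portion_result` list: `food`, `group`, `key_nutrient`,
#'   `density_per_100g`, `raw_grams`, `rounded_grams`, `moisture_class`,
#'   `delivered_key_amount`, `secondary_delivered` (for milk's carbohydrate),
#'   `tolerance_flag`.
#' @export
#' @examples
#' sugars <- default_portion_specs()[8, ]
#' equivalent_portion(list(name = "honey", carbohydrates = 50), sugars,
#'                    "high_moisture")   # 20 g
equivalent_portion <- function(record, spec,
                               moisture_class = c("high_moisture", "dry_raw"),
                               group_sd = NULL) {
  moisture_class <- match.arg(moisture_class)
  record <- as.list(record)
  spec <- as.list(spec)
  field <- switch(spec$key_nutrient,
                  protein = "protein", fat = "total_lipids",
                  carbohydrates = "carbohydrates",
                  stop_fx("unknown key nutrient '%s'", spec$key_nutrient,
                          class = "fx_validation_error"))
  density <- as.numeric(record[[field]] %||% NA)
  if (is.na(density) || density <= 0)
    stop_fx("food has no %s content: no finite portion delivers %g g",
            spec$key_nutrient, spec$key_amount,
            class = "fx_no_finite_portion_error")

  raw_grams <- 100 * spec$key_amount / density
  rounded <- if (moisture_class == "high_moisture")
    max(5, round_to_five(raw_grams)) else raw_grams
  delivered <- rounded * density / 100

  secondary <- NA_real_
  if (!is.null(spec$secondary_nutrient) && !is.na(spec$secondary_nutrient)) {
    sfield <- switch(spec$secondary_nutrient,
                     protein = "protein", fat = "total_lipids",
                     carbohydrates = "carbohydrates")
    sval <- as.numeric(record[[sfield]] %||% NA)
    if (!is.na(sval)) secondary <- rounded * sval / 100
  }

  tol <- if (!is.null(group_sd))
    portion_tolerance_check(delivered, spec, group_sd) else NA
  structure(list(food = as.character(record$name %||% "food"),
                 group = spec$group, key_nutrient = spec$key_nutrient,
                 density_per_100g = density,
                 raw_grams = raw_grams, rounded_grams = rounded,
                 moisture_class = moisture_class,
                 delivered_key_amount = delivered,
                 secondary_delivered = secondary,
                 tolerance_flag = tol),
            class = "portion_result")
}

#' @export
print.portion_result <- function(x, ...) {
  cat(sprintf("<portion_result> %s: %.6g g (raw %.6g g) delivers %.6g g %s [%s]\n",
              x$food, x$rounded_grams, x$raw_grams, x$delivered_key_amount,
              x$key_nutrient, x$moisture_class))
  invisible(x)
}

#' Check a delivered key amount against the group tolerance band
#'
#' A portion is acceptable when the key component it delivers stays within
#' the group mean plus/minus two standard deviations (inclusive).
#'
#' @param delivered Delivered key-nutrient grams.
#' @param spec Portion spec (needs `key_amount`).
#' @param group_sd Standard deviation (g) of the key amount within the group,
#'   >= 0.
#' @return TRUE iff `|delivered - key_amount| <= 2 * group_sd`.
#' @export
portion_tolerance_check <- function(delivered, spec, group_sd) {
  spec <- as.list(spec)
  if (group_sd < 0)
    stop_fx("group_sd must be >= 0", class = "fx_validation_error")
  abs(delivered - spec$key_amount) <= 2 * group_sd
}

#' Map the 19 exchange categories onto portion groups and moisture classes
#'
#' The classifier's 19 categories are finer than the 8 portion groups; this
#' table links each category to its portion spec and a default moisture class
#' ("high_moisture" foods get 5 g rounding; "dry_raw" keep exact weight).
#' Free-energy foods and alcoholic beverages have no key component and map to
#' NA (no portion is computed).
#'
#' @return data.frame with columns `category`, `portion_group`,
#'   `moisture_class`.
#' @export
category_portion_map <- function() {
  cats <- exchange_groups()
  map <- c("Oils and fats with protein" = "Fat and oils",
           "Fat and oils" = "Fat and oils",
           "Free energy foods" = NA,
           "Meat: Fish and poultry very high-fat content" = "Meats",
           "Meat: Fish and poultry low-fat content" = "Meats",
           "Meat: Fish and poultry high-fat content" = "Meats",
           "Meat: Fish and poultry very low-fat content" = "Meats",
           "Sugar with fat" = "Sugar, honey, and candy",
           "Sugar" = "Sugar, honey, and candy",
           "Alcoholic beverage" = NA,
           "Cereal with high-fat content" = "Cereals and by-products",
           "Cereal with low-fat content" = "Cereals and by-products",
           "Fruits" = "Fruits",
           "Dairy with sugar added" = "Milk",
           "Skim dairy products" = "Milk",
           "Whole dairy products" = "Milk",
           "Semi-skimmed dairy products" = "Milk",
           "Legumes" = "Legumes",
           "Vegetables" = "Vegetables")
  moist <- c("Fat and oils" = "dry_raw", "Meats" = "high_moisture",
             "Sugar, honey, and candy" = "dry_raw",
             "Cereals and by-products" = "dry_raw",
             "Fruits" = "high_moisture", "Milk" = "high_moisture",
             "Legumes" = "dry_raw", "Vegetables" = "high_moisture")
  data.frame(category = cats,
             portion_group = unname(map[cats]),
             moisture_class = unname(moist[map[cats]]),
             stringsAsFactors = FALSE)
}
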