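#' Nutrient component order used throughout the package
#'
#' Every nutrient vector in this package is an ordered 9-tuple in this fixed
#' component order. Energy is in kcal, cholesterol and sodium in mg, all other
#' components in g, always per 100 g of solid food or 100 mL of liquid.
#'
#' Carbohydrates and total lipids from a composition table are expanded into
#' sub-nutrients before entering this vector:
#' carbohydrates = starch + sugar + fiber, and
#' total lipids = unsaturated fat + saturated fat.
#'
#' @return Character vector of the nine component names, in canonical order.
#' @export
#' @examples
#' nutrient_components()
nutrient_components <- function() {
  c("energy", "protein", "unsaturated_fat", "saturated_fat",
    "cholesterol", "starch", "sugar", "fiber", "sodium")
}

#' The 19 default exchange-group names
#'
#' Default label vocabulary for the classifiers: the 19 food categories of the
#' Mexican equivalent-food system as used by the default synthetic profiles.
#'
#' @return Character vector of 19 group names.
#' @export
exchange_groups <- function() {
  c("Oils and fats with protein",
    "Fat and oils",
    "Free energy foods",
    "Meat: Fish and poultry very high-fat content",
    "Meat: Fish and poultry low-fat content",
    "Meat: Fish and poultry high-fat content",
    "Meat: Fish and poultry very low-fat content",
    "Sugar with fat",
    "Sugar",
    "Alcoholic beverage",
    "Cereal with high-fat content",
    "Cereal with low-fat content",
    "Fruits",
    "Dairy with sugar added",
    "Skim dairy products",
    "Whole dairy products",
    "Semi-skimmed dairy products",
    "Legumes",
    "Vegetables")
}

#' Default CSV column schema for food-composition tables
#'
#' Maps the package's internal field names to CSV header names. Pass a
#' modified copy to [read_food_table()] to read tables with other headers.
#' `starch_g`, `trans_fat_g`, `free_sugar_g`, `group`, `state` and
#' `household_measure` are optional columns; the nine composition variables
#' (energy through sodium) are mandatory.
#'
#' @return Named character vector: internal field -> CSV column name.
#' @export
#' @examples
#' sch <- default_food_schema()
#' sch[["energy"]] <- "kcal_per_100g"   # adapt to a foreign header
default_food_schema <- function() {
  c(name              = "name",
    group             = "group",
    state             = "state",
    energy            = "energy_kcal",
    protein           = "protein_g",
    total_lipids      = "total_lipids_g",
    saturated_fat     = "saturated_fat_g",
    trans_fat         = "trans_fat_g",
    cholesterol       = "cholesterol_mg",
    carbohydrates     = "carbohydrates_g",
    sugar             = "sugar_g",
    free_sugar        = "free_sugar_g",
    fiber             = "fiber_g",
    sodium            = "sodium_mg",
    starch            = "starch_g",
    household_measure = "household_measure")
}

# Mandatory raw composition variables (the 9 table columns, pre-expansion).
raw_nutrient_fields <- function() {
  c("energy", "protein", "total_lipids", "saturated_fat", "cholesterol",
    "carbohydrates", "sugar", "fiber", "sodium")
}

# Optional numeric fields carried through when present.
optional_nutrient_fields <- function() {
  c("trans_fat", "free_sugar", "starch")
}
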