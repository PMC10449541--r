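#' Default front-of-pack excess-nutrient cut points
#'
#' The regulatory thresholds (Mexican front-of-pack warning scheme) applied
#' per 100 g of a solid or 100 mL of a liquid. Shares of energy use the
#' Atwater conversion factors: 4 kcal/g for sugars, 9 kcal/g for fats.
#' All comparisons are inclusive (>=).
#'
#' @return A `label_rules` list:
#' \describe{
#'   \item{solid_energy_cut}{275 kcal/100 g: excess calories for solids.}
#'   \item{liquid_energy_cut}{70 kcal/100 mL: excess calories for liquids.}
#'   \item{liquid_free_sugar_cut}{8 g/100 mL free sugar: the alternative
#'     excess-calories trigger for liquids.}
#'   \item{sugar_energy_share_cut}{0.10: share of energy from free sugars.}
#'   \item{satfat_energy_share_cut}{0.10: share of energy from saturated fat.}
#'   \item{transfat_energy_share_cut}{0.01: share of energy from trans fat.}
#'   \item{sodium_per_kcal_cut}{1 mg sodium per kcal.}
#'   \item{sodium_abs_cut}{300 mg sodium.}
#'   \item{calorie_free_sodium_cut}{45 mg sodium for calorie-free drinks.}
#'   \item{calorie_free_energy_max}{5 kcal/100 mL: below this a liquid counts
#'     as a calorie-free drink.}
#' }
#' @export
default_label_rules <- function() {
  structure(list(
    solid_energy_cut = 275,
    liquid_energy_cut = 70,
    liquid_free_sugar_cut = 8,
    sugar_energy_share_cut = 0.10,
    satfat_energy_share_cut = 0.10,
    transfat_energy_share_cut = 0.01,
    sodium_per_kcal_cut = 1,
    sodium_abs_cut = 300,
    calorie_free_sodium_cut = 45,
    calorie_free_energy_max = 5,
    kcal_per_g_sugar = 4,
    kcal_per_g_fat = 9), class = "label_rules")
}

#' Flag one food's excess-nutrient labels
#'
#' Evaluates the five warning labels against the cut points in `rules`:
#' \itemize{
#'   \item excess calories — solids: energy >= 275 kcal; liquids: energy >=
#'     70 kcal OR free sugar >= 8 g.
#'   \item excess sugars — energy from free sugars (4 kcal/g) >= 10% of total.
#'   \item excess saturated fat — energy from saturated fat (9 kcal/g) >= 10%.
#'   \item excess trans fat — energy from trans fat (9 kcal/g) >= 1%; NA with
#'     a note when the record has no trans-fat value.
#'   \item excess sodium — >= 1 mg/kcal OR >= 300 mg; calorie-free drinks
#'     (liquid, energy below `calorie_free_energy_max`): >= 45 mg.
#' }
#' Free sugar falls back to total sugar when no `free_sugar` field is present
#' (noted in the evidence). For a zero-energy food, share-of-energy rules are
#' skipped with a note; absolute rules still apply.
#'
#' @param record Named list / one-row data.frame with `energy`, `sugar` (or
#'   `free_sugar`), `saturated_fat`, `sodium`, `state`, optionally `trans_fat`.
#' @param rules A `label_rules` list, see [default_label_rules()].
#' @return An `excess_labels` list: the five logicals (`excess_calories`,
#'   `excess_sugars`, `excess_saturated_fat`, `excess_trans_fat`,
#'   `excess_sodium`), `evidence` (per-label computed quantity and threshold),
#'   and `notes`.
#' @export
#' @examples
#' label_food(list(energy = 300, sugar = 2, saturated_fat = 1, sodium = 50,
#'                 state = "solid"))
label_food <- function(record, rules = default_label_rules()) {
  record <- as.list(record)
  state <- record$state %||% "solid"
  if (is.na(state)) state <- "solid"
  energy <- as.numeric(record$energy %||% NA)
  if (is.na(energy))
    stop_fx("record lacks an energy value", class = "fx_validation_error")
  sodium <- as.numeric(record$sodium %||% 0); sodium[is.na(sodium)] <- 0
  satfat <- as.numeric(record$saturated_fat %||% 0); satfat[is.na(satfat)] <- 0
  notes <- character(0)

  free_sugar <- record$free_sugar
  if (is.null(free_sugar) || is.na(free_sugar)) {
    free_sugar <- as.numeric(record$sugar %||% 0)
    notes <- c(notes, "free sugar taken as total sugar (no free_sugar field)")
  }
  free_sugar <- as.numeric(free_sugar); free_sugar[is.na(free_sugar)] <- 0

  evidence <- list()
  # excess calories
  if (state == "liquid") {
    cal <- energy >= rules$liquid_energy_cut ||
      free_sugar >= rules$liquid_free_sugar_cut
    evidence$excess_calories <- list(
      quantity = energy, threshold = rules$liquid_energy_cut,
      alt_quantity = free_sugar, alt_threshold = rules$liquid_free_sugar_cut)
  } else {
    cal <- energy >= rules$solid_energy_cut
    evidence$excess_calories <- list(quantity = energy,
                                     threshold = rules$solid_energy_cut)
  }

  share_rule <- function(grams, kcal_per_g, cut, label) {
    if (energy <= 0) {
      notes <<- c(notes, sprintf("%s: share-of-energy rule skipped (zero energy)",
                                 label))
      evidence[[label]] <<- list(quantity = NA_real_, threshold = cut)
      return(NA)
    }
    share <- kcal_per_g * grams / energy
    evidence[[label]] <<- list(quantity = share, threshold = cut)
    share >= cut
  }
  sug <- share_rule(free_sugar, rules$kcal_per_g_sugar,
                    rules$sugar_energy_share_cut, "excess_sugars")
  sat <- share_rule(satfat, rules$kcal_per_g_fat,
                    rules$satfat_energy_share_cut, "excess_saturated_fat")
  transfat <- record$trans_fat
  if (is.null(transfat) || is.na(transfat)) {
    trans <- NA
    notes <- c(notes, "excess_trans_fat: not evaluated (no trans_fat value)")
    evidence$excess_trans_fat <- list(quantity = NA_real_,
                                      threshold = rules$transfat_energy_share_cut)
  } else {
    trans <- share_rule(as.numeric(transfat), rules$kcal_per_g_fat,
                        rules$transfat_energy_share_cut, "excess_trans_fat")
  }
  # zero-energy foods trip no share rule
  if (energy <= 0) { sug <- isTRUE(sug); sat <- isTRUE(sat)
                     if (!is.na(trans)) trans <- isTRUE(trans) }

  # excess sodium
  calorie_free_drink <- state == "liquid" && energy < rules$calorie_free_energy_max
  if (calorie_free_drink) {
    sod <- sodium >= rules$calorie_free_sodium_cut
    evidence$excess_sodium <- list(quantity = sodium,
                                   threshold = rules$calorie_free_sodium_cut,
                                   basis = "calorie_free_drink")
  } else {
    per_kcal <- if (energy > 0) sodium / energy else NA_real_
    sod <- (is.finite(per_kcal) && per_kcal >= rules$sodium_per_kcal_cut) ||
      sodium >= rules$sodium_abs_cut
    if (energy <= 0)
      notes <- c(notes, "excess_sodium: per-kcal rule skipped (zero energy)")
    evidence$excess_sodium <- list(quantity = sodium,
                                   per_kcal = per_kcal,
                                   threshold = rules$sodium_abs_cut,
                                   per_kcal_threshold = rules$sodium_per_kcal_cut)
  }

  structure(list(excess_calories = cal, excess_sugars = sug,
                 excess_saturated_fat = sat, excess_trans_fat = trans,
                 excess_sodium = sod, evidence = evidence, notes = notes),
            class = "excess_labels")
}

#' @export
print.excess_labels <- function(x, ...) {
  flags <- unlist(x[c("excess_calories", "excess_sugars",
                      "excess_saturated_fat", "excess_trans_fat",
                      "excess_sodium")])
  cat("<excess_labels>", paste(names(flags)[which(flags)], collapse = ", "),
      "\n")
  invisible(x)
}

#' Label every food in a table
#'
#' Applies [label_food()] to each record, order-preserving, collecting
#' per-food errors instead of raising them, and tallies how many foods carry
#' each label.
#'
#' @param table A [food_table()].
#' @param rules See [default_label_rules()].
#' @return List with `labels` (data.frame: name + five label columns),
#'   `details` (list of `excess_labels`), and `summary` (count of TRUE per
#'   label).
#' @export
label_table <- function(table, rules = default_label_rules()) {
  stopifnot(inherits(table, "food_table"))
  rec <- table$records
  details <- vector("list", nrow(rec))
  cols <- c("excess_calories", "excess_sugars", "excess_saturated_fat",
            "excess_trans_fat", "excess_sodium")
  out <- as.data.frame(matrix(NA, nrow(rec), length(cols),
                              dimnames = list(NULL, cols)))
  for (i in seq_len(nrow(rec))) {
    res <- tryCatch(label_food(rec[i, , drop = FALSE], rules),
                    foodexchange_error = function(e) e)
    details[[i]] <- res
    if (inherits(res, "excess_labels"))
      out[i, ] <- unlist(res[cols])
  }
  labels <- cbind(data.frame(name = rec$name, stringsAsFactors = FALSE), out)
  summary <- vapply(cols, function(cn) sum(out[[cn]], na.rm = TRUE), integer(1))
  list(labels = labels, details = details, summary = summary)
}
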