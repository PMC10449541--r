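#' Default synthetic profiles for the 19 exchange groups
#'
#' One nutrient profile per exchange group: a per-100 g (or per-100 mL for
#' liquids) mean sub-nutrient vector, a per-component coefficient of
#' variation, and a physical state. The means are invented fixtures — NOT
#' measured composition data — chosen so each group is dominated by its
#' defining nutrient (sugar groups by sugar, lean meats by protein with
#' little fat, oils by fat, and so on) and no two group directions are
#' parallel. The coefficient of variation defaults to 0.30 per component,
#' a typical relative spread within a food subgroup.
#'
#' @param cv Coefficient of variation applied to every component.
#' @return List of 19 `group_profile` lists: `group`, `state`, `means`
#'   (named 9-vector in [nutrient_components()] order), `cv` (named 9-vector).
#' @export
default_group_profiles <- function(cv = 0.30) {
  #                e     pro  unsat   sat   chol starch sugar fiber sodium
  m <- rbind(
    c(600, 18.0, 42.00, 8.00,  0,  12.0,  4.0, 8.0, 350),   # oils+protein (salted nuts)
    c(880,  0.0, 70.00, 25.00,  0,   0.0,  0.0, 0.0,   2),  # fat and oils
    c( 15,  0.8,  0.10, 0.02,  0,   1.0,  1.5, 0.8, 120),   # free energy foods
    c(300, 18.0, 14.00, 9.00, 85,   0.0,  0.0, 0.0, 450),   # meat very high fat
    c(120, 21.0,  2.20, 1.30, 65,   0.0,  0.0, 0.0,  70),   # meat low fat
    c(220, 19.0,  9.00, 6.00, 80,   0.0,  0.0, 0.0,  90),   # meat high fat
    c( 95, 22.0,  0.70, 0.30, 50,   0.0,  0.0, 0.0,  60),   # meat very low fat
    c(480,  5.0, 12.00, 14.00, 10,   8.0, 52.0, 3.0,  80),  # sugar with fat
    c(380,  0.1,  0.00, 0.00,  0,   2.0, 92.0, 0.0,  10),   # sugar
    c( 70,  0.3,  0.00, 0.00,  0,   0.0,  3.0, 0.0,   8),   # alcoholic beverage
    c(420,  8.0, 10.00, 5.00,  0,  52.0,  6.0, 4.0, 320),   # cereal high fat
    c(350,  9.0,  1.50, 0.50,  0,  65.0,  2.5, 5.0,   5),   # cereal low fat
    c( 55,  0.7,  0.20, 0.10,  0,   1.0, 10.5, 2.2,   2),   # fruits
    c( 90,  3.2,  1.10, 2.00, 12,   0.5, 13.0, 0.0,  55),   # dairy w/ sugar
    c( 35,  3.5,  0.06, 0.12,  2,   0.0,  5.0, 0.0,  52),   # skim dairy
    c( 62,  3.2,  1.20, 2.20, 12,   0.0,  4.8, 0.0,  45),   # whole dairy
    c( 48,  3.4,  0.55, 1.05,  7,   0.0,  4.9, 0.0,  48),   # semi-skimmed dairy
    c(130,  8.5,  0.45, 0.15,  0,  18.0,  1.5, 6.5,   5),   # legumes
    c( 28,  1.8,  0.15, 0.05,  0,   2.0,  2.8, 2.4,  25))   # vegetables
  colnames(m) <- nutrient_components()
  states <- rep("solid", 19)
  states[c(10, 14, 15, 16, 17)] <- "liquid"   # beverages and dairy drinks
  groups <- exchange_groups()
  lapply(seq_along(groups), function(i) {
    structure(list(group = groups[i], state = states[i],
                   means = m[i, ],
                   cv = stats::setNames(rep(cv, 9), nutrient_components())),
              class = "group_profile")
  })
}

#' Generate a labeled synthetic food-composition table
#'
#' Draws `n_per_group` foods per profile with multiplicative Gaussian noise:
#' each component is `mean * (1 + noise_scale * cv * eps)` with eps standard
#' normal, clipped at 0. Multiplicative noise keeps components that a group
#' never contains (e.g. sugar in oils) exactly zero, preserving group sparsity
#' patterns. Raw aggregate columns are reconstructed from the drawn
#' sub-nutrients (carbohydrates = starch + sugar + fiber, total lipids =
#' saturated + unsaturated), and starch is written explicitly, so
#' [expand_features()] inverts the generation exactly. Deterministic given
#' `seed` (Mersenne-Twister / inversion sampling).
#'
#' @param profiles List of `group_profile`s, default the 19 built-ins.
#' @param n_per_group Foods drawn per group (>= 1).
#' @param noise_scale Multiplier on each component's coefficient of
#'   variation; 0 reproduces every group mean exactly.
#' @param seed Integer seed.
#' @return A labeled [food_table()].
#' @export
#' @examples
#' tab <- generate_food_table(n_per_group = 5, noise_scale = 0.1, seed = 7)
#' table(tab$records$group)
generate_food_table <- function(profiles = default_group_profiles(),
                                n_per_group = 50, noise_scale = 0.1,
                                seed = 1) {
  if (!length(profiles))
    stop_fx("profiles must be non-empty", class = "fx_empty_input_error")
  if (n_per_group < 1)
    stop_fx("n_per_group must be >= 1", class = "fx_validation_error")
  with_seed(seed, {
    rows <- lapply(profiles, function(p) {
      eps <- matrix(stats::rnorm(n_per_group * 9), n_per_group, 9)
      fac <- 1 + noise_scale * sweep(eps, 2, p$cv, `*`)
      vals <- pmax(sweep(fac, 2, p$means, `*`), 0)
      colnames(vals) <- nutrient_components()
      data.frame(
        name = sprintf("%s %03d", p$group, seq_len(n_per_group)),
        group = p$group, state = p$state,
        energy = vals[, "energy"], protein = vals[, "protein"],
        total_lipids = vals[, "unsaturated_fat"] + vals[, "saturated_fat"],
        saturated_fat = vals[, "saturated_fat"],
        cholesterol = vals[, "cholesterol"],
        carbohydrates = vals[, "starch"] + vals[, "sugar"] + vals[, "fiber"],
        sugar = vals[, "sugar"], fiber = vals[, "fiber"],
        sodium = vals[, "sodium"], starch = vals[, "starch"],
        stringsAsFactors = FALSE)
    })
    food_table(do.call(rbind, rows))
  })
}
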