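# foodexchange

Food exchange lists (FELs) group foods into categories — fruits, cereals,
lean meats, fats — within which stated portions are nutritionally
interchangeable. Dietitians use them to plan diabetic and weight-management
diets, but keeping a list current against thousands of new food products is
slow manual work: each food must be classified into a group and its
equivalent portion computed by hand. `foodexchange` automates that loop for
anyone maintaining an exchange list from a food-composition table (one row
per food, composition per 100 g of solid or 100 mL of liquid).

## The model

Each food is a vector in a 9-dimensional nutrient space. The aggregate
table columns are first split into sub-nutrients,

    carbohydrates = starch + sugar + fiber
    total lipids  = unsaturated fat + saturated fat

giving the components (energy, protein, unsaturated fat, saturated fat,
cholesterol, starch, sugar, fiber, sodium). Because kcal, g and mg live on
incomparable scales, each column *j* is made dimensionless against a
reference table of *N* foods:

    x̄_ij = N · x_ij / Σ_i x_ij

so every active column has mean 1. In this space:

- **Similarity** between foods A and B is the cosine of the angle between
  their vectors, `Sim(A,B) = ⟨A,B⟩ / (‖A‖‖B‖)` — it compares nutrient
  *concentration*, not amount.
- **Equivalence factor** `α = ‖A‖ cosθ_AB / ‖B‖ = ⟨A,B⟩/‖B‖²` is the
  least-squares scalar bringing B closest to A: `α · 100 g` of B replaces
  100 g of A. A two-food blend `C ≈ αA + βB` is solved the same way with
  nonnegative least squares.
- **Classification** assigns a food to the exchange group whose unit-norm
  centroid `W_j` (the normalized group mean, spherical-k-means style)
  maximizes `Sim(A, W_j)`; the full ranking gives top-k predictions. A
  small two-hidden-layer MLP over the same inputs (plus the vector's
  magnitude, which cosine scoring discards) smooths the centroid
  classifier's linear boundaries.
- **Excess labels** flag foods at or above front-of-pack regulatory cut
  points (275 kcal/100 g solids, 70 kcal or 8 g free sugar/100 mL liquids,
  10% of energy from free sugars or saturated fat, 1% from trans fat,
  1 mg sodium/kcal or 300 mg, 45 mg for calorie-free drinks).
- **Portions**: each group's portion delivers a fixed amount of its key
  nutritional component (e.g. fruits 15 g carbohydrate, meats 7 g protein),
  so `grams = 100 · key_amount / density`, rounded to the nearest 5 g for
  high-moisture foods.

A labeled synthetic generator with 19 group profiles makes the whole
pipeline testable without any external database.

## Worked example

```r
library(foodexchange)

tab   <- generate_food_table(n_per_group = 20, noise_scale = 0.1, seed = 42)
dt    <- fit_dimensionless(tab)
model <- fit_skm(dt, tab$records$group)

predict_skm(model, dt$matrix["Fruits 003", ], true_group = "Fruits")
#>            group     score
#> 1         Fruits 0.9999047
#> 2     Vegetables 0.8816637
#> 3        Legumes 0.7574006
#> ...
#> true group 'Fruits' at rank 1

rank_equivalents("Fruits 003", tab, dt$scale, k = 3)[, c(2, 4:6)]
#>   candidate_name similarity     alpha    grams
#> 1     Fruits 009  0.9999727 0.9809327 98.09327
#> 2     Fruits 017  0.9999655 0.9661369 96.61369
#> 3     Fruits 010  0.9999649 0.9388042 93.88042
```

The centroid classifier puts this synthetic fruit in its own group with
score 0.9999, and its closest equivalent is another fruit: 98.1 g of
"Fruits 009" replaces 100 g of it (α = 0.981). Labeling and portioning the
same food:

```r
rec <- tab$records[tab$records$name == "Fruits 003", ]
label_food(rec)
#> <excess_labels> excess_sugars

specs <- default_portion_specs()
equivalent_portion(rec, specs[specs$group == "Fruits", ], "high_moisture")
#> <portion_result> Fruits 003: 115 g (raw 113.108 g) delivers 15.2509 g carbohydrates [high_moisture]
```

At 13.3 g sugar per 55.8 kcal this food draws well over 10% of its energy
from sugars, so it carries the excess-sugars label; its fruit portion (15 g
carbohydrate) is 113.1 g, rounded to 115 g for household use. The pipeline
(`run_pipeline()`, or `exec/foodexchange pipeline --table foods.csv`) runs
all of these stages per food and adds a stratified cross-validation summary:

```r
stratified_cv(tab, model_spec_skm(), n_splits = 5, seed = 42)$fold_accuracy
#> 1 1 1 1 1
```

## Command line

```sh
foodexchange simulate    --n 100 --noise 0.1 --seed 7 --out foods.csv
foodexchange classify    --table foods.csv --model skm --top 3 --out report.json
foodexchange equivalents --food "Fruits 001" --table foods.csv --k 5 --out eq.json
foodexchange label       --table foods.csv --out labels.json
foodexchange evaluate    --table foods.csv --cv 5 --models skm,mlp --seed 7 --out eval.json
```

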