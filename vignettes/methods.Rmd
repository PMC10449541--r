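---
title: "Methods: nutrient-vector exchange lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutrient-vector exchange lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodexchange)
```

## The problem and the representation

A food exchange list assigns every food to a group within which stated
portions are nutritionally interchangeable. Building one from a
food-composition table needs three computations per food: which group it
belongs to, which other foods can replace it and in what amount, and
whether it should carry excess-nutrient warnings. This package treats all
three as geometry in a nutrient vector space.

Each food is a 9-vector of per-100 g (solids) or per-100 mL (liquids)
values: energy (kcal), protein, unsaturated fat, saturated fat (g),
cholesterol (mg), starch, sugar, fiber (g), sodium (mg). Composition
tables usually report aggregates, so `expand_features()` decomposes
carbohydrates into starch + sugar + fiber (starch derived by difference
when not tabulated) and total lipids into unsaturated + saturated fat.
The decomposition matters: a fruit and a cracker can share total
carbohydrate but differ completely in the sugar/starch/fiber split that
drives their exchange behavior.

Missing nutrient cells are imputed as zero — in composition databases a
blank sodium or cholesterol cell almost always means "not relevant for
this food", not "unknown" — and every imputation is logged so the
assumption is auditable. Negative *reported* values are rejected as data
errors; negative *derived* values (starch or unsaturated fat coming out
below zero because of rounding in the source table) are clipped to zero
with a warning, since rejecting a food over a 0.1 g bookkeeping
inconsistency would be worse than absorbing it.

## The dimensionless space

Kcal, grams and milligrams are incommensurable: a 50 kcal energy gap and a
50 mg sodium gap are numerically equal but nutritionally unrelated, so no
distance computed on raw columns is meaningful. Every comparison therefore
happens after the per-column rescaling

$$\bar{x}_{ij} = \frac{N\,x_{ij}}{\sum_{i=1}^{N} x_{ij}},$$

which gives every active column mean exactly 1 (asserted to 1e-9 in the
tests). Two details are deliberate:

- **Frozen projection.** New foods are projected with the *reference*
  column sums (`project_food()`), never by refitting: classifying one food
  must not move the space. The projection reuses the fit's exact
  floating-point operation order, so a reference food projects onto its
  own fitted row bit-for-bit.
- **Degenerate columns.** A column that is zero across the whole reference
  table (a nutrient absent from a small or specialized table) maps to
  zeros and is flagged, rather than erroring — small synthetic tables
  legitimately zero out nutrients.

## Similarity, equivalence, blends

Similarity is the cosine of the angle between dimensionless vectors.
Cosine compares concentration profiles and ignores amounts, which is
exactly the exchange-list notion of "the same kind of food". For
nonnegative vectors it lies in [0, 1]; we clamp against floating-point
overshoot. Zero vectors are an error, not a similarity of 0 — a food with
no measured nutrients cannot be compared.

The equivalence factor is the closed-form least-squares projection
$\alpha = \langle A,B\rangle/\lVert B\rVert^2$: among all scalings $tB$,
$\alpha B$ is closest to $A$ (property-tested against a 2,001-point grid).
$\alpha$ is computed in the dimensionless space, where the optimum is not
dominated by whichever nutrient has the largest unit; the raw-space factor
is also reported (`alpha_raw`) because both are informative when converting
to grams. Note the asymmetry: $\alpha(A,B)\,\alpha(B,A) = \cos^2\theta$,
with equality to 1 only for parallel foods.

Two-food blends $C \approx \alpha A + \beta B$ are solved by the 2×2
normal equations with a nonnegativity constraint — negative food amounts
are physically meaningless, so when the unconstrained optimum leaves the
quadrant we fall back to the best boundary solution (one coefficient
clamped at 0). The objective (least squares) and the constraint are this
package's choices; nothing deeper than convexity and interpretability
recommends them, and the residual norm is always reported so a bad blend
is visible. Parallel components are rejected with a pointer to the
single-food factor. Mixtures of more than two foods are out of scope.

## Classification

**Centroid classifier (`fit_skm`).** With labels known, each group's
centroid is placed supervised — the unit-normalized mean of the group's
dimensionless vectors — rather than by iterative reassignment; running
unsupervised updates against known labels would only blur the groups.
Classification is argmax of cosine similarity over centroids, returning
the full ranking for top-k evaluation. Ties break by centroid order
(first-appearance order of groups in the training labels), and a true
group tied with others shares the best rank (rank = 1 + number of strictly
better scores). Both rules are arbitrary but deterministic, which is what
matters for reproducibility.

**MLP (`fit_mlp`).** The centroid classifier is linear on the unit sphere;
a small multilayer perceptron smooths its boundaries. Input is 10
features: the 9 dimensionless components plus the vector's Euclidean norm.
The norm is included because cosine scoring discards magnitude, yet
magnitude separates, e.g., a concentrated syrup from diluted juice with the
same profile; we use the norm of the *dimensionless* vector (the raw norm
is unit-contaminated), computable via `project_food()` if the raw variant
is wanted. Architecture: two ReLU hidden layers (default 32 + 32),
softmax output, cross-entropy loss, full-batch Adam (learning rate 0.01),
300 epochs, features standardized on the training split. Widths, epochs
and rate are exposed arguments; the defaults were chosen as the smallest
configuration that cleanly separates the synthetic groups, and nothing in
the method depends on them. An internal stratified 80/20 split tracks
validation loss per epoch. Everything — split, initialization — derives
from one seed, and retraining with the same seed reproduces the final loss
exactly.

**Evaluation.** `topk_accuracy()` is the fraction of foods whose true
group sits within the k best-ranked predictions. `stratified_cv()` runs
k-fold cross-validation (default 5 folds) with per-group balanced folds
(counts differ by at most 1); groups smaller than the fold count are
pooled into a common stratum for assignment only, with a warning. Every
fold refits both the dimensionless scale *and* the model on its training
portion — the per-fold scale factors are returned so tests can verify no
validation statistic leaks into the space. Random Forest and XGBoost can
be dropped into the same harness through thin `model_spec_rf()` /
`model_spec_xgb()` adapters around the off-the-shelf packages; they are
comparison baselines, not part of the method.

## Excess-nutrient labels

`label_food()` implements the front-of-pack cut points: solids with
≥ 275 kcal/100 g or liquids with ≥ 70 kcal or ≥ 8 g free sugar/100 mL are
"excess calories"; ≥ 10% of energy from free sugars or from saturated fat,
and ≥ 1% from trans fat, trip the respective labels (energy shares use the
Atwater factors, 4 kcal/g sugar and 9 kcal/g fat — the cut points are
stated as shares, the factors are the standard conversion); sodium trips
at ≥ 1 mg/kcal or ≥ 300 mg, and at ≥ 45 mg for calorie-free drinks. All
bounds are inclusive, and every label carries the computed quantity and
threshold as evidence.

Three readings were genuinely open and are resolved as follows:

- The liquid "≥ 8 g free sugar" clause feeds **excess calories** (as the
  rule table prints it), not excess sugars.
- *Free* sugar falls back to total sugar when the table has no free-sugar
  column, with a note — this overestimates free sugar for foods with
  intrinsic sugars (fruit, plain dairy), which is the conservative
  direction for a warning label.
- "Calorie-free drink" is undefined in the source scheme; we use liquid
  with < 5 kcal/100 mL (the common regulatory convention), configurable.

Zero-energy foods skip share-of-energy rules (noted) but keep absolute
rules; trans fat is optional input and its label is `NA`, not `FALSE`,
when absent. Monotonicity — raising sodium, sugar or saturated fat never
clears a label — is property-tested.

## Portions

A group's portion delivers a fixed mass of its key nutritional component:
vegetables 4 g carbohydrate, fruits 15 g, cereals 15 g, sugars 10 g,
legumes 8 g protein, meats 7 g, milk 9 g protein, fats 5 g fat — each
anchored to a reference food (carrot, apple, tortilla, sugar, beans, egg,
milk, oil). So `raw_grams = 100 · key_amount / density`. High-moisture
foods round to the nearest 5 g for household use — half rounds **up**
(32.5 → 35; the source rule names no tie-break, and half-up keeps portions
generous) and a portion that would round to zero is floored at 5 g, the
smallest household-measurable multiple. Dry or raw foods keep the exact
weight. Milk lists two key components (9 g protein, 12 g carbohydrate);
the portion is solved on protein and the carbohydrate delivered is
reported for inspection, since no reconciliation rule exists. Moisture
class is caller-supplied (the source assigns it by example, not by rule);
`category_portion_map()` ships a default mapping from the 19 classifier
categories to the 8 portion groups and classes. The ±2 SD acceptance band
uses a group SD computed from the table at hand — the canonical
per-group SDs are not published — so the flag is advisory.

## The synthetic generator

`generate_food_table()` draws each food as
`mean × (1 + noise_scale · cv · ε)`, ε standard normal per component,
clipped at 0. Noise is multiplicative so components a group never contains
(sugar in oils) stay exactly zero, preserving the sparsity structure that
makes groups distinguishable. The 19 default profiles are invented
fixtures — NOT measured composition data — with each group dominated by
its defining nutrient and pairwise mean-vector cosines below 0.999. The
per-component coefficient of variation defaults to 0.30, a typical
relative spread within a real food subgroup, and `noise_scale` (default
0.1) multiplies it. Aggregate columns are reconstructed from the drawn
sub-nutrients, and starch is written explicitly, so `expand_features()`
inverts generation exactly. The RNG is Mersenne-Twister with inversion
normals, fixed by seed.

What the generator emulates: per-group unimodal nutrient distributions
with group-specific sparsity, mixed solids and liquids, label structure.
What it does not: multimodal subgroups, correlated nutrients within a
food (real energy is nearly a linear function of the macronutrients),
heavy-tailed outliers, measurement error patterns, or any statistical
match to a real national database. Passing tests on synthetic data
therefore demonstrate the *machinery* — exact separability recovery,
leak-free validation, calibration of the equivalence algebra — not field
accuracy on any particular real table, which depends entirely on that
table's quality and labeling.

## Validation scale and numerical conventions

The package validates itself on deliberately modest problem sizes — 19
groups × 50 foods (950 rows) for classification and cross-validation,
1,000 random vector pairs for the projection-optimality property, 200
planted blends — chosen because every result at these sizes is already
stable to the third digit and the entire suite stays interactive.
Tolerances: column-mean-one to 1e-9; exact identity (not tolerance) for
fit/project consistency; blend recovery to 1e-6 with residual below 1e-9;
cosine clamped to [0, 1]. Degenerate inputs (zero vectors, single-class
labels, empty tables, zero key-nutrient density) raise typed conditions
(`fx_*_error` classes) rather than returning sentinels.

## Limitations

- Classification quality on real data is bounded by the composition
  table's own consistency; foods mislabeled at source are learned as
  labeled.
- The 9 components omit micronutrients, added-versus-intrinsic sugar
  distinctions, and food origin; two foods can be cosine-identical yet
  culinarily non-interchangeable.
- The equivalence factor optimizes the whole dimensionless vector; it does
  not guarantee matching any single nutrient exactly (use the blend solver
  and its residual when one nutrient must be met).
- Liquids are handled per 100 mL as stored, with no density conversion
  between mass and volume bases.
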