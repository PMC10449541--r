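Package: foodexchange
Title: Food Exchange Lists from Nutrient Vectors by Cosine Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and updates food exchange lists from per-100 g
    food-composition tables. Expands raw composition variables into a
    nine-dimensional sub-nutrient vector, applies a dimensionless
    per-column rescaling, classifies foods into 19 exchange groups by
    cosine similarity to unit-norm group centroids (spherical k-means
    style) or with a small multilayer perceptron, ranks equivalent foods
    with a closed-form equivalence factor, solves two-food blends by
    non-negative least squares, computes equivalent portions against
    group reference foods, and flags foods exceeding front-of-pack
    regulatory cut points for calories, sugars, fats, and sodium.
    Includes a labeled synthetic food-table generator so the whole
    pipeline is testable without external data, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    xgboost,
    yaml
Config/testthat/edition: 3
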