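# Shared fixtures: small composition tables built in code.

# one fully-specified solid food row (internal field names)
basic_record <- function(...) {
  rec <- list(name = "test food", group = NA_character_, state = "solid",
              energy = 100, protein = 5, total_lipids = 10, saturated_fat = 3,
              cholesterol = 20, carbohydrates = 10, sugar = 4, fiber = 2,
              sodium = 50)
  over <- list(...)
  rec[names(over)] <- over
  rec
}

# write a small CSV in the default schema; returns the path
write_fixture_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  sch <- default_food_schema()
  names(df) <- unname(sch[names(df)])
  write.csv(df, path, row.names = FALSE)
  path
}

# random strictly-positive 9-vector
rand_vec9 <- function() runif(9, 0.01, 100)

# a tiny labeled two-group table, exactly separable
two_group_table <- function(n = 10, noise = 0.05, seed = 42) {
  generate_food_table(default_group_profiles()[c(2, 9)], n_per_group = n,
                      noise_scale = noise, seed = seed)
}
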