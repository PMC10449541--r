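#' Expand a food record into the 9-component sub-nutrient vector
#'
#' Splits the aggregate composition variables into the sub-nutrients used for
#' classification and similarity: carbohydrates are decomposed into
#' starch + sugar + fiber and total lipids into unsaturated + saturated fat.
#' When a starch value is not given it is derived as
#' `carbohydrates - sugar - fiber`; unsaturated fat is always derived as
#' `total_lipids - saturated_fat`. Negative derived amounts (small table
#' inconsistencies) are clipped to 0 with a warning.
#'
#' @param record Named list or one-row data.frame with fields `energy`,
#'   `protein`, `total_lipids`, `saturated_fat`, `cholesterol`,
#'   `carbohydrates`, `sugar`, `fiber`, `sodium` and optionally `starch`.
#' @param warn Emit a warning when a derived sub-nutrient is clipped at 0.
#'
#' @return Named numeric 9-vector in [nutrient_components()] order, with a
#'   `"clipped"` attribute listing any clipped components.
#' @export
#' @examples
#' expand_features(list(energy = 100, protein = 2, total_lipids = 10,
#'                      saturated_fat = 3, cholesterol = 0, carbohydrates = 10,
#'                      sugar = 4, fiber = 2, sodium = 50))
expand_features <- function(record, warn = TRUE) {
  record <- as.list(record)
  need <- setdiff(raw_nutrient_fields(), names(record))
  if (length(need))
    stop_fx("record is missing fields: %s", paste(need, collapse = ", "),
            class = "fx_schema_error")
  num <- function(f) {
    v <- record[[f]]
    if (is.null(v) || length(v) == 0 || is.na(v)) NA_real_ else as.numeric(v)
  }
  raw <- vapply(raw_nutrient_fields(), num, numeric(1))
  raw[is.na(raw)] <- 0
  check_nonneg_finite(raw, "food record")

  clipped <- character(0)
  starch <- num("starch")
  if (is.na(starch)) {
    starch <- raw[["carbohydrates"]] - raw[["sugar"]] - raw[["fiber"]]
    if (starch < 0) {
      clipped <- c(clipped, "starch")
      starch <- 0
    }
  }
  unsat <- raw[["total_lipids"]] - raw[["saturated_fat"]]
  if (unsat < 0) {
    clipped <- c(clipped, "unsaturated_fat")
    unsat <- 0
  }
  if (warn && length(clipped))
    warning(sprintf("derived sub-nutrient(s) clipped to 0: %s",
                    paste(clipped, collapse = ", ")), call. = FALSE)

  v <- c(energy = raw[["energy"]], protein = raw[["protein"]],
         unsaturated_fat = unsat, saturated_fat = raw[["saturated_fat"]],
         cholesterol = raw[["cholesterol"]], starch = starch,
         sugar = raw[["sugar"]], fiber = raw[["fiber"]],
         sodium = raw[["sodium"]])
  structure(v, clipped = clipped)
}

#' Construct a food table from a records data.frame
#'
#' Validates and normalizes a data.frame of food records (internal field
#' names, see [default_food_schema()] for the CSV counterparts), imputes
#' missing nutrient values as 0 (the only imputation policy supported, with a
#' per-cell log), and expands every record into its 9-component sub-nutrient
#' vector.
#'
#' @param records data.frame with at least the nine composition fields
#'   (`energy`, `protein`, `total_lipids`, `saturated_fat`, `cholesterol`,
#'   `carbohydrates`, `sugar`, `fiber`, `sodium`); optional `name`, `group`,
#'   `state` ("solid"/"liquid"), `trans_fat`, `free_sugar`, `starch`,
#'   `household_measure`.
#'
#' @return An object of class `food_table`: list with `records` (normalized
#'   data.frame), `vectors` (N x 9 matrix, rows matching records in order),
#'   `n`, and `log` (data.frame of imputations and clips).
#' @export
food_table <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0)
    stop_fx("food table has no rows", class = "fx_empty_input_error")

  need <- setdiff(raw_nutrient_fields(), names(records))
  if (length(need))
    stop_fx("missing mandatory column(s): %s", paste(need, collapse = ", "),
            class = "fx_schema_error")

  if (is.null(records$name))
    records$name <- sprintf("food_%04d", seq_len(nrow(records)))
  records$name <- as.character(records$name)
  if (is.null(records$group)) records$group <- NA_character_
  records$group <- as.character(records$group)
  if (is.null(records$state)) records$state <- "solid"
  records$state <- as.character(records$state)
  records$state[is.na(records$state) | records$state == ""] <- "solid"
  bad_state <- !records$state %in% c("solid", "liquid")
  if (any(bad_state))
    stop_fx("invalid state %s (must be 'solid' or 'liquid')",
            paste(unique(records$state[bad_state]), collapse = ", "),
            class = "fx_validation_error")

  num_fields <- c(raw_nutrient_fields(),
                  intersect(optional_nutrient_fields(), names(records)))
  log <- list()
  for (f in num_fields) {
    col <- suppressWarnings(as.numeric(records[[f]]))
    miss <- which(is.na(col))
    if (length(miss)) {
      log[[length(log) + 1L]] <- data.frame(
        row = miss, field = f, event = "imputed_zero",
        detail = "missing value filled with 0", stringsAsFactors = FALSE)
      col[miss] <- 0
    }
    neg <- which(col < 0)
    if (length(neg))
      stop_fx("negative value in column '%s', row %d", f, neg[1],
              class = "fx_validation_error")
    records[[f]] <- col
  }

  vectors <- matrix(NA_real_, nrow(records), 9,
                    dimnames = list(records$name, nutrient_components()))
  for (i in seq_len(nrow(records))) {
    v <- suppressWarnings(expand_features(records[i, , drop = FALSE]))
    vectors[i, ] <- v
    for (comp in attr(v, "clipped"))
      log[[length(log) + 1L]] <- data.frame(
        row = i, field = comp, event = "clipped_zero",
        detail = "negative derived sub-nutrient clipped to 0",
        stringsAsFactors = FALSE)
  }

  # flag (not fix) aggregate inconsistencies beyond rounding tolerance
  tol <- 1e-6
  over_sf <- which(records$sugar + records$fiber >
                     records$carbohydrates + tol + 1e-9 * abs(records$carbohydrates))
  for (i in over_sf)
    log[[length(log) + 1L]] <- data.frame(
      row = i, field = "carbohydrates", event = "inconsistent",
      detail = "sugar + fiber exceeds carbohydrates", stringsAsFactors = FALSE)
  over_fat <- which(records$saturated_fat >
                      records$total_lipids + tol + 1e-9 * abs(records$total_lipids))
  for (i in over_fat)
    log[[length(log) + 1L]] <- data.frame(
      row = i, field = "total_lipids", event = "inconsistent",
      detail = "saturated fat exceeds total lipids", stringsAsFactors = FALSE)

  log <- if (length(log)) do.call(rbind, log) else
    data.frame(row = integer(0), field = character(0), event = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  structure(list(records = records, vectors = vectors,
                 n = nrow(records), log = log),
            class = "food_table")
}

#' @export
print.food_table <- function(x, ...) {
  cat(sprintf("<food_table> %d foods, %d labeled, %d log entries\n",
              x$n, sum(!is.na(x$records$group)), nrow(x$log)))
  invisible(x)
}

#' Read a food-composition table from CSV
#'
#' Reads a CSV with one row per food and per-100 g (solids) or per-100 mL
#' (liquids) composition values, maps its columns through `schema`, imputes
#' missing nutrient cells as 0, and expands each row into the 9-component
#' sub-nutrient vector. Every imputation and clip is recorded in the returned
#' table's `log`.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param schema Named character vector mapping internal field names to CSV
#'   column names; see [default_food_schema()].
#'
#' @return A [food_table()] object.
#' @export
read_food_table <- function(path, schema = default_food_schema()) {
  if (!file.exists(path))
    stop_fx("file not found: %s", path, class = "fx_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0)
    stop_fx("empty food table: %s", path, class = "fx_empty_input_error")
  mandatory <- raw_nutrient_fields()
  missing_cols <- mandatory[!schema[mandatory] %in% names(raw)]
  if (length(missing_cols))
    stop_fx("CSV is missing mandatory column(s): %s",
            paste(schema[missing_cols], collapse = ", "),
            class = "fx_schema_error")
  records <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(schema)) {
    col <- schema[[field]]
    if (col %in% names(raw)) records[[field]] <- raw[[col]]
  }
  food_table(records)
}

#' Write a food table back to CSV in the standard schema
#'
#' @param table A [food_table()].
#' @param path Output CSV path.
#' @param schema Column-name mapping, as in [read_food_table()].
#' @return Invisibly, the path.
#' @export
write_food_table <- function(table, path, schema = default_food_schema()) {
  stopifnot(inherits(table, "food_table"))
  rec <- table$records
  out <- data.frame(row.names = seq_len(nrow(rec)))
  for (field in names(schema))
    if (field %in% names(rec)) out[[schema[[field]]]] <- rec[[field]]
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a result collection to CSV or JSON
#'
#' Tabular results (data.frames, e.g. ranked equivalents or a label report)
#' can go to either format; nested results (lists) only to JSON. JSON output
#' round-trips losslessly through [jsonlite::fromJSON].
#'
#' @param results data.frame or list.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, the path.
#' @export
write_results <- function(results, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (is.null(results))
    stop_fx("results must not be NULL", class = "fx_validation_error")
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_fx("directory does not exist: %s", dir, class = "fx_io_error")
  if (format == "csv") {
    if (!is.data.frame(results))
      stop_fx("CSV output requires a data.frame", class = "fx_validation_error")
    utils::write.csv(results, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}
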