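`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code with a locally-set RNG state (Mersenne-Twister / Inversion),
# restoring the caller's .Random.seed afterwards. All package randomness
# funnels through this so results are reproducible and callers' RNG streams
# are never disturbed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

vec_norm <- function(x) sqrt(sum(x^2))

stop_fx <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "foodexchange_error")))
}

check_nonneg_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop_fx("%s contains non-finite values", what, class = "fx_validation_error")
  if (any(x < 0))
    stop_fx("%s contains negative values", what, class = "fx_validation_error")
  invisible(x)
}

as_nutrient_vector <- function(x) {
  comp <- nutrient_components()
  if (!is.null(names(x)) && all(comp %in% names(x))) x <- x[comp]
  x <- as.numeric(x)
  if (length(x) != length(comp))
    stop_fx("nutrient vector must have %d components", length(comp),
            class = "fx_validation_error")
  names(x) <- comp
  x
}
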