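#' @importFrom rlang .data abort warn %||%
#' @importFrom stats cor pchisq pt sd var rnorm runif setNames coef median
#' @importFrom tibble tibble as_tibble
NULL

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Seeded permutation of a vector.
shuffle <- function(x, seed = NULL) {
  if (is.null(seed)) return(sample(x))
  with_seed(seed, sample(x))
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    abort(sprintf("`%s` must be a single positive integer, got %s", name,
                  paste(format(x), collapse = ", ")))
  }
  as.integer(x)
}
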