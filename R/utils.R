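#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so seeded generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Integer percentage, rounding half away from zero
#'
#' Computes `100 * count / total` rounded to the nearest integer with ties
#' going away from zero (so 26.83 -> 27, 23.499 -> 23, 76.5006 -> 77). This
#' is the rounding rule used in all report percentages.
#'
#' @param count numerator count(s).
#' @param total denominator.
#' @return Integer percentage(s).
#' @examples
#' percent_round(220, 820)  # 27
#' percent_round(15, 820)   # 2
#' @export
percent_round <- function(count, total) {
  stopifnot(is.numeric(count), is.numeric(total), all(total != 0))
  x <- 100 * count / total
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# scalar count check
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is_count(x, min))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
}
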