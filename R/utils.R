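# Internal helpers: structured conditions, RNG hygiene, unit conversion.

abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "aggkin_error"), call = call))
}

#' Signal an invalid-input error
#' @noRd
abort_invalid <- function(msg) abort(msg, "aggkin_invalid_input")
abort_degenerate <- function(msg) abort(msg, "aggkin_degenerate_model")
abort_numerical <- function(msg) abort(msg, "aggkin_numerical")
abort_load <- function(msg) abort(msg, "aggkin_load_error")

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Convert micromolar to molar
#'
#' Plate metadata carries concentrations in micromolar; all kinetic
#' computations use molar and seconds internally.
#'
#' @param x numeric vector of concentrations in micromolar.
#' @return concentrations in molar.
#' @export
uM_to_M <- function(x) x * 1e-6

#' Convert hours to seconds
#' @param x numeric vector of times in hours.
#' @return times in seconds.
#' @export
hours_to_seconds <- function(x) x * 3600

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar_positive <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0)
    abort_invalid(sprintf("`%s` must be a single positive finite number", name))
  invisible(x)
}
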