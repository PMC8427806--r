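#' Round half away from zero
#'
#' Display rounding used for reported ratio tables: exact halves round up in
#' magnitude (base `round()` rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(50.195, 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Convert lb/acre to kg/ha
#'
#' Yield models are expressed in lb·acre⁻¹; this helper converts to SI field
#' units (1 lb·acre⁻¹ = 1.12085 kg·ha⁻¹).
#'
#' @param x yield in lb·acre⁻¹.
#' @return yield in kg·ha⁻¹.
#' @export
lb_acre_to_kg_ha <- function(x) x * 0.45359237 / 0.40468564224

# run code with a temporarily-seeded RNG, restoring prior state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
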