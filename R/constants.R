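# Physical constants used throughout; energies in kcal unless noted.
.R_KCAL <- 1.987204e-3   # gas constant, kcal/(mol K)
.R_CAL <- 1.987204       # gas constant, cal/(mol K)
.KB_OVER_H <- 2.083661912e10  # k_B/h, s^-1 K^-1 (Eyring prefactor)
.T_REF <- 298.15         # reference temperature, K

#' Convert Celsius to Kelvin
#' @param temp_C temperature in degrees Celsius
#' @return temperature in Kelvin
#' @export
celsius_to_kelvin <- function(temp_C) temp_C + 273.15

# Wrap angles (degrees) to [-180, 180)
wrap_angle <- function(a) ((a + 180) %% 360) - 180

# run expression with a locally set RNG seed, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
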