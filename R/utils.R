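#' Compartment classes
#'
#' The membrane compartment vocabulary used throughout the package. Four
#' labels name membrane profiles (plasma membrane, nuclear envelope,
#' endo-membranes, mitosome); `"none"` marks gold particles associated with
#' no membrane and is never a valid profile label.
#'
#' @param membranes Logical; if `TRUE` (default) return only the four
#'   membrane profile labels, otherwise include `"none"`.
#' @return Character vector of compartment labels.
#' @export
#' @examples
#' compartmentClasses()
compartmentClasses <- function(membranes = TRUE) {
  cls <- c("plasma_membrane", "nuclear_envelope", "endo_membrane",
           "mitosome", "none")
  if (membranes) cls[1:4] else cls
}

.membraneClasses <- function() compartmentClasses(membranes = TRUE)

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG state. All stochastic operations in the package funnel through this.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

## Derive n reproducible child seeds (< 2^31) from a parent seed.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.assertScalarNumber <- function(x, name, positive = FALSE,
                                nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonnegative && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

## Total length of a polyline given as an n x 2 coordinate matrix (nm).
polylineLength <- function(coords) {
  if (!is.matrix(coords) || ncol(coords) != 2L || nrow(coords) < 2L)
    stop("a polyline needs an n x 2 coordinate matrix with n >= 2",
         call. = FALSE)
  d <- diff(coords)
  sum(sqrt(rowSums(d^2)))
}
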