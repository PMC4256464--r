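## Stereological length estimation. A square test-line lattice of spacing d
## carries test-line length per unit area L_A = 2/d; for a randomly
## translated and rotated lattice the classical relation B_A = (pi/2) I_L
## gives the design-unbiased profile-length estimator L-hat = (pi/4) d I,
## where I is the total number of lattice-line crossings.

#' Draw a randomly placed square lattice
#'
#' Offset is uniform on `[0, d)^2` and rotation uniform on `[0, pi/2)`,
#' both drawn from `seed`. Rotation randomisation makes length estimation
#' unbiased for anisotropic membranes.
#'
#' @param spacingNm Lattice spacing d > 0, nm. Protocol values are 262, 618
#'   or 914 nm (plasma membrane, nuclear envelope) and 914 or 1540 nm
#'   (endo-membranes).
#' @param seed Integer seed.
#' @return A [GridSpec-class].
#' @export
#' @examples
#' makeGrid(262, seed = 3L)
makeGrid <- function(spacingNm, seed = 1L) {
  .assertScalarNumber(spacingNm, "spacingNm", positive = TRUE)
  withSeed(seed, {
    off <- stats::runif(2, 0, spacingNm)
    ang <- stats::runif(1, 0, pi / 2)
    new("GridSpec", spacingNm = as.numeric(spacingNm), offset = off,
        angleRad = ang, seed = as.integer(seed))
  })
}

## Crossings of one coordinate family: lines at offset + k*d. 'a', 'b' are
## the segment endpoint coordinates perpendicular to the family. A segment
## endpoint exactly on a line counts once; a segment collinear with a line
## (a == b on a line) counts zero.
.familyCrossings <- function(a, b, offset, d) {
  lo <- (pmin(a, b) - offset) / d
  hi <- (pmax(a, b) - offset) / d
  n <- floor(hi) - ceiling(lo) + 1
  n[a == b] <- 0
  pmax(n, 0)
}

#' Count lattice-line intersections per compartment
#'
#' Counts crossing points between membrane polyline segments and both line
#' families of a square lattice. Segments are mapped into the lattice frame
#' (rotation removed), where the families are vertical and horizontal lines
#' at multiples of the spacing plus the offset. A segment endpoint lying
#' exactly on a line counts as one intersection; a segment collinear with a
#' line contributes zero.
#'
#' @param profiles List of membrane profiles (`compartment`, `coords`,
#'   `closed`), coordinates in nm, or a [CellScene-class] /
#'   [MicrographAnnotation-class].
#' @param grid A [GridSpec-class].
#' @return Named integer vector: intersections per membrane compartment
#'   (zero where a compartment has no profiles).
#' @export
#' @examples
#' seg <- list(list(compartment = "plasma_membrane",
#'                  coords = rbind(c(1, 1), c(1001, 1)), closed = FALSE))
#' grid <- new("GridSpec", spacingNm = 262, offset = c(0, 0),
#'             angleRad = 0, seed = 0L)
#' countIntersections(seg, grid)  # 3 crossings with vertical lines
countIntersections <- function(profiles, grid) {
  if (is(profiles, "CellScene") || is(profiles, "MicrographAnnotation"))
    profiles <- profiles@profiles
  stopifnot(is(grid, "GridSpec"))
  validObject(grid)
  counts <- stats::setNames(integer(length(.membraneClasses())),
                            .membraneClasses())
  ca <- cos(-grid@angleRad); sa <- sin(-grid@angleRad)
  for (p in profiles) {
    xy <- p$coords
    ## rotate into the lattice frame
    gx <- ca * xy[, 1L] - sa * xy[, 2L]
    gy <- sa * xy[, 1L] + ca * xy[, 2L]
    n <- length(gx)
    I <- sum(.familyCrossings(gx[-n], gx[-1L], grid@offset[1L],
                              grid@spacingNm)) +
         sum(.familyCrossings(gy[-n], gy[-1L], grid@offset[2L],
                              grid@spacingNm))
    counts[p$compartment] <- counts[p$compartment] + as.integer(I)
  }
  counts
}

#' Stereological membrane length estimate
#'
#' \eqn{\hat L = (\pi/4)\, d\, I} for `I` crossings with a square lattice of
#' spacing `d`. Unbiased over uniform random lattice translation and
#' rotation for any rectifiable profile.
#'
#' @param I Nonnegative intersection count(s).
#' @param spacingNm Lattice spacing d > 0, nm.
#' @return Estimated length(s), nm.
#' @export
#' @examples
#' estimateLength(3, 262)  # (pi/4) * 786 ~ 617.3 nm
estimateLength <- function(I, spacingNm) {
  .assertScalarNumber(spacingNm, "spacingNm", positive = TRUE)
  if (any(!is.finite(I)) || any(I < 0))
    stop("intersection counts must be finite and >= 0", call. = FALSE)
  (pi / 4) * spacingNm * I
}
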