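## Synthetic scene geometry. Shapes are vector polylines in nm; no pixel
## rendering. Closed curves repeat their first vertex as the last.

## Smoothed star-convex closed blob: radius R modulated by a few random
## Fourier harmonics. Returns an (n+1) x 2 closed polyline.
.blobCurve <- function(center, radius, nVertices = 128L, roughness = 0.08,
                       harmonics = 2:5) {
  amp <- stats::rnorm(length(harmonics), 0, roughness / sqrt(harmonics))
  phase <- stats::runif(length(harmonics), 0, 2 * pi)
  theta <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  mod <- rep(1, length(theta))
  for (k in seq_along(harmonics))
    mod <- mod + amp[k] * cos(harmonics[k] * theta + phase[k])
  r <- radius * pmax(mod, 0.2)
  xy <- cbind(center[1L] + r * cos(theta), center[2L] + r * sin(theta))
  rbind(xy, xy[1L, , drop = FALSE])
}

## Ellipse polyline (closed), axes are full lengths (minor, major), nm.
.ellipseCurve <- function(center, minorAxis, majorAxis, angle,
                          nVertices = 40L) {
  theta <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  x <- (majorAxis / 2) * cos(theta)
  y <- (minorAxis / 2) * sin(theta)
  ca <- cos(angle); sa <- sin(angle)
  xy <- cbind(center[1L] + ca * x - sa * y, center[2L] + sa * x + ca * y)
  rbind(xy, xy[1L, , drop = FALSE])
}

## Open random-walk polyline of total contour length len, emulating a
## tubulovesicular endo-membrane profile.
.tubuleCurve <- function(start, len, nSegments = 12L, headingSd = 0.45) {
  step <- len / nSegments
  heading <- stats::runif(1, 0, 2 * pi) +
    cumsum(c(0, stats::rnorm(nSegments - 1L, 0, headingSd)))
  dx <- step * cos(heading)
  dy <- step * sin(heading)
  cbind(start[1L] + cumsum(c(0, dx)), start[2L] + cumsum(c(0, dy)))
}

#' Generate a synthetic cryo-section scene
#'
#' Builds the vector geometry of one simulated meront section: one closed
#' plasma-membrane profile (a smoothed random star-convex curve of
#' characteristic radius `cellRadiusNm`), one closed nuclear-envelope
#' profile inside it, `nEndoTubules` open endo-membrane polylines, and
#' `nMitosomes` closed elliptical mitosome profiles with axes drawn
#' uniformly within `mitoAxisRangeNm`. The exact summed polyline length per
#' compartment is recorded as ground truth.
#'
#' @param params A [SceneParams-class] object.
#' @return A [CellScene-class] with profiles and `trueLengthNm`.
#' @export
#' @examples
#' scene <- makeScene(SceneParams(seed = 7L))
#' trueLengthNm(scene)
makeScene <- function(params) {
  stopifnot(is(params, "SceneParams"))
  validObject(params)
  withSeed(params@seed, {
    center <- rep(params@fieldSizeNm / 2, 2L)
    R <- params@cellRadiusNm
    prof <- list(list(compartment = "plasma_membrane",
                      coords = .blobCurve(center, R), closed = TRUE))

    neCenter <- center + stats::runif(2, -0.2, 0.2) * R
    prof[[length(prof) + 1L]] <- list(
      compartment = "nuclear_envelope",
      coords = .blobCurve(neCenter, 0.45 * R, nVertices = 96L,
                          roughness = 0.06),
      closed = TRUE)

    for (i in seq_len(params@nEndoTubules)) {
      u <- stats::runif(1, 0, 2 * pi)
      rad <- 0.8 * R * sqrt(stats::runif(1))
      start <- center + rad * c(cos(u), sin(u))
      len <- stats::runif(1, params@endoLenRangeNm[1L],
                          params@endoLenRangeNm[2L])
      prof[[length(prof) + 1L]] <- list(
        compartment = "endo_membrane",
        coords = .tubuleCurve(start, len), closed = FALSE)
    }

    for (i in seq_len(params@nMitosomes)) {
      u <- stats::runif(1, 0, 2 * pi)
      rad <- 0.75 * R * sqrt(stats::runif(1))
      mCenter <- center + rad * c(cos(u), sin(u))
      axes <- sort(stats::runif(2, params@mitoAxisRangeNm[1L],
                                params@mitoAxisRangeNm[2L]))
      prof[[length(prof) + 1L]] <- list(
        compartment = "mitosome",
        coords = .ellipseCurve(mCenter, axes[1L], axes[2L],
                               stats::runif(1, 0, pi)),
        closed = TRUE)
    }

    lens <- vapply(.membraneClasses(), function(cls)
      sum(vapply(prof, function(p)
        if (p$compartment == cls) polylineLength(p$coords) else 0,
        numeric(1))), numeric(1))

    new("CellScene", profiles = prof, trueLengthNm = lens, params = params)
  })
}
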