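## Membrane association of gold particles and labelling densities.

## Minimum distance from each point (P x 2) to a polyline (V x 2), vectorised
## over point x segment pairs.
.distPointsToPolyline <- function(pts, coords) {
  P <- nrow(pts)
  if (P == 0L) return(numeric(0))
  V <- nrow(coords)
  ax <- coords[-V, 1L]; ay <- coords[-V, 2L]
  dx <- coords[-1L, 1L] - ax; dy <- coords[-1L, 2L] - ay
  len2 <- dx^2 + dy^2
  S <- length(ax)
  PX <- matrix(pts[, 1L], P, S)
  PY <- matrix(pts[, 2L], P, S)
  AX <- matrix(ax, P, S, byrow = TRUE)
  AY <- matrix(ay, P, S, byrow = TRUE)
  DX <- matrix(dx, P, S, byrow = TRUE)
  DY <- matrix(dy, P, S, byrow = TRUE)
  L2 <- matrix(pmax(len2, .Machine$double.xmin), P, S, byrow = TRUE)
  t <- pmin(pmax(((PX - AX) * DX + (PY - AY) * DY) / L2, 0), 1)
  d2 <- (PX - AX - t * DX)^2 + (PY - AY - t * DY)^2
  sqrt(apply(d2, 1L, min))
}

#' Distance from a point to a membrane polyline
#'
#' Euclidean distance from the point to the nearest point on any segment of
#' the polyline.
#'
#' @param point Numeric pair (x, y), nm.
#' @param polyline An n x 2 coordinate matrix, n >= 2, nm.
#' @return Distance in nm.
#' @export
#' @examples
#' distanceToProfile(c(0, 5), rbind(c(-10, 0), c(10, 0)))   # 5
#' distanceToProfile(c(20, 0), rbind(c(-10, 0), c(10, 0)))  # 10
distanceToProfile <- function(point, polyline) {
  if (!is.matrix(polyline) || ncol(polyline) != 2L || nrow(polyline) < 2L)
    stop("polyline must be an n x 2 matrix with n >= 2 points", call. = FALSE)
  .distPointsToPolyline(matrix(point, nrow = 1L), polyline)
}

#' Assign gold particles to membrane compartments
#'
#' Applies the membrane-association rule: a particle whose centre is less
#' than `assocDistNm` (strict `<`) from the nearest membrane profile is
#' assigned to that profile's compartment; all others are unassigned. A
#' particle within the threshold of several profiles goes to the nearest;
#' exact distance ties are broken by lexicographic compartment name.
#'
#' @param particles n x 2 matrix of particle centres, nm, or a
#'   [MicrographAnnotation-class].
#' @param profiles List of membrane profiles (used only when `particles` is
#'   a matrix).
#' @param params An [AssignmentParams-class].
#' @return A list: `counts` (named integer per membrane compartment),
#'   `unassigned` (integer), and `assignment` (per-particle compartment or
#'   `"none"`).
#' @export
#' @examples
#' prof <- list(list(compartment = "plasma_membrane",
#'                   coords = rbind(c(0, 0), c(100, 0)), closed = FALSE))
#' assignParticles(rbind(c(50, 5), c(50, 40)), prof)$counts
assignParticles <- function(particles, profiles = NULL,
                            params = AssignmentParams()) {
  if (is(particles, "MicrographAnnotation")) {
    profiles <- particles@profiles
    particles <- particles@particles
  }
  stopifnot(is(params, "AssignmentParams"))
  validObject(params)
  counts <- stats::setNames(integer(length(.membraneClasses())),
                            .membraneClasses())
  n <- nrow(particles)
  if (n == 0L || length(profiles) == 0L)
    return(list(counts = counts, unassigned = n,
                assignment = rep("none", n)))

  dists <- vapply(profiles, function(p)
    .distPointsToPolyline(particles, p$coords), numeric(n))
  dists <- matrix(dists, nrow = n)
  comp <- vapply(profiles, `[[`, character(1), "compartment")

  assignment <- rep("none", n)
  dmin <- apply(dists, 1L, min)
  within <- dmin < params@assocDistNm
  if (any(within)) {
    idx <- which(within)
    assignment[idx] <- vapply(idx, function(i) {
      cand <- comp[dists[i, ] == dmin[i]]
      sort(cand)[1L]  # lexicographic tie-break over exactly tied profiles
    }, character(1))
  }
  tab <- table(factor(assignment[assignment != "none"],
                      levels = .membraneClasses()))
  counts[] <- as.integer(tab)
  list(counts = counts, unassigned = sum(assignment == "none"),
       assignment = assignment)
}

#' Labelling density table
#'
#' Computes per-compartment labelling density D = N / L (gold per micron)
#' from membrane-associated gold counts and estimated membrane lengths.
#' When `counts`/`lengthsNm` are matrices (micrographs in rows), values are
#' pooled within the set by ratio of sums — total gold over total estimated
#' length — never by averaging per-micrograph ratios. Density is undefined
#' (`NA`, not zero) where the estimated length is zero or absent.
#'
#' @param counts Named nonnegative vector, or micrograph x compartment
#'   matrix, of membrane-associated gold counts.
#' @param lengthsNm Estimated membrane lengths in nm, same shape as
#'   `counts`; `NA` marks compartments quantified by counts only.
#' @param condition,experimentId Optional metadata carried into the table.
#' @return A data frame with columns `compartment`, `N`, `L_nm`, `D`
#'   (gold/µm) and `density_defined`.
#' @export
#' @examples
#' labellingDensity(c(plasma_membrane = 20), c(plasma_membrane = 4000))
labellingDensity <- function(counts, lengthsNm, condition = NA_character_,
                             experimentId = NA_character_) {
  if (is.matrix(counts)) counts <- colSums(counts)
  if (is.matrix(lengthsNm)) lengthsNm <- colSums(lengthsNm)
  if (any(counts < 0, na.rm = TRUE) || any(lengthsNm < 0, na.rm = TRUE))
    stop("counts and lengths must be >= 0", call. = FALSE)
  cls <- names(counts)
  if (is.null(cls)) stop("counts must be named by compartment", call. = FALSE)
  lengthsNm <- lengthsNm[cls]
  defined <- !is.na(lengthsNm) & lengthsNm > 0
  D <- ifelse(defined, counts / (lengthsNm / 1000), NA_real_)
  data.frame(compartment = cls, N = as.numeric(counts),
             L_nm = as.numeric(lengthsNm), D = as.numeric(D),
             density_defined = defined,
             condition = condition, experiment_id = experimentId,
             row.names = NULL)
}

#' Default compartment-to-grid-spacing map
#'
#' Fine spacing (262 nm by default, alternatives 618 and 914 nm) for the
#' plasma membrane and nuclear envelope; coarse spacing (914 nm by default,
#' alternative 1540 nm) for endo-membranes. Mitosome membranes are not
#' length-estimated by grid — their labelling is reported as counts — so
#' their spacing is `NA`.
#'
#' @param fine,coarse Spacings in nm.
#' @return Named numeric vector over the membrane compartments.
#' @export
#' @examples
#' defaultSpacingMap()
defaultSpacingMap <- function(fine = 262, coarse = 914) {
  c(plasma_membrane = fine, nuclear_envelope = fine,
    endo_membrane = coarse, mitosome = NA_real_)
}

#' Quantify a set of annotated micrographs
#'
#' Runs the measurement stages on every annotation: a randomly placed
#' square lattice per micrograph and spacing, intersection counting and
#' length estimation per compartment, membrane association of gold
#' particles, then pooling within each (antibody, experiment, condition,
#' sampling stream) group by ratio of sums. SUR and comprehensive sampling
#' streams are tallied separately and never pooled.
#'
#' @param annotations List of [MicrographAnnotation-class].
#' @param spacingMap Named spacing per compartment, nm ([defaultSpacingMap()]);
#'   `NA` marks count-only compartments.
#' @param assignParams An [AssignmentParams-class].
#' @param seed Integer seed for the random grid placements.
#' @return A data frame, one row per (antibody, experiment, condition,
#'   stream, compartment): `n_micrographs`, `N`, `L_nm`, `D`,
#'   `density_defined`, with per-group unassigned-particle tallies in
#'   attribute `"unassigned"`.
#' @export
quantifyAnnotations <- function(annotations, spacingMap = defaultSpacingMap(),
                                assignParams = AssignmentParams(),
                                seed = 1L) {
  stopifnot(length(annotations) > 0L)
  ids <- vapply(annotations, function(a)
    paste(a@antibodyId, a@experimentId, a@condition, a@samplingStream,
          a@micrographId, sep = "\r"), character(1))
  annotations <- annotations[order(ids)]  # order-independent reruns

  spacings <- sort(unique(spacingMap[!is.na(spacingMap)]))
  gridSeeds <- matrix(childSeeds(seed, length(annotations) *
                                   max(1L, length(spacings))),
                      nrow = length(annotations))

  rows <- list(); unrows <- list()
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(annotations)) {
    a <- annotations[[i]]
    key <- paste(a@antibodyId, a@experimentId, a@condition,
                 a@samplingStream, sep = "\r")
    if (is.null(acc[[key]]))
      acc[[key]] <- list(
        N = stats::setNames(numeric(4), .membraneClasses()),
        L = stats::setNames(numeric(4), .membraneClasses()),
        unassigned = 0, total = 0, m = 0L)
    g <- acc[[key]]

    lens <- stats::setNames(rep(NA_real_, 4), .membraneClasses())
    for (j in seq_along(spacings)) {
      d <- spacings[j]
      grid <- makeGrid(d, seed = gridSeeds[i, j])
      I <- countIntersections(a@profiles, grid)
      for (cls in names(spacingMap)[!is.na(spacingMap) & spacingMap == d])
        lens[cls] <- estimateLength(I[[cls]], d)
    }
    asg <- assignParticles(a@particles, a@profiles, assignParams)

    g$N <- g$N + asg$counts
    g$L <- g$L + ifelse(is.na(lens), 0, lens)
    g$unassigned <- g$unassigned + asg$unassigned
    g$total <- g$total + nrow(a@particles)
    g$m <- g$m + 1L
    acc[[key]] <- g
  }

  countOnly <- names(spacingMap)[is.na(spacingMap)]
  for (key in ls(acc)) {
    g <- acc[[key]]
    meta <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    L <- g$L
    L[countOnly] <- NA_real_
    tab <- labellingDensity(g$N, L, condition = meta[3L],
                            experimentId = meta[2L])
    tab$antibody_id <- meta[1L]
    tab$sampling_stream <- meta[4L]
    tab$n_micrographs <- g$m
    rows[[length(rows) + 1L]] <- tab
    unrows[[length(unrows) + 1L]] <- data.frame(
      antibody_id = meta[1L], experiment_id = meta[2L], condition = meta[3L],
      sampling_stream = meta[4L], unassigned = g$unassigned,
      total_particles = g$total)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$antibody_id, out$experiment_id, out$condition,
                   out$sampling_stream, out$compartment), ]
  rownames(out) <- NULL
  attr(out, "unassigned") <- do.call(rbind, unrows)
  out
}
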