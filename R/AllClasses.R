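## Central S4 containers. Geometry is always in nanometres, origin at the
## top-left corner of the field, y increasing downward.

.validProfiles <- function(profiles, requireMembraneClass = TRUE) {
  if (!is.list(profiles)) return("'profiles' must be a list")
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    if (!is.list(p) ||
        !all(c("compartment", "coords", "closed") %in% names(p)))
      return(sprintf(
        "profile %d must be a list with fields compartment, coords, closed", i))
    if (!is.character(p$compartment) || length(p$compartment) != 1L ||
        !(p$compartment %in% .membraneClasses()))
      return(sprintf(
        "profile %d has compartment '%s'; must be one of: %s", i,
        paste(p$compartment, collapse = ","),
        paste(.membraneClasses(), collapse = ", ")))
    if (!is.matrix(p$coords) || ncol(p$coords) != 2L || nrow(p$coords) < 2L ||
        !all(is.finite(p$coords)))
      return(sprintf(
        "profile %d needs a finite n x 2 coordinate matrix, n >= 2", i))
    if (!is.logical(p$closed) || length(p$closed) != 1L || is.na(p$closed))
      return(sprintf("profile %d: 'closed' must be TRUE or FALSE", i))
    if (p$closed &&
        !isTRUE(all.equal(p$coords[1L, ], p$coords[nrow(p$coords), ],
                          tolerance = 0, check.attributes = FALSE)))
      return(sprintf(
        "profile %d is closed but first and last vertices differ", i))
  }
  TRUE
}

#' Parameters of a synthetic cryo-section scene
#'
#' Describes the geometry of one simulated meront section: a closed
#' plasma-membrane blob of characteristic radius `cellRadiusNm`, a nuclear
#' envelope inside it, `nEndoTubules` open tubulovesicular endo-membrane
#' polylines, and `nMitosomes` closed elliptical mitosome profiles whose
#' minor and major axes are drawn uniformly within `mitoAxisRangeNm`
#' (default 50--300 nm, the defining size range of the organelle).
#' Identical parameters and seed reproduce the scene bit for bit.
#'
#' @slot cellRadiusNm Length scale of the plasma-membrane blob (nm).
#' @slot nMitosomes Number of mitosome profiles.
#' @slot mitoAxisRangeNm Numeric pair (min, max) of mitosome axis lengths, nm.
#' @slot nEndoTubules Number of open endo-membrane polylines.
#' @slot endoLenRangeNm Numeric pair (min, max) of endo-membrane contour
#'   lengths, nm.
#' @slot fieldSizeNm Edge length of the square field, nm.
#' @slot seed Integer RNG seed.
#' @export
setClass("SceneParams", representation(
  cellRadiusNm = "numeric",
  nMitosomes = "integer",
  mitoAxisRangeNm = "numeric",
  nEndoTubules = "integer",
  endoLenRangeNm = "numeric",
  fieldSizeNm = "numeric",
  seed = "integer"
))

setValidity("SceneParams", function(object) {
  rng <- function(r, nm) {
    if (length(r) != 2L || !all(is.finite(r)) || any(r <= 0))
      return(sprintf("'%s' must be two positive finite numbers", nm))
    if (r[1L] > r[2L])
      return(sprintf("'%s': min exceeds max", nm))
    TRUE
  }
  for (chk in list(
    rng(object@mitoAxisRangeNm, "mitoAxisRangeNm"),
    rng(object@endoLenRangeNm, "endoLenRangeNm")))
    if (!isTRUE(chk)) return(chk)
  if (object@cellRadiusNm <= 0 || object@fieldSizeNm <= 0)
    return("all length scales must be strictly positive")
  if (object@nMitosomes < 0L || object@nEndoTubules < 0L)
    return("profile counts must be >= 0")
  TRUE
})

#' @rdname SceneParams-class
#' @param cellRadiusNm,nMitosomes,mitoAxisRangeNm,nEndoTubules,endoLenRangeNm,fieldSizeNm,seed
#'   See the slot descriptions.
#' @return A validated `SceneParams` object.
#' @export
#' @examples
#' SceneParams(nMitosomes = 2L)
SceneParams <- function(cellRadiusNm = 1000, nMitosomes = 3L,
                        mitoAxisRangeNm = c(50, 300), nEndoTubules = 5L,
                        endoLenRangeNm = c(300, 1200), fieldSizeNm = 3000,
                        seed = 1L) {
  new("SceneParams",
      cellRadiusNm = as.numeric(cellRadiusNm),
      nMitosomes = as.integer(nMitosomes),
      mitoAxisRangeNm = as.numeric(mitoAxisRangeNm),
      nEndoTubules = as.integer(nEndoTubules),
      endoLenRangeNm = as.numeric(endoLenRangeNm),
      fieldSizeNm = as.numeric(fieldSizeNm),
      seed = as.integer(seed))
}

#' Immunogold labelling model
#'
#' Stochastic model of gold deposition on a scene: a Poisson process of
#' specific gold along each compartment's membrane at rate
#' `specificDensity[c]` (gold per micron of membrane profile), laterally
#' jittered off the membrane line by a centred normal with SD `jitterSdNm`;
#' plus a uniform nonspecific background at `backgroundIntensity` gold per
#' square micron of field. In the peptide-inhibited condition the specific
#' component is multiplied by `1 - inhibitionEfficiency`.
#'
#' @slot specificDensity Named numeric, gold/µm of membrane, one entry per
#'   membrane compartment class.
#' @slot backgroundIntensity Nonspecific intensity, gold/µm² of field.
#' @slot jitterSdNm SD of lateral displacement of specific gold, nm.
#' @slot inhibitionEfficiency Fraction of specific labelling suppressed in
#'   the inhibited condition, in [0, 1].
#' @slot particleDiameterNm Gold particle diameter, nm (10 nm protein-A gold).
#' @export
setClass("LabellingModel", representation(
  specificDensity = "numeric",
  backgroundIntensity = "numeric",
  jitterSdNm = "numeric",
  inhibitionEfficiency = "numeric",
  particleDiameterNm = "numeric"
))

setValidity("LabellingModel", function(object) {
  sd <- object@specificDensity
  if (!setequal(names(sd), .membraneClasses()))
    return(sprintf("specificDensity must be named by: %s",
                   paste(.membraneClasses(), collapse = ", ")))
  if (any(!is.finite(sd)) || any(sd < 0))
    return("specific densities must be finite and >= 0")
  if (object@backgroundIntensity < 0) return("backgroundIntensity must be >= 0")
  if (object@jitterSdNm < 0) return("jitterSdNm must be >= 0")
  if (object@inhibitionEfficiency < 0 || object@inhibitionEfficiency > 1)
    return("inhibitionEfficiency must lie in [0, 1]")
  if (object@particleDiameterNm <= 0) return("particleDiameterNm must be > 0")
  TRUE
})

#' @rdname LabellingModel-class
#' @param specificDensity,backgroundIntensity,jitterSdNm,inhibitionEfficiency,particleDiameterNm
#'   See the slot descriptions.
#' @return A validated `LabellingModel`.
#' @export
#' @examples
#' LabellingModel()  # defaults: plasma-membrane dominated labelling
LabellingModel <- function(
    specificDensity = c(plasma_membrane = 5, nuclear_envelope = 1,
                        endo_membrane = 1, mitosome = 0),
    backgroundIntensity = 100 / 3, jitterSdNm = 8,
    inhibitionEfficiency = 1, particleDiameterNm = 10) {
  sd <- specificDensity
  if (is.null(names(sd)))
    names(sd) <- .membraneClasses()[seq_along(sd)]
  missing <- setdiff(.membraneClasses(), names(sd))
  sd[missing] <- 0
  new("LabellingModel",
      specificDensity = sd[.membraneClasses()],
      backgroundIntensity = as.numeric(backgroundIntensity),
      jitterSdNm = as.numeric(jitterSdNm),
      inhibitionEfficiency = as.numeric(inhibitionEfficiency),
      particleDiameterNm = as.numeric(particleDiameterNm))
}

#' Ground-truth cell scene
#'
#' Geometric ground truth of one simulated cell section: membrane profiles
#' (compartment label, polyline, closed flag) plus the exact polyline length
#' per compartment. Produced by [makeScene()]; consumed by [placeGold()] and
#' by parameter-recovery tests, never by the blind analysis pipeline.
#'
#' @slot profiles List of profiles; each is `list(compartment, coords, closed)`
#'   with `coords` an n x 2 matrix in nm.
#' @slot trueLengthNm Named numeric: exact summed polyline length per
#'   membrane compartment (0 where absent).
#' @slot params The `SceneParams` the scene was generated from.
#' @export
setClass("CellScene", representation(
  profiles = "list",
  trueLengthNm = "numeric",
  params = "SceneParams"
))

setValidity("CellScene", function(object) {
  ok <- .validProfiles(object@profiles)
  if (!isTRUE(ok)) return(ok)
  if (!setequal(names(object@trueLengthNm), .membraneClasses()))
    return("trueLengthNm must be named by the four membrane classes")
  for (cls in .membraneClasses()) {
    tot <- sum(vapply(object@profiles, function(p)
      if (p$compartment == cls) polylineLength(p$coords) else 0, numeric(1)))
    if (!isTRUE(all.equal(tot, unname(object@trueLengthNm[cls]),
                          tolerance = 1e-9)))
      return(sprintf(
        "trueLengthNm['%s'] does not equal the summed polyline length", cls))
  }
  TRUE
})

#' One observed micrograph annotation
#'
#' A single annotated field as the analysis pipeline sees it: membrane
#' polylines with compartment labels, gold particle coordinates, and
#' acquisition metadata. Carries no ground truth.
#'
#' @slot micrographId,experimentId,antibodyId Character identifiers.
#' @slot condition `"native"` or `"inhibited"` (peptide-inhibition control).
#' @slot samplingStream `"sur"` (systematic uniform random fields) or
#'   `"comprehensive"` (dedicated mitosome scanning); the two streams are
#'   never pooled.
#' @slot nmPerPx Original pixel size, provenance metadata only — all stored
#'   geometry is in nm.
#' @slot fieldSizeNm Edge length of the square field, nm.
#' @slot profiles Membrane profiles as in [CellScene-class].
#' @slot particles n x 2 matrix of gold particle centres, nm.
#' @export
setClass("MicrographAnnotation", representation(
  micrographId = "character",
  experimentId = "character",
  antibodyId = "character",
  condition = "character",
  samplingStream = "character",
  nmPerPx = "numeric",
  fieldSizeNm = "numeric",
  profiles = "list",
  particles = "matrix"
))

setValidity("MicrographAnnotation", function(object) {
  if (!(object@condition %in% c("native", "inhibited")))
    return(sprintf("condition '%s' invalid; must be 'native' or 'inhibited'",
                   object@condition))
  if (!(object@samplingStream %in% c("sur", "comprehensive")))
    return(sprintf(
      "samplingStream '%s' invalid; must be 'sur' or 'comprehensive'",
      object@samplingStream))
  ok <- .validProfiles(object@profiles)
  if (!isTRUE(ok)) return(ok)
  p <- object@particles
  if (!is.numeric(p) || ncol(p) != 2L || (nrow(p) > 0L && !all(is.finite(p))))
    return("particles must be a finite n x 2 numeric matrix")
  if (object@fieldSizeNm <= 0) return("fieldSizeNm must be > 0")
  TRUE
})

#' @rdname MicrographAnnotation-class
#' @param micrographId,experimentId,antibodyId,condition,samplingStream,nmPerPx,fieldSizeNm,profiles,particles
#'   See the slot descriptions.
#' @return A validated `MicrographAnnotation`.
#' @export
MicrographAnnotation <- function(micrographId, experimentId, antibodyId,
                                 condition, samplingStream = "sur",
                                 nmPerPx = NA_real_, fieldSizeNm,
                                 profiles = list(),
                                 particles = matrix(numeric(0), ncol = 2)) {
  new("MicrographAnnotation",
      micrographId = as.character(micrographId),
      experimentId = as.character(experimentId),
      antibodyId = as.character(antibodyId),
      condition = as.character(condition),
      samplingStream = as.character(samplingStream),
      nmPerPx = as.numeric(nmPerPx),
      fieldSizeNm = as.numeric(fieldSizeNm),
      profiles = profiles,
      particles = particles)
}

#' A randomly placed square test-line lattice
#'
#' Two orthogonal families of parallel lines at spacing `spacingNm`, shifted
#' by a uniform offset in `[0, d)^2` and rotated by a uniform angle in
#' `[0, pi/2)`. Random translation and rotation make the length estimator
#' design-unbiased for membranes of any orientation.
#'
#' @slot spacingNm Lattice spacing d, nm.
#' @slot offset Numeric pair (dx, dy), each in `[0, d)`.
#' @slot angleRad Rotation of the lattice, in `[0, pi/2)`.
#' @slot seed Seed used to draw offset and angle.
#' @export
setClass("GridSpec", representation(
  spacingNm = "numeric",
  offset = "numeric",
  angleRad = "numeric",
  seed = "integer"
))

setValidity("GridSpec", function(object) {
  d <- object@spacingNm
  if (d <= 0) return("spacingNm must be > 0")
  if (length(object@offset) != 2L || any(object@offset < 0) ||
      any(object@offset >= d))
    return("offset components must lie in [0, spacingNm)")
  if (object@angleRad < 0 || object@angleRad >= pi / 2)
    return("angleRad must lie in [0, pi/2)")
  TRUE
})

#' Parameters of the membrane-association rule
#'
#' A gold particle is membrane-associated when its centre lies less than
#' `assocDistNm` from the nearest membrane profile; the default 15 nm reads
#' the "less than one particle width away" rule for 10 nm gold as an
#' edge-to-membrane gap under one particle diameter (radius + diameter).
#' Particles within the threshold of several profiles go to the nearest;
#' exact ties are broken by lexicographic compartment name.
#'
#' @slot particleDiameterNm Gold particle diameter, nm.
#' @slot assocDistNm Centre-to-membrane association threshold, nm
#'   (strict `<`).
#' @slot tieBreak Tie-break rule; only `"nearest_then_lexicographic"`.
#' @export
setClass("AssignmentParams", representation(
  particleDiameterNm = "numeric",
  assocDistNm = "numeric",
  tieBreak = "character"
))

setValidity("AssignmentParams", function(object) {
  if (object@particleDiameterNm <= 0 || object@assocDistNm <= 0)
    return("thresholds must be > 0")
  if (!identical(object@tieBreak, "nearest_then_lexicographic"))
    return("tieBreak must be 'nearest_then_lexicographic'")
  TRUE
})

#' @rdname AssignmentParams-class
#' @param particleDiameterNm,assocDistNm,tieBreak See the slot descriptions.
#' @return A validated `AssignmentParams`.
#' @export
#' @examples
#' AssignmentParams()
AssignmentParams <- function(particleDiameterNm = 10,
                             assocDistNm = particleDiameterNm * 1.5,
                             tieBreak = "nearest_then_lexicographic") {
  new("AssignmentParams",
      particleDiameterNm = as.numeric(particleDiameterNm),
      assocDistNm = as.numeric(assocDistNm),
      tieBreak = tieBreak)
}

setMethod("show", "SceneParams", function(object) {
  cat("SceneParams: cell radius", object@cellRadiusNm, "nm,",
      object@nMitosomes, "mitosome(s) [",
      paste(object@mitoAxisRangeNm, collapse = "-"), "nm ],",
      object@nEndoTubules, "endo tubule(s), field",
      object@fieldSizeNm, "nm, seed", object@seed, "\n")
})

setMethod("show", "LabellingModel", function(object) {
  cat("LabellingModel (gold/µm of membrane):\n")
  print(object@specificDensity)
  cat("background", signif(object@backgroundIntensity, 4), "gold/µm² |",
      "jitter SD", object@jitterSdNm, "nm | inhibition",
      object@inhibitionEfficiency, "| particle",
      object@particleDiameterNm, "nm\n")
})

setMethod("show", "CellScene", function(object) {
  cat("CellScene:", length(object@profiles), "profiles\n")
  print(round(object@trueLengthNm, 1))
})

setMethod("show", "MicrographAnnotation", function(object) {
  cat(sprintf(
    "MicrographAnnotation %s [exp %s, ab %s, %s, %s]: %d profiles, %d gold\n",
    object@micrographId, object@experimentId, object@antibodyId,
    object@condition, object@samplingStream,
    length(object@profiles), nrow(object@particles)))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: d = %g nm, offset (%.2f, %.2f), angle %.4f rad, seed %d\n",
    object@spacingNm, object@offset[1L], object@offset[2L],
    object@angleRad, object@seed))
})

#' Accessors for scene and annotation objects
#'
#' @param x A `CellScene` or `MicrographAnnotation`.
#' @return `profiles()` the list of membrane profiles; `particles()` the
#'   n x 2 particle coordinate matrix; `trueLengthNm()` the named vector of
#'   exact membrane lengths.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))
#' @rdname accessors
#' @export
setMethod("profiles", "CellScene", function(x) x@profiles)
#' @rdname accessors
#' @export
setMethod("profiles", "MicrographAnnotation", function(x) x@profiles)

#' @rdname accessors
#' @export
setGeneric("particles", function(x) standardGeneric("particles"))
#' @rdname accessors
#' @export
setMethod("particles", "MicrographAnnotation", function(x) x@particles)

#' @rdname accessors
#' @export
setGeneric("trueLengthNm", function(x) standardGeneric("trueLengthNm"))
#' @rdname accessors
#' @export
setMethod("trueLengthNm", "CellScene", function(x) x@trueLengthNm)
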