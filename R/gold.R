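## Gold deposition: a Poisson process along each membrane at the model's
## compartment rate (gold per micron of profile), plus a uniform spatial
## Poisson background over the field.

## Points at arc-length positions u along a polyline, displaced
## perpendicular to the local segment by 'offsets' (signed, nm).
.pointsAlongPolyline <- function(coords, u, offsets) {
  seg <- diff(coords)
  segLen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(segLen))
  idx <- findInterval(u, cum, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(segLen))
  frac <- (u - cum[idx]) / segLen[idx]
  base <- coords[idx, , drop = FALSE] + frac * seg[idx, , drop = FALSE]
  tang <- seg[idx, , drop = FALSE] / segLen[idx]
  normal <- cbind(-tang[, 2L], tang[, 1L])
  base + offsets * normal
}

#' Deposit gold particles on a scene
#'
#' Draws specific gold as a Poisson process along each compartment's
#' membrane at rate `specificDensity[c]` gold/µm — multiplied by
#' `1 - inhibitionEfficiency` when `condition = "inhibited"` — with each
#' particle displaced perpendicular to the membrane line by
#' `Normal(0, jitterSdNm)`; and nonspecific background gold as a spatial
#' Poisson process at `backgroundIntensity` gold/µm² over the field.
#'
#' @param scene A [CellScene-class].
#' @param model A [LabellingModel-class].
#' @param condition `"native"` or `"inhibited"`.
#' @param seed Integer seed.
#' @return An n x 2 matrix of particle coordinates (nm) with attribute
#'   `"origin"`: the true source compartment, or `"background"` — kept for
#'   diagnostics only, never used by the analysis pipeline.
#' @export
#' @examples
#' scene <- makeScene(SceneParams(seed = 1L))
#' gold <- placeGold(scene, LabellingModel(), "native", seed = 2L)
#' table(attr(gold, "origin"))
placeGold <- function(scene, model, condition = c("native", "inhibited"),
                      seed = 1L) {
  stopifnot(is(scene, "CellScene"), is(model, "LabellingModel"))
  condition <- match.arg(condition)
  validObject(model)
  factor <- if (condition == "inhibited") 1 - model@inhibitionEfficiency else 1

  withSeed(seed, {
    pts <- list()
    origin <- character(0)
    for (p in scene@profiles) {
      lambda <- model@specificDensity[[p$compartment]] * factor
      if (lambda <= 0) next
      len <- polylineLength(p$coords)
      n <- stats::rpois(1L, lambda * len / 1000)
      if (n == 0L) next
      u <- stats::runif(n, 0, len)
      off <- stats::rnorm(n, 0, model@jitterSdNm)
      pts[[length(pts) + 1L]] <- .pointsAlongPolyline(p$coords, u, off)
      origin <- c(origin, rep(p$compartment, n))
    }
    fs <- scene@params@fieldSizeNm
    nBg <- stats::rpois(1L, model@backgroundIntensity * (fs / 1000)^2)
    if (nBg > 0L) {
      pts[[length(pts) + 1L]] <- cbind(stats::runif(nBg, 0, fs),
                                       stats::runif(nBg, 0, fs))
      origin <- c(origin, rep("background", nBg))
    }
    out <- if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), ncol = 2)
    colnames(out) <- c("x", "y")
    attr(out, "origin") <- origin
    out
  })
}

#' Simulate a full labelling study
#'
#' Emits paired native and peptide-inhibited annotation sets for
#' `nExperiments` replicate experiments, `micrographsPerCondition`
#' micrographs each — by default 3 experiments of 18 micrographs per
#' condition, the scale of an SUR-sampled immunogold quantification
#' protocol taking 16–20 micrographs per sample. Each micrograph is an
#' independently generated scene; a ground-truth sidecar records the true
#' labelling parameters and per-micrograph membrane lengths for recovery
#' tests, separate from the annotations the blind pipeline consumes.
#'
#' @param sceneParams A [SceneParams-class] (its own `seed` slot is ignored;
#'   per-micrograph seeds derive from `seed`).
#' @param model A [LabellingModel-class].
#' @param nExperiments Number of replicate experiments (>= 1).
#' @param micrographsPerCondition Micrographs per condition per experiment.
#' @param antibodyId Label carried in the annotations.
#' @param seed Integer master seed.
#' @return A list with `annotations` (list of
#'   [MicrographAnnotation-class]) and `truth` (list: model parameters and a
#'   per-micrograph data frame of true lengths and true particle counts).
#' @export
#' @examples
#' study <- simulateStudy(SceneParams(), LabellingModel(),
#'                        nExperiments = 2L, micrographsPerCondition = 2L,
#'                        seed = 11L)
#' length(study$annotations)  # 2 x 2 x 2 = 8
simulateStudy <- function(sceneParams, model, nExperiments = 3L,
                          micrographsPerCondition = 18L,
                          antibodyId = "ab1", seed = 1L) {
  stopifnot(is(sceneParams, "SceneParams"), is(model, "LabellingModel"))
  nExperiments <- as.integer(nExperiments)
  micrographsPerCondition <- as.integer(micrographsPerCondition)
  if (nExperiments < 1L || micrographsPerCondition < 1L)
    stop("nExperiments and micrographsPerCondition must be >= 1")

  conditions <- c("native", "inhibited")
  total <- nExperiments * micrographsPerCondition * length(conditions)
  seeds <- matrix(childSeeds(seed, 2L * total), ncol = 2L)

  annotations <- vector("list", total)
  truthRows <- vector("list", total)
  i <- 0L
  for (e in seq_len(nExperiments)) {
    for (cond in conditions) {
      for (m in seq_len(micrographsPerCondition)) {
        i <- i + 1L
        sp <- sceneParams
        sp@seed <- seeds[i, 1L]
        scene <- makeScene(sp)
        gold <- placeGold(scene, model, cond, seed = seeds[i, 2L])
        id <- sprintf("e%d_%s_m%02d", e, cond, m)
        annotations[[i]] <- MicrographAnnotation(
          micrographId = id,
          experimentId = sprintf("exp%d", e),
          antibodyId = antibodyId,
          condition = cond,
          samplingStream = "sur",
          fieldSizeNm = sp@fieldSizeNm,
          profiles = scene@profiles,
          particles = `attr<-`(gold, "origin", NULL))
        org <- attr(gold, "origin")
        truthRows[[i]] <- data.frame(
          micrograph_id = id, experiment_id = sprintf("exp%d", e),
          condition = cond,
          t(trueLengthNm(scene)),
          n_specific = sum(org != "background"),
          n_background = sum(org == "background"),
          check.names = FALSE)
      }
    }
  }

  truth <- list(
    specific_density = as.list(model@specificDensity),
    background_intensity = model@backgroundIntensity,
    inhibition_efficiency = model@inhibitionEfficiency,
    jitter_sd_nm = model@jitterSdNm,
    particle_diameter_nm = model@particleDiameterNm,
    seed = as.integer(seed),
    per_micrograph = do.call(rbind, truthRows))
  list(annotations = annotations, truth = truth)
}
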