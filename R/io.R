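## JSON annotation files and the pipeline driver. One JSON document per
## micrograph; geometry in nm; ground truth in a separate sidecar so the
## analysis stays blind.

.annotationToList <- function(a) {
  list(
    record_type = "micrograph_annotation",
    micrograph_id = a@micrographId,
    experiment_id = a@experimentId,
    antibody_id = a@antibodyId,
    condition = a@condition,
    sampling_stream = a@samplingStream,
    nm_per_px = a@nmPerPx,
    field_size_nm = a@fieldSizeNm,
    profiles = lapply(a@profiles, function(p)
      list(compartment = p$compartment, closed = p$closed,
           coords = unname(p$coords))),
    particles = unname(a@particles))
}

.listToAnnotation <- function(x, file = "<memory>") {
  need <- c("micrograph_id", "experiment_id", "antibody_id", "condition",
            "sampling_stream", "field_size_nm", "profiles", "particles")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(sprintf("%s: missing required field(s): %s", file,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!(x$condition %in% c("native", "inhibited")))
    stop(sprintf("%s: invalid condition '%s' (must be native or inhibited)",
                 file, x$condition), call. = FALSE)
  if (!(x$sampling_stream %in% c("sur", "comprehensive")))
    stop(sprintf(
      "%s: invalid sampling_stream '%s' (must be sur or comprehensive)",
      file, x$sampling_stream), call. = FALSE)
  profiles <- lapply(seq_along(x$profiles), function(i) {
    p <- x$profiles[[i]]
    if (!(p$compartment %in% .membraneClasses()))
      stop(sprintf("%s: profile %d has unknown compartment label '%s'",
                   file, i, p$compartment), call. = FALSE)
    coords <- matrix(as.numeric(unlist(p$coords)), ncol = 2L, byrow = FALSE)
    if (is.list(p$coords))  # row-major list-of-pairs form
      coords <- do.call(rbind, lapply(p$coords, as.numeric))
    if (!all(is.finite(coords)))
      stop(sprintf("%s: profile %d has non-finite coordinates", file, i),
           call. = FALSE)
    list(compartment = p$compartment, coords = coords,
         closed = isTRUE(p$closed))
  })
  particles <- x$particles
  if (is.list(particles) && length(particles))
    particles <- do.call(rbind, lapply(particles, as.numeric))
  if (length(particles) == 0L)
    particles <- matrix(numeric(0), ncol = 2L)
  particles <- matrix(as.numeric(particles), ncol = 2L)
  MicrographAnnotation(
    micrographId = x$micrograph_id, experimentId = x$experiment_id,
    antibodyId = x$antibody_id, condition = x$condition,
    samplingStream = x$sampling_stream,
    nmPerPx = if (is.null(x$nm_per_px)) NA_real_ else as.numeric(x$nm_per_px),
    fieldSizeNm = as.numeric(x$field_size_nm),
    profiles = profiles, particles = particles)
}

#' Write micrograph annotations to a directory
#'
#' One JSON file per annotation, named by micrograph id; full double
#' precision so write/read round-trips are exact.
#'
#' @param annotations List of [MicrographAnnotation-class].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
writeAnnotations <- function(annotations, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(annotations, function(a) {
    path <- file.path(dir, paste0(a@micrographId, ".json"))
    jsonlite::write_json(.annotationToList(a), path, auto_unbox = TRUE,
                         digits = I(17), na = "null",
                         pretty = FALSE)  # exact round-trip
    path
  }, character(1))
  invisible(paths)
}

#' Read and validate micrograph annotations
#'
#' Reads every `*.json` annotation document in a directory, validating the
#' schema; malformed JSON, unknown compartment labels or invalid enumerated
#' values are hard errors naming the offending file and field. Ground-truth
#' sidecar files are skipped. An empty directory yields an empty list with
#' a warning.
#'
#' @param path Directory of annotation JSON files, or a single file.
#' @return List of [MicrographAnnotation-class].
#' @export
readAnnotations <- function(path) {
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.json$", full.names = TRUE) else path
  out <- list()
  for (f in sort(files)) {
    x <- tryCatch(jsonlite::read_json(f, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("%s: malformed JSON (%s)", f,
                                 conditionMessage(e)), call. = FALSE))
    if (identical(x$record_type, "ground_truth")) next
    ann <- .listToAnnotation(x, file = f)
    validObject(ann)
    out[[length(out) + 1L]] <- ann
  }
  if (length(out) == 0L)
    warning(sprintf("no annotation files found under '%s'", path))
  out
}

#' Write / read a ground-truth sidecar
#'
#' Serialises the `truth` record of [simulateStudy()] to JSON at full
#' precision so it round-trips unchanged.
#'
#' @param truth The ground-truth list.
#' @param path File path.
#' @return `writeGroundTruth()` the path, invisibly; `readGroundTruth()`
#'   the restored list.
#' @export
writeGroundTruth <- function(truth, path) {
  truth$record_type <- "ground_truth"
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$record_type <- NULL
  x$per_micrograph <- as.data.frame(x$per_micrograph)
  x$specific_density <- as.list(vapply(x$specific_density, as.numeric,
                                       numeric(1)))
  for (f in c("background_intensity", "inhibition_efficiency",
              "jitter_sd_nm", "particle_diameter_nm"))
    x[[f]] <- as.numeric(x[[f]])
  x
}

#' Default study configuration
#'
#' The protocol defaults: fine grid spacing 262 nm (alternatives 618 and
#' 914 nm) for plasma membrane and nuclear envelope, coarse spacing 914 nm
#' (alternative 1540 nm) for endo-membranes, no grid for mitosomes; 10 nm
#' gold with a 15 nm association threshold; 3 replicate experiments of 18
#' micrographs per condition (within the 16–20 per sample of the sampling
#' protocol); mitosome axes 50–300 nm.
#'
#' @param annotationsDir,outDir Paths used by [runPipeline()].
#' @param seed Integer seed for grid placement.
#' @return A named list of configuration values.
#' @export
#' @examples
#' str(defaultStudyConfig())
defaultStudyConfig <- function(annotationsDir = ".", outDir = ".",
                               seed = 1L) {
  list(
    annotations_dir = annotationsDir,
    out_dir = outDir,
    spacing_map = defaultSpacingMap(),
    spacing_alternatives = list(fine = c(262, 618, 914),
                                coarse = c(914, 1540)),
    particle_diameter_nm = 10,
    assoc_dist_nm = 15,
    clamp = TRUE,
    fsp_mode = "per_compartment",
    n_experiments = 3L,
    micrographs_per_condition = 18L,
    micrographs_per_sample_range = c(16L, 20L),
    mito_axis_range_nm = c(50, 300),
    seed = as.integer(seed))
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full quantification pipeline
#'
#' Reads annotations, then executes grids, intersection counting, length
#' estimation, particle assignment, density pooling, specificity
#' correction and replicate aggregation, writing all tabular outputs plus
#' a provenance record. Re-running with identical configuration and inputs
#' reproduces byte-identical outputs; inputs are never modified. Missing
#' inhibited-condition data for an antibody aborts: specificity cannot be
#' computed without its peptide control.
#'
#' @param config A configuration list, see [defaultStudyConfig()].
#' @return Invisibly, a list with the quantified table, the specificity
#'   table, the two aggregate tables and the paths written.
#' @export
runPipeline <- function(config = defaultStudyConfig()) {
  annotations <- readAnnotations(config$annotations_dir)
  if (length(annotations) == 0L)
    stop("no annotations to analyse", call. = FALSE)

  ap <- AssignmentParams(particleDiameterNm = config$particle_diameter_nm,
                         assocDistNm = config$assoc_dist_nm)
  quantified <- quantifyAnnotations(annotations,
                                    spacingMap = config$spacing_map,
                                    assignParams = ap,
                                    seed = config$seed)
  spec <- specificityAnalysis(quantified, clamp = isTRUE(config$clamp),
                              fspMode = config$fsp_mode)
  aggNg <- aggregateSpecificity(spec, "Ngsp")
  aggDsp <- aggregateSpecificity(spec, "Dsp")

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    quantified = file.path(config$out_dir, "quantified.csv"),
    density = file.path(config$out_dir, "density_table.csv"),
    distribution = file.path(config$out_dir, "distribution_table.csv"),
    provenance = file.path(config$out_dir, "provenance.json"))

  utils::write.csv(quantified, paths[["quantified"]], row.names = FALSE)
  ## density report: D(0), D(-), D(sp) per compartment and experiment,
  ## negatives retained, with the cross-experiment mean +/- SEM appended
  utils::write.csv(
    spec[, c("antibody_id", "experiment_id", "compartment", "D0", "Dminus",
             "Dsp", "Fsp_raw", "Fsp_clamped", "fsp_basis", "d0_zero")],
    paths[["density"]], row.names = FALSE)
  dist <- spec[, c("antibody_id", "experiment_id", "compartment", "N0",
                   "Ngsp")]
  utils::write.csv(
    merge(dist, aggNg[, c("antibody_id", "compartment", "mean", "sem", "n")],
          by = c("antibody_id", "compartment"), sort = TRUE),
    paths[["distribution"]], row.names = FALSE)

  provenance <- list(
    package = "goldstereo",
    version = as.character(utils::packageVersion("goldstereo")),
    config = config[setdiff(names(config),
                            c("annotations_dir", "out_dir"))],
    config_hash = .configHash(config[setdiff(names(config),
                                             c("annotations_dir",
                                               "out_dir"))]),
    seed = config$seed,
    n_annotations = length(annotations),
    micrograph_ids = sort(vapply(annotations, function(a) a@micrographId,
                                 character(1))))
  jsonlite::write_json(provenance, paths[["provenance"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(quantified = quantified, specificity = spec,
                 aggregate_ngsp = aggNg, aggregate_dsp = aggDsp,
                 paths = paths))
}
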