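## Specificity correction against the peptide-inhibition control:
##   D(sp) = D(0) - D(-)          specific labelling density
##   F(sp) = D(sp) / D(0)         specific fraction (clamped to [0,1] for
##                                the distribution, raw value retained)
##   Ng(sp) = F(sp) x N(0)        per-compartment distribution of specific
##                                gold, summarised over replicate
##                                experiments as mean +/- SEM.

#' Specific labelling density
#'
#' `D(sp) = D(0) - D(-)`. Negative values are returned as-is: they indicate
#' induction of signal by the inhibited antiserum over a compartment and
#' are reported, not clipped. Undefined (`NA`) input densities propagate.
#'
#' @param D0 Raw (native) labelling density, gold/µm.
#' @param Dminus Density under the peptide-inhibition control, gold/µm.
#' @return `D0 - Dminus`, vectorised.
#' @export
#' @examples
#' specificDensity(10, 2)  # 8
#' specificDensity(2, 3)   # -1, retained
specificDensity <- function(D0, Dminus) {
  if (any(D0 < 0, na.rm = TRUE) || any(Dminus < 0, na.rm = TRUE))
    stop("densities must be >= 0", call. = FALSE)
  D0 - Dminus
}

#' Specific labelling fraction
#'
#' Raw `F(sp) = (D(0) - D(-)) / D(0)` and its clamp to `[0, 1]`. When
#' `D(0) = 0` both are defined as 0: no label implies no specific label,
#' and the convention keeps empty compartments from poisoning reports.
#'
#' @inheritParams specificDensity
#' @return A list with numeric components `raw` and `clamped`.
#' @export
#' @examples
#' specificFraction(10, 2)  # raw 0.8
#' specificFraction(2, 3)   # raw -0.5, clamped 0
specificFraction <- function(D0, Dminus) {
  if (any(D0 < 0, na.rm = TRUE) || any(Dminus < 0, na.rm = TRUE))
    stop("densities must be >= 0", call. = FALSE)
  raw <- ifelse(D0 == 0, 0, (D0 - Dminus) / D0)
  list(raw = raw, clamped = pmin(1, pmax(0, raw)))
}

#' Distribution of specific gold over compartments
#'
#' `Ng(sp) = F(sp) x N(0)` per compartment: the specific fraction
#' multiplied with the initial (native) gold particle counts.
#'
#' @param Fsp Named specific fraction per compartment (clamped values for a
#'   non-negative frequency distribution).
#' @param N0 Named native gold counts per compartment; the compartment sets
#'   must match.
#' @return Named numeric `Ng(sp)` per compartment (real-valued).
#' @export
#' @examples
#' specificDistribution(c(plasma_membrane = 0.8, mitosome = 0),
#'                      c(plasma_membrane = 50, mitosome = 4))
specificDistribution <- function(Fsp, N0) {
  if (is.null(names(Fsp)) || is.null(names(N0)) ||
      !setequal(names(Fsp), names(N0)))
    stop("Fsp and N0 must be named by the same compartment set",
         call. = FALSE)
  if (any(N0 < 0, na.rm = TRUE)) stop("N0 must be >= 0", call. = FALSE)
  Fsp * N0[names(Fsp)]
}

#' Mean and standard error across replicate experiments
#'
#' Per-compartment sample mean and SEM (sample SD with n-1 denominator,
#' divided by sqrt(n)) of a per-experiment statistic.
#'
#' @param values Either a numeric vector of per-experiment values, or a
#'   long data frame with columns `compartment` and `value` (one row per
#'   experiment and compartment).
#' @param statistic Label carried into the result.
#' @return A data frame with `compartment` (or `"all"`), `mean`, `sem`,
#'   `n`, `statistic`; `sem` is `NA` with a warning when `n < 2`.
#' @export
#' @examples
#' aggregateExperiments(c(1, 2, 3))  # mean 2, SEM 1/sqrt(3)
aggregateExperiments <- function(values, statistic = "value") {
  if (is.numeric(values))
    values <- data.frame(compartment = "all", value = values)
  stopifnot(all(c("compartment", "value") %in% names(values)))
  out <- do.call(rbind, lapply(split(values$value, values$compartment),
    function(v) {
      n <- sum(!is.na(v))
      data.frame(mean = mean(v, na.rm = TRUE),
                 sem = if (n >= 2L) stats::sd(v, na.rm = TRUE) / sqrt(n)
                       else NA_real_,
                 n = n)
    }))
  out <- data.frame(compartment = rownames(out), out, row.names = NULL)
  out$mean[out$n == 0L] <- NA_real_  # statistic undefined in every replicate
  if (any(out$n == 1L))
    warning("SEM unavailable for groups with fewer than 2 experiments")
  out$statistic <- statistic
  out
}

## Pick, per compartment, the sampling stream its counts come from:
## mitosomes from the comprehensive scan when one exists, everything else
## from the SUR stream.
.streamFor <- function(compartment, streams) {
  if (compartment == "mitosome" && "comprehensive" %in% streams)
    "comprehensive" else "sur"
}

#' Per-experiment specificity analysis
#'
#' Joins native and inhibited quantification rows within each experiment
#' and computes, per compartment: `D(0)`, `D(-)`, `D(sp) = D(0) - D(-)`,
#' raw and clamped `F(sp)`, the native count `N(0)` and the specific
#' distribution `Ng(sp) = F(sp) x N(0)`. Compartments quantified by counts
#' only (no grid length estimate, e.g. mitosomes) get their specific
#' fraction from per-micrograph count rates instead of densities; the
#' `fsp_basis` column records which was used. With
#' `fspMode = "section_wide"` a single fraction — computed from total gold
#' over total estimated membrane length — is applied to every compartment.
#'
#' @param quantified Output of [quantifyAnnotations()].
#' @param clamp Use the clamped fraction for `Ng(sp)` (default); raw
#'   fractions are always reported alongside.
#' @param fspMode `"per_compartment"` (default) or `"section_wide"`.
#' @return A data frame, one row per (antibody, experiment, compartment).
#' @export
specificityAnalysis <- function(quantified, clamp = TRUE,
                                fspMode = c("per_compartment",
                                            "section_wide")) {
  fspMode <- match.arg(fspMode)
  rows <- list()
  for (ab in unique(quantified$antibody_id)) {
    qa <- quantified[quantified$antibody_id == ab, ]
    if (!("inhibited" %in% qa$condition))
      stop(sprintf(paste0(
        "antibody '%s' has no inhibited-condition annotations; ",
        "specificity cannot be computed without the peptide control"), ab),
        call. = FALSE)
    for (ex in unique(qa$experiment_id)) {
      qe <- qa[qa$experiment_id == ex, ]
      nat <- qe[qe$condition == "native", ]
      inh <- qe[qe$condition == "inhibited", ]
      if (nrow(inh) == 0L)
        stop(sprintf(paste0(
          "experiment '%s' of antibody '%s' lacks inhibited-condition ",
          "annotations; specificity cannot be computed"), ex, ab),
          call. = FALSE)
      streams <- unique(qe$sampling_stream)

      cls <- sort(unique(nat$compartment))
      one <- function(df, compartment) {
        s <- .streamFor(compartment, streams)
        df[df$compartment == compartment & df$sampling_stream == s, ]
      }
      res <- lapply(cls, function(cc) {
        n0 <- one(nat, cc); nm <- one(inh, cc)
        if (nrow(n0) != 1L || nrow(nm) != 1L)
          return(NULL)
        D0 <- n0$D; Dm <- nm$D
        if (n0$density_defined && nm$density_defined) {
          fr <- specificFraction(D0, Dm)
          basis <- "density"
        } else {
          ## no usable density (count-only compartment, or a zero length
          ## estimate): specific fraction from per-micrograph count rates,
          ## which share the sampling effort within an experiment
          fr <- specificFraction(n0$N / n0$n_micrographs,
                                 nm$N / nm$n_micrographs)
          basis <- "count_rate"
        }
        data.frame(antibody_id = ab, experiment_id = ex, compartment = cc,
                   D0 = D0, Dminus = Dm,
                   Dsp = if (is.na(D0) || is.na(Dm)) NA_real_
                         else specificDensity(D0, Dm),
                   Fsp_raw = fr$raw, Fsp_clamped = fr$clamped,
                   N0 = n0$N, fsp_basis = basis,
                   d0_zero = isTRUE(n0$density_defined) && D0 == 0)
      })
      res <- do.call(rbind, res)

      if (fspMode == "section_wide") {
        def <- res$fsp_basis == "density"
        pool <- function(df) {
          dd <- df[df$compartment %in% res$compartment[def] &
                     df$density_defined, ]
          sum(dd$N) / (sum(dd$L_nm) / 1000)
        }
        fw <- specificFraction(pool(nat), pool(inh))
        res$Fsp_raw <- fw$raw
        res$Fsp_clamped <- fw$clamped
      }

      f <- if (clamp) res$Fsp_clamped else res$Fsp_raw
      res$Ngsp <- f * res$N0
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-experiment summary of the specificity analysis
#'
#' Mean and SEM over replicate experiments, per antibody and compartment,
#' of a column of the [specificityAnalysis()] table (default: the specific
#' distribution `Ng(sp)`).
#'
#' @param specTable Output of [specificityAnalysis()].
#' @param statistic Column to summarise (`"Ngsp"`, `"Dsp"`, `"Fsp_raw"`, ...).
#' @return A data frame: antibody, compartment, mean, sem, n.
#' @export
aggregateSpecificity <- function(specTable, statistic = "Ngsp") {
  stopifnot(statistic %in% names(specTable))
  out <- do.call(rbind, lapply(split(specTable, specTable$antibody_id),
    function(df) {
      agg <- aggregateExperiments(
        data.frame(compartment = df$compartment, value = df[[statistic]]),
        statistic = statistic)
      agg$antibody_id <- df$antibody_id[1L]
      agg
    }))
  rownames(out) <- NULL
  out[, c("antibody_id", "compartment", "mean", "sem", "n", "statistic")]
}
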