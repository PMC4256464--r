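#' Bar chart of the specific gold distribution
#'
#' Plots per-compartment mean `Ng(sp)` (or any aggregated statistic) with
#' standard-error bars over replicate experiments.
#'
#' @param agg Output of [aggregateSpecificity()] for one antibody.
#' @param main Plot title.
#' @param ylab Y-axis label.
#' @return Invisibly, the bar midpoints.
#' @export
plotSpecificDistribution <- function(agg, main = unique(agg$antibody_id),
                                     ylab = "specific gold Ng(sp)") {
  stopifnot(length(unique(agg$antibody_id)) == 1L)
  o <- match(.membraneClasses(), agg$compartment)
  o <- o[!is.na(o)]
  agg <- agg[o, ]
  upper <- agg$mean + ifelse(is.na(agg$sem), 0, agg$sem)
  mids <- graphics::barplot(agg$mean, names.arg = agg$compartment,
                            ylim = c(min(0, agg$mean), max(upper) * 1.1),
                            las = 2, main = main, ylab = ylab)
  ok <- !is.na(agg$sem) & agg$sem > 0
  if (any(ok))
    graphics::arrows(mids[ok], agg$mean[ok] - agg$sem[ok], mids[ok],
                     agg$mean[ok] + agg$sem[ok], angle = 90, code = 3,
                     length = 0.05)
  invisible(mids)
}
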