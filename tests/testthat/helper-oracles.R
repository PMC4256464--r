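## Independent brute-force oracles used to validate the geometric kernels.

## All-pairs intersection oracle: enumerates every lattice line whose
## grid-frame coordinate range covers the polylines, then tests each
## (segment, line) pair by a sign product on the perpendicular coordinate.
## Endpoint on a line counts once; a collinear segment counts zero.
oracleCountIntersections <- function(profiles, grid) {
  d <- grid@spacingNm
  a <- grid@angleRad
  ca <- cos(-a); sa <- sin(-a)
  counts <- setNames(integer(4), compartmentClasses())
  for (p in profiles) {
    xy <- p$coords
    gx <- ca * xy[, 1] - sa * xy[, 2]
    gy <- sa * xy[, 1] + ca * xy[, 2]
    tot <- 0L
    for (fam in 1:2) {
      s <- if (fam == 1) gx else gy
      off <- grid@offset[fam]
      ks <- seq(floor((min(s) - off) / d) - 1, ceiling((max(s) - off) / d) + 1)
      lines <- off + ks * d
      for (i in seq_len(length(s) - 1)) {
        s1 <- s[i]; s2 <- s[i + 1]
        for (cc in lines) {
          if (s1 == s2) next              # parallel; collinear counts zero
          if ((s1 - cc) * (s2 - cc) <= 0) tot <- tot + 1L
        }
      }
    }
    counts[p$compartment] <- counts[p$compartment] + tot
  }
  counts
}

## Per-segment minimisation oracle for point-to-polyline distance, using
## 1-D numerical optimisation over each segment's parameter.
oracleDistanceToProfile <- function(point, polyline) {
  best <- Inf
  for (i in seq_len(nrow(polyline) - 1)) {
    a <- polyline[i, ]; b <- polyline[i + 1, ]
    f <- function(t) sqrt(sum((point - (a + t * (b - a)))^2))
    opt <- stats::optimize(f, c(0, 1), tol = 1e-12)
    best <- min(best, opt$objective, f(0), f(1))
  }
  best
}

## Random polyline set over a field, for property tests.
randomProfiles <- function(nProfiles, maxSegments, fieldNm = 2000) {
  cls <- compartmentClasses()
  lapply(seq_len(nProfiles), function(i) {
    n <- sample(2:(maxSegments + 1), 1)
    list(compartment = sample(cls, 1),
         coords = cbind(runif(n, 0, fieldNm), runif(n, 0, fieldNm)),
         closed = FALSE)
  })
}
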