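test_that("point-to-polyline distance matches closed-form cases", {
  seg <- rbind(c(-10, 0), c(10, 0))
  expect_equal(distanceToProfile(c(0, 5), seg), 5)
  expect_equal(distanceToProfile(c(20, 0), seg), 10)  # beyond the end
  expect_error(distanceToProfile(c(0, 0), rbind(c(1, 1))), "n >= 2")
})

test_that("distance computation matches the per-segment oracle", {
  set.seed(42)
  for (i in 1:500) {
    n <- sample(2:8, 1)
    poly <- cbind(runif(n, -100, 100), runif(n, -100, 100))
    pt <- runif(2, -150, 150)
    d <- distanceToProfile(pt, poly)
    expect_equal(d, oracleDistanceToProfile(pt, poly), tolerance = 1e-9)
  }
})

test_that("the membrane-association rule assigns and tie-breaks correctly", {
  prof <- list(
    list(compartment = "plasma_membrane",
         coords = rbind(c(-100, 0), c(100, 0)), closed = FALSE),
    list(compartment = "endo_membrane",
         coords = rbind(c(-50, 10), c(50, 10)), closed = FALSE),
    list(compartment = "mitosome",
         coords = rbind(c(-50, -10), c(50, -10)), closed = FALSE))

  ## within threshold of one profile
  a <- assignParticles(rbind(c(80, 5)), prof)
  expect_identical(unname(a$counts["plasma_membrane"]), 1L)
  ## outside every threshold
  b <- assignParticles(rbind(c(0, 200)), prof)
  expect_identical(b$unassigned, 1L)
  expect_identical(sum(b$counts), 0L)
  ## exactly 10 nm from both endo_membrane and mitosome (and plasma at 0? no:
  ## particle at (0, 20) is 10 from endo (y=10) and 20 from plasma):
  tie <- assignParticles(rbind(c(0, 0)), prof[2:3])
  expect_identical(unname(tie$counts["endo_membrane"]), 1L)  # lexicographic
  expect_identical(unname(tie$counts["mitosome"]), 0L)
  ## strict inequality at the boundary: exactly assoc_dist is NOT associated
  edge <- assignParticles(rbind(c(0, 15)), prof[1],
                          AssignmentParams(assocDistNm = 15))
  expect_identical(edge$unassigned, 1L)
  ## empty inputs
  z <- assignParticles(matrix(numeric(0), ncol = 2), prof)
  expect_identical(sum(z$counts) + z$unassigned, 0L)
})

test_that("assignment conserves particles and is monotone in threshold", {
  set.seed(7)
  for (i in 1:20) {
    prof <- randomProfiles(3, 6, fieldNm = 300)
    pts <- cbind(runif(40, 0, 300), runif(40, 0, 300))
    prev <- NULL
    for (th in c(5, 15, 40)) {
      a <- assignParticles(pts, prof, AssignmentParams(assocDistNm = th))
      expect_identical(sum(a$counts) + a$unassigned, nrow(pts))
      if (!is.null(prev)) expect_true(all(a$counts >= prev))
      prev <- a$counts
    }
  }
})

test_that("specific particles are recovered to their true compartment", {
  ## jitter far below the association threshold, no background
  mod <- LabellingModel(backgroundIntensity = 0, jitterSdNm = 2)
  hits <- 0; tot <- 0
  for (s in 1:15) {
    scene <- makeScene(SceneParams(seed = s))
    gold <- placeGold(scene, mod, "native", seed = 1000L + s)
    truth <- attr(gold, "origin")
    a <- assignParticles(`attr<-`(gold, "origin", NULL), profiles(scene))
    hits <- hits + sum(a$assignment == truth)
    tot <- tot + length(truth)
  }
  expect_gte(hits / tot, 0.99)
})

test_that("labelling density is N over L with ratio-of-sums pooling", {
  t1 <- labellingDensity(c(plasma_membrane = 20), c(plasma_membrane = 4000))
  expect_equal(t1$D, 5)
  t0 <- labellingDensity(c(plasma_membrane = 0), c(plasma_membrane = 4000))
  expect_equal(t0$D, 0)

  ## two micrographs pooled as total gold over total length, 10/4 = 2.5
  N <- rbind(c(plasma_membrane = 10), c(plasma_membrane = 0))
  L <- rbind(c(plasma_membrane = 1000), c(plasma_membrane = 3000))
  expect_equal(labellingDensity(N, L)$D, 2.5)

  ## zero length: density undefined, not zero
  tz <- labellingDensity(c(mitosome = 3), c(mitosome = 0))
  expect_true(is.na(tz$D))
  expect_false(tz$density_defined)

  expect_error(labellingDensity(c(a = -1), c(a = 10)), ">= 0")
})

test_that("sampling streams are tallied separately, never pooled", {
  scene <- makeScene(SceneParams(seed = 12L))
  mkann <- function(id, stream) MicrographAnnotation(
    micrographId = id, experimentId = "exp1", antibodyId = "ab",
    condition = "native", samplingStream = stream, fieldSizeNm = 3000,
    profiles = profiles(scene),
    particles = rbind(c(1500, 1500)))
  q <- quantifyAnnotations(list(mkann("m1", "sur"), mkann("m2", "sur"),
                                mkann("m3", "comprehensive")),
                           seed = 2L)
  expect_setequal(unique(q$sampling_stream), c("sur", "comprehensive"))
  expect_identical(unique(q$n_micrographs[q$sampling_stream == "sur"]), 2L)
  expect_identical(
    unique(q$n_micrographs[q$sampling_stream == "comprehensive"]), 1L)
})
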