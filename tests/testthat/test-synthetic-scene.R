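test_that("scene geometry honours its parameters", {
  ## absent compartment
  s0 <- makeScene(SceneParams(nMitosomes = 0L, seed = 3L))
  expect_identical(unname(trueLengthNm(s0)["mitosome"]), 0)

  ## degenerate axis range gives a circle of known circumference
  s1 <- makeScene(SceneParams(nMitosomes = 1L,
                              mitoAxisRangeNm = c(300, 300), seed = 4L))
  expect_equal(unname(trueLengthNm(s1)["mitosome"]), pi * 300,
               tolerance = 5e-3)

  ## structural invariants
  for (p in profiles(s1)) {
    expect_gte(nrow(p$coords), 2L)
    if (p$closed)
      expect_identical(p$coords[1, ], p$coords[nrow(p$coords), ])
  }
  ## true lengths equal the analytic polyline sums (validity enforces this)
  expect_true(validObject(s1, test = TRUE))
})

test_that("scene generation is deterministic in (params, seed)", {
  p <- SceneParams(seed = 77L)
  expect_identical(makeScene(p), makeScene(p))
  p2 <- p; p2@seed <- 78L
  expect_false(identical(profiles(makeScene(p))[[1]]$coords,
                         profiles(makeScene(p2))[[1]]$coords))
})

test_that("invalid scene parameters are rejected", {
  expect_error(SceneParams(mitoAxisRangeNm = c(300, 50)), "min exceeds max")
  expect_error(SceneParams(cellRadiusNm = -1), "positive")
  expect_error(SceneParams(endoLenRangeNm = c(0, 100)), "positive")
})

test_that("gold placement follows the Poisson labelling model", {
  scene <- makeScene(SceneParams(seed = 10L))
  Lpm <- trueLengthNm(scene)[["plasma_membrane"]] / 1000  # µm

  ## zero-rate process is empty
  empty <- placeGold(scene, LabellingModel(
    specificDensity = c(plasma_membrane = 0, nuclear_envelope = 0,
                        endo_membrane = 0, mitosome = 0),
    backgroundIntensity = 0), "native", seed = 1L)
  expect_identical(nrow(empty), 0L)

  expect_error(placeGold(scene, LabellingModel(), "blocked"), "arg")

  ## Monte-Carlo mean and dispersion against the Poisson expectation
  mod <- LabellingModel(
    specificDensity = c(plasma_membrane = 5, nuclear_envelope = 0,
                        endo_membrane = 0, mitosome = 0),
    backgroundIntensity = 0, jitterSdNm = 0, inhibitionEfficiency = 1)
  counts <- vapply(seq_len(2000), function(s)
    nrow(placeGold(scene, mod, "native", seed = s)), numeric(1))
  mu <- 5 * Lpm
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 2000))
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.2)

  ## complete inhibition leaves only background at beta x area
  mod2 <- LabellingModel(
    specificDensity = c(plasma_membrane = 5, nuclear_envelope = 0,
                        endo_membrane = 0, mitosome = 0),
    backgroundIntensity = 10, jitterSdNm = 0, inhibitionEfficiency = 1)
  area <- (scene@params@fieldSizeNm / 1000)^2
  cInh <- vapply(seq_len(2000), function(s) {
    g <- placeGold(scene, mod2, "inhibited", seed = s)
    expect_true(all(attr(g, "origin") == "background"))
    nrow(g)
  }, numeric(1))
  expect_lt(abs(mean(cInh) - 10 * area), 3 * sqrt(10 * area / 2000))
})

test_that("expected particle count is non-increasing in inhibition", {
  scene <- makeScene(SceneParams(seed = 21L))
  means <- vapply(c(0, 0.5, 1), function(rho) {
    mod <- LabellingModel(inhibitionEfficiency = rho,
                          backgroundIntensity = 5)
    mean(vapply(1:200, function(s)
      nrow(placeGold(scene, mod, "inhibited", seed = s)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
})

test_that("simulateStudy emits the protocol-scale paired design", {
  st <- simulateStudy(SceneParams(), LabellingModel(),
                      nExperiments = 3L, micrographsPerCondition = 3L,
                      seed = 5L)
  expect_length(st$annotations, 3 * 3 * 2)
  conds <- vapply(st$annotations, function(a) a@condition, character(1))
  expect_identical(sum(conds == "native"), 9L)
  expect_identical(sum(conds == "inhibited"), 9L)

  ## determinism of the whole study
  st2 <- simulateStudy(SceneParams(), LabellingModel(),
                       nExperiments = 3L, micrographsPerCondition = 3L,
                       seed = 5L)
  expect_identical(st$annotations, st2$annotations)
  expect_identical(st$truth, st2$truth)
})
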