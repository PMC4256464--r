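test_that("specific density subtracts the control and keeps negatives", {
  expect_equal(specificDensity(10, 2), 8)
  expect_equal(specificDensity(3, 3), 0)
  expect_equal(specificDensity(2, 3), -1)  # induction retained, not clipped
  expect_error(specificDensity(-1, 0), ">= 0")
})

test_that("specific fraction is D(sp)/D(0), clamped for distributions", {
  f <- specificFraction(10, 2)
  expect_equal(f$raw, 0.8)
  expect_equal(f$clamped, 0.8)
  g <- specificFraction(2, 3)
  expect_equal(g$raw, -0.5)
  expect_equal(g$clamped, 0)
  ## no raw label, no specific label
  z <- specificFraction(0, 5)
  expect_equal(z$raw, 0)
  expect_equal(z$clamped, 0)
})

test_that("the specific distribution multiplies fractions into counts", {
  Fsp <- c(plasma_membrane = 0.8, mitosome = 0)
  N0 <- c(plasma_membrane = 50, mitosome = 4)
  expect_equal(specificDistribution(Fsp, N0),
               c(plasma_membrane = 40, mitosome = 0))
  expect_equal(specificDistribution(c(a = 1, b = 1), c(a = 3, b = 7)),
               c(a = 3, b = 7))
  expect_equal(unname(specificDistribution(c(a = 0, b = 0), c(a = 3, b = 7))),
               c(0, 0))
  expect_error(specificDistribution(c(a = 1), c(b = 1)), "same compartment")
  ## bound under clamped fractions
  set.seed(3)
  for (i in 1:50) {
    fr <- specificFraction(runif(4, 0, 5), runif(4, 0, 5))
    n0 <- rpois(4, 20)
    names(fr$clamped) <- names(n0) <- letters[1:4]
    ng <- specificDistribution(fr$clamped, n0)
    expect_true(all(ng >= 0 & ng <= n0))
  }
})

test_that("replicate aggregation gives mean and SEM with n-1 variance", {
  a <- aggregateExperiments(c(1, 2, 3))
  expect_equal(a$mean, 2)
  expect_equal(a$sem, 1 / sqrt(3))
  expect_equal(aggregateExperiments(c(4, 4, 4))$sem, 0)
  expect_warning(one <- aggregateExperiments(c(5)), "fewer than 2")
  expect_true(is.na(one$sem))

  ## Monte-Carlo: mean SEM of normal triplets approaches sigma * c4 / sqrt(3)
  set.seed(11)
  sems <- replicate(1000, aggregateExperiments(rnorm(3, 5, 1))$sem)
  c4 <- sqrt(2 / 2) * gamma(3 / 2) / gamma(2 / 2)  # E[sd] factor at n = 3
  expect_lt(abs(mean(sems) - c4 / sqrt(3)), 3 * sd(sems) / sqrt(1000))
})

test_that("specificity analysis computes the per-experiment statistics", {
  sp <- specificityAnalysis(fakeQuantified())
  e1 <- sp[sp$experiment_id == "e1", ]
  pm <- e1[e1$compartment == "plasma_membrane", ]
  expect_equal(pm$D0, 10)
  expect_equal(pm$Dminus, 2)
  expect_equal(pm$Dsp, 8)
  expect_equal(pm$Fsp_raw, 0.8)
  expect_equal(pm$Ngsp, 80)

  ## identity D(sp) + D(-) = D(0), exactly, wherever densities exist
  d <- sp[!is.na(sp$Dsp), ]
  expect_identical(d$Dsp + d$Dminus, d$D0)

  ## negative specificity retained raw, clamped for the distribution
  ne <- e1[e1$compartment == "nuclear_envelope", ]
  expect_equal(ne$Dsp, -1)
  expect_lt(ne$Fsp_raw, 0)
  expect_equal(ne$Fsp_clamped, 0)
  expect_equal(ne$Ngsp, 0)

  ## count-only compartment uses per-micrograph count rates
  mi <- e1[e1$compartment == "mitosome", ]
  expect_identical(mi$fsp_basis, "count_rate")
  expect_equal(mi$Fsp_raw, 0.5)
  expect_equal(mi$Ngsp, 3)

  ## unclamped distribution on request
  spRaw <- specificityAnalysis(fakeQuantified(), clamp = FALSE)
  neRaw <- spRaw[spRaw$experiment_id == "e1" &
                   spRaw$compartment == "nuclear_envelope", ]
  expect_equal(neRaw$Ngsp, neRaw$Fsp_raw * neRaw$N0)
  expect_lt(neRaw$Ngsp, 0)
})

test_that("section-wide mode applies one fraction to all compartments", {
  sp <- specificityAnalysis(fakeQuantified(), fspMode = "section_wide")
  e1 <- sp[sp$experiment_id == "e1", ]
  expect_identical(length(unique(e1$Fsp_raw)), 1L)
  ## (110/15 - 35/15) / (110/15)
  expect_equal(unique(e1$Fsp_raw), 75 / 110)
})

test_that("missing inhibition controls abort the analysis", {
  q <- fakeQuantified()
  expect_error(specificityAnalysis(q[q$condition == "native", ]),
               "peptide control")
})

test_that("aggregation across experiments summarises per compartment", {
  agg <- aggregateSpecificity(specificityAnalysis(fakeQuantified()), "Dsp")
  ## mitosome D(sp) is undefined in every experiment: NA, no spurious number
  mito <- agg[agg$compartment == "mitosome", ]
  expect_true(is.na(mito$mean) && is.na(mito$sem))
  expect_identical(mito$n, 0L)
  pm <- agg[agg$compartment == "plasma_membrane", ]
  expect_equal(pm$mean, 8)       # both experiments give D(sp) = 8
  expect_equal(pm$sem, 0)
  expect_identical(pm$n, 2L)
})
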