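test_that("ellipsoid volume matches direct arithmetic and scales correctly", {
  expect_equal(ellipsoidVolume(1, 1, 1), pi / 6)
  expect_equal(ellipsoidVolume(2, 1, 1), pi / 3)
  expect_equal(ellipsoidVolume(1.2, 0.9, 0.8), 0.864 * pi / 6)
  expect_error(ellipsoidVolume(0, 1, 1), "domain")
  expect_error(ellipsoidVolume(1, -2, 1), "domain")
  # homogeneity of degree 3 under uniform scaling, monotone in each axis
  set.seed(41)
  for (i in 1:20) {
    dims <- runif(3, 0.2, 3)
    k <- runif(1, 0.5, 2)
    expect_equal(ellipsoidVolume(k * dims[1], k * dims[2], k * dims[3]),
                 k^3 * ellipsoidVolume(dims[1], dims[2], dims[3]))
    expect_gt(ellipsoidVolume(dims[1] * 1.1, dims[2], dims[3]),
              ellipsoidVolume(dims[1], dims[2], dims[3]))
  }
})

test_that("allometric residuals reproduce the normal-equations solution", {
  x <- c(10, 15, 22, 30, 41)
  fit <- allometricResiduals(x^1.17, x)
  expect_equal(fit@slope, 1.17, tolerance = 1e-10)
  expect_equal(fit@residuals, rep(0, 5), tolerance = 1e-10)

  set.seed(42)
  cov <- 10^runif(50, 0.5, 2)
  resp <- 10^(0.3 + 0.8 * log10(cov) + rnorm(50, 0, 0.1))
  fit2 <- allometricResiduals(resp, cov)
  # closed-form normal equations
  lx <- log10(cov); ly <- log10(resp)
  b <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  a <- mean(ly) - b * mean(lx)
  expect_equal(fit2@slope, b, tolerance = 1e-9)
  expect_equal(fit2@intercept, a, tolerance = 1e-9)
  expect_lt(abs(sum(fit2@residuals)), 1e-9)
  # residuals orthogonal to the log covariate
  expect_lt(abs(sum(fit2@residuals * lx)), 1e-8)
  # multiplying the response by a constant only shifts the intercept
  fit3 <- allometricResiduals(3.7 * resp, cov)
  expect_equal(fit3@residuals, fit2@residuals, tolerance = 1e-9)
  expect_equal(fit3@slope, fit2@slope, tolerance = 1e-9)

  expect_error(allometricResiduals(c(1, 2, 3), c(5, 5, 5)), "degenerate")
  expect_error(allometricResiduals(c(1, 2), c(1, 2)), "at least 3")
})

test_that("brain morphospace axes are centred pooled residuals", {
  rec <- generateMorphometricCohort(morphGenConfig(nPerGroup = 25, seed = 5))
  space <- buildBrainMorphospace(rec)
  expect_s4_class(space, "TraitSpace")
  expect_equal(nTraits(space), 3)
  expect_equal(nIndividuals(space), 150)
  expect_true(all(abs(colMeans(traitValues(space))) < 1e-9))
  expect_equal(traitNames(space),
               c("rel_brain_weight", "rel_telencephalon", "rel_optic_tectum"))
})

test_that("individuals with missing measurements are excluded and reported", {
  rec <- generateMorphometricCohort(morphGenConfig(nPerGroup = 10, seed = 6))
  rec$optic_tectum_height_mm[4] <- NA
  rec$brain_weight_mg[9] <- NA
  space <- buildBrainMorphospace(rec)
  expect_equal(nIndividuals(space), 58)
  ex <- exclusionReport(space)
  expect_setequal(ex$individual_id, rec$individual_id[c(4, 9)])
  expect_match(ex$reason[ex$individual_id == rec$individual_id[4]],
               "optic_tectum")
  expect_match(ex$reason[ex$individual_id == rec$individual_id[9]],
               "brain weight")
  # too few usable fish is an error
  few <- rec[1:4, ]
  few$brain_weight_mg[1:2] <- NA
  expect_error(buildBrainMorphospace(few), "insufficient")
})

test_that("injected group offsets are recovered by the morphospace axes", {
  offs <- c(F1_P1xP2 = 0.08, F2_P2xP1 = -0.06)
  cfg <- morphGenConfig(nPerGroup = 60, telencephalonOffsets = offs,
                        noiseSd = 0.03, seed = 7)
  space <- buildBrainMorphospace(generateMorphometricCohort(cfg))
  ax2 <- traitValues(space)[, "rel_telencephalon"]
  g <- groupLabels(space)
  # group-mean differences on axis 2 recover the injected offset difference
  est <- mean(ax2[g == "F1_P1xP2"]) - mean(ax2[g == "F2_P2xP1"])
  se <- sqrt(var(ax2[g == "F1_P1xP2"]) / 60 + var(ax2[g == "F2_P2xP1"]) / 60)
  expect_lt(abs(est - (0.08 - (-0.06))), 3 * se + 0.01)
  # unperturbed parental groups sit near each other
  est0 <- mean(ax2[g == "P1"]) - mean(ax2[g == "P2"])
  se0 <- sqrt(var(ax2[g == "P1"]) / 60 + var(ax2[g == "P2"]) / 60)
  expect_lt(abs(est0), 3 * se0 + 0.01)
})

test_that("cognitive space is log10 trials for dual-task passers only", {
  out <- rbind(
    data.frame(individual_id = "a", group = "P1", task = "associative",
               reached_criterion = TRUE, trials_to_criterion = 10),
    data.frame(individual_id = "a", group = "P1", task = "reversal",
               reached_criterion = TRUE, trials_to_criterion = 20),
    data.frame(individual_id = "b", group = "P2", task = "associative",
               reached_criterion = FALSE, trials_to_criterion = NA),
    data.frame(individual_id = "c", group = "P2", task = "associative",
               reached_criterion = TRUE, trials_to_criterion = 7),
    data.frame(individual_id = "c", group = "P2", task = "reversal",
               reached_criterion = TRUE, trials_to_criterion = 24))
  space <- buildCognitiveSpace(out)
  expect_equal(nIndividuals(space), 2)
  expect_equal(unname(traitValues(space)["a", ]), c(1, log10(20)))
  expect_equal(unname(traitValues(space)["c", 1]), log10(7))
  ex <- exclusionReport(space)
  expect_equal(ex$individual_id, "b")
  expect_match(ex$reason, "associative")
  expect_error(buildCognitiveSpace(out[3, ]), "insufficient")
})
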