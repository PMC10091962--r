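test_that("trait cohorts honour the additive null and are reproducible", {
  cfg <- traitGenConfig(d = 3, muP1 = c(0, 0, 0), muP2 = c(2, 0, 0),
                        nPerGroup = 400, seed = 31)
  coh <- generateTraitCohort(cfg)
  sp <- coh$space
  expect_equal(nIndividuals(sp), 2400)
  expect_true(all(table(groupLabels(sp)) == 400))
  expect_true(all(is.finite(traitValues(sp))))
  # F1 mean ~ midparent mean within 3 SE (F1 cov = I/2 here)
  f1 <- traitValues(sp)[groupLabels(sp) == "F1_P1xP2", ]
  se <- sqrt(0.5 / 400)
  expect_true(all(abs(colMeans(f1) - c(1, 0, 0)) < 3.5 * se))
  # determinism: identical configs give identical cohorts
  coh2 <- generateTraitCohort(traitGenConfig(d = 3, muP1 = c(0, 0, 0),
                                             muP2 = c(2, 0, 0),
                                             nPerGroup = 400, seed = 31))
  expect_identical(traitValues(sp), traitValues(coh2$space))
  expect_error(traitGenConfig(d = 2, sigmaP1 = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("injected mismatch is orthogonalised and exactly recorded", {
  cfg <- traitGenConfig(d = 3, muP1 = c(0, 0, 0), muP2 = c(2, 0, 0),
                        mismatch = c(0.4, 0.3, 0), nPerGroup = 50, seed = 32)
  coh <- generateTraitCohort(cfg)
  # the axis component of the configured vector is projected out
  expect_equal(coh$truth$mismatchMagnitude, 0.3)
  expect_equal(coh$truth$means$F1_P1xP2, c(1, 0.3, 0))
  # heterosis shifts F1 but not F2
  cfg2 <- traitGenConfig(d = 2, muP1 = c(0, 0), muP2 = c(2, 0),
                         heterosis = c(0, 0.5), nPerGroup = 10, seed = 1)
  t2 <- generateTraitCohort(cfg2)$truth
  expect_equal(t2$means$F1_P2xP1, c(1, 0.5))
  expect_equal(t2$means$F2_P2xP1, c(1, 0))
})

test_that("injected transgressives are displaced by the stated amount", {
  cfg <- traitGenConfig(d = 2, muP1 = c(0, 0), muP2 = c(1, 0),
                        nPerGroup = 40, transgressionFraction = 0.2,
                        transgressionShift = c(6, 6), seed = 33)
  coh <- generateTraitCohort(cfg)
  # 20% of each of the four hybrid groups
  expect_length(coh$truth$injectedIds, 4 * 8)
  inj <- traitValues(coh$space)[coh$truth$injectedIds, ]
  expect_true(all(rowSums(inj) > 4))  # visibly displaced
})

test_that("trial generator reflects its learning-curve parameters", {
  # strong learners: nearly every fish reaches criterion at trial 7-8
  fast <- generateTrialLog(trialGenConfig(nFish = 40, intercept = 0,
                                          slope = 10, seed = 34))
  out <- scoreTrialLog(fast)
  assoc <- out[out$task == "associative", ]
  expect_gt(mean(assoc$reached_criterion), 0.95)
  expect_lte(quantile(assoc$trials_to_criterion, 0.9, na.rm = TRUE), 8)
  # determinism
  again <- generateTrialLog(trialGenConfig(nFish = 40, intercept = 0,
                                           slope = 10, seed = 34))
  expect_identical(fast, again)
  # reversal sequences exist only for associative passers
  flat <- generateTrialLog(trialGenConfig(nFish = 60, intercept = 0,
                                          slope = 0, individualSd = 0,
                                          seed = 35))
  sc <- scoreTrialLog(flat)
  passers <- sc$individual_id[sc$task == "associative" &
                                sc$reached_criterion]
  expect_setequal(sc$individual_id[sc$task == "reversal"], passers)
})

test_that("chance-level learners match the run-occurrence DP oracle", {
  # a = b = 0, no individual variation: per-trial success is exactly 0.5
  pHit <- oracleRunProbability(40, 0.5, 7)
  hits <- numeric(20)
  for (r in 1:20) {
    log <- generateTrialLog(trialGenConfig(nFish = 50, intercept = 0,
                                           slope = 0, individualSd = 0,
                                           seed = 3000 + r))
    sc <- scoreTrialLog(log)
    hits[r] <- mean(sc$reached_criterion[sc$task == "associative"])
  }
  est <- mean(hits)
  se <- sqrt(pHit * (1 - pHit) / (20 * 50))
  expect_lt(abs(est - pHit), 3 * se)
})
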