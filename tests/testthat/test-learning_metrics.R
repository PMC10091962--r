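test_that("trials to criterion detects the first qualifying run", {
  r1 <- trialsToCriterion(rep(1, 7))
  expect_true(r1$reached_criterion)
  expect_equal(r1$trials_to_criterion, 7L)
  r2 <- trialsToCriterion(c(0, rep(1, 7)))
  expect_equal(r2$trials_to_criterion, 8L)
  # 40 alternating trials never reach criterion
  r3 <- trialsToCriterion(rep(c(1, 0), 20), maxTrials = 40)
  expect_false(r3$reached_criterion)
  expect_true(is.na(r3$trials_to_criterion))
  expect_equal(r3$censored_at, 40L)
  # a run completing after the censoring bound does not count
  late <- c(rep(0, 35), rep(1, 7))
  r4 <- trialsToCriterion(late, maxTrials = 40)
  expect_false(r4$reached_criterion)
  r5 <- trialsToCriterion(late, maxTrials = 60)
  expect_equal(r5$trials_to_criterion, 42L)
  expect_error(trialsToCriterion(c(1, 2, 1)), "0 or 1")
  expect_error(trialsToCriterion(integer(0)), "empty")
})

test_that("criterion detection matches the sliding-window oracle on fuzz", {
  set.seed(25)
  for (i in 1:300) {
    n <- sample(7:60, 1)
    p <- runif(1, 0.2, 0.9)
    s <- rbinom(n, 1, p)
    mx <- sample(c(40L, 60L), 1)
    got <- trialsToCriterion(s, maxTrials = mx)
    want <- oracleTrialsToCriterion(s, 7, mx)
    expect_equal(got$trials_to_criterion, want)
    expect_equal(got$reached_criterion, !is.na(want))
  }
})

test_that("first-run stability and prefix monotonicity hold", {
  set.seed(26)
  for (i in 1:50) {
    s <- rbinom(30, 1, 0.7)
    base <- trialsToCriterion(s, maxTrials = 60)
    # appending trials after a completed criterion run never changes the
    # first-run index
    longer <- trialsToCriterion(c(s, rbinom(10, 1, 0.5)), maxTrials = 60)
    if (base$reached_criterion)
      expect_equal(longer$trials_to_criterion, base$trials_to_criterion)
    # prepending k failures shifts the index by exactly k (while in bounds)
    if (base$reached_criterion && base$trials_to_criterion <= 50) {
      k <- sample(1:5, 1)
      shifted <- trialsToCriterion(c(rep(0, k), s), maxTrials = 60)
      if (base$trials_to_criterion + k <= 60)
        expect_equal(shifted$trials_to_criterion,
                     base$trials_to_criterion + k)
    }
  }
})

test_that("trial logs score per individual and task with task censoring", {
  log <- rbind(
    data.frame(individual_id = "a", group = "P1", sex = "F",
               task = "associative", trial_index = 1:10,
               correct = c(0, 0, 0, rep(1, 7))),
    data.frame(individual_id = "a", group = "P1", sex = "F",
               task = "reversal", trial_index = 1:50,
               correct = c(rep(c(0, 1), 21), rep(1, 8))),
    data.frame(individual_id = "b", group = "P2", sex = "F",
               task = "associative", trial_index = 1:40,
               correct = rep(c(1, 0), 20)))
  out <- scoreTrialLog(log)
  expect_equal(nrow(out), 3)
  a_assoc <- out[out$individual_id == "a" & out$task == "associative", ]
  expect_equal(a_assoc$trials_to_criterion, 10L)
  a_rev <- out[out$individual_id == "a" & out$task == "reversal", ]
  expect_equal(a_rev$censored_at, 60L)
  # alternating up to trial 42 (a correct), then 8 corrects: run completes
  # at trial 48
  expect_equal(a_rev$trials_to_criterion, 48L)
  expect_false(out[out$individual_id == "b", "reached_criterion"])
})

test_that("success rates reproduce printed-style percentages", {
  out <- rbind(
    data.frame(group = "F2_P1xP2", task = "associative",
               reached_criterion = rep(c(TRUE, FALSE), c(22, 3))),
    data.frame(group = "F2_P2xP1", task = "associative",
               reached_criterion = rep(c(TRUE, FALSE), c(19, 5))),
    data.frame(group = "P1", task = "reversal",
               reached_criterion = rep(TRUE, 22)))
  sr <- successRates(out, task = "associative")
  expect_equal(sr$percentage[sr$group == "F2_P1xP2"], 88)
  expect_equal(sr$percentage[sr$group == "F2_P2xP1"], 79)
  sr2 <- successRates(out, task = "reversal")
  expect_equal(sr2$percentage[sr2$group == "P1"], 100)
  # empty group: undefined percentage reported as NA, not zero
  sr3 <- successRates(out, groups = c("P1", "P2"), task = "reversal")
  expect_true(is.na(sr3$percentage[sr3$group == "P2"]))
  expect_error(successRates(out, groups = "Q9"), "unknown group")
})
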