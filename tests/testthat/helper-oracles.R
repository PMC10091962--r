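# Independent oracles used across the suite. Deliberately naive
# implementations (double loops, brute-force scans) kept separate from the
# package's own code paths.

# Gaussian product-kernel density by explicit double loop.
oracleKernelDensity <- function(points, h, x) {
  sapply(seq_len(nrow(x)), function(i) {
    mean(sapply(seq_len(nrow(points)), function(j) {
      prod(stats::dnorm((x[i, ] - points[j, ]) / h) / h)
    }))
  })
}

# First trial index completing a run of `runLength` consecutive correct
# choices, by sliding-window scan; NA if none within maxTrials.
oracleTrialsToCriterion <- function(correct, runLength = 7, maxTrials = 40) {
  horizon <- min(length(correct), maxTrials)
  if (horizon >= runLength) {
    for (t in runLength:horizon) {
      if (all(correct[(t - runLength + 1):t] == 1)) return(t)
    }
  }
  NA_integer_
}

# Linear interpolation between order statistics (the type-7 convention),
# written out by hand.
oracleQuantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  idx <- (n - 1) * p + 1
  lo <- floor(idx)
  hi <- ceiling(idx)
  s[lo] + (idx - lo) * (s[hi] - s[lo])
}

# P(a run of `runLength` successes occurs within nTrials Bernoulli(p)
# trials), by dynamic programming over the current streak length.
oracleRunProbability <- function(nTrials, p, runLength = 7) {
  state <- c(1, rep(0, runLength - 1))  # P(streak == 0..runLength-1), alive
  done <- 0
  for (t in seq_len(nTrials)) {
    nxt <- rep(0, runLength)
    for (s in seq_len(runLength)) {
      if (state[s] == 0) next
      if (s == runLength) done <- done + p * state[s]
      else nxt[s + 1] <- nxt[s + 1] + p * state[s]
      nxt[1] <- nxt[1] + (1 - p) * state[s]
    }
    state <- nxt
  }
  done
}

# Small complete trait table used by io tests.
makeToyTraitTable <- function(n = 3) {
  cfg <- morphGenConfig(nPerGroup = max(2, ceiling(n / 6)), seed = 404)
  rec <- generateMorphometricCohort(cfg)
  rec[seq_len(n), ]
}
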