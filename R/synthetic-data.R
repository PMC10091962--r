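#' @include AllClasses.R io-tables.R utils.R
NULL

.checkPD <- function(sigma, what) {
  sigma <- as.matrix(sigma)
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-10)))
    stop("config error: ", what, " must be symmetric")
  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (!ok) stop("config error: ", what, " must be positive definite")
  sigma
}

#' Configuration for a synthetic trait cohort
#'
#' Describes the generative model of a two-species crossing design directly
#' in trait space: parental species are distinct multivariate normals;
#' F1 hybrids are centred at the midparent mean plus an optional heterosis
#' shift and an optional mismatch displacement (the configured vector is
#' projected orthogonal to the true inter-parental axis, so the ground-truth
#' mismatch magnitude is exactly known) with covariance (Sigma1 + Sigma2)/4
#' (the variance of a midparent of independent parental draws); F2 hybrids
#' share the F1 mean without heterosis and have their covariance inflated by
#' a scalar segregation factor. A stated fraction of hybrid individuals can
#' additionally be displaced by a fixed vector to inject known transgression.
#'
#' @param d trait-space dimension.
#' @param muP1,muP2 parental mean d-vectors.
#' @param sigmaP1,sigmaP2 parental d x d positive-definite covariances.
#' @param nPerGroup individuals per crossing group (default 35, the study's
#'   brain-morphospace group scale).
#' @param heterosis d-vector added to the F1 mean (default zero).
#' @param mismatch d-vector whose component orthogonal to the inter-parental
#'   axis is added to the F1 and F2 means (default zero).
#' @param segregationFactor scalar >= 0 multiplying the F2 covariance
#'   (default 1: no excess segregation variance).
#' @param transgressionFraction fraction of each hybrid group displaced by
#'   `transgressionShift` (default 0).
#' @param transgressionShift displacement d-vector for injected
#'   transgressives.
#' @param seed integer RNG seed.
#' @return Validated config (list of class "TraitGenConfig").
#' @export
traitGenConfig <- function(d = 3,
                           muP1 = rep(0, d),
                           muP2 = c(1.5, rep(0, d - 1)),
                           sigmaP1 = diag(d),
                           sigmaP2 = diag(d),
                           nPerGroup = 35,
                           heterosis = rep(0, d),
                           mismatch = rep(0, d),
                           segregationFactor = 1,
                           transgressionFraction = 0,
                           transgressionShift = rep(0, d),
                           seed = 1) {
  stopifnot(d >= 1, nPerGroup >= 1, segregationFactor >= 0,
            transgressionFraction >= 0, transgressionFraction <= 1,
            length(muP1) == d, length(muP2) == d, length(heterosis) == d,
            length(mismatch) == d, length(transgressionShift) == d)
  cfg <- list(d = as.integer(d), muP1 = as.numeric(muP1),
              muP2 = as.numeric(muP2),
              sigmaP1 = .checkPD(sigmaP1, "sigmaP1"),
              sigmaP2 = .checkPD(sigmaP2, "sigmaP2"),
              nPerGroup = as.integer(nPerGroup),
              heterosis = as.numeric(heterosis),
              mismatch = as.numeric(mismatch),
              segregationFactor = segregationFactor,
              transgressionFraction = transgressionFraction,
              transgressionShift = as.numeric(transgressionShift),
              seed = as.integer(seed))
  class(cfg) <- "TraitGenConfig"
  cfg
}

#' Generate a synthetic trait cohort with known ground truth
#'
#' Draws all six crossing groups from the generative model described by
#' [traitGenConfig()] and returns the trait space together with the exact
#' ground truth (true group means, injected mismatch magnitude, indices of
#' injected transgressive individuals), so that pipeline estimates can be
#' checked against known values. A pure function of the config (including
#' its seed): identical configs yield identical cohorts.
#'
#' @param config a [traitGenConfig()].
#' @return List with `space` (a [TraitSpace-class]) and `truth` (list:
#'   per-group true means, mismatch magnitude, heterosis, injected ids).
#' @export
generateTraitCohort <- function(config) {
  stopifnot(inherits(config, "TraitGenConfig"))
  set.seed(config$seed)
  d <- config$d
  n <- config$nPerGroup
  axis <- config$muP2 - config$muP1
  axisLen <- sqrt(sum(axis^2))
  mPerp <- if (axisLen > 0) {
    u <- axis / axisLen
    config$mismatch - sum(config$mismatch * u) * u
  } else config$mismatch
  mid <- (config$muP1 + config$muP2) / 2
  sigF1 <- (config$sigmaP1 + config$sigmaP2) / 4
  means <- list(P1 = config$muP1, P2 = config$muP2,
                F1_P1xP2 = mid + config$heterosis + mPerp,
                F1_P2xP1 = mid + config$heterosis + mPerp,
                F2_P1xP2 = mid + mPerp,
                F2_P2xP1 = mid + mPerp)
  covs <- list(P1 = config$sigmaP1, P2 = config$sigmaP2,
               F1_P1xP2 = sigF1, F1_P2xP1 = sigF1,
               F2_P1xP2 = sigF1 * config$segregationFactor,
               F2_P2xP1 = sigF1 * config$segregationFactor)
  blocks <- list()
  groups <- character(0)
  injected <- character(0)
  for (g in crossingGroups()) {
    x <- MASS::mvrnorm(n, means[[g]], covs[[g]])
    x <- matrix(x, nrow = n)
    rownames(x) <- sprintf("%s_%03d", g, seq_len(n))
    if (g %in% .hybridGroups() && config$transgressionFraction > 0) {
      k <- round(config$transgressionFraction * n)
      if (k > 0) {
        idx <- sample.int(n, k)
        x[idx, ] <- sweep(x[idx, , drop = FALSE], 2,
                          config$transgressionShift, "+")
        injected <- c(injected, rownames(x)[idx])
      }
    }
    blocks[[g]] <- x
    groups <- c(groups, rep(g, n))
  }
  values <- do.call(rbind, blocks)
  colnames(values) <- sprintf("trait_%d", seq_len(d))
  truth <- list(means = means,
                mismatchMagnitude = sqrt(sum(mPerp^2)),
                heterosis = config$heterosis,
                segregationFactor = config$segregationFactor,
                transgressionFraction = config$transgressionFraction,
                injectedIds = injected,
                seed = config$seed)
  list(space = TraitSpace(values, groups, metadata = list(truth = truth)),
       truth = truth)
}

#' Configuration for a synthetic raw morphometric cohort
#'
#' Generative model for raw trait-table records (body length, brain weight,
#' six brain-region dimension triples) with known per-group offsets on the
#' log10 scale, so that the morphospace axes built by
#' [buildBrainMorphospace()] recover the injected offsets. Brain weight
#' follows a log-log allometry on body length (default slope 1.17, the
#' study-scale value); a latent brain-size variable scales the six region
#' volumes, with fixed realistic volume fractions (optic tectum dominating),
#' and group offsets perturb the focal regions multiplicatively.
#'
#' @param nPerGroup individuals per crossing group (default 20, pooled-sex
#'   study scale per group).
#' @param allometricSlope brain-weight vs body-length log-log slope.
#' @param brainWeightOffsets,telencephalonOffsets,opticTectumOffsets named
#'   numeric vectors of per-group log10 offsets (dex); missing groups get 0.
#' @param noiseSd residual SD on the log10 scale (default 0.03 dex).
#' @param seed integer RNG seed.
#' @return Validated config (list of class "MorphGenConfig").
#' @export
morphGenConfig <- function(nPerGroup = 20,
                           allometricSlope = 1.17,
                           brainWeightOffsets = c(),
                           telencephalonOffsets = c(),
                           opticTectumOffsets = c(),
                           noiseSd = 0.03,
                           seed = 1) {
  stopifnot(nPerGroup >= 2, noiseSd >= 0)
  fill <- function(off) {
    out <- stats::setNames(rep(0, 6), crossingGroups())
    out[names(off)] <- off
    out
  }
  cfg <- list(nPerGroup = as.integer(nPerGroup),
              allometricSlope = allometricSlope,
              brainWeightOffsets = fill(brainWeightOffsets),
              telencephalonOffsets = fill(telencephalonOffsets),
              opticTectumOffsets = fill(opticTectumOffsets),
              noiseSd = noiseSd, seed = as.integer(seed))
  class(cfg) <- "MorphGenConfig"
  cfg
}

# Fixed region volume fractions of total brain volume (realistic for a
# small poeciliid: optic tectum dominates, olfactory bulbs smallest).
.regionFractions <- c(telencephalon = 0.15, optic_tectum = 0.45,
                      cerebellum = 0.18, dorsal_medulla = 0.08,
                      hypothalamus = 0.09, olfactory_bulbs = 0.05)

# Dimension triple (L, W, H) with L:W:H = 1.25:1:0.8 whose ellipsoid
# volume equals v exactly (1.25 * 1 * 0.8 = 1).
.dimsFromVolume <- function(v) {
  u <- (6 * v / pi)^(1 / 3)
  cbind(length = 1.25 * u, width = u, height = 0.8 * u)
}

#' Generate a synthetic raw morphometric cohort
#'
#' Emits trait-table records (the [readTraitTable()] schema) for all six
#' crossing groups under the model of [morphGenConfig()]. Identical configs
#' yield identical cohorts.
#'
#' @param config a [morphGenConfig()].
#' @return data.frame of trait-table records.
#' @export
generateMorphometricCohort <- function(config) {
  stopifnot(inherits(config, "MorphGenConfig"))
  set.seed(config$seed)
  rows <- list()
  for (g in crossingGroups()) {
    n <- config$nPerGroup
    bodyLen <- 10^stats::rnorm(n, log10(22), 0.04)      # ~18-28 mm
    # brain weight (mg): allometry anchored at ~4.5 mg for a 22 mm fish
    lbw <- (log10(4.5) - config$allometricSlope * log10(22)) +
      config$allometricSlope * log10(bodyLen) +
      config$brainWeightOffsets[[g]] +
      stats::rnorm(n, 0, config$noiseSd)
    brainWeight <- 10^lbw
    # latent total brain volume (mm^3), tracking brain weight
    totalVol <- 10^(lbw + stats::rnorm(n, 0, 0.02))
    df <- data.frame(individual_id = sprintf("%s_%03d", g, seq_len(n)),
                     group = g, generation = .generationOf(g),
                     sex = rep(c("F", "M"), length.out = n),
                     body_length_mm = bodyLen,
                     brain_weight_mg = brainWeight,
                     stringsAsFactors = FALSE)
    for (r in .brainRegions) {
      off <- switch(r,
                    telencephalon = config$telencephalonOffsets[[g]],
                    optic_tectum = config$opticTectumOffsets[[g]],
                    0)
      vol <- .regionFractions[[r]] * totalVol *
        10^(off + stats::rnorm(n, 0, config$noiseSd))
      dims <- .dimsFromVolume(vol)
      df[[paste0(r, "_length_mm")]] <- dims[, "length"]
      df[[paste0(r, "_width_mm")]] <- dims[, "width"]
      df[[paste0(r, "_height_mm")]] <- dims[, "height"]
    }
    rows[[g]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration for a synthetic trial log
#'
#' Bernoulli learning curves: fish i succeeds at trial t with probability
#' logistic(a + u_i + b t), u_i ~ Normal(0, individualSd^2). Defaults are
#' chosen to emulate the observed female success profile (roughly 80-100%
#' of fish reaching a 7-trial criterion within the 40-trial associative
#' bound).
#'
#' @param nFish number of fish.
#' @param intercept a, baseline log-odds of a correct choice (default 0:
#'   chance performance at the start).
#' @param slope b, per-trial log-odds improvement (default 0.12).
#' @param individualSd SD of the individual random intercept (default 0.5).
#' @param maxTrials named censoring bounds per task
#'   (default c(associative = 40, reversal = 60)).
#' @param runLength criterion run length (default 7); generation stops at
#'   criterion or at the bound.
#' @param groups optional per-fish group labels (recycled; default "P1").
#' @param sex per-fish sex labels (recycled; default "F").
#' @param seed integer RNG seed.
#' @return Validated config (list of class "TrialGenConfig").
#' @export
trialGenConfig <- function(nFish = 25, intercept = 0, slope = 0.12,
                           individualSd = 0.5,
                           maxTrials = c(associative = 40L, reversal = 60L),
                           runLength = 7L, groups = "P1", sex = "F",
                           seed = 1) {
  stopifnot(nFish >= 1, individualSd >= 0, all(maxTrials >= runLength))
  cfg <- list(nFish = as.integer(nFish), intercept = intercept,
              slope = slope, individualSd = individualSd,
              maxTrials = maxTrials, runLength = as.integer(runLength),
              groups = rep_len(groups, nFish), sex = rep_len(sex, nFish),
              seed = as.integer(seed))
  class(cfg) <- "TrialGenConfig"
  cfg
}

# Simulate one fish's sequence for one task: stop at criterion or bound.
.simulateSequence <- function(a, b, u, maxTrials, runLength) {
  correct <- integer(0)
  run <- 0L
  for (t in seq_len(maxTrials)) {
    p <- stats::plogis(a + u + b * t)
    x <- stats::rbinom(1, 1, p)
    correct <- c(correct, x)
    run <- if (x == 1L) run + 1L else 0L
    if (run >= runLength) break
  }
  correct
}

#' Generate a synthetic trial log
#'
#' Simulates the two-task protocol under the model of [trialGenConfig()]:
#' every fish runs the associative task; only fish that reach the
#' associative criterion progress to the reversal task (as in the assay
#' protocol). Identical configs yield identical logs.
#'
#' @param config a [trialGenConfig()].
#' @return data.frame in the trial-log schema (individual_id, group, sex,
#'   task, trial_index, correct).
#' @export
generateTrialLog <- function(config) {
  stopifnot(inherits(config, "TrialGenConfig"))
  set.seed(config$seed)
  u <- stats::rnorm(config$nFish, 0, config$individualSd)
  rows <- list()
  for (i in seq_len(config$nFish)) {
    id <- sprintf("fish_%03d", i)
    assoc <- .simulateSequence(config$intercept, config$slope, u[i],
                               config$maxTrials[["associative"]],
                               config$runLength)
    rows[[paste0(id, "_a")]] <- data.frame(
      individual_id = id, group = config$groups[i], sex = config$sex[i],
      task = "associative", trial_index = seq_along(assoc),
      correct = assoc, stringsAsFactors = FALSE)
    reached <- sum(assoc[max(1, length(assoc) - config$runLength + 1):
                           length(assoc)]) == config$runLength &&
      length(assoc) <= config$maxTrials[["associative"]]
    if (reached) {
      rev <- .simulateSequence(config$intercept, config$slope, u[i],
                               config$maxTrials[["reversal"]],
                               config$runLength)
      rows[[paste0(id, "_r")]] <- data.frame(
        individual_id = id, group = config$groups[i], sex = config$sex[i],
        task = "reversal", trial_index = seq_along(rev),
        correct = rev, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
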