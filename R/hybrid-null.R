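#' @include kde.R geometry.R
NULL

#' Simulate one midparent-resampled hybrid population
#'
#' Each simulated hybrid is the coordinate-wise mean of one individual drawn
#' uniformly (with replacement) from each parental species — the midparent
#' value of a random parental pair. Uses the current RNG state; seed control
#' lives in [buildEnsemble()].
#'
#' @param p1,p2 parental [TraitSpace-class] objects or matrices (same d).
#' @param nSim number of simulated hybrids.
#' @return nSim x d numeric matrix of simulated hybrid phenotypes.
#' @export
simulateMidparentPopulation <- function(p1, p2, nSim) {
  m1 <- .asTraitMatrix(p1)
  m2 <- .asTraitMatrix(p2)
  if (!nrow(m1) || !nrow(m2)) stop("empty parental matrix")
  if (ncol(m1) != ncol(m2)) stop("parental matrices differ in dimension")
  if (nSim < 1) stop("nSim must be >= 1")
  i1 <- sample.int(nrow(m1), nSim, replace = TRUE)
  i2 <- sample.int(nrow(m2), nSim, replace = TRUE)
  out <- (m1[i1, , drop = FALSE] + m2[i2, , drop = FALSE]) / 2
  rownames(out) <- sprintf("sim_%03d", seq_len(nSim))
  out
}

#' Build a simulated-hybrid null ensemble
#'
#' Generates `reps` replicate midparent populations of `nSim` individuals
#' each and computes, per replicate, the mean phenotype, the 95% KDE
#' hypervolume (phenotypic dispersion), and the parental bias and phenotypic
#' mismatch of the replicate mean relative to the observed parental means.
#' Mirrors the study design defaults: 35 simulated hybrids for a 3-D brain
#' morphospace, 25 for the 2-D cognitive space, 100 repetitions. Replicate r
#' uses a sub-seed derived deterministically from `seed` and r, so single
#' replicates are individually reproducible.
#'
#' @param p1,p2 parental [TraitSpace-class] objects or matrices.
#' @param nSim simulated hybrids per replicate (study defaults: 35 brain,
#'   25 cognition).
#' @param reps number of replicate populations (default 100).
#' @param seed integer seed for the ensemble.
#' @param level contour level for per-replicate hypervolumes.
#' @param computeHypervolume set FALSE to skip the (grid-based) per-replicate
#'   hypervolume and only compute geometry; hypervolume column is then NA.
#' @param gridPoints grid resolution forwarded to [fitKde()].
#' @return A [SimulatedHybridEnsemble-class].
#' @examples
#' set.seed(1)
#' p1 <- matrix(rnorm(60), ncol = 2)
#' p2 <- matrix(rnorm(60, 1.5), ncol = 2)
#' ens <- buildEnsemble(p1, p2, nSim = 25, reps = 5, seed = 7)
#' head(ensembleStats(ens))
#' @export
buildEnsemble <- function(p1, p2, nSim = 35, reps = 100, seed = 1,
                          level = 0.95, computeHypervolume = TRUE,
                          gridPoints = NULL) {
  m1 <- .asTraitMatrix(p1)
  m2 <- .asTraitMatrix(p2)
  if (reps < 1) stop("reps must be >= 1")
  meanP1 <- colMeans(m1)
  meanP2 <- colMeans(m2)
  d <- ncol(m1)
  populations <- vector("list", reps)
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(.deriveSeed(seed, r))
    pop <- simulateMidparentPopulation(m1, m2, nSim)
    populations[[r]] <- pop
    mu <- colMeans(pop)
    hv <- NA_real_
    if (computeHypervolume) {
      kde <- tryCatch(
        fitKde(pop, level = level, gridPoints = gridPoints),
        error = function(e)
          stop("KDE failed in replicate ", r, ": ", conditionMessage(e)))
      hv <- hypervolume(kde)
    }
    geo <- hybridGeometry(mu, meanP1, meanP2)
    row <- c(list(rep = r),
             stats::setNames(as.list(mu), paste0("mean_", seq_len(d))),
             list(hypervolume = hv, parental_bias = geo@parentalBias,
                  phenotypic_mismatch = geo@phenotypicMismatch))
    rows[[r]] <- as.data.frame(row)
  }
  new("SimulatedHybridEnsemble", reps = as.integer(reps),
      nSim = as.integer(nSim), populations = populations,
      stats = do.call(rbind, rows), seed = as.integer(seed))
}

#' Empirical percentile of an observed statistic within a null ensemble
#'
#' Midrank convention for ties:
#' percentile = 100 (number below + half the number equal) / reps.
#' Also flags values outside the central 95% of the null distribution
#' (percentile below 2.5 or above 97.5).
#'
#' @param observed single observed statistic.
#' @param ensembleStat numeric vector of the per-replicate null statistics
#'   (at least 20 replicates for a meaningful percentile).
#' @return List with `percentile` in \[0, 100\] and logical
#'   `outsideCentral95`.
#' @examples
#' percentileOf(0.5, stats::runif(100))
#' @export
percentileOf <- function(observed, ensembleStat) {
  ensembleStat <- ensembleStat[!is.na(ensembleStat)]
  if (length(ensembleStat) < 1L) stop("empty ensemble statistic")
  if (length(ensembleStat) < 20L)
    warning("fewer than 20 replicates; percentile is coarse")
  pct <- 100 * (sum(ensembleStat < observed) +
                  0.5 * sum(ensembleStat == observed)) / length(ensembleStat)
  list(percentile = pct, outsideCentral95 = pct < 2.5 || pct > 97.5)
}
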