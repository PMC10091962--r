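#' @import methods
NULL

#' Crossing-group labels
#'
#' The six crossing groups of a reciprocal two-species design: the two
#' parental species (`P1`, `P2`) and the reciprocal F1 and F2 hybrid groups,
#' encoded mother-species x father-species.
#'
#' @return Character vector of the six valid group labels.
#' @export
crossingGroups <- function() {
  c("P1", "P2", "F1_P1xP2", "F1_P2xP1", "F2_P1xP2", "F2_P2xP1")
}

.hybridGroups <- function() setdiff(crossingGroups(), c("P1", "P2"))

.generationOf <- function(group) {
  ifelse(group %in% c("P1", "P2"), "parental",
         ifelse(grepl("^F1_", group), "F1", "F2"))
}

#' TraitSpace: a multivariate trait space with group labels
#'
#' An n x d numeric trait matrix (rows = individuals, columns = traits) with
#' a crossing-group label per individual. This is the common currency of the
#' dispersion, transgression and geometry analyses: d = 3 for the brain
#' morphospace, d = 2 for the cognitive space, but any d >= 1 is supported.
#'
#' @slot values numeric matrix, n x d, all entries finite; rownames are
#'   individual ids, colnames are trait names.
#' @slot group character vector of length n with the crossing-group label of
#'   each individual.
#' @slot metadata list of free-form provenance (e.g. an `exclusions`
#'   data.frame listing individuals dropped during construction).
#'
#' @seealso [buildBrainMorphospace()], [buildCognitiveSpace()], [fitKde()]
#' @export
setClass("TraitSpace",
  representation(values = "matrix", group = "character", metadata = "list"),
  prototype(metadata = list()))

setValidity("TraitSpace", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (nrow(v) < 1L) msg <- c(msg, "trait space needs at least one individual")
  if (is.numeric(v) && any(!is.finite(v)))
    msg <- c(msg, "all trait values must be finite")
  if (length(object@group) != nrow(v))
    msg <- c(msg, "'group' must have one label per row of 'values'")
  if (is.null(colnames(v))) msg <- c(msg, "'values' must have column names")
  if (length(msg)) msg else TRUE
})

#' Construct a TraitSpace
#'
#' @param values numeric matrix (n individuals x d traits). Row names are
#'   used as individual ids (generated if absent); column names are trait
#'   names.
#' @param group character vector (length n) of crossing-group labels.
#' @param metadata optional list of provenance information.
#' @return A [TraitSpace-class] object.
#' @examples
#' m <- cbind(a = rnorm(10), b = rnorm(10))
#' ts <- TraitSpace(m, group = rep(c("P1", "P2"), each = 5))
#' nIndividuals(ts)
#' @export
TraitSpace <- function(values, group, metadata = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("ind_%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("trait_%d", seq_len(ncol(values)))
  new("TraitSpace", values = values, group = as.character(group),
      metadata = metadata)
}

#' KdeModel: a fitted Gaussian product-kernel density estimate
#'
#' Holds the training points, the diagonal (per-axis) bandwidth, an optional
#' evaluation grid with densities, the density at each training point, and
#' the contour threshold: the density level at or above which the stated
#' fraction (default 95%) of the training individuals lie. The superlevel set
#' of the threshold is the group's dispersion region; its volume is the
#' phenotypic dispersion statistic and membership in it drives the
#' transgression classification.
#'
#' @slot points numeric matrix of training points (n x d).
#' @slot bandwidth numeric vector of d per-axis kernel standard deviations.
#' @slot level the contour level (fraction of individuals contained).
#' @slot threshold density value: the (1 - level) quantile of the training
#'   point densities.
#' @slot trainDensity density of the estimate at each training point.
#' @slot gridSpec list with one element per axis: `list(min, max, n)`; empty
#'   if no grid was evaluated.
#' @slot gridDensity array of densities at the grid points (dim = grid sizes);
#'   empty if no grid was evaluated.
#'
#' @seealso [fitKde()], [hypervolume()], [containsPoint()]
#' @export
setClass("KdeModel",
  representation(points = "matrix", bandwidth = "numeric", level = "numeric",
                 threshold = "numeric", trainDensity = "numeric",
                 gridSpec = "list", gridDensity = "array"),
  prototype(gridSpec = list(), gridDensity = array(numeric(0), dim = 0L)))

setValidity("KdeModel", function(object) {
  msg <- character()
  d <- ncol(object@points)
  if (length(object@bandwidth) != d)
    msg <- c(msg, "bandwidth must have one entry per trait axis")
  if (any(object@bandwidth <= 0)) msg <- c(msg, "bandwidth must be positive")
  if (length(object@level) != 1L || object@level <= 0 || object@level >= 1)
    msg <- c(msg, "level must be a single value in (0, 1)")
  if (length(object@threshold) != 1L || object@threshold < 0)
    msg <- c(msg, "threshold must be a single nonnegative density")
  if (length(object@trainDensity) != nrow(object@points))
    msg <- c(msg, "trainDensity must have one value per training point")
  if (any(object@trainDensity < 0)) msg <- c(msg, "densities must be >= 0")
  if (length(object@gridSpec) && length(object@gridSpec) != d)
    msg <- c(msg, "gridSpec must have one element per axis")
  if (length(msg)) msg else TRUE
})

#' TransgressionResult: per-individual transgression flags for one group
#'
#' An individual is transgressive when its trait combination falls outside
#' the 95% kernel density regions of both parental species.
#'
#' @slot group label of the hybrid group classified.
#' @slot flags data.frame with columns individual_id, transgressive (logical),
#'   density_p1, density_p2, threshold_p1, threshold_p2.
#' @slot n number of individuals classified.
#' @slot nTransgressive number flagged transgressive.
#' @slot proportion nTransgressive / n.
#'
#' @seealso [classifyTransgressive()]
#' @export
setClass("TransgressionResult",
  representation(group = "character", flags = "data.frame", n = "integer",
                 nTransgressive = "integer", proportion = "numeric"))

setValidity("TransgressionResult", function(object) {
  msg <- character()
  if (object@nTransgressive < 0L || object@nTransgressive > object@n)
    msg <- c(msg, "0 <= nTransgressive <= n must hold")
  if (object@n > 0L &&
      abs(object@proportion - object@nTransgressive / object@n) > 1e-12)
    msg <- c(msg, "proportion must equal nTransgressive / n")
  if (length(msg)) msg else TRUE
})

#' SimulatedHybridEnsemble: replicate midparent-resampled null populations
#'
#' Each replicate population is built by repeatedly drawing one individual
#' from each parental species and taking the coordinate-wise mean of the pair
#' (the midparent value). Per-replicate summary statistics (mean phenotype,
#' 95% KDE hypervolume, parental bias, phenotypic mismatch) form the null
#' distributions against which observed hybrid groups are ranked.
#'
#' @slot reps number of replicate populations.
#' @slot nSim simulated individuals per replicate.
#' @slot populations list of reps matrices (nSim x d).
#' @slot stats data.frame with one row per replicate: rep, mean_<trait> ...,
#'   hypervolume (NA if not computed), parental_bias, phenotypic_mismatch.
#' @slot seed integer seed the ensemble was generated from.
#'
#' @seealso [buildEnsemble()], [percentileOf()]
#' @export
setClass("SimulatedHybridEnsemble",
  representation(reps = "integer", nSim = "integer", populations = "list",
                 stats = "data.frame", seed = "integer"))

setValidity("SimulatedHybridEnsemble", function(object) {
  msg <- character()
  if (length(object@populations) != object@reps)
    msg <- c(msg, "one population per replicate required")
  if (nrow(object@stats) != object@reps)
    msg <- c(msg, "per-replicate stats must have reps rows")
  if (length(msg)) msg else TRUE
})

#' GeometryResult: position of a hybrid mean relative to the parental axis
#'
#' Decomposes the displacement of a hybrid group's mean phenotype from the
#' midpoint between the two parental means into a component along the
#' inter-parental axis (parental bias) and a perpendicular component
#' (phenotypic mismatch). The two satisfy
#' bias^2 + mismatch^2 = ||hybrid mean - midpoint||^2.
#'
#' @slot hybridMean d-vector: the hybrid group mean phenotype.
#' @slot midpoint d-vector: arithmetic mean of the two parental means.
#' @slot axisUnit unit d-vector pointing from the parent-1 mean toward the
#'   parent-2 mean.
#' @slot parentalBias nonnegative deviation along the axis (trait units).
#' @slot biasDirection one of "toward_P1", "toward_P2", "none".
#' @slot phenotypicMismatch nonnegative perpendicular deviation from the line
#'   through the parental means.
#' @slot interparentalDistance distance between the parental means.
#'
#' @seealso [hybridGeometry()], [parentalBias()], [phenotypicMismatch()]
#' @export
setClass("GeometryResult",
  representation(hybridMean = "numeric", midpoint = "numeric",
                 axisUnit = "numeric", parentalBias = "numeric",
                 biasDirection = "character", phenotypicMismatch = "numeric",
                 interparentalDistance = "numeric"))

setValidity("GeometryResult", function(object) {
  msg <- character()
  if (abs(sqrt(sum(object@axisUnit^2)) - 1) > 1e-9)
    msg <- c(msg, "axisUnit must have unit norm")
  gap <- object@parentalBias^2 + object@phenotypicMismatch^2 -
    sum((object@hybridMean - object@midpoint)^2)
  scale <- max(1, sum((object@hybridMean - object@midpoint)^2))
  if (abs(gap) / scale > 1e-9)
    msg <- c(msg, "bias^2 + mismatch^2 must equal squared midpoint deviation")
  if (!object@biasDirection %in% c("toward_P1", "toward_P2", "none"))
    msg <- c(msg, "invalid biasDirection")
  if (length(msg)) msg else TRUE
})
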