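#' @include AllClasses.R
NULL

#' Trait values of a TraitSpace
#' @param x a [TraitSpace-class].
#' @return The n x d numeric trait matrix.
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))

#' Group labels of a TraitSpace
#' @param x a [TraitSpace-class].
#' @return Character vector of crossing-group labels, one per individual.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Trait names of a TraitSpace
#' @param x a [TraitSpace-class].
#' @return Character vector of trait (column) names.
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' Number of individuals
#' @param x a [TraitSpace-class].
#' @return Integer count of rows (individuals).
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' Number of trait axes
#' @param x a [TraitSpace-class].
#' @return Integer dimension d of the trait space.
#' @export
setGeneric("nTraits", function(x) standardGeneric("nTraits"))

#' Exclusion report of a constructed trait space
#' @param x a [TraitSpace-class] built by [buildBrainMorphospace()] or
#'   [buildCognitiveSpace()].
#' @return data.frame (individual_id, reason) of excluded individuals; empty
#'   if none were excluded.
#' @export
setGeneric("exclusionReport", function(x) standardGeneric("exclusionReport"))

#' Evaluate a fitted kernel density at arbitrary points
#'
#' Density is evaluated by the exact kernel sum over the training points,
#' never by grid interpolation.
#'
#' @param model a [KdeModel-class].
#' @param x a d-vector or an m x d matrix of evaluation points.
#' @return Numeric vector of m density values.
#' @export
setGeneric("densityAt", function(model, x) standardGeneric("densityAt"))

#' Test membership in the KDE contour region
#'
#' A point belongs to the region when its exact kernel-sum density is at or
#' above the model's contour threshold (the level-fraction training-point
#' density quantile).
#'
#' @param model a [KdeModel-class].
#' @param x a d-vector or an m x d matrix of points.
#' @return Logical vector of m membership flags.
#' @export
setGeneric("containsPoint", function(model, x) standardGeneric("containsPoint"))

#' Hypervolume of the KDE contour region
#'
#' The phenotypic dispersion statistic: the volume, in product trait units,
#' of the superlevel set of the contour threshold, measured as the number of
#' grid cells whose center density reaches the threshold times the cell
#' volume.
#'
#' @param model a [KdeModel-class] fitted with an evaluation grid.
#' @param level optional contour level overriding the model's own (the
#'   threshold is recomputed from the training densities).
#' @return Volume (single number) in product trait units.
#' @export
setGeneric("hypervolume", function(model, level = NULL)
  standardGeneric("hypervolume"))

#' Per-axis bandwidth of a fitted KDE
#' @param model a [KdeModel-class].
#' @return Numeric vector of d kernel standard deviations.
#' @export
setGeneric("kdeBandwidth", function(model) standardGeneric("kdeBandwidth"))

#' Contour threshold of a fitted KDE
#' @param model a [KdeModel-class].
#' @return The density level bounding the contour region.
#' @export
setGeneric("densityThreshold", function(model)
  standardGeneric("densityThreshold"))

#' Per-individual flags of a transgression classification
#' @param x a [TransgressionResult-class].
#' @return data.frame of per-individual flags and densities.
#' @export
setGeneric("transgressionFlags", function(x)
  standardGeneric("transgressionFlags"))

#' Proportion of transgressive individuals
#' @param x a [TransgressionResult-class].
#' @return Fraction of classified individuals outside both parental regions.
#' @export
setGeneric("transgressionProportion", function(x)
  standardGeneric("transgressionProportion"))

#' Per-replicate statistics of a simulated-hybrid ensemble
#' @param x a [SimulatedHybridEnsemble-class].
#' @return data.frame with one row per replicate.
#' @export
setGeneric("ensembleStats", function(x) standardGeneric("ensembleStats"))

#' Replicate populations of a simulated-hybrid ensemble
#' @param x a [SimulatedHybridEnsemble-class].
#' @return List of nSim x d matrices, one per replicate.
#' @export
setGeneric("ensemblePopulations", function(x)
  standardGeneric("ensemblePopulations"))
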