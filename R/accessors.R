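#' @include AllGenerics.R
NULL

#' @describeIn TraitSpace trait matrix accessor
#' @param x a TraitSpace
#' @export
setMethod("traitValues", "TraitSpace", function(x) x@values)

#' @describeIn TraitSpace group-label accessor
#' @export
setMethod("groupLabels", "TraitSpace", function(x) x@group)

#' @describeIn TraitSpace trait-name accessor
#' @export
setMethod("traitNames", "TraitSpace", function(x) colnames(x@values))

#' @describeIn TraitSpace number of individuals
#' @export
setMethod("nIndividuals", "TraitSpace", function(x) nrow(x@values))

#' @describeIn TraitSpace number of trait axes
#' @export
setMethod("nTraits", "TraitSpace", function(x) ncol(x@values))

#' @describeIn TraitSpace exclusion report recorded at construction
#' @export
setMethod("exclusionReport", "TraitSpace", function(x) {
  ex <- x@metadata$exclusions
  if (is.null(ex))
    ex <- data.frame(individual_id = character(), reason = character())
  ex
})

#' Subset a TraitSpace by individuals
#'
#' @param x a [TraitSpace-class].
#' @param i row (individual) index: logical, integer or id character vector.
#' @param j unused.
#' @param ... unused.
#' @param drop unused (always FALSE).
#' @return A [TraitSpace-class] with the selected individuals.
#' @export
setMethod("[", "TraitSpace", function(x, i, j, ..., drop = FALSE) {
  TraitSpace(x@values[i, , drop = FALSE], x@group[i], x@metadata)
})

#' Extract the individuals of one or more crossing groups
#'
#' @param x a [TraitSpace-class].
#' @param groups character vector of group labels to keep.
#' @return A [TraitSpace-class] restricted to those groups.
#' @export
subsetByGroup <- function(x, groups) {
  stopifnot(is(x, "TraitSpace"))
  keep <- x@group %in% groups
  if (!any(keep))
    stop("no individuals in group(s): ", paste(groups, collapse = ", "))
  x[keep]
}

setMethod("show", "TraitSpace", function(object) {
  cat(sprintf("TraitSpace: %d individuals x %d traits\n",
              nrow(object@values), ncol(object@values)))
  cat("  traits:", paste(colnames(object@values), collapse = ", "), "\n")
  tab <- table(object@group)
  cat("  groups:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  ex <- object@metadata$exclusions
  if (!is.null(ex) && nrow(ex))
    cat(sprintf("  %d individual(s) excluded at construction\n", nrow(ex)))
})

#' @describeIn KdeModel per-axis bandwidth
#' @param model a KdeModel
#' @export
setMethod("kdeBandwidth", "KdeModel", function(model) model@bandwidth)

#' @describeIn KdeModel contour threshold density
#' @export
setMethod("densityThreshold", "KdeModel", function(model) model@threshold)

setMethod("show", "KdeModel", function(object) {
  d <- ncol(object@points)
  cat(sprintf("KdeModel: %d training points in %d-D\n",
              nrow(object@points), d))
  cat("  bandwidth:", paste(signif(object@bandwidth, 4), collapse = ", "),
      "\n")
  cat(sprintf("  %.0f%% contour threshold: %.6g\n",
              100 * object@level, object@threshold))
  if (length(object@gridSpec)) {
    ns <- vapply(object@gridSpec, function(g) g$n, numeric(1))
    cat("  grid:", paste(ns, collapse = " x "), "points\n")
  } else cat("  grid: none (membership-only model)\n")
})

#' @describeIn TransgressionResult per-individual flags
#' @param x a TransgressionResult
#' @export
setMethod("transgressionFlags", "TransgressionResult", function(x) x@flags)

#' @describeIn TransgressionResult proportion transgressive
#' @export
setMethod("transgressionProportion", "TransgressionResult",
          function(x) x@proportion)

setMethod("show", "TransgressionResult", function(object) {
  cat(sprintf(
    "TransgressionResult [%s]: %d / %d transgressive (%.1f%%)\n",
    object@group, object@nTransgressive, object@n, 100 * object@proportion))
})

#' @describeIn SimulatedHybridEnsemble per-replicate statistics
#' @param x a SimulatedHybridEnsemble
#' @export
setMethod("ensembleStats", "SimulatedHybridEnsemble", function(x) x@stats)

#' @describeIn SimulatedHybridEnsemble replicate populations
#' @export
setMethod("ensemblePopulations", "SimulatedHybridEnsemble",
          function(x) x@populations)

setMethod("show", "SimulatedHybridEnsemble", function(object) {
  cat(sprintf(
    "SimulatedHybridEnsemble: %d replicates x %d simulated hybrids (seed %d)\n",
    object@reps, object@nSim, object@seed))
  if (nrow(object@stats)) {
    cols <- intersect(c("hypervolume", "parental_bias", "phenotypic_mismatch"),
                      names(object@stats))
    for (cl in cols) {
      v <- object@stats[[cl]]
      if (all(is.na(v))) next
      cat(sprintf("  %s: median %.4g [%.4g, %.4g]\n", cl,
                  stats::median(v, na.rm = TRUE),
                  stats::quantile(v, 0.025, na.rm = TRUE, names = FALSE),
                  stats::quantile(v, 0.975, na.rm = TRUE, names = FALSE)))
    }
  }
})

setMethod("show", "GeometryResult", function(object) {
  cat("GeometryResult:\n")
  cat(sprintf("  parental bias: %.6g (%s)\n",
              object@parentalBias, object@biasDirection))
  cat(sprintf("  phenotypic mismatch: %.6g\n", object@phenotypicMismatch))
  cat(sprintf("  inter-parental distance: %.6g\n",
              object@interparentalDistance))
})
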