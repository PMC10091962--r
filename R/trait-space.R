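#' @include AllClasses.R io-tables.R
NULL

#' Ellipsoid volume of a brain region
#'
#' Estimates region volume from its three linear dimensions as
#' \eqn{V = (L \times W \times H)\,\pi/6}, the volume of the ellipsoid with
#' those principal diameters.
#'
#' @param length_mm,width_mm,height_mm strictly positive dimensions in mm
#'   (vectorized).
#' @return Volume(s) in mm^3.
#' @examples
#' ellipsoidVolume(1, 1, 1)  # pi/6, the unit sphere
#' @export
ellipsoidVolume <- function(length_mm, width_mm, height_mm) {
  v <- c(length_mm, width_mm, height_mm)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("domain error: all three dimensions must be positive and finite")
  length_mm * width_mm * height_mm * pi / 6
}

#' AllometricFit: a pooled log-log OLS allometry
#'
#' @slot slope,intercept coefficients of the OLS fit of log10(response) on
#'   log10(covariate), pooled across all groups.
#' @slot residuals per-individual residuals (the "relative" trait values).
#' @slot covariateName,responseName labels.
#' @export
setClass("AllometricFit",
  representation(slope = "numeric", intercept = "numeric",
                 residuals = "numeric", covariateName = "character",
                 responseName = "character"))

setValidity("AllometricFit", function(object) {
  if (length(object@residuals) &&
      abs(sum(object@residuals)) > 1e-6 * max(1, length(object@residuals)))
    "OLS residuals must sum to zero" else TRUE
})

setMethod("show", "AllometricFit", function(object) {
  cat(sprintf("AllometricFit: log10(%s) ~ log10(%s)\n",
              object@responseName, object@covariateName))
  cat(sprintf("  slope %.4f, intercept %.4f, n = %d\n",
              object@slope, object@intercept, length(object@residuals)))
})

#' Pooled allometric residuals on the log10 scale
#'
#' Fits log10(response) = a + b log10(covariate) by ordinary least squares,
#' pooled across all groups, and returns the per-individual residuals: the
#' "relative" trait (e.g. brain weight relative to body size) used as a
#' trait-space axis. Residuals sum to zero and are orthogonal to the
#' log-covariate by the OLS normal equations.
#'
#' @param response,covariate strictly positive numeric vectors of equal
#'   length (n >= 3).
#' @param responseName,covariateName labels stored in the fit.
#' @return An [AllometricFit-class].
#' @examples
#' x <- c(10, 20, 30, 40)
#' allometricResiduals(x^1.17, x)  # exact power law: slope 1.17, residuals 0
#' @export
allometricResiduals <- function(response, covariate,
                                responseName = "response",
                                covariateName = "covariate") {
  if (length(response) != length(covariate))
    stop("response and covariate must have the same length")
  if (length(response) < 3) stop("need at least 3 observations")
  if (any(!is.finite(response)) || any(!is.finite(covariate)) ||
      any(response <= 0) || any(covariate <= 0))
    stop("response and covariate must be positive and finite")
  lx <- log10(covariate)
  ly <- log10(response)
  if (stats::sd(lx) == 0)
    stop("degenerate fit: covariate has zero variance on the log scale")
  fit <- stats::lm(ly ~ lx)
  new("AllometricFit",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      residuals = unname(stats::resid(fit)),
      covariateName = covariateName, responseName = responseName)
}

# Region volumes (mm^3) per individual from the dimension columns; NA when
# any of the three dimensions is missing.
.regionVolumes <- function(records) {
  vols <- sapply(.brainRegions, function(r) {
    L <- records[[paste0(r, "_length_mm")]]
    W <- records[[paste0(r, "_width_mm")]]
    H <- records[[paste0(r, "_height_mm")]]
    ifelse(is.na(L) | is.na(W) | is.na(H), NA_real_, L * W * H * pi / 6)
  })
  matrix(vols, nrow = nrow(records),
         dimnames = list(NULL, .brainRegions))
}

#' Build the 3-D brain morphospace
#'
#' Constructs the brain trait space with sexes pooled:
#' axis 1 is the pooled OLS residual of log10 brain weight on log10 body
#' length (relative brain size); axes 2 and 3 are the residuals of log10
#' telencephalon and log10 optic-tectum ellipsoid volume on log10 brain
#' remainder volume, where total brain volume is the sum of the six region
#' ellipsoid volumes and the remainder excludes the focal region.
#' Individuals missing any required measurement are excluded and listed in
#' the exclusion report.
#'
#' @param records trait-table data.frame ([readTraitTable()] /
#'   [generateMorphometricCohort()]).
#' @return A [TraitSpace-class] (d = 3) whose metadata carries the exclusion
#'   report ([exclusionReport()]).
#' @export
buildBrainMorphospace <- function(records) {
  validateTraitRecords(records)
  vols <- .regionVolumes(records)
  total <- rowSums(vols)
  reason <- rep(NA_character_, nrow(records))
  need <- is.na(records$brain_weight_mg)
  reason[need & is.na(reason)] <- "missing brain weight"
  miss <- is.na(total)
  if (any(miss & is.na(reason))) {
    for (i in which(miss & is.na(reason))) {
      mr <- .brainRegions[is.na(vols[i, ])][1]
      reason[i] <- paste0("missing ", mr, " dimensions")
    }
  }
  usable <- is.na(reason)
  if (sum(usable) < 3)
    stop("insufficient data: fewer than 3 individuals with complete ",
         "brain measurements")
  r <- records[usable, ]
  v <- vols[usable, , drop = FALSE]
  tot <- total[usable]
  ax1 <- allometricResiduals(r$brain_weight_mg, r$body_length_mm,
                             "brain_weight_mg", "body_length_mm")
  remTel <- tot - v[, "telencephalon"]
  remOT <- tot - v[, "optic_tectum"]
  ax2 <- allometricResiduals(v[, "telencephalon"], remTel,
                             "telencephalon_volume", "brain_remainder")
  ax3 <- allometricResiduals(v[, "optic_tectum"], remOT,
                             "optic_tectum_volume", "brain_remainder")
  m <- cbind(rel_brain_weight = ax1@residuals,
             rel_telencephalon = ax2@residuals,
             rel_optic_tectum = ax3@residuals)
  rownames(m) <- r$individual_id
  exclusions <- data.frame(individual_id = records$individual_id[!usable],
                           reason = reason[!usable],
                           stringsAsFactors = FALSE)
  TraitSpace(m, group = r$group,
             metadata = list(exclusions = exclusions,
                             fits = list(brain_weight = ax1,
                                         telencephalon = ax2,
                                         optic_tectum = ax3)))
}

#' Build the 2-D cognitive space
#'
#' Axis 1 is log10 trials-to-criterion in the associative task, axis 2 in
#' the reversal task. Only individuals that reached criterion in *both*
#' tasks enter the space; the rest are excluded with a reason (a fish that
#' fails the associative task never runs the reversal).
#'
#' @param outcomes data.frame from [scoreTrialLog()] with columns
#'   individual_id, task, reached_criterion, trials_to_criterion and
#'   optionally group.
#' @return A [TraitSpace-class] (d = 2) with an exclusion report.
#' @export
buildCognitiveSpace <- function(outcomes) {
  stopifnot(all(c("individual_id", "task", "reached_criterion",
                  "trials_to_criterion") %in% names(outcomes)))
  ids <- unique(outcomes$individual_id)
  rows <- list()
  excl <- list()
  for (id in ids) {
    sub <- outcomes[outcomes$individual_id == id, ]
    al <- sub[sub$task == "associative", ]
    rl <- sub[sub$task == "reversal", ]
    if (!nrow(al) || !al$reached_criterion[1]) {
      excl[[id]] <- "did not reach associative criterion"
      next
    }
    if (!nrow(rl) || !rl$reached_criterion[1]) {
      excl[[id]] <- "did not reach reversal criterion"
      next
    }
    rows[[id]] <- data.frame(
      individual_id = id,
      group = if ("group" %in% names(sub)) sub$group[1] else "P1",
      log_trials_associative = log10(al$trials_to_criterion[1]),
      log_trials_reversal = log10(rl$trials_to_criterion[1]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("insufficient data: no individual reached criterion in both tasks")
  df <- do.call(rbind, rows)
  m <- as.matrix(df[, c("log_trials_associative", "log_trials_reversal")])
  rownames(m) <- df$individual_id
  exclusions <- data.frame(individual_id = names(excl),
                           reason = unlist(excl, use.names = FALSE),
                           stringsAsFactors = FALSE)
  if (!nrow(exclusions))
    exclusions <- data.frame(individual_id = character(),
                             reason = character())
  TraitSpace(m, group = df$group,
             metadata = list(exclusions = exclusions))
}

#' Write an exclusion report to CSV
#'
#' @param x a [TraitSpace-class] with an exclusion report.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeExclusionReport <- function(x, path) {
  utils::write.csv(exclusionReport(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
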