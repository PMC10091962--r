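#' @include AllClasses.R
NULL

.axisGeometry <- function(hybridMean, meanP1, meanP2) {
  hybridMean <- as.numeric(hybridMean)
  meanP1 <- as.numeric(meanP1)
  meanP2 <- as.numeric(meanP2)
  if (length(meanP1) != length(hybridMean) ||
      length(meanP2) != length(hybridMean))
    stop("dimension mismatch between hybrid and parental means")
  if (any(!is.finite(c(hybridMean, meanP1, meanP2))))
    stop("means must be finite")
  axis <- meanP2 - meanP1
  len <- sqrt(sum(axis^2))
  if (len == 0)
    stop("undefined axis: parental means coincide")
  u <- axis / len
  mid <- (meanP1 + meanP2) / 2
  dev <- hybridMean - mid
  proj <- sum(dev * u)
  perp <- dev - proj * u
  list(mid = mid, u = u, len = len, proj = proj,
       mismatch = sqrt(sum(perp^2)))
}

#' Parental bias of a hybrid mean phenotype
#'
#' Deviation of the hybrid group's mean phenotype from the midpoint of the
#' two parental means, measured along the inter-parental axis:
#' \eqn{|(\bar h - m) \cdot u|} with \eqn{u} the unit vector from the
#' parent-1 mean toward the parent-2 mean and \eqn{m} the parental midpoint.
#' The direction records which parent the mean is displaced toward
#' ("none" when the projection is below 1e-12).
#'
#' @param hybridMean d-vector: hybrid group mean phenotype.
#' @param meanP1,meanP2 d-vectors: parental mean phenotypes (must differ).
#' @return List with elements `bias` (nonnegative, trait units) and
#'   `direction` ("toward_P1", "toward_P2" or "none").
#' @examples
#' parentalBias(c(0, 0), c(-1, 0), c(1, 0))   # at the midpoint: bias 0
#' parentalBias(c(-1, 0), c(-1, 0), c(1, 0))  # at parent 1: bias 1
#' @export
parentalBias <- function(hybridMean, meanP1, meanP2) {
  g <- .axisGeometry(hybridMean, meanP1, meanP2)
  direction <- if (abs(g$proj) < 1e-12) "none"
               else if (g$proj > 0) "toward_P2" else "toward_P1"
  list(bias = abs(g$proj), direction = direction)
}

#' Phenotypic mismatch of a hybrid mean phenotype
#'
#' Perpendicular distance of the hybrid group's mean phenotype from the
#' (infinite) line through the two parental mean phenotypes: the norm of the
#' component of \eqn{\bar h - m} orthogonal to the inter-parental axis.
#'
#' @inheritParams parentalBias
#' @return Nonnegative mismatch in trait units.
#' @examples
#' phenotypicMismatch(c(1, 1), c(0, 0), c(2, 0))  # 1
#' @export
phenotypicMismatch <- function(hybridMean, meanP1, meanP2) {
  .axisGeometry(hybridMean, meanP1, meanP2)$mismatch
}

#' Full axis geometry of a hybrid mean phenotype
#'
#' Computes the parental-bias / phenotypic-mismatch decomposition of the
#' hybrid group's mean relative to the inter-parental axis. The two
#' components satisfy bias^2 + mismatch^2 = ||hybrid mean - midpoint||^2
#' exactly (to floating-point tolerance).
#'
#' @inheritParams parentalBias
#' @return A [GeometryResult-class].
#' @export
hybridGeometry <- function(hybridMean, meanP1, meanP2) {
  g <- .axisGeometry(hybridMean, meanP1, meanP2)
  pb <- parentalBias(hybridMean, meanP1, meanP2)
  new("GeometryResult",
      hybridMean = as.numeric(hybridMean), midpoint = g$mid, axisUnit = g$u,
      parentalBias = pb$bias, biasDirection = pb$direction,
      phenotypicMismatch = g$mismatch, interparentalDistance = g$len)
}
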