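#' @include AllClasses.R AllGenerics.R
NULL

# Exact Gaussian product-kernel density of `points` (n x d) with per-axis
# bandwidth `h` evaluated at the rows of `x` (m x d). O(m * n * d), computed
# on the log scale for numerical range.
.kernelDensity <- function(points, h, x) {
  n <- nrow(points)
  d <- ncol(points)
  logk <- matrix(0, nrow(x), n)
  for (j in seq_len(d)) {
    logk <- logk +
      stats::dnorm(outer(x[, j], points[, j], "-") / h[j], log = TRUE) -
      log(h[j])
  }
  rowSums(exp(logk)) / n
}

#' Select a diagonal KDE bandwidth by cross-validated grid search
#'
#' The bandwidth on axis j is \eqn{h_j = c \sigma_j n^{-1/(d+4)}}, where
#' \eqn{\sigma_j} is the per-axis sample standard deviation and the single
#' scale factor c is chosen from a fixed logarithmic grid of 25 values in
#' \[0.25, 4\] by minimising the least-squares (unbiased) cross-validation
#' criterion
#' \deqn{LSCV(c) = \int \hat f^2 - \frac{2}{n}\sum_i \hat f_{-i}(X_i),}
#' both terms of which have closed forms for the Gaussian product kernel.
#' The search is deterministic for fixed input; ties resolve to the smallest
#' factor.
#'
#' @param points n x d numeric matrix (or [TraitSpace-class]) of trait values.
#' @param cGrid scale-factor grid searched over; default 25 log-spaced values
#'   in \[0.25, 4\].
#' @return Numeric vector of d per-axis bandwidths (kernel SDs).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), ncol = 2)
#' selectBandwidth(x)
#' @export
selectBandwidth <- function(points,
                            cGrid = exp(seq(log(0.25), log(4),
                                            length.out = 25))) {
  p <- .asTraitMatrix(points)
  .checkFiniteMatrix(p, "points")
  n <- nrow(p)
  d <- ncol(p)
  if (n < d + 2L)
    stop("insufficient data: need at least d + 2 = ", d + 2L, " points")
  sds <- apply(p, 2, stats::sd)
  if (any(sds <= 0)) {
    bad <- which(sds <= 0)
    stop("degenerate axis with zero variance: column ",
         paste(bad, collapse = ", "))
  }
  h0 <- sds * n^(-1 / (d + 4))
  # Squared Mahalanobis-style distances under the pilot bandwidth h0:
  # S_ij = sum_k (x_ik - x_jk)^2 / h0_k^2.
  scaled <- sweep(p, 2, h0, "/")
  S <- as.matrix(stats::dist(scaled))^2
  ph0 <- prod(h0)
  norm0 <- (2 * pi)^(-d / 2)
  crit <- vapply(cGrid, function(cc) {
    # integral of fhat^2: convolution kernel has per-axis SD sqrt(2) c h0_k
    t1 <- sum(exp(-S / (4 * cc^2))) * norm0 /
      (n^2 * 2^(d / 2) * cc^d * ph0)
    # leave-one-out sum: subtract the n diagonal (zero-distance) terms
    t2 <- (sum(exp(-S / (2 * cc^2))) - n) * norm0 / (cc^d * ph0) *
      2 / (n * (n - 1))
    t1 - t2
  }, numeric(1))
  cStar <- cGrid[which.min(crit)]
  stats::setNames(cStar * h0, colnames(p))
}

# Default per-axis grid: data range padded by `pad` bandwidths.
.defaultGridSpec <- function(p, h, gridPoints, pad) {
  lapply(seq_len(ncol(p)), function(j) {
    list(min = min(p[, j]) - pad * h[j],
         max = max(p[, j]) + pad * h[j],
         n = gridPoints)
  })
}

.gridAxes <- function(gridSpec) {
  lapply(gridSpec, function(g) seq(g$min, g$max, length.out = g$n))
}

.cellVolume <- function(gridSpec) {
  prod(vapply(gridSpec, function(g) (g$max - g$min) / (g$n - 1), numeric(1)))
}

# Density over a rectangular grid, exploiting kernel separability:
# d = 1 -> row sums, d = 2 -> one matrix product, d >= 3 -> accumulate the
# rank-1 tensor contribution of each training point.
.gridDensity <- function(points, h, gridSpec) {
  axes <- .gridAxes(gridSpec)
  n <- nrow(points)
  d <- ncol(points)
  A <- lapply(seq_len(d), function(j)
    stats::dnorm(outer(axes[[j]], points[, j], "-") / h[j]) / h[j])
  if (d == 1L) {
    dens <- rowSums(A[[1]]) / n
    return(array(dens, dim = length(axes[[1]])))
  }
  if (d == 2L)
    return(tcrossprod(A[[1]], A[[2]]) / n)
  dims <- vapply(axes, length, integer(1))
  dens <- array(0, dim = dims)
  for (i in seq_len(n)) {
    contrib <- A[[1]][, i]
    for (j in 2:d) contrib <- outer(contrib, A[[j]][, i])
    dens <- dens + contrib
  }
  dens / n
}

#' Fit a Gaussian product-kernel density estimate
#'
#' Fits the KDE
#' \deqn{\hat f(x) = \frac{1}{n}\sum_{i=1}^n \prod_{j=1}^d
#'   \frac{1}{h_j}\phi\!\left(\frac{x_j - p_{ij}}{h_j}\right)}
#' to a group's trait cloud, evaluates it on a rectangular grid (for
#' hypervolume measurement) and at the training points, and sets the contour
#' threshold to the (1 - level) quantile of the training-point densities, so
#' the contour region contains the stated fraction of the group's
#' individuals.
#'
#' @param points n x d matrix or [TraitSpace-class].
#' @param bandwidth optional d-vector of per-axis kernel SDs; default is
#'   [selectBandwidth()].
#' @param gridSpec optional list of d `list(min, max, n)` axis
#'   specifications. The grid must cover the data range; the default pads the
#'   range by `pad` bandwidths per axis. Supplying a grid that fails to cover
#'   the data is an error.
#' @param level contour level: fraction of individuals the contour region
#'   must contain (default 0.95).
#' @param gridPoints points per grid axis for the default grid; default 151
#'   for d <= 2, 101 for d >= 3.
#' @param pad default-grid padding in bandwidths (default 4, which keeps the
#'   numerically integrated grid density within \[0.98, 1.02\]).
#' @param computeGrid set FALSE to skip grid evaluation (membership and
#'   threshold still work; [hypervolume()] does not).
#' @return A [KdeModel-class].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), ncol = 2)
#' m <- fitKde(x)
#' hypervolume(m)
#' @export
fitKde <- function(points, bandwidth = NULL, gridSpec = NULL, level = 0.95,
                   gridPoints = NULL, pad = 4, computeGrid = TRUE) {
  p <- .asTraitMatrix(points)
  .checkFiniteMatrix(p, "points")
  d <- ncol(p)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (is.null(bandwidth)) bandwidth <- selectBandwidth(p)
  if (length(bandwidth) == 1L && d > 1L) bandwidth <- rep(bandwidth, d)
  if (length(bandwidth) != d || any(bandwidth <= 0))
    stop("bandwidth must be ", d, " positive values")
  if (is.null(gridPoints)) gridPoints <- if (d <= 2L) 151L else 101L
  if (is.null(gridSpec)) {
    gridSpec <- .defaultGridSpec(p, bandwidth, gridPoints, pad)
  } else {
    if (length(gridSpec) != d) stop("gridSpec must have one element per axis")
    for (j in seq_len(d)) {
      g <- gridSpec[[j]]
      if (g$min > min(p[, j]) || g$max < max(p[, j]))
        stop("coverage error: grid axis ", j, " does not cover the data")
    }
  }
  trainDensity <- .kernelDensity(p, bandwidth, p)
  threshold <- stats::quantile(trainDensity, probs = 1 - level, type = 7,
                               names = FALSE)
  gridDensity <- if (computeGrid) {
    gd <- .gridDensity(p, bandwidth, gridSpec)
    array(gd, dim = if (is.null(dim(gd))) length(gd) else dim(gd))
  } else {
    array(numeric(0), dim = 0L)
  }
  new("KdeModel", points = p, bandwidth = unname(bandwidth), level = level,
      threshold = threshold, trainDensity = trainDensity,
      gridSpec = if (computeGrid) gridSpec else list(),
      gridDensity = gridDensity)
}

#' Contour threshold at an arbitrary level
#'
#' The density value such that the stated fraction of the model's own
#' training individuals have estimated density at or above it: the
#' (1 - level) empirical quantile, with linear interpolation between order
#' statistics, of the densities at the training points.
#'
#' @param model a [KdeModel-class].
#' @param level fraction of individuals the contour region must contain.
#' @return The density threshold (single number).
#' @export
contourThreshold <- function(model, level = 0.95) {
  stopifnot(is(model, "KdeModel"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  stats::quantile(model@trainDensity, probs = 1 - level, type = 7,
                  names = FALSE)
}

#' @describeIn densityAt exact kernel-sum evaluation
#' @export
setMethod("densityAt", "KdeModel", function(model, x) {
  x <- .asRowMatrix(x, ncol(model@points))
  .kernelDensity(model@points, model@bandwidth, x)
})

#' @describeIn containsPoint membership by exact kernel sum vs threshold
#' @export
setMethod("containsPoint", "KdeModel", function(model, x) {
  densityAt(model, x) >= model@threshold
})

#' @describeIn hypervolume grid-cell counting over the evaluation grid
#' @export
setMethod("hypervolume", "KdeModel", function(model, level = NULL) {
  if (!length(model@gridSpec))
    stop("model was fitted without a grid; refit with computeGrid = TRUE")
  thr <- if (is.null(level)) model@threshold else contourThreshold(model, level)
  nCells <- sum(model@gridDensity >= thr)
  if (nCells == 0L) {
    warning("empty superlevel set; returning zero volume")
    return(0)
  }
  nCells * .cellVolume(model@gridSpec)
})

#' Numerically integrated grid density
#'
#' Riemann sum of the grid densities times the cell volume; close to 1 for a
#' grid that pads the data range by at least 4 bandwidths.
#'
#' @param model a [KdeModel-class] fitted with a grid.
#' @return The numeric integral estimate.
#' @export
gridIntegral <- function(model) {
  stopifnot(is(model, "KdeModel"))
  if (!length(model@gridSpec)) stop("model has no grid")
  sum(model@gridDensity) * .cellVolume(model@gridSpec)
}

# Accept a d-vector or m x d matrix; always return an m x d matrix.
.asRowMatrix <- function(x, d) {
  if (is.null(dim(x))) {
    if (length(x) != d)
      stop("dimension mismatch: expected ", d, " coordinates")
    x <- matrix(x, nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != d)
      stop("dimension mismatch: expected ", d, " columns")
  }
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("evaluation points must be finite")
  x
}

#' Serialize a KdeModel to JSON
#'
#' Writes bandwidth, level, threshold and grid specification (and optionally
#' the training points) for reproducibility records.
#'
#' @param model a [KdeModel-class].
#' @param path file to write; if NULL the JSON string is returned.
#' @param includePoints include the training points (default FALSE).
#' @return The JSON string, invisibly when written to a file.
#' @export
kdeToJson <- function(model, path = NULL, includePoints = FALSE) {
  stopifnot(is(model, "KdeModel"))
  obj <- list(
    d = ncol(model@points), n = nrow(model@points),
    bandwidth = model@bandwidth, level = model@level,
    threshold = model@threshold,
    gridSpec = model@gridSpec)
  if (includePoints) obj$points <- model@points
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
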