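test_that("bias and mismatch handle the canonical configurations", {
  # hybrid at the midpoint: bias 0, direction none
  pb <- parentalBias(c(0, 0), c(-1, 0), c(1, 0))
  expect_equal(pb$bias, 0)
  expect_equal(pb$direction, "none")
  # hybrid at a parental mean: bias = half the inter-parental distance
  pb1 <- parentalBias(c(-1, 0), c(-1, 0), c(1, 0))
  expect_equal(pb1$bias, 1)
  expect_equal(pb1$direction, "toward_P1")
  # axis-aligned 2-D: parents (0,0), (2,0), hybrid (1,1)
  expect_equal(phenotypicMismatch(c(1, 1), c(0, 0), c(2, 0)), 1)
  expect_equal(parentalBias(c(1, 1), c(0, 0), c(2, 0))$bias, 0)
  # any point on the parental line has zero mismatch
  expect_equal(phenotypicMismatch(c(5, 0), c(0, 0), c(2, 0)), 0)
  expect_error(parentalBias(c(1, 1), c(1, 2), c(1, 2)), "undefined axis")
})

test_that("Pythagoras decomposition and brute-force minimisation agree", {
  set.seed(15)
  for (i in 1:300) {
    d <- sample(2:3, 1)
    p1 <- rnorm(d); p2 <- rnorm(d)
    if (sqrt(sum((p2 - p1)^2)) < 1e-3) next
    h <- rnorm(d, sd = 2)
    geo <- hybridGeometry(h, p1, p2)
    mid <- (p1 + p2) / 2
    # exact decomposition
    expect_lt(abs(geo@parentalBias^2 + geo@phenotypicMismatch^2 -
                    sum((h - mid)^2)), 1e-9)
    # bias via 1-D minimisation along the axis line
    u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    tStar <- optimize(function(t) sum((h - (mid + t * u))^2),
                      c(-100, 100), tol = 1e-12)$minimum
    expect_lt(abs(geo@parentalBias - abs(tStar)), 1e-4)
    # mismatch = distance from the line at the optimum
    expect_lt(abs(geo@phenotypicMismatch -
                    sqrt(sum((h - (mid + tStar * u))^2))), 1e-6)
  }
})

test_that("mismatch equals the fine-grid minimum distance to the line", {
  set.seed(16)
  for (i in 1:50) {
    d <- sample(2:3, 1)
    p1 <- rnorm(d); p2 <- p1 + rnorm(d)
    h <- rnorm(d, sd = 2)
    if (sqrt(sum((p2 - p1)^2)) < 0.1) next
    u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    mid <- (p1 + p2) / 2
    ts <- seq(-50, 50, length.out = 200001)
    dists <- sqrt(colSums((outer(u, ts) + mid - h)^2))
    expect_equal(phenotypicMismatch(h, p1, p2), min(dists),
                 tolerance = 1e-6)
  }
})

test_that("geometry is invariant under rigid motions and equivariant to scale", {
  set.seed(17)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  for (i in 1:25) {
    p1 <- rnorm(2); p2 <- p1 + rnorm(2) + 0.5; h <- rnorm(2)
    g0 <- hybridGeometry(h, p1, p2)
    shift <- rnorm(2)
    g1 <- hybridGeometry(as.numeric(R %*% h) + shift,
                         as.numeric(R %*% p1) + shift,
                         as.numeric(R %*% p2) + shift)
    expect_equal(g1@parentalBias, g0@parentalBias, tolerance = 1e-9)
    expect_equal(g1@phenotypicMismatch, g0@phenotypicMismatch,
                 tolerance = 1e-9)
    g2 <- hybridGeometry(3 * h, 3 * p1, 3 * p2)
    expect_equal(g2@parentalBias, 3 * g0@parentalBias, tolerance = 1e-9)
    expect_equal(g2@phenotypicMismatch, 3 * g0@phenotypicMismatch,
                 tolerance = 1e-9)
    # swapping parent labels flips the direction, not the magnitudes
    g3 <- hybridGeometry(h, p2, p1)
    expect_equal(g3@parentalBias, g0@parentalBias, tolerance = 1e-12)
    expect_equal(g3@phenotypicMismatch, g0@phenotypicMismatch,
                 tolerance = 1e-12)
    if (g0@biasDirection != "none")
      expect_equal(g3@biasDirection,
                   setNames(c("toward_P2", "toward_P1"),
                            c("toward_P1", "toward_P2"))[[g0@biasDirection]])
  }
})
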