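test_that("bandwidth selection is deterministic, scale-equivariant and sane", {
  set.seed(8)
  x <- matrix(rnorm(160), ncol = 2)
  h1 <- selectBandwidth(x)
  expect_identical(h1, selectBandwidth(x))
  # scaling an axis by k scales its bandwidth by k
  k <- c(3.5, 0.4)
  h2 <- selectBandwidth(sweep(x, 2, k, "*"))
  expect_equal(unname(h2), unname(h1 * k), tolerance = 1e-9)

  # 1-D standard normal, n = 500: within a factor 2 of the reference rule
  set.seed(9)
  z <- matrix(rnorm(500), ncol = 1)
  h <- selectBandwidth(z)
  ref <- 1.06 * sd(z) * 500^(-1 / 5)
  expect_gt(h, ref / 2)
  expect_lt(h, ref * 2)

  expect_error(selectBandwidth(matrix(1, 10, 2)), "zero variance")
  expect_error(selectBandwidth(matrix(rnorm(4), 2, 2)), "insufficient")
})

test_that("fitted density equals the brute-force kernel sum", {
  set.seed(10)
  p <- matrix(rnorm(120, sd = c(1, 2)), ncol = 2, byrow = TRUE)
  m <- fitKde(p, computeGrid = FALSE)
  x <- matrix(rnorm(200, sd = 2), ncol = 2)
  expect_lt(max(abs(densityAt(m, x) -
                      oracleKernelDensity(p, kdeBandwidth(m), x))), 1e-12)
  expect_error(densityAt(m, c(1, 2, 3)), "dimension mismatch")
})

test_that("single-kernel and symmetric configurations behave exactly", {
  # one training point: mode at the point, grid integral ~ 1
  m1 <- fitKde(matrix(c(0.3, -0.2), 1, 2), bandwidth = c(0.5, 0.5),
               gridPoints = 101)
  expect_equal(gridIntegral(m1), 1, tolerance = 0.02)
  expect_equal(densityAt(m1, c(0.3, -0.2)), 1 / (2 * pi * 0.25))
  expect_true(all(densityAt(m1, matrix(rnorm(20), ncol = 2)) <=
                    densityAt(m1, c(0.3, -0.2))))

  # two symmetric points: density symmetric about the midpoint
  p <- matrix(c(-1, 1, 0, 0), ncol = 2)
  m2 <- fitKde(p, bandwidth = c(0.7, 0.7), computeGrid = FALSE)
  xs <- cbind(seq(0.1, 2, by = 0.1), rnorm(20, sd = 0.3))
  mirror <- cbind(-xs[, 1], xs[, 2])
  expect_lt(max(abs(densityAt(m2, xs) - densityAt(m2, mirror))), 1e-9)
})

test_that("contour threshold is the interpolated training-density quantile", {
  set.seed(11)
  p <- matrix(rnorm(40), ncol = 2)
  m <- fitKde(p, computeGrid = FALSE)
  dens <- densityAt(m, p)
  expect_equal(contourThreshold(m, 0.95), oracleQuantile(dens, 0.05))
  expect_equal(densityThreshold(m), oracleQuantile(dens, 0.05))
  for (lv in c(0.5, 0.8, 0.9))
    expect_equal(contourThreshold(m, lv), oracleQuantile(dens, 1 - lv))
  # in the level -> 1 limit the threshold drops to the minimum training
  # density (every individual inside the region)
  expect_equal(contourThreshold(m, 1 - 1e-9), min(dens), tolerance = 1e-6)
  # equal densities: threshold equals that density
  grid4 <- matrix(c(-1, -1, 1, 1, -1, 1, -1, 1), ncol = 2)
  m4 <- fitKde(grid4, bandwidth = c(1, 1), computeGrid = FALSE)
  expect_equal(densityThreshold(m4), densityAt(m4, grid4)[1])
})

test_that("membership agrees with the threshold definition on training data", {
  set.seed(12)
  for (d in c(2, 3)) {
    n <- 60
    p <- matrix(rnorm(n * d), ncol = d)
    m <- fitKde(p, computeGrid = FALSE)
    frac <- mean(containsPoint(m, p))
    expect_gte(frac, 0.95 - 1 / n)
    expect_lte(frac, 0.95 + 1 / n)
    # sample mean is inside; a far point is outside
    expect_true(containsPoint(m, colMeans(p)))
    expect_false(containsPoint(m, rep(10 * max(abs(p)), d)))
  }
})

test_that("hypervolume behaves like a Riemann superlevel-set measure", {
  set.seed(13)
  p <- matrix(rnorm(400), ncol = 2)
  m <- fitKde(p, gridPoints = 101)
  v1 <- hypervolume(m)
  # grid refinement changes the volume by < 5%
  m2 <- fitKde(p, bandwidth = kdeBandwidth(m), gridPoints = 201)
  expect_lt(abs(hypervolume(m2) - v1) / v1, 0.05)
  # translation invariance
  m3 <- fitKde(sweep(p, 2, c(5, -3), "+"), bandwidth = kdeBandwidth(m),
               gridPoints = 101)
  expect_equal(hypervolume(m3), v1, tolerance = 1e-9)
  # a region holding fewer individuals is smaller
  expect_lte(hypervolume(m, level = 0.5), hypervolume(m, level = 0.95))
  # grid density integrates to ~1 and is nonnegative
  expect_true(all(m@gridDensity >= 0))
  expect_gte(gridIntegral(m), 0.98)
  expect_lte(gridIntegral(m), 1.02)
})

test_that("user grids must cover the data", {
  p <- matrix(rnorm(60), ncol = 2)
  bad <- list(list(min = -0.1, max = 0.1, n = 21),
              list(min = -5, max = 5, n = 21))
  expect_error(fitKde(p, bandwidth = c(0.3, 0.3), gridSpec = bad),
               "coverage")
})

test_that("KDE models serialize to JSON with their reproducibility fields", {
  set.seed(14)
  m <- fitKde(matrix(rnorm(60), ncol = 2), gridPoints = 31)
  js <- jsonlite::fromJSON(kdeToJson(m), simplifyDataFrame = FALSE)
  expect_equal(js$bandwidth, kdeBandwidth(m))
  expect_equal(js$threshold, densityThreshold(m))
  expect_equal(length(js$gridSpec), 2)
})
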