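test_that("actvsum recomputation is the clipped vector magnitude", {
  expect_equal(compute_actvsum(rep(0, 4), rep(0, 4), rep(0, 4)), rep(0, 4))
  expect_equal(compute_actvsum(0.3, 0.4, 0), 0.5)
  expect_equal(compute_actvsum(2, 2, 2), 2)
  expect_error(compute_actvsum(1:3, 1:2, 1:3), class = "fd_size_error")
})

test_that("high-pass filter subtracts the centred rolling mean", {
  expect_equal(highpass(rep(1.2, 10), 2, 4), rep(0, 10))

  ramp <- seq(0, 18, by = 2)
  hp <- highpass(ramp, 2, 4)
  expect_equal(hp[2:9], rep(0, 8))  # symmetric window on a linear ramp

  x <- c(0, 2, 0, 2, 0, 2)
  expect_equal(highpass(x, 2, 4), oracle_highpass(x, 2, 4))

  withr::with_seed(11, {
    for (w in c(4, 6, 10)) {
      y <- rnorm(25)
      expect_equal(highpass(y, 2, w), oracle_highpass(y, 2, w),
                   tolerance = 1e-12)
    }
  })
  expect_error(highpass(1:5, 2, 1), class = "fd_parameter_error")
})

test_that("a second high-pass pass attenuates smooth inputs to < 10%", {
  # smooth fixture: the residual of one pass is nearly annihilated by a
  # second pass, so repeated filtering changes little beyond the first
  t <- seq(0, 240, by = 2)
  x <- sin(2 * pi * t / 60) + 0.3 * cos(2 * pi * t / 90)
  h1 <- highpass(x, 2, 4)
  h2 <- highpass(h1, 2, 4)
  # away from the shrinking-window edges (first/last samples keep their
  # boundary residual by construction)
  interior <- 3:(length(t) - 2)
  expect_lt(max(abs(h2[interior])), 0.1 * max(abs(h1[interior])))
})

test_that("first derivative is the cadence-scaled forward difference", {
  expect_equal(first_derivative(rep(3, 5), 2), rep(0, 4))
  expect_equal(first_derivative(c(0, 2, 6), 2), c(1, 2))
  withr::with_seed(3, {
    x <- rnorm(30)
    d <- first_derivative(x, 2)
    expect_equal(x[1] + cumsum(d * 2), x[-1])  # inverse identity
  })
  expect_error(first_derivative(1, 2), class = "fd_size_error")
})

test_that("make_variant covers exactly the 12 processing combinations", {
  g <- variant_grid()
  expect_equal(nrow(g), 12)
  expect_equal(nrow(unique(g)), 12)

  tr <- make_trace(n = 8, seed = 1)
  raw_y <- make_variant(tr, "raw", "Y")
  expect_identical(raw_y$values, tr$jerk_y)

  d_xyz <- make_variant(tr, "derivative", "XYZ")
  expect_true(is.matrix(d_xyz$values))
  expect_equal(dim(d_xyz$values), c(7, 3))
  expect_equal(d_xyz$values[, 2], first_derivative(tr$jerk_y, tr$cadence))

  hp_x <- make_variant(tr, "highpass", "X")
  expect_length(hp_x$values, 8)

  expect_error(make_variant(tr, "wavelet", "Y"), class = "fd_parameter_error")
  expect_error(make_variant(tr, "raw", "W"), class = "fd_parameter_error")

  # purity: identical inputs give bit-identical outputs
  expect_identical(make_variant(tr, "highpass", "XYZ"),
                   make_variant(tr, "highpass", "XYZ"))
})

test_that("zscore standardizes to mean 0 and sample SD 1", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  withr::with_seed(2, {
    z <- zscore(runif(40))
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
  })
  expect_error(zscore(rep(5, 3)), class = "fd_degenerate_error")
})

test_that("ordered-quantile normalization matches its quantile definition", {
  # n = 3 distinct values map to qnorm(1/6, 3/6, 5/6)
  tr <- normalize_response(c(10, 30, 20))
  expect_equal(sort(tr$scores), qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)

  # odd-length tie-free column: median maps to 0
  x <- c(5, 9, 1, 7, 3)
  expect_equal(normalize_response(x)$scores[x == 5], 0)

  # bijection on the observed support; monotone
  withr::with_seed(8, {
    y <- rlnorm(25)
    tr2 <- normalize_response(y)
    expect_equal(predict(tr2, tr2$scores, inverse = TRUE), y,
                 tolerance = 1e-9)
    expect_equal(order(tr2$scores), order(y))
  })
  expect_error(normalize_response(c(1, 2)), class = "fd_size_error")
})

test_that("orq inverse extrapolates linearly beyond the tails", {
  tr <- normalize_response(c(1, 2, 3, 4, 5))
  zmax <- max(tr$scores)
  inside <- predict(tr, zmax, inverse = TRUE)
  beyond <- predict(tr, zmax + 1, inverse = TRUE)
  slope <- (5 - 4) / (tr$scores[5] - tr$scores[4])
  expect_equal(beyond, inside + slope, tolerance = 1e-10)
})
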