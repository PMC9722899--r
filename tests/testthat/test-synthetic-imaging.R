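test_that("render_shape produces valid, symmetric, positive images", {
  g <- tiny_grid()
  for (shape in c("point", "sphere", "annulus", "ellipse", "crescent")) {
    nu <- quick_render(shape, grid = g)
    expect_true(all(nu > 0))
    expect_equal(dim(nu), c(64L, 64L))
  }
  # a centered point with a symmetric PSF equals its own 180-degree rotation
  pt <- quick_render("point", position = c(31.5, 31.5))
  expect_lt(max(abs(pt - pt[64:1, 64:1])), 1e-12)
  # zero amplitude leaves only the background
  flat <- render_shape(shape_spec("sphere", amplitude = 0), c(31.5, 31.5),
                       0, g)
  expect_equal(max(abs(flat - 100)), 0)
})

test_that("integer shifts of the render match an independent re-render", {
  g <- tiny_grid()
  for (shape in c("sphere", "crescent")) {
    a <- quick_render(shape, position = c(30.3, 31.8), orientation = 0.7)
    b <- quick_render(shape, position = c(31.3, 31.8), orientation = 0.7)
    # b is a translated by (+1, 0): compare interior
    expect_lt(max(abs(b[15:55, 15:55] - a[14:54, 15:55])), 1e-9)
  }
})

test_that("signal mass above background is invariant under sub-pixel shifts", {
  g <- tiny_grid()
  for (shape in c("point", "sphere", "annulus", "ellipse", "crescent")) {
    m0 <- sum(quick_render(shape, position = c(31.5, 31.5)) - 100)
    for (d in list(c(0.25, 0), c(0.5, 0.5), c(-0.33, 0.41))) {
      m1 <- sum(quick_render(shape, position = c(31.5, 31.5) + d) - 100)
      expect_lt(abs(m1 - m0) / m0, 1e-3)
    }
  }
})

test_that("render_shape rejects invalid inputs", {
  g <- tiny_grid()
  expect_error(render_shape(shape_spec("sphere"), c(100, 5), 0, g), "inside")
  expect_error(shape_spec("blob"), "arg")
  expect_error(shape_spec("sphere", radius = -2), "lengths")
  expect_error(render_shape(shape_spec("sphere", radius = 80), c(31, 31), 0, g),
               "larger than the grid")
})

test_that("corrupt_with_noise implements the SNR convention and Poisson model", {
  nu <- quick_render("point", position = c(31.5, 31.5))
  a <- corrupt_with_noise(nu, snr = 10, seed = 42)
  b <- corrupt_with_noise(nu, snr = 10, seed = 42)
  expect_identical(unclass(a), unclass(b))
  # peak of rescaled expected image sits at snr * sqrt(background)
  expected <- attr(a, "expected")
  expect_equal(max(expected) - 100, 10 * sqrt(100), tolerance = 1e-10)
  expect_error(corrupt_with_noise(nu - 200, 10), "positive")

  # Monte-Carlo: sample mean of the peak pixel matches its expectation
  peak_idx <- which.max(expected)
  n <- 1e4
  draws <- with(list(), {
    set.seed(7)
    rpois(n, expected[peak_idx])
  })
  se <- sqrt(expected[peak_idx] / n)
  expect_lt(abs(mean(draws) - expected[peak_idx]), 3 * se)

  # empirical SNR over repeated draws approximates the nominal value
  set.seed(8)
  peaks <- replicate(300, {
    img <- corrupt_with_noise(nu, snr = 10)
    (max(attr(img, "expected")) - 100) / sqrt(100)
  })
  expect_equal(mean(peaks), 10, tolerance = 1e-6)
})

test_that("Poisson sampling has variance equal to the mean per pixel", {
  nu <- quick_render("sphere")
  set.seed(11)
  idx <- sample(length(nu), 20)
  n <- 1e4
  for (i in idx) {
    draws <- rpois(n, nu[i])
    # chi-squared test of variance = mean at the 1% level
    stat <- (n - 1) * var(draws) / nu[i]
    expect_gt(stat, qchisq(0.005, n - 1))
    expect_lt(stat, qchisq(0.995, n - 1))
  }
})

test_that("render_scene composes single renders additively", {
  g <- tiny_grid()
  sp <- shape_spec("sphere")
  # one particle: identical to the single-shape pipeline under the same seed
  tr <- scene_truth(x = 30.2, y = 33.1, orientation = 0.3, grid = g)
  sc <- render_scene(tr, sp, g, snr = 10, seed = 5)
  single <- corrupt_with_noise(render_shape(sp, c(30.2, 33.1), 0.3, g),
                               snr = 10, seed = 5)
  expect_identical(unclass(sc$image), unclass(single))
  expect_identical(sc$truth, tr)

  # two well-separated particles: local patches match single renders
  tr2 <- scene_truth(x = c(16, 48), y = c(16, 48), grid = g)
  sc2 <- render_scene(tr2, sp, g, snr = NULL)
  one <- render_shape(sp, c(16, 16), 0, g)
  expect_lt(max(abs(sc2$image[10:24, 10:24] - one[10:24, 10:24])), 1e-9)

  expect_error(render_scene(tr2[0, ], sp, g), "at least one")
})

test_that("a crowded scene keeps its full truth table inside the grid", {
  g <- grid_spec(256, 256)
  set.seed(3)
  tr <- scene_truth(x = runif(20, 10, 245), y = runif(20, 10, 245),
                    orientation = runif(20, 0, 2 * pi), grid = g)
  sc <- render_scene(tr, shape_spec("sphere"), g, snr = 10, seed = 1)
  expect_equal(nrow(sc$truth), 20L)
  expect_true(all(sc$truth$x >= 0 & sc$truth$x <= 255))
  expect_true(all(sc$truth$y >= 0 & sc$truth$y <= 255))
})
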