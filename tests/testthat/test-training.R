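test_that("sampled transforms cover their ranges and respect seeds", {
  rg0 <- transform_ranges(translation = 0, rotation = FALSE, reflection = FALSE)
  id <- sample_transform(rg0, seed = 1)
  expect_equal(id$t, c(0, 0))
  expect_equal(id$angle, 0)
  expect_false(any(id$flip))

  s1 <- sample_transform(seed = 77)
  s2 <- sample_transform(seed = 77)
  expect_identical(s1, s2)

  set.seed(10)
  draws <- replicate(1e4, {
    s <- sample_transform(transform_ranges())
    c(s$angle, s$t)
  })
  # rotation uniform on [0, 2pi): mean pi; translation uniform on [-8, 8]
  expect_lt(abs(mean(draws[1, ]) - pi), 3 * (2 * pi / sqrt(12)) / 100)
  expect_lt(abs(mean(draws[2, ])), 3 * (16 / sqrt(12)) / 100)
})

test_that("transform_image warps exactly for identity and symmetric cases", {
  img <- matrix(quick_render("sphere", position = c(31.5, 31.5)), 64, 64)
  id <- lodestar:::identity_transform()
  expect_equal(transform_image(img, id), img)

  # rotating a 180-degree symmetric disk by pi about the center is a no-op
  spec <- lodestar:::identity_transform()
  spec$angle <- pi
  rot <- transform_image(img, spec)
  expect_lt(max(abs(rot - img)) / max(img), 1e-3)
})

test_that("translations move the image content by the requested amount", {
  img <- unclass(quick_render("point", position = c(31.5, 31.5)))
  spec <- lodestar:::identity_transform()
  spec$t <- c(3.5, -2.25)
  out <- transform_image(img, spec)
  # locate the peak by quadratic interpolation around the maximum
  subpix_peak <- function(m) {
    idx <- which.max(m)
    i <- (idx - 1) %% nrow(m) + 1; j <- (idx - 1) %/% nrow(m) + 1
    di <- 0.5 * (m[i + 1, j] - m[i - 1, j]) /
      (2 * m[i, j] - m[i + 1, j] - m[i - 1, j])
    dj <- 0.5 * (m[i, j + 1] - m[i, j - 1]) /
      (2 * m[i, j] - m[i, j + 1] - m[i, j - 1])
    c(i - 1 + di, j - 1 + dj)
  }
  p0 <- subpix_peak(img)
  p1 <- subpix_peak(out)
  expect_lt(max(abs((p1 - p0) - spec$t)), 0.1)
})

test_that("invert_prediction undoes its transform exactly", {
  for (seed in 1:5) {
    spec <- sample_transform(seed = seed)
    p <- c(25.3, 40.1)
    moved <- lodestar:::transform_point(p, spec, c(64, 64))
    pred <- tibble::tibble(x = moved[1], y = moved[2])
    back <- invert_prediction(pred, spec, dim_in = c(64, 64))
    expect_equal(c(back$x, back$y), p, tolerance = 1e-10)
  }
  # extra channels subtract their sampled offsets
  spec <- lodestar:::identity_transform()
  spec$dz <- 1.5
  pred <- tibble::tibble(x = 1, y = 1, z = 2.0)
  expect_equal(invert_prediction(pred, spec, dim_in = c(64, 64))$z, 0.5)
  spec$lns <- 0.3
  pred$log_scale <- 1.0
  expect_equal(invert_prediction(pred, spec, dim_in = c(64, 64))$log_scale, 0.7)
})

test_that("loss functions match hand evaluation", {
  # identical predictions: zero consistency loss
  same <- matrix(5, nrow = 4, ncol = 2)
  expect_equal(consistency_loss(same), 0)
  # K = 2, values {0, 2}: |0-1| + |2-1| = 2
  expect_equal(consistency_loss(matrix(c(0, 2), 2, 1)), 2)
  # permutation invariance
  set.seed(6)
  m <- matrix(rnorm(12), 4, 3)
  expect_equal(consistency_loss(m), consistency_loss(m[c(3, 1, 4, 2), ]))

  # internal loss vanishes when every pixel predicts the same position
  # (the offset channels cancel the pixel-index ramp)
  arr <- array(0, c(8, 8, 3))
  arr[, , 1] <- -matrix((0:7) * 2, 8, 8)
  arr[, , 2] <- -matrix((0:7) * 2, 8, 8, byrow = TRUE)
  st <- lodestar:::new_feature_stack(arr, network_config(channels = 4L),
                                     c(16L, 16L))
  w <- matrix(1 / 64, 8, 8)
  pooled <- pooled_prediction(st, weights = w)
  expect_equal(internal_loss(st, pooled, w), 0)

  # weight concentrated on one pixel: only that deviation counts
  w1 <- matrix(0, 8, 8); w1[2, 7] <- 1
  pooled1 <- tibble::tibble(x = 0, y = 0)
  maps <- lodestar:::property_maps(st)
  expect_equal(internal_loss(st, pooled1, w1),
               abs(maps$x[2, 7]) + abs(maps$y[2, 7]))

  # random maps: brute-force double sum
  set.seed(9)
  arr2 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  st2 <- lodestar:::new_feature_stack(arr2, network_config(channels = 4L),
                                      c(16L, 16L))
  w2 <- train_weights(st2, seed = 4)
  pooled2 <- pooled_prediction(st2, weights = w2)
  maps2 <- lodestar:::property_maps(st2)
  brute <- sum(abs(maps2$x - pooled2$x) * w2) + sum(abs(maps2$y - pooled2$y) * w2)
  expect_equal(internal_loss(st2, pooled2, w2), brute, tolerance = 1e-10)
})

test_that("a perfectly equivariant hand-built predictor has zero batch loss", {
  # oracle: the true position of a rendered point transforms exactly with
  # the sampled group element, so inverted predictions agree across views
  pos <- c(30.7, 33.2)
  preds <- t(vapply(1:6, function(s) {
    spec <- sample_transform(seed = s)
    moved <- lodestar:::transform_point(pos, spec, c(64, 64))
    inv <- invert_prediction(tibble::tibble(x = moved[1], y = moved[2]),
                             spec, dim_in = c(64, 64))
    c(inv$x, inv$y)
  }, numeric(2)))
  expect_lt(consistency_loss(preds), 1e-9)
})

test_that("training runs deterministically and zero steps change nothing", {
  img <- unclass(corrupt_with_noise(quick_render("point"), 10, seed = 1))
  cfg_net <- network_config(channels = 4L, n_pre = 2L, n_post = 2L)
  net <- build_network(cfg_net, seed = 2)
  fit0 <- train_lodestar(img, net, train_config(steps = 0L), seed = 1)
  expect_identical(fit0$network$layers, net$layers)

  tc <- train_config(steps = 3L)
  fit1 <- train_lodestar(img, net, tc, seed = 5)
  fit2 <- train_lodestar(img, net, tc, seed = 5)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$network$layers, fit2$network$layers)
  expect_false(identical(fit1$network$layers, net$layers))
  expect_true(all(is.finite(fit1$history$loss)))
})

test_that("training rejects incompatible symmetry configurations", {
  img <- unclass(quick_render("point"))
  net <- build_network(network_config(channels = 4L, n_pre = 2L, n_post = 2L))
  expect_error(
    train_lodestar(img, net,
                   train_config(ranges = transform_ranges(dz_range = 1))),
    "z")
  expect_error(
    train_lodestar(img, net, train_config(crop = 200L)),
    "even|crop")
})
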